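# evaluate `code` under a fixed RNG seed, restoring global RNG state after
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

#' Generate a random annotated circular genome
#'
#' Background sequence is i.i.d. at the requested GC; genes are placed
#' without overlap, separated by spacers of at least 1 bp, and named
#' `gene001`, `gene002`, ... Output is deterministic for a fixed seed.
#'
#' @param length genome size in bp.
#' @param n_genes number of CDS features to place.
#' @param mean_gene_len mean gene length in bp (lengths are drawn around
#'   this with 20 percent spread).
#' @param gc requested GC fraction in (0, 1).
#' @param seed integer RNG seed.
#' @param keep_clear optional data frame of intervals (`start`, `end`,
#'   0-based half-open) where no gene may be placed — used to reserve
#'   room for planted repeats.
#' @return an [annotated_genome()].
#' @export
generate_genome <- function(length, n_genes, mean_gene_len = 1000,
                            gc = 0.45, seed = 1, keep_clear = NULL) {
  stopifnot(gc > 0, gc < 1, n_genes >= 0)
  if (length < n_genes * mean_gene_len) {
    stop("infeasible packing: length < n_genes * mean_gene_len")
  }
  with_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    seqstr <- paste(bases, collapse = "")
    feats <- empty_features()
    if (n_genes > 0L) {
      glens <- pmax(60L, as.integer(round(
        stats::rnorm(n_genes, mean_gene_len, 0.2 * mean_gene_len))))
      # free segments = genome minus reserved windows
      segs <- free_segments(length, keep_clear)
      feats <- place_genes(glens, segs)
    }
    annotated_genome("synthetic", seqstr, topology = "circular",
                     features = feats)
  })
}

free_segments <- function(len, keep_clear) {
  if (is.null(keep_clear) || nrow(keep_clear) == 0L) {
    return(data.frame(start = 0L, end = len))
  }
  kc <- keep_clear[order(keep_clear$start), , drop = FALSE]
  if (any(kc$end > len)) stop("keep_clear interval beyond genome length")
  starts <- c(0L, kc$end)
  ends <- c(kc$start, len)
  out <- data.frame(start = starts, end = ends)
  out[out$end > out$start, , drop = FALSE]
}

place_genes <- function(glens, segs) {
  n <- length(glens)
  seg_len <- segs$end - segs$start
  # proportional allocation of gene counts to segments
  alloc <- floor(n * seg_len / sum(seg_len))
  while (sum(alloc) < n) {
    i <- which.max(seg_len - alloc * mean(glens))
    alloc[i] <- alloc[i] + 1L
  }
  rows <- list(); gi <- 0L
  for (s in seq_len(nrow(segs))) {
    ns <- alloc[s]
    if (ns == 0L) next
    lens <- glens[(gi + 1L):(gi + ns)]
    slack <- seg_len[s] - sum(lens) - (ns + 1L)
    if (slack < 0L) stop("infeasible packing: reserved windows too dense")
    u <- diff(c(0, sort(stats::runif(ns)), 1))
    gaps <- 1L + floor(u * slack)
    pos <- segs$start[s]
    for (j in seq_len(ns)) {
      pos <- pos + gaps[j]
      rows[[length(rows) + 1L]] <- data.frame(
        name = "", start = pos, end = pos + lens[j],
        strand = sample(c("+", "-"), 1L), kind = "CDS",
        stringsAsFactors = FALSE)
      pos <- pos + lens[j]
      gi <- gi + 1L
    }
  }
  f <- do.call(rbind, rows)
  f <- f[order(f$start), , drop = FALSE]
  f$name <- sprintf("gene%03d", seq_len(nrow(f)))
  rownames(f) <- NULL
  f
}

#' Construct a repeat-pair record
#'
#' @param label pair label (e.g. `"R1"`).
#' @param start1,end1,start2,end2 0-based half-open copy coordinates;
#'   copy 1 must precede copy 2.
#' @param orientation `"direct"` or `"inverted"`.
#' @param length aligned span in bp.
#' @param mismatch_positions 1-based alignment columns that mismatch.
#' @return one-row data frame (class `repeat_pair` rows are plain rows;
#'   `identity = (length - n_mismatches) / length`).
#' @export
repeat_pair <- function(label, start1, end1, start2, end2, orientation,
                        length, mismatch_positions = integer()) {
  stopifnot(orientation %in% c("direct", "inverted"))
  if (start1 > start2) {
    tmp <- c(start1, end1); start1 <- start2; end1 <- end2
    start2 <- tmp[1]; end2 <- tmp[2]
  }
  nm <- base::length(mismatch_positions)
  data.frame(label = label, start1 = start1, end1 = end1,
             start2 = start2, end2 = end2, orientation = orientation,
             length = length,
             n_mismatches = nm,
             identity = (length - nm) / length,
             mismatch_positions = I(list(as.integer(mismatch_positions))),
             stringsAsFactors = FALSE)
}

#' Plant a repeat pair into a genome
#'
#' The sequence already present at `loc1` becomes copy 1; copy 2 is
#' written at `loc2` as copy 1 (reverse-complemented when inverted) with
#' exactly `mismatches` substituted alignment columns. Mismatch columns
#' are interior (never the first or last column) and re-sampled until at
#' least one clean window of `min_seed_gap` bp survives, so that the pair
#' is discoverable at the default seed length. The single base just
#' outside each end of the pair is forced to mismatch its aligned
#' partner, making the planted pair maximal by construction — otherwise
#' its ground-truth length would be ill-defined.
#'
#' @param genome an [annotated_genome()].
#' @param length repeat length in bp.
#' @param mismatches number of substituted alignment columns
#'   (`< length`).
#' @param orientation `"direct"` or `"inverted"`.
#' @param loc1,loc2 0-based start positions of the two copies (disjoint,
#'   no wrap, inside intergenic space unless `allow_gene_overlap`).
#' @param seed optional RNG seed.
#' @param label pair label recorded in the returned truth.
#' @param allow_gene_overlap permit copies to overlap gene features.
#' @param min_seed_gap minimum guaranteed clean stretch between
#'   mismatches, in bp.
#' @return `list(genome = modified genome, pair = repeat-pair record)`.
#' @export
plant_repeat_pair <- function(genome, length, mismatches,
                              orientation = c("direct", "inverted"),
                              loc1, loc2, seed = NULL, label = "R",
                              allow_gene_overlap = FALSE,
                              min_seed_gap = 21L) {
  orientation <- match.arg(orientation)
  len <- genome_length(genome)
  L <- as.integer(length)
  stopifnot(mismatches < L, L >= 1L)
  a1 <- as.integer(loc1); a2 <- as.integer(loc2)
  if (a1 > a2) { tmp <- a1; a1 <- a2; a2 <- tmp }
  b1 <- a1 + L; b2 <- a2 + L
  if (a1 < 1L || b2 > len - 1L) {
    stop("copies (with 1 bp flanks) must lie inside [1, length-1)")
  }
  if (b1 > a2) stop("repeat copies must be disjoint")
  if (!allow_gene_overlap) {
    f <- genome$features
    g <- f[f$kind %in% genic_kinds(), , drop = FALSE]
    if (nrow(g) > 0L) {
      hit <- (g$start < b1 & g$end > a1) | (g$start < b2 & g$end > a2)
      if (any(hit)) {
        stop("repeat copy overlaps gene feature(s) ",
             paste(g$name[hit], collapse = ", "),
             "; set allow_gene_overlap = TRUE to override")
      }
    }
  }
  with_seed(seed, {
    s <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
    copy1 <- s[(a1 + 1L):b1]
    cols <- integer(0)
    if (mismatches > 0L) {
      # mismatch columns stay a seed-length clear of both pair ends: a
      # near-terminal mismatch would leave the true repeat boundary
      # ambiguous (competing trimmings with near-equal identity)
      margin <- min(min_seed_gap + 4L, max(1L, (L - mismatches) %/% 4L))
      lo <- margin + 1L; hi <- L - margin
      if (hi - lo + 1L < mismatches) stop("too many mismatches for interior columns")
      repeat {
        cols <- sort(sample(lo:hi, mismatches))
        if (max(diff(c(0L, cols, L + 1L))) - 1L >= min_seed_gap) break
      }
    }
    copy2_aln <- copy1
    for (j in cols) {
      copy2_aln[j] <- sample(setdiff(c("A", "C", "G", "T"), copy1[j]), 1L)
    }
    copy2 <- if (orientation == "inverted") {
      rev(unname(comp_base[copy2_aln]))
    } else copy2_aln
    s[(a2 + 1L):b2] <- copy2
    # force the alignment column just outside each end to mismatch
    if (orientation == "direct") {
      if (s[a2] == s[a1]) s[a2] <- sample(setdiff(c("A","C","G","T"), s[a1]), 1L)
      if (s[b2 + 1L] == s[b1 + 1L]) {
        s[b2 + 1L] <- sample(setdiff(c("A","C","G","T"), s[b1 + 1L]), 1L)
      }
    } else {
      if (s[b2 + 1L] == comp_base[[s[a1]]]) {
        s[b2 + 1L] <- sample(setdiff(c("A","C","G","T"), comp_base[[s[a1]]]), 1L)
      }
      if (s[a2] == comp_base[[s[b1 + 1L]]]) {
        s[a2] <- sample(setdiff(c("A","C","G","T"), comp_base[[s[b1 + 1L]]]), 1L)
      }
    }
    genome$sequence <- paste(s, collapse = "")
    list(genome = genome,
         pair = repeat_pair(label, a1, b1, a2, b2, orientation, L, cols))
  })
}

# map a 0-based half-open interval through an inversion of [m1, m2);
# errors if the interval straddles a breakpoint
map_interval_through_inversion <- function(start, end, m1, m2) {
  if (end <= m1 || start >= m2) {
    return(list(start = start, end = end, flipped = FALSE))
  }
  if (start >= m1 && end <= m2) {
    return(list(start = m1 + m2 - end, end = m1 + m2 - start,
                flipped = TRUE))
  }
  stop("interval [", start, ",", end, ") straddles an inversion breakpoint")
}

#' Apply a repeat-mediated inversion to a genome
#'
#' Models homologous recombination between the two copies of an
#' inverted-orientation repeat pair: the segment between the copy
#' midpoints is reverse-complemented in place. Features inside the
#' segment flip strand and order. Recombination between direct-orientation
#' copies excises the intervening segment (a deletion) rather than
#' inverting it, and is rejected.
#'
#' @param genome an [annotated_genome()].
#' @param pair a repeat-pair record (e.g. from [plant_repeat_pair()])
#'   with `orientation == "inverted"` and both copies of equal length.
#' @return `list(genome = rearranged genome, event = list(breakpoints,
#'   mediating_repeat))`.
#' @export
apply_planted_inversion <- function(genome, pair) {
  if (pair$orientation != "inverted") {
    stop("recombination between direct-orientation copies deletes the ",
         "intervening segment instead of inverting it; only ",
         "inverted-orientation pairs mediate inversions")
  }
  # crossover at the copy midpoint; the breakpoint in copy 2 sits at the
  # aligned column of copy 1's breakpoint, so both hybrid copies occupy
  # exactly the original intervals whatever the parity of the length
  t <- (pair$end1 - pair$start1) %/% 2L
  m1 <- pair$start1 + t
  m2 <- pair$end2 - t
  stopifnot(m1 < m2)
  len <- genome_length(genome)
  s <- genome$sequence
  genome$sequence <- paste0(
    substr(s, 1L, m1),
    revcomp(substr(s, m1 + 1L, m2)),
    substr(s, m2 + 1L, len))
  f <- genome$features
  if (nrow(f) > 0L) {
    for (r in seq_len(nrow(f))) {
      mp <- map_interval_through_inversion(f$start[r], f$end[r], m1, m2)
      if (mp$flipped) {
        f$start[r] <- mp$start; f$end[r] <- mp$end
        f$strand[r] <- if (f$strand[r] == "+") "-" else "+"
      }
    }
    genome$features <- validate_features(f, len)
  }
  list(genome = genome,
       event = list(breakpoints = c(m1, m2),
                    mediating_repeat = pair$label))
}

# propagate a set of repeat-pair coordinate records through a sequence
# inversion of [m1, m2)
map_pairs_through_inversion <- function(pairs, m1, m2) {
  for (r in seq_len(nrow(pairs))) {
    s1 <- pairs$start1[r]; e1 <- pairs$end1[r]
    s2 <- pairs$start2[r]; e2 <- pairs$end2[r]
    # the mediating pair itself: breakpoints at the copy midpoints split
    # both copies symmetrically and the hybrid copies occupy the same
    # intervals with relative orientation preserved
    if (s1 < m1 && m1 < e1 && s2 < m2 && m2 < e2 &&
        m1 - s1 == e2 - m2 && e1 - m1 == m2 - s2) {
      next
    }
    c1 <- map_interval_through_inversion(s1, e1, m1, m2)
    c2 <- map_interval_through_inversion(s2, e2, m1, m2)
    if (xor(c1$flipped, c2$flipped)) {
      pairs$orientation[r] <- if (pairs$orientation[r] == "direct") {
        "inverted"
      } else "direct"
    }
    if (c1$start <= c2$start) {
      pairs$start1[r] <- c1$start; pairs$end1[r] <- c1$end
      pairs$start2[r] <- c2$start; pairs$end2[r] <- c2$end
    } else {
      pairs$start1[r] <- c2$start; pairs$end1[r] <- c2$end
      pairs$start2[r] <- c1$start; pairs$end2[r] <- c1$end
    }
  }
  pairs
}

#' Build the two-inversion study case with full ground truth
#'
#' Constructs an ancestral circular genome of `length` bp partitioned
#' into five gene regions A–E, plants an inverted-orientation 566-bp pair
#' (R1, 13 mismatches) at the B|C and D|E junctions, a direct-orientation
#' 435-bp pair (R2, 18 mismatches) at the A|B and C|D junctions, and
#' eight decoy pairs (107–380 bp) inside region interiors, for ten pairs
#' in all. Two successive repeat-mediated inversions are then applied:
#' first within R1 (inverting blocks C–D, giving block order
#' 1, 2, -4, -3, 5), then within R2 (giving the observed order
#' 1, 4, -2, -3, 5). The returned truth records the planted pairs in
#' ancestral and observed coordinates, the applied two-event scenario,
#' the expected signed block permutation and the block-level repeat
#' placements of the ancestral configuration.
#'
#' @param seed integer RNG seed; the whole construction is deterministic
#'   given the seed.
#' @param length genome size in bp (default 160 kb, mitogenome scale).
#' @return `list(ancestral, observed, truth)`.
#' @export
make_paper_case <- function(seed = 1, length = 160000L) {
  len <- as.integer(length)
  stopifnot(len >= 40000L)
  u <- len / 160000
  sc <- function(x) as.integer(round(x * u))
  j <- sc(c(32000, 64000, 96000, 128000))   # region junctions A|B..D|E
  r1_len <- 566L; r2_len <- 435L
  r1_starts <- c(j[2] - r1_len %/% 2L, j[4] - r1_len %/% 2L)
  r2_starts <- c(j[1] - r2_len %/% 2L, j[3] - r2_len %/% 2L)
  decoys <- data.frame(
    label = paste0("D", 1:8),
    length = c(107L, 150L, 180L, 210L, 250L, 280L, 320L, 380L),
    mismatches = c(2L, 3L, 4L, 4L, 5L, 6L, 7L, 9L),
    orientation = rep(c("direct", "inverted"), 4),
    loc1 = sc(c(8000, 40000, 72000, 104000, 136000, 12000, 44000, 20000)),
    loc2 = sc(c(16000, 48000, 80000, 112000, 144000, 150000, 76000, 56000)),
    stringsAsFactors = FALSE
  )
  margin <- 120L
  jwin <- max(sc(800), r1_len %/% 2L + margin)  # junction clearance
  kc <- rbind(
    data.frame(start = j - jwin, end = j + jwin),
    data.frame(start = c(decoys$loc1, decoys$loc2) - margin,
               end = c(decoys$loc1, decoys$loc2) +
                 rep(decoys$length, 2) + margin)
  )
  g <- generate_genome(len, n_genes = 70L, mean_gene_len = sc(1200),
                       gc = 0.447, seed = seed, keep_clear = kc)
  g$id <- "ancestral"
  pairs <- NULL
  plant <- function(gnm, length, mism, orient, l1, l2, lab, sd) {
    res <- plant_repeat_pair(gnm, length, mism, orient, l1, l2,
                             seed = sd, label = lab)
    pairs <<- rbind(pairs, res$pair)
    res$genome
  }
  g <- plant(g, r1_len, 13L, "inverted", r1_starts[1], r1_starts[2],
             "R1", seed + 101L)
  g <- plant(g, r2_len, 18L, "direct", r2_starts[1], r2_starts[2],
             "R2", seed + 102L)
  for (i in seq_len(nrow(decoys))) {
    g <- plant(g, decoys$length[i], decoys$mismatches[i],
               decoys$orientation[i], decoys$loc1[i], decoys$loc2[i],
               decoys$label[i], seed + 200L + i)
  }
  ancestral <- g
  planted_ancestral <- pairs

  # event 1: recombination within R1 inverts blocks C-D
  e1 <- apply_planted_inversion(g, pairs[pairs$label == "R1", ])
  pairs <- map_pairs_through_inversion(pairs, e1$event$breakpoints[1],
                                       e1$event$breakpoints[2])
  # event 2: recombination within R2 (now inverted) inverts blocks B,-D
  e2 <- apply_planted_inversion(e1$genome, pairs[pairs$label == "R2", ])
  pairs <- map_pairs_through_inversion(pairs, e2$event$breakpoints[1],
                                       e2$event$breakpoints[2])
  observed <- e2$genome
  observed$id <- "observed"

  truth <- list(
    planted_repeats = planted_ancestral,
    observed_repeats = pairs,
    applied_scenario = list(
      source = 1:5,
      target = c(1L, 4L, -2L, -3L, 5L),
      events = list(
        list(segment = c(3L, 4L), mediating_repeat = "R1",
             breakpoints = e1$event$breakpoints),
        list(segment = c(2L, 3L), mediating_repeat = "R2",
             breakpoints = e2$event$breakpoints)
      )
    ),
    expected_blocks = c(1L, 4L, -2L, -3L, 5L),
    placements = data.frame(
      label = c("R1", "R2"),
      left_junction = c(2L, 1L),
      right_junction = c(4L, 3L),
      relative_orientation = c("inverted", "direct"),
      stringsAsFactors = FALSE
    ),
    seed = seed,
    parameters = list(length = len, n_genes = 70L, gc = 0.447,
                      junctions = j, r1_len = r1_len, r2_len = r2_len,
                      r2_pre_event_placement = paste(
                        "R2 planted in direct orientation at the A|B and",
                        "C|D junctions; the first event flips its second",
                        "copy, enabling the second event"))
  )
  list(ancestral = ancestral, observed = observed, truth = truth)
}

#' Write a synthetic case to disk (FASTA + GFF3 + truth JSON)
#'
#' @param case output of [make_paper_case()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_synthetic_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    ancestral_fa = file.path(dir, "ancestral.fasta"),
    ancestral_gff = file.path(dir, "ancestral.gff3"),
    observed_fa = file.path(dir, "observed.fasta"),
    observed_gff = file.path(dir, "observed.gff3"),
    truth = file.path(dir, "truth.json")
  )
  write_fasta(case$ancestral, paths[["ancestral_fa"]])
  write_gff3(case$ancestral, paths[["ancestral_gff"]])
  write_fasta(case$observed, paths[["observed_fa"]])
  write_gff3(case$observed, paths[["observed_gff"]])
  truth <- case$truth
  truth$planted_repeats$mismatch_positions <- NULL
  truth$observed_repeats$mismatch_positions <- NULL
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
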