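#' Percent identity of a gapless repeat pair
#'
#' Matches over aligned length after reverse-complementing the second
#' copy when the pair is inverted. Alignment columns containing IUPAC
#' ambiguity codes count as mismatches.
#'
#' @param copy1_seq,copy2_seq equal-length DNA strings (gapless model).
#' @param orientation `"direct"` or `"inverted"`.
#' @return fraction in \[0, 1\].
#' @export
pair_identity <- function(copy1_seq, copy2_seq,
                          orientation = c("direct", "inverted")) {
  orientation <- match.arg(orientation)
  if (nchar(copy1_seq) != nchar(copy2_seq)) {
    stop("gapless identity requires equal-length copies")
  }
  if (orientation == "inverted") copy2_seq <- revcomp(copy2_seq)
  a <- strsplit(toupper(copy1_seq), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(copy2_seq), "", fixed = TRUE)[[1]]
  acgt <- c("A", "C", "G", "T")
  sum(a == b & a %in% acgt & b %in% acgt) / length(a)
}

# modular 1-based index into a character vector of length n
midx <- function(i, n) ((i - 1L) %% n) + 1L

# gapless extension to one side from a seed, by increasing offset e =
# 0, 1, ... where is_match(e) says whether the next column matches.
# Scoring: match +1, mismatch -penalty; stop once the running score
# drops `xdrop` below its maximum; return the number of columns in the
# maximum-score prefix (ties broken towards shorter).
extend_side <- function(is_match, penalty, xdrop, cap) {
  best <- 0; best_e <- 0L; score <- 0
  e <- 0L
  while (e < cap) {
    score <- score + (if (is_match(e)) 1 else -penalty)
    e <- e + 1L
    if (score > best) { best <- score; best_e <- e }
    if (best - score > xdrop) break
  }
  best_e
}

#' Find large repeat pairs within a genome
#'
#' Gapless seed-and-extend: all exact k-mers of the genome (and, for
#' inverted pairs, of its reverse complement; circular genomes are
#' indexed across the origin) are matched, and each non-self match is
#' extended in both directions with match score +1 and mismatch penalty
#' `min_identity / (1 - min_identity)`, trimming to the maximum-score
#' span (which always ends on matching columns). Pairs shorter than
#' `min_len` or below `min_identity`, self matches, and pairs whose
#' copies overlap by 50 percent or more are dropped; pairs contained in a
#' longer pair on the same diagonal are deduplicated. Results are sorted
#' by length (descending), then copy-1 start, and labelled R1, R2, ...
#'
#' @param genome an [annotated_genome()] (or plain DNA string).
#' @param min_len minimum reported pair length, bp.
#' @param min_identity minimum gapless identity in \[0, 1).
#' @param k exact seed length, `k <= min_len`.
#' @return data frame with columns `label`, `start1`, `end1`, `start2`,
#'   `end2` (0-based half-open; `end` may exceed the genome length for a
#'   copy wrapping the origin), `orientation`, `length`, `n_mismatches`,
#'   `identity`, `identity_pct` (rounded half-up to one decimal) and a
#'   `mismatch_positions` list column of 1-based alignment columns.
#' @export
find_repeat_pairs <- function(genome, min_len = 100L, min_identity = 0.90,
                              k = 21L) {
  if (k > min_len) stop("seed length k must not exceed min_len")
  if (min_identity < 0 || min_identity >= 1) {
    if (min_identity != 1) stop("min_identity must be in [0, 1]")
  }
  seqstr <- if (is(genome, "annotated_genome")) genome$sequence else toupper(genome)
  circular <- !is(genome, "annotated_genome") ||
    genome$topology == "circular"
  n <- nchar(seqstr)
  if (n < k || n <= min_len) return(empty_repeat_table())
  s <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  rs <- rev(unname(comp_base[s]))
  rs[is.na(rs)] <- "N"   # ambiguity codes never match anyway
  npos <- if (circular) n else n - k + 1L
  pad <- function(x) if (circular) paste0(paste(x, collapse = ""),
                                          paste(x[seq_len(k - 1L)],
                                                collapse = "")) else
                                            paste(x, collapse = "")
  kmf <- substring(pad(s), seq_len(npos), seq_len(npos) + k - 1L)
  kmr <- substring(pad(rs), seq_len(npos), seq_len(npos) + k - 1L)

  seeds <- list()
  # direct seeds: duplicated forward k-mers
  dupk <- unique(kmf[duplicated(kmf)])
  dupk <- dupk[!grepl("[^ACGT]", dupk)]
  if (length(dupk) > 0L) {
    pos <- which(kmf %in% dupk)
    grp <- split(pos, kmf[pos])
    for (g in grp) {
      if (length(g) > 50L) next   # low-complexity guard
      cmb <- utils::combn(g, 2L)
      seeds[[length(seeds) + 1L]] <- data.frame(
        p1 = cmb[1, ] - 1L, p2 = cmb[2, ] - 1L, orientation = "direct")
    }
  }
  # inverted seeds: forward k-mers present on the reverse-complement strand
  common <- intersect(kmf, kmr)
  common <- common[!grepl("[^ACGT]", common)]
  if (length(common) > 0L) {
    pf <- which(kmf %in% common)
    pr <- which(kmr %in% common)
    gf <- split(pf, kmf[pf]); gr <- split(pr, kmr[pr])
    for (key in names(gf)) {
      f <- gf[[key]]; r <- gr[[key]]
      if (length(f) * length(r) > 100L) next
      for (i in f) for (jj in r) {
        # 0-based forward start of the k-mer occurrence on the rc strand
        q <- (n - (jj - 1L) - k) %% n
        a <- i - 1L; b <- q
        if (a == b) next                      # palindromic self-match
        seeds[[length(seeds) + 1L]] <- data.frame(
          p1 = min(a, b), p2 = max(a, b), orientation = "inverted")
      }
    }
  }
  if (length(seeds) == 0L) return(empty_repeat_table())
  seeds <- unique(do.call(rbind, seeds))
  # one extension per (orientation, diagonal) cluster
  diag <- ifelse(seeds$orientation == "direct",
                 (seeds$p2 - seeds$p1) %% n,
                 (seeds$p1 + seeds$p2) %% n)
  key <- paste(seeds$orientation, diag)
  reps <- lapply(split(seq_len(nrow(seeds)), key), function(idx) {
    sub <- seeds[idx, , drop = FALSE]
    # extension recovers the full pair from any seed of a cluster, but
    # distant clusters on one diagonal need separate extensions
    sub <- sub[order(sub$p1), , drop = FALSE]
    pick <- c(TRUE, diff(sub$p1) > 4L * min_len)
    lapply(which(pick), function(i) {
      extend_seed(s, rs, n, sub$p1[i], sub$p2[i], sub$orientation[i],
                  k, min_identity, circular)
    })
  })
  pairs <- do.call(rbind, unlist(reps, recursive = FALSE))
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty_repeat_table())
  pairs <- pairs[pairs$length >= min_len & pairs$identity >= min_identity, ,
                 drop = FALSE]
  if (nrow(pairs) == 0L) return(empty_repeat_table())
  # drop heavily overlapping copies (palindrome-like)
  ov <- pmax(0L, pmin(pairs$end1, pairs$end2) -
               pmax(pairs$start1, pairs$start2))
  pairs <- pairs[ov < 0.5 * pairs$length, , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty_repeat_table())
  # dedupe identical / contained pairs
  pairs <- pairs[order(-pairs$length, -pairs$identity, pairs$start1), ,
                 drop = FALSE]
  keep <- rep(TRUE, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (!keep[i]) next
    if (i < nrow(pairs)) {
      for (jj in (i + 1L):nrow(pairs)) {
        if (!keep[jj]) next
        if (pairs$orientation[jj] == pairs$orientation[i] &&
            pairs$start1[jj] >= pairs$start1[i] &&
            pairs$end1[jj] <= pairs$end1[i] &&
            pairs$start2[jj] >= pairs$start2[i] &&
            pairs$end2[jj] <= pairs$end2[i]) {
          keep[jj] <- FALSE
        }
      }
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  pairs$label <- paste0("R", seq_len(nrow(pairs)))
  pairs$identity_pct <- round_half_up(100 * pairs$identity, 1)
  rownames(pairs) <- NULL
  pairs[c("label", "start1", "end1", "start2", "end2", "orientation",
          "length", "n_mismatches", "identity", "identity_pct",
          "mismatch_positions")]
}

empty_repeat_table <- function() {
  data.frame(label = character(), start1 = integer(), end1 = integer(),
             start2 = integer(), end2 = integer(),
             orientation = character(), length = integer(),
             n_mismatches = integer(), identity = numeric(),
             identity_pct = numeric(),
             mismatch_positions = I(list()),
             stringsAsFactors = FALSE)
}

# extend a single k-mer seed (0-based starts p1, p2) gaplessly in both
# directions; returns a one-row pair data frame
extend_seed <- function(s, rs, n, p1, p2, orientation, k, min_identity,
                        circular) {
  penalty <- if (min_identity >= 1) Inf else
    max(1, min_identity / (1 - min_identity))
  xdrop <- if (is.finite(penalty)) 10 * penalty + 10 else 0
  cap <- min(20000L, n)
  at <- function(p) s[midx(p + 1L, n)]
  if (!circular) {
    at <- function(p) if (p < 0L || p >= n) "!" else s[p + 1L]
  }
  if (orientation == "direct") {
    er <- extend_side(function(e) {
      x <- at(p1 + k + e); y <- at(p2 + k + e)
      x == y && x %in% c("A", "C", "G", "T")
    }, penalty, xdrop, cap)
    el <- extend_side(function(e) {
      x <- at(p1 - 1L - e); y <- at(p2 - 1L - e)
      x == y && x %in% c("A", "C", "G", "T")
    }, penalty, xdrop, cap)
    a1 <- p1 - el; b1 <- p1 + k + er
    a2 <- p2 - el; b2 <- p2 + k + er
    len <- b1 - a1
    m1 <- vapply(0:(len - 1L), function(e) at(a1 + e), "")
    m2 <- vapply(0:(len - 1L), function(e) at(a2 + e), "")
    mism <- which(!(m1 == m2 & m1 %in% c("A", "C", "G", "T")))
  } else {
    # inverted: seed occupies copy1 [p1, p1+k) and copy2 [p2, p2+k);
    # alignment column j (0-based from copy1 left end) pairs copy1 base
    # a1+j with the complement of copy2 base b2-1-j
    er <- extend_side(function(e) {
      x <- at(p1 + k + e); y <- at(p2 - 1L - e)
      !is.na(comp_base[y]) && x == comp_base[[y]] &&
        x %in% c("A", "C", "G", "T")
    }, penalty, xdrop, cap)
    el <- extend_side(function(e) {
      x <- at(p1 - 1L - e); y <- at(p2 + k + e)
      !is.na(comp_base[y]) && x == comp_base[[y]] &&
        x %in% c("A", "C", "G", "T")
    }, penalty, xdrop, cap)
    a1 <- p1 - el; b1 <- p1 + k + er
    a2 <- p2 - er; b2 <- p2 + k + el
    len <- b1 - a1
    m1 <- vapply(0:(len - 1L), function(e) at(a1 + e), "")
    m2 <- vapply(0:(len - 1L), function(e) at(b2 - 1L - e), "")
    m2 <- unname(comp_base[m2]); m2[is.na(m2)] <- "!"
    mism <- which(!(m1 == m2 & m1 %in% c("A", "C", "G", "T")))
  }
  # canonical interval normalization: starts in [0, n)
  norm <- function(a, b) { a2 <- a %% n; c(a2, a2 + (b - a)) }
  c1 <- norm(a1, b1); c2 <- norm(a2, b2)
  if (c1[1] > c2[1]) { tmp <- c1; c1 <- c2; c2 <- tmp }
  data.frame(start1 = c1[1], end1 = c1[2], start2 = c2[1], end2 = c2[2],
             orientation = orientation, length = len,
             n_mismatches = length(mism),
             identity = (len - length(mism)) / len,
             mismatch_positions = I(list(as.integer(mism))),
             stringsAsFactors = FALSE)
}

#' Survey large repeat pairs across several genomes
#'
#' Runs [find_repeat_pairs()] on each genome at the given thresholds and
#' localizes every copy against the genome's annotations ("within
#' \emph{geneX}" or "between \emph{geneX} and \emph{geneY}"). Pairs are
#' grouped across genomes by their shared flanking-feature context and
#' the groups labelled S1, S2, ... in order of prevalence, so that the
#' same physical pair carries one label in every genome that has it.
#'
#' @param genomes list of annotated genomes.
#' @param min_len minimum pair length, bp.
#' @param min_identity minimum gapless identity.
#' @param k seed length.
#' @return data frame: `genome_id`, `label`, copy coordinates,
#'   `orientation`, `length`, `identity_pct`, `copy1_context`,
#'   `copy2_context`.
#' @export
cross_genome_repeat_survey <- function(genomes, min_len = 400L,
                                       min_identity = 0.90, k = 21L) {
  rows <- lapply(genomes, function(g) {
    pr <- find_repeat_pairs(g, min_len = min_len,
                            min_identity = min_identity, k = k)
    if (nrow(pr) == 0L) return(NULL)
    if (nrow(g$features) == 0L) {
      warning("genome '", g$id, "' is unannotated; reporting coordinates only")
      ctx1 <- sprintf("%d-%d", pr$start1, pr$end1)
      ctx2 <- sprintf("%d-%d", pr$start2, pr$end2)
    } else {
      ctx1 <- vapply(seq_len(nrow(pr)), function(i)
        locate_context(g, pr$start1[i], pr$end1[i]), "")
      ctx2 <- vapply(seq_len(nrow(pr)), function(i)
        locate_context(g, pr$start2[i], pr$end2[i]), "")
    }
    data.frame(genome_id = g$id, start1 = pr$start1, end1 = pr$end1,
               start2 = pr$start2, end2 = pr$end2,
               orientation = pr$orientation, length = pr$length,
               identity_pct = pr$identity_pct,
               copy1_context = ctx1, copy2_context = ctx2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(genome_id = character(), label = character(),
                      start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      orientation = character(), length = integer(),
                      identity_pct = numeric(),
                      copy1_context = character(),
                      copy2_context = character(),
                      stringsAsFactors = FALSE))
  }
  ctxkey <- apply(cbind(out$copy1_context, out$copy2_context), 1,
                  function(x) paste(sort(x), collapse = " // "))
  freq <- sort(table(ctxkey), decreasing = TRUE)
  labels <- setNames(paste0("S", seq_along(freq)), names(freq))
  out$label <- unname(labels[ctxkey])
  out <- out[order(out$label, out$genome_id), ]
  rownames(out) <- NULL
  out[c("genome_id", "label", "start1", "end1", "start2", "end2",
        "orientation", "length", "identity_pct", "copy1_context",
        "copy2_context")]
}

# human-readable location of an interval relative to annotations
locate_context <- function(genome, start, end) {
  f <- genome$features
  f <- f[f$kind %in% genic_kinds(), , drop = FALSE]
  if (nrow(f) == 0L) return(sprintf("%d-%d", start, end))
  inside <- f$start <= start & f$end >= end
  if (any(inside)) return(paste0("within ", f$name[which(inside)[1]]))
  ov <- f$start < end & f$end > start
  if (any(ov)) return(paste0("overlapping ", f$name[which(ov)[1]]))
  prev <- f[f$end <= start, , drop = FALSE]
  nxt <- f[f$start >= end, , drop = FALSE]
  pn <- if (nrow(prev) > 0L) prev$name[nrow(prev)] else f$name[nrow(f)]
  nn <- if (nrow(nxt) > 0L) nxt$name[1] else f$name[1]
  paste0("between ", pn, " and ", nn)
}

#' Write a repeat-pair table as TSV
#' @param pairs output of [find_repeat_pairs()].
#' @param path output TSV.
#' @param genome optional genome for annotation context columns.
#' @export
write_repeats_tsv <- function(pairs, path, genome = NULL) {
  out <- pairs[setdiff(names(pairs), "mismatch_positions")]
  if (!is.null(genome) && nrow(out) > 0L) {
    out$copy1_context <- vapply(seq_len(nrow(out)), function(i)
      locate_context(genome, out$start1[i], out$end1[i]), "")
    out$copy2_context <- vapply(seq_len(nrow(out)), function(i)
      locate_context(genome, out$start2[i], out$end2[i]), "")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
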