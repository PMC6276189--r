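#' Find unique exact anchor matches between two genomes
#'
#' Anchors are maximal runs of `min_anchor_len`-mers that occur exactly
#' once in each genome (counting both strands) and agree on one diagonal.
#' Because uniqueness is required, k-mers inside large repeat copies
#' never seed anchors — repeats are excluded from the collinear-block
#' skeleton automatically, which is load-bearing for junction analysis.
#' Circular genomes are treated as linearized at their origin; use
#' [rotate()] first if the origin of either genome falls inside a region
#' of interest.
#'
#' @param genomeA,genomeB annotated genomes (A is the reference).
#' @param min_anchor_len minimum anchor length, bp.
#' @return data frame sorted by `posA`: `posA`, `posB` (0-based starts),
#'   `length`, `strand` (`"same"`/`"opposite"`).
#' @export
find_anchors <- function(genomeA, genomeB, min_anchor_len = 25L) {
  k <- as.integer(min_anchor_len)
  sA <- if (is(genomeA, "annotated_genome")) genomeA$sequence else toupper(genomeA)
  sB <- if (is(genomeB, "annotated_genome")) genomeB$sequence else toupper(genomeB)
  la <- nchar(sA); lb <- nchar(sB)
  if (la < k || lb < k) return(empty_anchor_table())
  kmers <- function(x, n) substring(x, seq_len(n - k + 1L), seq(k, n))
  kmA <- kmers(sA, la); kmArc <- kmers(revcomp(sA), la)
  kmB <- kmers(sB, lb); kmBrc <- kmers(revcomp(sB), lb)
  countA <- table_counts(c(kmA, kmArc))
  countB <- table_counts(c(kmB, kmBrc))
  uniqA <- countA[kmA] == 1L
  cb <- countB[kmA]; cb[is.na(cb)] <- 0L
  cand <- which(uniqA & cb == 1L)
  if (length(cand) == 0L) return(empty_anchor_table())
  mF <- match(kmA[cand], kmB)
  mR <- match(kmA[cand], kmBrc)
  same <- !is.na(mF)
  opp <- !is.na(mR) & !same
  rows <- list()
  if (any(same)) {
    rows[[1]] <- data.frame(posA = cand[same] - 1L, posB = mF[same] - 1L,
                            strand = "same")
  }
  if (any(opp)) {
    rows[[length(rows) + 1L]] <- data.frame(
      posA = cand[opp] - 1L,
      posB = lb - (mR[opp] - 1L) - k,   # forward start of the rc occurrence
      strand = "opposite")
  }
  sd <- do.call(rbind, rows)
  # merge runs of consecutive k-mers on one diagonal into maximal anchors
  sd$diag <- ifelse(sd$strand == "same", sd$posB - sd$posA,
                    sd$posA + sd$posB)
  sd <- sd[order(sd$strand, sd$diag, sd$posA), ]
  new_run <- c(TRUE, diff(sd$posA) != 1L |
                 sd$diag[-1] != sd$diag[-nrow(sd)] |
                 sd$strand[-1] != sd$strand[-nrow(sd)])
  run_id <- cumsum(new_run)
  first <- !duplicated(run_id)
  run_len <- as.integer(table(run_id))
  anchors <- data.frame(
    posA = sd$posA[first],
    posB = NA_integer_,
    length = k + run_len - 1L,
    strand = sd$strand[first],
    stringsAsFactors = FALSE
  )
  # B start: first element for same strand, last for opposite
  lastB <- sd$posB[cumsum(run_len)]
  anchors$posB <- ifelse(anchors$strand == "same", sd$posB[first], lastB)
  anchors <- anchors[order(anchors$posA), ]
  rownames(anchors) <- NULL
  anchors
}

table_counts <- function(x) {
  t <- table(x)
  setNames(as.integer(t), names(t))
}

empty_anchor_table <- function() {
  data.frame(posA = integer(), posB = integer(), length = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Chain anchors into locally collinear blocks
#'
#' Greedy chaining over anchors sorted by reference position:
#' consecutive anchors join one chain iff they share the relative
#' strand, both coordinate gaps are at most `max_gap`, and the B
#' coordinate is monotone in the strand-consistent direction (increasing
#' for same strand, decreasing for opposite). Chains spanning less than
#' `min_block` bp in either genome are discarded; survivors are labelled
#' A, B, C, ... in reference order, with block boundaries at the
#' outermost anchor endpoints.
#'
#' @param anchors output of [find_anchors()].
#' @param max_gap maximum within-chain coordinate gap, bp.
#' @param min_block minimum block span, bp.
#' @return data frame: `label`, `startA`, `endA`, `startB`, `endB`
#'   (0-based half-open), `sign` (+1 same strand, -1 opposite),
#'   `n_anchors`.
#' @export
chain_anchors <- function(anchors, max_gap = 5000L, min_block = 1000L) {
  if (nrow(anchors) == 0L) return(empty_block_table())
  a <- anchors[order(anchors$posA), ]
  slop <- max(a$length)            # tolerated anchor overlap
  chain_id <- integer(nrow(a)); chain_id[1] <- 1L
  for (i in seq_len(nrow(a))[-1]) {
    p <- i - 1L
    gapA <- a$posA[i] - (a$posA[p] + a$length[p])
    ok <- a$strand[i] == a$strand[p] && gapA <= max_gap && gapA >= -slop
    if (ok) {
      if (a$strand[i] == "same") {
        gapB <- a$posB[i] - (a$posB[p] + a$length[p])
      } else {
        gapB <- a$posB[p] - (a$posB[i] + a$length[i])
      }
      ok <- gapB <= max_gap && gapB >= -slop
    }
    chain_id[i] <- if (ok) chain_id[p] else chain_id[p] + 1L
  }
  blocks <- lapply(split(seq_len(nrow(a)), chain_id), function(idx) {
    ch <- a[idx, ]
    data.frame(startA = min(ch$posA), endA = max(ch$posA + ch$length),
               startB = min(ch$posB), endB = max(ch$posB + ch$length),
               sign = if (ch$strand[1] == "same") 1L else -1L,
               n_anchors = nrow(ch))
  })
  b <- do.call(rbind, blocks)
  b <- b[(b$endA - b$startA) >= min_block &
           (b$endB - b$startB) >= min_block, , drop = FALSE]
  if (nrow(b) == 0L) return(empty_block_table())
  b <- b[order(b$startA), ]
  b$label <- make_block_labels(nrow(b))
  rownames(b) <- NULL
  b[c("label", "startA", "endA", "startB", "endB", "sign", "n_anchors")]
}

make_block_labels <- function(n) {
  if (n <= 26L) LETTERS[seq_len(n)] else
    paste0("B", sprintf("%02d", seq_len(n)))
}

empty_block_table <- function() {
  data.frame(label = character(), startA = integer(), endA = integer(),
             startB = integer(), endB = integer(), sign = integer(),
             n_anchors = integer(), stringsAsFactors = FALSE)
}

#' Signed block permutation of the observed genome
#'
#' Blocks (labelled in reference order) are re-sorted by their position
#' in genome B; each contributes its reference rank, signed by relative
#' orientation. Identical genomes give the identity permutation.
#'
#' @param blocks output of [chain_anchors()].
#' @return integer vector; a signed permutation of 1..n.
#' @export
blocks_to_permutation <- function(blocks) {
  n <- nrow(blocks)
  if (n == 0L) return(integer(0))
  b <- blocks[order(blocks$startA), ]
  b$rank <- seq_len(n)
  ordB <- order(b$startB)
  sorted <- b[ordB, ]
  if (n > 1L) {
    ov <- sorted$startB[-1] < sorted$endB[-n] - 100L
    if (any(ov)) {
      stop("blocks overlap in genome B — chaining produced inconsistent ",
           "intervals")
    }
  }
  as.integer(sorted$sign * sorted$rank)
}

#' Associate repeat copies with block junctions
#'
#' For each junction between blocks adjacent in the observed genome,
#' reports every repeat copy overlapping the inter-block gap or lying
#' within `window` bp of it, and whether the junction falls in
#' intergenic space.
#'
#' @param blocks output of [chain_anchors()].
#' @param repeats output of [find_repeat_pairs()] on the observed genome.
#' @param window association distance, bp.
#' @param genome the observed [annotated_genome()] (for the intergenic
#'   flag; optional).
#' @return data frame with one row per junction-copy association (or a
#'   single `repeat_label = NA` row for an unassociated junction):
#'   `junction_index` (1..n-1, position in observed block order),
#'   `junction` (label pair), `gap_start`, `gap_end`, `repeat_label`,
#'   `copy`, `distance`, `intergenic`.
#' @export
junction_repeat_association <- function(blocks, repeats, window = 100L,
                                        genome = NULL) {
  n <- nrow(blocks)
  if (n < 2L) {
    return(data.frame(junction_index = integer(), junction = character(),
                      gap_start = integer(), gap_end = integer(),
                      repeat_label = character(), copy = integer(),
                      distance = integer(), intergenic = logical(),
                      stringsAsFactors = FALSE))
  }
  b <- blocks[order(blocks$startB), ]
  inter <- if (!is.null(genome)) intergenic_intervals(genome) else NULL
  len <- if (!is.null(genome)) genome_length(genome) else NA_integer_
  copies <- if (nrow(repeats) > 0L) {
    rbind(
      data.frame(label = repeats$label, copy = 1L,
                 start = repeats$start1, end = repeats$end1),
      data.frame(label = repeats$label, copy = 2L,
                 start = repeats$start2, end = repeats$end2))
  } else NULL
  rows <- list()
  for (p in seq_len(n - 1L)) {
    gs <- b$endB[p]; ge <- b$startB[p + 1L]
    if (ge < gs) { tmp <- gs; gs <- ge; ge <- tmp }
    jlab <- paste0(b$label[p], "-", b$label[p + 1L])
    mid <- (gs + ge) %/% 2L
    ig <- NA
    if (!is.null(inter)) {
      m <- mid %% len
      ig <- any((inter$start <= m & inter$end > m) |
                  (inter$end > len & m < (inter$end - len)))
    }
    hit <- NULL
    if (!is.null(copies)) {
      d <- pmax(0L, pmax(gs - copies$end, copies$start - ge))
      hit <- which(d <= window)
    }
    if (length(hit) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        junction_index = p, junction = jlab, gap_start = gs, gap_end = ge,
        repeat_label = NA_character_, copy = NA_integer_,
        distance = NA_integer_, intergenic = ig,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        junction_index = p, junction = jlab, gap_start = gs, gap_end = ge,
        repeat_label = copies$label[hit], copy = copies$copy[hit],
        distance = d[hit], intergenic = ig,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a block table as TSV
#' @param blocks output of [chain_anchors()].
#' @param path output TSV.
#' @export
write_blocks_tsv <- function(blocks, path) {
  write.table(blocks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
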