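validate_signed_perm <- function(perm) {
  if (length(perm) == 0L) stop("empty permutation")
  if (!setequal(abs(perm), seq_along(perm))) {
    stop("absolute values must be a permutation of 1..n")
  }
  as.integer(perm)
}

#' Apply an inversion to a signed permutation
#'
#' Elements `i..j` (1-based, inclusive) are reversed and their signs
#' flipped — the block-order image of reversing a genomic segment.
#'
#' @param perm signed permutation (integer vector).
#' @param i,j segment bounds, `1 <= i <= j <= length(perm)`.
#' @export
apply_inversion <- function(perm, i, j) {
  n <- length(perm)
  if (i < 1L || j > n || i > j) stop("inversion indices out of range")
  perm[i:j] <- -rev(perm[i:j])
  perm
}

perm_key <- function(perm) paste(perm, collapse = ",")

all_inversions <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Minimal number of inversions between two signed permutations
#'
#' Breadth-first search over all inversions (sorting signed permutations
#' by reversals). The state space is guarded to `n <= 10`; the search
#' stops at `max_depth` and returns `NA_integer_` (never a truncated
#' count) when the target is not reached within it.
#'
#' @param source,target signed permutations of equal length over the
#'   same absolute values.
#' @param max_depth search depth bound.
#' @return minimal inversion count, or `NA_integer_` if not found within
#'   `max_depth`.
#' @export
inversion_distance_bfs <- function(source, target, max_depth = 6L) {
  source <- validate_signed_perm(source)
  target <- validate_signed_perm(target)
  if (length(source) != length(target)) stop("length mismatch")
  n <- length(source)
  if (n > 10L) stop("state-space guard: n must be <= 10")
  if (identical(source, target)) return(0L)
  moves <- all_inversions(n)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(perm_key(source), TRUE, envir = visited)
  frontier <- list(source)
  tkey <- perm_key(target)
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (p in frontier) {
      for (m in seq_len(nrow(moves))) {
        q <- apply_inversion(p, moves[m, 1], moves[m, 2])
        key <- perm_key(q)
        if (key == tkey) return(depth)
        if (!exists(key, envir = visited, inherits = FALSE)) {
          assign(key, TRUE, envir = visited)
          nxt[[length(nxt) + 1L]] <- q
        }
      }
    }
    frontier <- nxt
    if (length(frontier) == 0L) break
  }
  NA_integer_
}

#' Construct a repeat placement record
#'
#' A placement puts one copy of a repeat pair at block junction
#' `left_junction` and the other at `right_junction` (junction `h` lies
#' between block-order positions `h` and `h + 1`; 0 and `n` are the
#' outer ends). An inversion of blocks `i..j` is mediated by a pair with
#' copies at junctions `i - 1` and `j` in inverted relative orientation.
#'
#' @param label repeat label.
#' @param left_junction,right_junction junction indices,
#'   `0 <= left < right <= n`.
#' @param relative_orientation `"direct"` or `"inverted"`.
#' @export
repeat_placement <- function(label, left_junction, right_junction,
                             relative_orientation) {
  stopifnot(left_junction < right_junction,
            relative_orientation %in% c("direct", "inverted"))
  data.frame(label = label, left_junction = as.integer(left_junction),
             right_junction = as.integer(right_junction),
             relative_orientation = relative_orientation,
             stringsAsFactors = FALSE)
}

#' Propagate repeat placements through an inversion event
#'
#' Junction indices strictly inside the inverted span are reflected
#' (`h -> i - 1 + j - h`); the boundary junctions `i - 1` and `j` — where
#' the recombination breakpoints lie — keep their index. A pair's
#' relative orientation flips iff exactly one of its copies lies
#' strictly inside the span.
#'
#' @param placements data frame of [repeat_placement()] rows.
#' @param event list with `segment = c(i, j)`.
#' @param n number of blocks.
#' @export
track_repeats_through_event <- function(placements, event, n) {
  i <- event$segment[1]; j <- event$segment[2]
  if (i < 1L || j > n || i > j) stop("event segment invalid for n blocks")
  reflect <- function(h) {
    if (h > i - 1L && h < j) i - 1L + j - h else h
  }
  for (r in seq_len(nrow(placements))) {
    l <- placements$left_junction[r]; rt <- placements$right_junction[r]
    inside <- sum(c(l, rt) > i - 1L & c(l, rt) < j)
    l2 <- reflect(l); r2 <- reflect(rt)
    placements$left_junction[r] <- min(l2, r2)
    placements$right_junction[r] <- max(l2, r2)
    if (inside == 1L) {
      placements$relative_orientation[r] <-
        if (placements$relative_orientation[r] == "direct") "inverted"
      else "direct"
    }
  }
  placements
}

#' Find minimal repeat-mediated inversion scenarios
#'
#' Depth-bounded search in which an inversion of blocks `i..j` is
#' allowed only while some repeat pair has one copy at junction `i - 1`
#' and the other at junction `j` in inverted relative orientation at
#' that moment (the homologous-recombination constraint). Placements are
#' propagated through every applied event with
#' [track_repeats_through_event()]. All scenarios of minimal length are
#' returned, sorted lexicographically by their event segments; each is
#' verified to replay `source` into `target` on construction.
#'
#' @param source,target signed permutations; `placements` describe the
#'   `source` configuration.
#' @param placements data frame of [repeat_placement()] rows.
#' @param max_events scenario length bound.
#' @return list of scenarios (possibly empty), each a list with
#'   `events` (each event: `segment`, `mediating_repeat`), `source`,
#'   `target` and `intermediates` (block orders after each event).
#' @export
find_repeat_mediated_scenarios <- function(source, target, placements,
                                           max_events = 4L) {
  source <- validate_signed_perm(source)
  target <- validate_signed_perm(target)
  if (length(source) != length(target)) stop("length mismatch")
  n <- length(source)
  if (n > 10L) stop("state-space guard: n must be <= 10")
  found <- list()
  search <- function(perm, pl, path, depth_left) {
    if (identical(perm, target)) {
      found[[length(found) + 1L]] <<- path
      return(invisible())
    }
    if (depth_left == 0L) return(invisible())
    if (nrow(pl) == 0L) return(invisible())
    inv <- pl[pl$relative_orientation == "inverted", , drop = FALSE]
    for (r in seq_len(nrow(inv))) {
      i <- inv$left_junction[r] + 1L
      j <- inv$right_junction[r]
      if (i < 1L || j > n || i > j) next
      ev <- list(segment = c(i, j), mediating_repeat = inv$label[r])
      q <- apply_inversion(perm, i, j)
      pl2 <- track_repeats_through_event(pl, ev, n)
      search(q, pl2, c(path, list(ev)), depth_left - 1L)
    }
    invisible()
  }
  for (d in 0:max_events) {
    found <- list()
    search(source, placements, list(), d)
    found <- Filter(function(p) length(p) == d, found)
    if (length(found) > 0L) break
  }
  if (length(found) == 0L) return(list())
  # sort lexicographically by event segments, drop duplicates
  keys <- vapply(found, function(p)
    paste(vapply(p, function(e)
      paste(e$segment[1], e$segment[2], e$mediating_repeat, sep = ","), ""),
      collapse = ";"), "")
  found <- found[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  found <- found[order(keys)]
  lapply(found, function(events) {
    perm <- source
    inter <- list()
    for (e in events) {
      perm <- apply_inversion(perm, e$segment[1], e$segment[2])
      inter[[length(inter) + 1L]] <- perm
    }
    stopifnot(identical(perm, target))   # replay invariant
    list(events = events, source = source, target = target,
         intermediates = inter)
  })
}

#' Parse signed permutations from text
#'
#' One permutation per line, signed integers separated by commas.
#' @param path file path.
#' @return list of integer vectors.
#' @export
read_permutations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l)
    validate_signed_perm(as.integer(strsplit(trimws(l), "[,\\s]+")[[1]])))
}

#' Write signed permutations as text
#' @param perms list of integer vectors (or a single vector).
#' @param path file path.
#' @export
write_permutations <- function(perms, path) {
  if (!is.list(perms)) perms <- list(perms)
  writeLines(vapply(perms, perm_key, ""), path)
  invisible(path)
}
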