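# Shared fixtures and independent brute-force oracles for the test suite.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

rand_dna <- function(n, seed = NULL, gc = 0.5) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                 prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                          (1 - gc) / 2)), collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

rc_chars <- function(v) rev(unname(COMP[v]))

# memoized study-case fixture shared across test files (the 160 kb
# construction plus anchoring is the expensive part of the suite)
.fixture_cache <- new.env(parent = emptyenv())
paper_case_fixture <- function(seed = 1) {
  key <- paste0("case", seed)
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, make_paper_case(seed = seed), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}
paper_report_fixture <- function(seed = 1) {
  key <- paste0("report", seed)
  if (!exists(key, envir = .fixture_cache)) {
    case <- paper_case_fixture(seed)
    assign(key, compare_genomes(case$ancestral, case$observed),
           envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# brute-force enumeration of maximal exact repeat pairs of a LINEAR
# sequence via full diagonal/anti-diagonal scans (oracle for the
# seed-and-extend finder at min_identity = 1)
bf_exact_repeats <- function(seqstr, min_len) {
  s <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  n <- length(s)
  comp <- unname(COMP[s])
  rows <- list()
  # direct: offset d, match vector between s[i] and s[i+d]
  for (d in seq_len(n - min_len)) {
    m <- s[seq_len(n - d)] == s[seq_len(n - d) + d]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values & r$lengths >= min_len)) {
      p1 <- starts[i] - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        start1 = p1, end1 = p1 + r$lengths[i],
        start2 = p1 + d, end2 = p1 + d + r$lengths[i],
        orientation = "direct", length = r$lengths[i])
    }
  }
  # inverted: anti-diagonal c = p + q (0-based), match iff
  # s[p] == comp(s[q]); keep runs entirely on the p < q side
  for (c in seq(2L * min_len - 1L, 2L * n - 3L)) {
    p <- max(0L, c - n + 1L):min(n - 1L, c)
    m <- s[p + 1L] == comp[(c - p) + 1L]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values & r$lengths >= min_len)) {
      pr <- p[starts[i]:ends[i]]
      pr <- pr[2L * pr < c]          # p < q half only (mirror dropped)
      if (length(pr) < min_len) next
      a1 <- min(pr); b1 <- max(pr) + 1L
      b2 <- c - a1 + 1L; a2 <- c - max(pr)
      rows[[length(rows) + 1L]] <- data.frame(
        start1 = a1, end1 = b1, start2 = a2, end2 = b2,
        orientation = "inverted", length = b1 - a1)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      orientation = character(), length = integer()))
  }
  out <- unique(do.call(rbind, rows))
  # drop pairs contained in a longer pair (same maximality rule)
  out <- out[order(-out$length), ]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    jj <- which(keep & seq_len(nrow(out)) > i)
    for (j2 in jj) {
      if (out$orientation[j2] == out$orientation[i] &&
          out$start1[j2] >= out$start1[i] && out$end1[j2] <= out$end1[i] &&
          out$start2[j2] >= out$start2[i] && out$end2[j2] <= out$end2[i]) {
        keep[j2] <- FALSE
      }
    }
  }
  out <- out[keep, ]
  rownames(out) <- NULL
  out[order(out$start1, out$start2), ]
}

# count occurrences of a substring on both strands (anchor uniqueness
# oracle)
bf_substring_count <- function(seqstr, sub) {
  cnt <- function(hay, needle) {
    hits <- gregexpr(needle, hay, fixed = TRUE)[[1]]
    if (hits[1] == -1L) 0L else length(hits)
  }
  rc <- paste(rc_chars(strsplit(sub, "", fixed = TRUE)[[1]]), collapse = "")
  cnt(seqstr, sub) + cnt(seqstr, rc)
}

# signed-permutation reversal distance through igraph (independent of
# the package's BFS): explicit state graph + shortest path
signed_perms <- function(n) {
  base <- combinat_perms(seq_len(n))
  out <- list()
  signs <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
  for (p in base) for (r in seq_len(nrow(signs))) {
    out[[length(out) + 1L]] <- p * signs[r, ]
  }
  out
}

combinat_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

igraph_reversal_distance <- function(source, target) {
  n <- length(source)
  states <- signed_perms(n)
  keys <- vapply(states, paste, "", collapse = ",")
  idx <- seq_along(states)
  names(idx) <- keys
  edges <- integer(0)
  for (si in idx) {
    p <- states[[si]]
    for (i in seq_len(n)) for (j in i:n) {
      q <- p
      q[i:j] <- -rev(q[i:j])
      ti <- idx[[paste(q, collapse = ",")]]
      if (ti > si) edges <- c(edges, si, ti)
    }
  }
  g <- igraph::make_graph(edges, n = length(states), directed = FALSE)
  d <- igraph::distances(g, v = idx[[paste(source, collapse = ",")]],
                         to = idx[[paste(target, collapse = ",")]])
  as.integer(d[1, 1])
}

# brute-force inverse of a signed permutation
bf_invert_perm <- function(p) {
  q <- integer(length(p))
  for (i in seq_along(p)) q[abs(p[i])] <- sign(p[i]) * i
  q
}

# standard-code codon translation used as a test-side oracle
bf_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# build a query CDS carrying k planted C<->U edits against a random
# reference protein, with the exact expected site list as truth
random_editing_fixture <- function(n_codons = 100, k = 5) {
  code <- Biostrings::GENETIC_CODE
  aas <- setdiff(unique(code), "*")
  by_aa <- split(names(code), unname(code))
  ref_aa <- sample(aas, n_codons, replace = TRUE)
  ref_aa[1] <- "M"
  codons <- vapply(ref_aa, function(a) sample(by_aa[[a]], 1), "")
  query <- codons
  truth <- list()
  idx_pool <- sample(2:n_codons)
  for (ci in idx_pool) {
    if (length(truth) >= k) break
    cod <- codons[ci]
    base <- strsplit(cod, "")[[1]]
    ok <- NULL
    for (pos in sample(0:2)) {
      b <- base[pos + 1]
      nb <- if (b == "C") "T" else if (b == "T") "C" else next
      mut <- base; mut[pos + 1] <- nb
      mutc <- paste(mut, collapse = "")
      if (code[[mutc]] == code[[cod]]) next       # silent, no call
      # prediction must pick this position: lowest C<->T flip of the
      # mutated codon restoring the reference residue
      first <- NA_integer_
      for (p2 in 0:2) {
        b2 <- mut[p2 + 1]
        nb2 <- if (b2 == "C") "T" else if (b2 == "T") "C" else next
        m2 <- mut; m2[p2 + 1] <- nb2
        if (code[[paste(m2, collapse = "")]] == code[[cod]]) {
          first <- p2; break
        }
      }
      if (!is.na(first) && first == pos) { ok <- list(pos = pos, mut = mutc, b = nb); break }
    }
    if (is.null(ok)) next
    query[ci] <- ok$mut
    truth[[length(truth) + 1L]] <- data.frame(
      cds_pos = 3L * (ci - 1L) + ok$pos,
      # the QUERY carries the flipped base; editing restores the original
      direction = if (ok$b == "C") "C2U" else "U2C",
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(cds_pos = integer(), direction = character())
  list(query = paste(query, collapse = ""),
       refs = rep(paste(ref_aa, collapse = ""), 2),
       truth = truth)
}
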