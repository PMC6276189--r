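test_that("pair_identity matches hand computations", {
  a <- rand_dna(100, seed = 1)
  expect_equal(pair_identity(a, a, "direct"), 1.0)
  expect_equal(pair_identity(a, revcomp(a), "inverted"), 1.0)
  b <- rand_dna(566, seed = 2)
  bb <- strsplit(b, "", fixed = TRUE)[[1]]
  mut <- bb
  idx <- withr::with_seed(3, sample(566, 13))
  for (i in idx) mut[i] <- setdiff(c("A", "C", "G", "T"), bb[i])[1]
  expect_equal(round(pair_identity(b, paste(mut, collapse = ""),
                                   "direct"), 4), round(553 / 566, 4))
  # ambiguity codes count as mismatches
  expect_equal(pair_identity("ANGT", "ANGT", "direct"), 0.75)
  expect_error(pair_identity("ACGT", "ACG", "direct"), "equal-length")
})

test_that("seed-and-extend equals the brute-force scan on exact repeats", {
  for (seed in 1:10) {
    n <- 1500L
    s <- strsplit(rand_dna(n, seed = seed), "", fixed = TRUE)[[1]]
    # plant one exact direct and one exact inverted repeat
    withr::with_seed(seed + 100, {
      s[501:560] <- s[101:160]                      # direct, 60 bp
      s[1201:1300] <- rc_chars(s[801:900])          # inverted, 100 bp
    })
    seqstr <- paste(s, collapse = "")
    g <- annotated_genome("t", seqstr, topology = "linear")
    got <- find_repeat_pairs(g, min_len = 40L, min_identity = 1, k = 21L)
    want <- bf_exact_repeats(seqstr, min_len = 40L)
    # same overlap filter as the finder
    ov <- pmax(0L, pmin(want$end1, want$end2) -
                 pmax(want$start1, want$start2))
    want <- want[ov < 0.5 * want$length, ]
    cols <- c("start1", "end1", "start2", "end2", "orientation", "length")
    got <- got[do.call(order, got[cols]), cols]
    want <- want[do.call(order, want[cols]), cols]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("planted mismatch pairs are recovered with exact coordinates", {
  for (seed in 1:6) {
    g <- generate_genome(30000, n_genes = 0, seed = seed)
    specs <- data.frame(len = c(566L, 435L, 150L),
                        mm = c(13L, 18L, 3L),
                        orient = c("inverted", "direct", "inverted"),
                        l1 = c(2000L, 8000L, 14000L),
                        l2 = c(5000L, 11000L, 17000L))
    truth <- NULL
    for (i in seq_len(nrow(specs))) {
      r <- plant_repeat_pair(g, specs$len[i], specs$mm[i],
                             specs$orient[i], specs$l1[i], specs$l2[i],
                             seed = seed * 10 + i)
      g <- r$genome
      truth <- rbind(truth, r$pair)
    }
    found <- find_repeat_pairs(g, min_len = 100L)
    expect_equal(nrow(found), 3L)
    cols <- c("start1", "end1", "start2", "end2", "orientation",
              "length", "n_mismatches")
    expect_equal(found[order(found$start1), cols],
                 truth[order(truth$start1), cols],
                 ignore_attr = TRUE, info = paste("seed", seed))
  }
})

test_that("a random genome yields no spurious large repeats", {
  hits <- vapply(1:20, function(seed) {
    g <- generate_genome(50000, n_genes = 0, seed = seed)
    nrow(find_repeat_pairs(g, min_len = 100L))
  }, integer(1))
  expect_true(all(hits == 0L))
})

test_that("reported pairs are invariant under rotation and revcomp", {
  g <- generate_genome(20000, n_genes = 0, seed = 31)
  g <- plant_repeat_pair(g, 300, 5, "inverted", 3000, 9000, seed = 1)$genome
  g <- plant_repeat_pair(g, 200, 2, "direct", 13000, 16000, seed = 2)$genome
  base <- find_repeat_pairs(g, min_len = 100L)
  sig <- function(p) {
    p <- p[order(p$length, p$orientation), ]
    p[c("length", "n_mismatches", "orientation")]
  }
  for (off in c(1000L, 8999L, 15500L)) {
    r <- find_repeat_pairs(rotate(g, off), min_len = 100L)
    expect_equal(sig(r), sig(base), ignore_attr = TRUE,
                 info = paste("offset", off))
  }
  rcg <- annotated_genome("rc", revcomp(g$sequence))
  expect_equal(sig(find_repeat_pairs(rcg, min_len = 100L)), sig(base),
               ignore_attr = TRUE)
})

test_that("guards: short genomes and bad seed lengths", {
  expect_error(find_repeat_pairs(rand_dna(500, seed = 1),
                                 min_len = 20L, k = 21L), "min_len")
  expect_equal(nrow(find_repeat_pairs(rand_dna(8, seed = 1),
                                      min_len = 11L, k = 11L)), 0L)
})

test_that("cross-genome survey groups shared pairs and drops lone copies", {
  mk <- function(seed, drop_copy = FALSE) {
    g <- generate_genome(30000, n_genes = 10, mean_gene_len = 800,
                         seed = seed,
                         keep_clear = data.frame(
                           start = c(4800, 11800, 20800),
                           end = c(5900, 12900, 21900)))
    g$id <- paste0("genome", seed)
    r <- plant_repeat_pair(g, 450, 10, "direct", 5000, 12000,
                           seed = seed, label = "P")
    g <- r$genome
    if (drop_copy) {
      # delete one copy (the repeat-pair loss scenario): overwrite it
      s <- strsplit(g$sequence, "", fixed = TRUE)[[1]]
      s[12001:12450] <- strsplit(rand_dna(450, seed = seed + 999),
                                 "", fixed = TRUE)[[1]]
      g$sequence <- paste(s, collapse = "")
    }
    g
  }
  gA <- mk(51); gB <- mk(52); gC <- mk(53, drop_copy = TRUE)
  tab <- cross_genome_repeat_survey(list(gA, gB, gC), min_len = 400L)
  expect_setequal(unique(tab$genome_id), c("genome51", "genome52"))
  expect_equal(length(unique(tab$label)), 1L)   # one shared label
  expect_equal(nrow(tab), 2L)
  expect_match(tab$copy1_context[1], "between|within")
  # a genome with no pair >= 400 bp contributes zero rows
  plain <- generate_genome(30000, n_genes = 0, seed = 60)
  plain$id <- "plain"
  expect_equal(nrow(cross_genome_repeat_survey(list(plain))), 0L)
})
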