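test_that("generator is deterministic and packs genes without overlap", {
  g1 <- generate_genome(10000, n_genes = 5, seed = 7)
  g2 <- generate_genome(10000, n_genes = 5, seed = 7)
  expect_identical(g1, g2)
  g3 <- generate_genome(10000, n_genes = 5, seed = 8)
  expect_false(identical(g1$sequence, g3$sequence))
  for (seed in 1:5) {
    g <- generate_genome(20000, n_genes = 12, mean_gene_len = 800,
                         seed = seed)
    f <- g$features
    expect_equal(nrow(f), 12L)
    expect_true(all(f$start[-1] >= f$end[-nrow(f)]))  # brute-force order
  }
  expect_error(generate_genome(1000, n_genes = 5, mean_gene_len = 500),
               "infeasible")
})

test_that("realized GC tracks the requested fraction at genome scale", {
  g <- generate_genome(160000, n_genes = 0, gc = 0.447, seed = 11)
  expect_lt(abs(gc_content(g) - 0.447), 0.02)  # binomial sampling bound
})

test_that("planted pairs carry the exact truth identity", {
  g <- generate_genome(30000, n_genes = 0, seed = 5)
  p1 <- plant_repeat_pair(g, 566, 13, "inverted", 2000, 10000,
                          seed = 1, label = "R1")
  expect_equal(round(100 * p1$pair$identity, 1), 97.7)
  p2 <- plant_repeat_pair(g, 435, 18, "direct", 2000, 10000,
                          seed = 2, label = "R2")
  expect_equal(round(100 * p2$pair$identity, 1), 95.9)
  # exact copies: perfect reverse-complement match
  p0 <- plant_repeat_pair(g, 200, 0, "inverted", 2000, 10000, seed = 3)
  s <- p0$genome$sequence
  expect_equal(substr(s, 2001, 2200),
               revcomp(substr(s, 10001, 10200)))
  # realized mismatch count equals the requested count
  s1 <- substr(p1$genome$sequence, 2001, 2566)
  s2 <- substr(p1$genome$sequence, 10001, 10566)
  expect_equal(round(566 * (1 - pair_identity(s1, s2, "inverted"))), 13)
})

test_that("planting respects gene features unless overridden", {
  g <- generate_genome(20000, n_genes = 8, mean_gene_len = 1000, seed = 2)
  f <- g$features
  inside_gene <- f$start[1] + 5L
  expect_error(
    plant_repeat_pair(g, 200, 0, "direct", inside_gene, 15000),
    "overlaps gene")
  expect_silent(
    plant_repeat_pair(g, 100, 0, "direct", inside_gene, 19000,
                      allow_gene_overlap = TRUE))
})

test_that("a planted inversion is an involution and conserves content", {
  g <- generate_genome(30000, n_genes = 10, mean_gene_len = 600, seed = 6,
                       keep_clear = data.frame(start = c(4900, 19900),
                                               end = c(5400, 20400)))
  res <- plant_repeat_pair(g, 300, 4, "inverted", 5000, 20000, seed = 1)
  inv1 <- apply_planted_inversion(res$genome, res$pair)
  expect_equal(sort(inv1$genome$features$name),
               sort(res$genome$features$name))      # gene conservation
  expect_equal(genome_length(inv1$genome), genome_length(res$genome))
  expect_equal(gc_content(inv1$genome), gc_content(res$genome))
  inv2 <- apply_planted_inversion(inv1$genome, res$pair)
  expect_equal(inv2$genome$sequence, res$genome$sequence)
  expect_equal(inv2$genome$features, res$genome$features)
  # a gene inside the segment flips strand (brute-force comparison)
  mid <- res$genome$features$start > 5150 & res$genome$features$end < 20150
  before <- res$genome$features[mid, ]
  for (nm in before$name) {
    after <- inv1$genome$features[inv1$genome$features$name == nm, ]
    expect_false(after$strand == before$strand[before$name == nm])
  }
  # direct-orientation recombination is a deletion, not an inversion
  d <- plant_repeat_pair(g, 300, 4, "direct", 5000, 20000, seed = 2)
  expect_error(apply_planted_inversion(d$genome, d$pair), "delet")
})

test_that("the study case records a consistent two-event ground truth", {
  case <- paper_case_fixture(1)
  tr <- case$truth
  expect_length(tr$applied_scenario$events, 2L)
  expect_equal(tr$expected_blocks, c(1L, 4L, -2L, -3L, 5L))
  # replay the recorded scenario over the identity block order
  perm <- tr$applied_scenario$source
  for (e in tr$applied_scenario$events) {
    perm <- apply_inversion(perm, e$segment[1], e$segment[2])
  }
  expect_equal(perm, tr$expected_blocks)
  # intermediate order after the first event
  inter <- apply_inversion(1:5, 3, 4)
  expect_equal(inter, c(1L, 2L, -4L, -3L, 5L))
  # ten planted pairs spanning 107..566 bp
  expect_equal(nrow(tr$planted_repeats), 10L)
  expect_equal(range(tr$planted_repeats$length), c(107L, 566L))
  # conservation through both inversions
  expect_equal(genome_length(case$observed), genome_length(case$ancestral))
  expect_equal(sort(case$observed$features$name),
               sort(case$ancestral$features$name))
  expect_equal(gc_content(case$observed), gc_content(case$ancestral))
})

test_that("the study case is byte-identical across runs at one seed", {
  c1 <- make_paper_case(seed = 42, length = 40000L)
  c2 <- make_paper_case(seed = 42, length = 40000L)
  expect_identical(c1, c2)
  c3 <- make_paper_case(seed = 43, length = 40000L)
  expect_false(identical(c1$ancestral$sequence, c3$ancestral$sequence))
})

test_that("synthetic cases serialize to FASTA + GFF3 + truth JSON", {
  dir <- withr::local_tempdir()
  case <- make_paper_case(seed = 5, length = 40000L)
  paths <- write_synthetic_case(case, dir)
  expect_true(all(file.exists(paths)))
  back <- read_fasta(paths[["observed_fa"]])[[1]]
  expect_equal(back$sequence, case$observed$sequence)
  back <- read_gff3(paths[["observed_gff"]], back)
  expect_equal(back$features, case$observed$features)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$expected_blocks, c(1L, 4L, -2L, -3L, 5L))
})
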