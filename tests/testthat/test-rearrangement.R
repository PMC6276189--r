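test_that("apply_inversion reproduces the two-step block algebra", {
  expect_equal(apply_inversion(c(1, 2, 3, 4, 5), 3, 4),
               c(1L, 2L, -4L, -3L, 5L))
  expect_equal(apply_inversion(c(1, 2, -4, -3, 5), 2, 3),
               c(1L, 4L, -2L, -3L, 5L))
  expect_error(apply_inversion(1:3, 0, 2), "range")
  expect_error(apply_inversion(1:3, 2, 4), "range")
})

test_that("inversions are involutions and conserve the element set", {
  withr::with_seed(5, {
    for (trial in 1:25) {
      n <- sample(3:7, 1)
      p <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
      i <- sample(n, 1)
      j <- if (i == n) n else sample(i:n, 1)
      q <- apply_inversion(p, i, j)
      expect_equal(sort(abs(q)), 1:n)
      expect_equal(apply_inversion(q, i, j), p)
    }
  })
})

test_that("BFS distance matches hand cases and is never truncated", {
  expect_equal(inversion_distance_bfs(1:5, c(1, 4, -2, -3, 5)), 2L)
  expect_equal(inversion_distance_bfs(1:4, 1:4), 0L)
  expect_equal(inversion_distance_bfs(1:3, c(1, -2, 3)), 1L)
  # the study-case order is NOT one inversion away from the identity:
  # exhaustive single-inversion enumeration excludes it
  images <- list()
  for (i in 1:5) for (j in i:5) {
    images[[length(images) + 1L]] <- apply_inversion(1:5, i, j)
  }
  expect_false(any(vapply(images, identical, TRUE,
                          c(1L, 4L, -2L, -3L, 5L))))
  expect_identical(inversion_distance_bfs(1:3, c(2, 1, 3),
                                          max_depth = 1L), NA_integer_)
  expect_error(inversion_distance_bfs(1:3, 1:4), "mismatch")
  expect_error(inversion_distance_bfs(1:11, 1:11), "guard")
})

test_that("BFS distance equals an independent graph shortest path", {
  skip_if_not_installed("igraph")
  # full state space for n = 3
  withr::with_seed(11, {
    targets <- signed_perms(3)
    for (t in sample(targets, 12)) {
      expect_equal(inversion_distance_bfs(1:3, t, max_depth = 9L),
                   igraph_reversal_distance(1:3, t),
                   info = paste(t, collapse = ","))
    }
  })
})

test_that("BFS distance is symmetric and satisfies the triangle bound", {
  withr::with_seed(7, {
    for (trial in 1:10) {
      n <- sample(3:5, 1)
      p <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
      q <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
      r <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
      dpq <- inversion_distance_bfs(p, q, max_depth = 8L)
      expect_equal(dpq, inversion_distance_bfs(q, p, max_depth = 8L))
      dpr <- inversion_distance_bfs(p, r, max_depth = 8L)
      dqr <- inversion_distance_bfs(q, r, max_depth = 8L)
      expect_lte(dpr, dpq + dqr)
    }
  })
})

test_that("placement tracking reflects junctions and flips orientation", {
  pl <- rbind(repeat_placement("X", 0L, 5L, "direct"),
              repeat_placement("Y", 2L, 4L, "direct"))
  # event spanning neither copy of X: X unchanged
  ev <- list(segment = c(2L, 3L))
  out <- track_repeats_through_event(pl, ev, 5L)
  expect_equal(out[out$label == "X", ], pl[pl$label == "X", ],
               ignore_attr = TRUE)
  # Y has exactly one copy (junction 2) strictly inside: flips
  expect_equal(out$relative_orientation[out$label == "Y"], "inverted")
  expect_equal(out$left_junction[out$label == "Y"], 2L)
  # event spanning both copies preserves relative orientation
  pl2 <- repeat_placement("Z", 2L, 3L, "direct")
  out2 <- track_repeats_through_event(pl2, list(segment = c(2L, 4L)), 5L)
  expect_equal(out2$relative_orientation, "direct")
  # hand-propagation through the study case's two events
  pl3 <- rbind(repeat_placement("R1", 2L, 4L, "inverted"),
               repeat_placement("R2", 1L, 3L, "direct"))
  s1 <- track_repeats_through_event(pl3, list(segment = c(3L, 4L)), 5L)
  expect_equal(s1$relative_orientation, c("inverted", "inverted"))
  expect_equal(s1$left_junction, c(2L, 1L))
  expect_equal(s1$right_junction, c(4L, 3L))
  s2 <- track_repeats_through_event(s1, list(segment = c(2L, 3L)), 5L)
  expect_equal(s2[s2$label == "R2", c("left_junction", "right_junction")],
               data.frame(left_junction = 1L, right_junction = 3L),
               ignore_attr = TRUE)
})

test_that("the constrained search returns exactly the two-step scenario", {
  case <- paper_case_fixture(1)
  sc <- find_repeat_mediated_scenarios(1:5, c(1L, 4L, -2L, -3L, 5L),
                                       case$truth$placements)
  expect_length(sc, 1L)
  expect_equal(sc[[1]]$events[[1]]$segment, c(3L, 4L))
  expect_equal(sc[[1]]$events[[1]]$mediating_repeat, "R1")
  expect_equal(sc[[1]]$events[[2]]$segment, c(2L, 3L))
  expect_equal(sc[[1]]$events[[2]]$mediating_repeat, "R2")
  expect_equal(sc[[1]]$intermediates[[1]], c(1L, 2L, -4L, -3L, 5L))
  expect_equal(sc[[1]]$intermediates[[2]], c(1L, 4L, -2L, -3L, 5L))
})

test_that("no placements means no scenarios for any true rearrangement", {
  empty <- repeat_placement(character(0), integer(0), integer(0),
                            character(0))
  expect_length(find_repeat_mediated_scenarios(1:4, c(1, -2, 3, 4),
                                               empty), 0L)
})

test_that("the recombination constraint never shortens a scenario", {
  checked <- 0L
  withr::with_seed(13, {
    for (trial in 1:50) {
      n <- sample(4:5, 1)
      npl <- sample(2:3, 1)
      pl <- do.call(rbind, lapply(seq_len(npl), function(i) {
        jj <- sort(sample(0:n, 2))
        repeat_placement(paste0("P", i), jj[1], jj[2],
                         if (i == 1L) "inverted" else
                           sample(c("direct", "inverted"), 1))
      }))
      # simulate a legal repeat-mediated history to get a reachable target
      m <- sample(1:2, 1)
      perm <- seq_len(n); cur <- pl
      for (step in seq_len(m)) {
        inv <- cur[cur$relative_orientation == "inverted", , drop = FALSE]
        if (nrow(inv) == 0L) break
        r <- sample(nrow(inv), 1)
        ev <- list(segment = c(inv$left_junction[r] + 1L,
                               inv$right_junction[r]))
        perm <- apply_inversion(perm, ev$segment[1], ev$segment[2])
        cur <- track_repeats_through_event(cur, ev, n)
      }
      if (identical(perm, seq_len(n))) next
      sc <- find_repeat_mediated_scenarios(seq_len(n), perm, pl,
                                           max_events = 3L)
      expect_gt(length(sc), 0L)
      d <- inversion_distance_bfs(seq_len(n), perm, max_depth = 4L)
      expect_gte(length(sc[[1]]$events), d)
      # every scenario replays source into target
      for (s in sc) {
        p2 <- s$source
        for (e in s$events) {
          p2 <- apply_inversion(p2, e$segment[1], e$segment[2])
        }
        expect_equal(p2, s$target)
      }
      checked <- checked + 1L
    }
  })
  expect_gt(checked, 10L)
})

test_that("permutation text round trips", {
  f <- withr::local_tempfile(fileext = ".txt")
  perms <- list(c(1L, 4L, -2L, -3L, 5L), c(-1L, 2L))
  write_permutations(perms, f)
  expect_equal(read_permutations(f), perms)
})
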