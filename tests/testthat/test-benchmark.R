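test_that("the plus/minus-one scoring rule and its bounds are exact", {
  tr <- matrix(FALSE, 3, 3); tr[1, 2] <- tr[1, 3] <- TRUE
  perfect <- score_adjacency(tr, tr)
  expect_equal(perfect$raw_score, 6)
  expect_equal(perfect$percent_score, 100)
  inverted <- score_adjacency(tr, !tr & !diag(3))
  expect_equal(inverted$raw_score, -6)
  expect_equal(inverted$percent_score, -100)
  # five agreeing cells, one wrong
  pred <- tr; pred[2, 1] <- TRUE
  s <- score_adjacency(tr, pred)
  expect_equal(s$raw_score, 4)
  expect_equal(s$percent_score, 100 * 4 / 6, tolerance = 1e-12)
  # parity: raw score has the parity of N^2 - N
  expect_true((s$raw_score %% 2) == 0)
  expect_error(score_adjacency(tr, matrix(FALSE, 2, 2)))
})

test_that("scores are invariant under joint node relabeling", {
  set.seed(701)
  tr <- matrix(sample(c(TRUE, FALSE), 9, replace = TRUE), 3); diag(tr) <- FALSE
  pr <- matrix(sample(c(TRUE, FALSE), 9, replace = TRUE), 3); diag(pr) <- FALSE
  perm <- c(3, 1, 2)
  expect_equal(score_adjacency(tr, pr)$raw_score,
               score_adjacency(tr[perm, perm], pr[perm, perm])$raw_score)
})

test_that("edge detection applies the fraction-of-bins rule with DC excluded", {
  nb <- 101
  sp <- list("1->2" = c(10, rep(0, nb - 1)),           # only DC above: no edge
             "2->1" = c(0, rep(c(1, 0), c(10, nb - 11))))  # exactly 10% above
  thr <- c("1->2" = 0.5, "2->1" = 0.5)
  M <- detect_edges(sp, thr, fraction = 0.10, n_nodes = 2)
  expect_false(M[1, 2])
  expect_true(M[2, 1])     # boundary counts (>= convention)
  expect_identical(detect_edges(list("1->2" = rep(0, nb)), 0.5, n_nodes = 2),
                   matrix(FALSE, 2, 2))
})

test_that("a strong unidirectional system is recovered end to end by both estimators", {
  g <- directed_graph(2, data.frame(from = 1, to = 2, lag = 2))
  for (method in c("npd", "npg")) {
    res <- run_benchmark(list(g), method = method, seed = 11,
                         trial_len = 256, n_trials = 60, n_surrogates = 100,
                         percentile = 99)
    expect_equal(res[[1]]$percent_score, 100)
    expect_identical(res[[1]]$predicted, adjacency(g))
  }
})

test_that("benchmark runs are reproducible under a fixed seed", {
  graphs <- lapply(1:2, function(k) random_graph(3, 1, seed = 720 + k))
  r1 <- run_benchmark(graphs, method = "npd", seed = 12, trial_len = 256,
                      n_trials = 40, n_surrogates = 100, percentile = 99)
  r2 <- run_benchmark(graphs, method = "npd", seed = 12, trial_len = 256,
                      n_trials = 40, n_surrogates = 100, percentile = 99)
  expect_identical(vapply(r1, `[[`, 0, "percent_score"),
                   vapply(r2, `[[`, 0, "percent_score"))
  expect_true(all(vapply(r1, function(r) abs(r$percent_score) <= 100, TRUE)))
})
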