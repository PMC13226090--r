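test_that("preprocessing log-transforms and selects genes by MAD with deterministic ties", {
  X <- rbind(hi = c(0, 10, 40, 5), mid = c(1, 3, 7, 2),
             flat = c(4, 4, 4, 4), lo2 = c(1, 2, 1, 2), lo1 = c(1, 2, 1, 2))
  colnames(X) <- paste0("s", 1:4)
  pp <- preprocess(X, n_top_genes = 3)
  expect_equal(pp$values, log2(X + 1)[pp$selected_genes, ])
  # constant gene has MAD 0 and is ranked last
  expect_false("flat" %in% pp$selected_genes)
  # lo1/lo2 have identical MAD: the tie breaks lexicographically
  expect_equal(pp$selected_genes[3], "lo1")
  expect_warning(ppa <- preprocess(X, n_top_genes = 99), "keeping all")
  expect_equal(nrow(ppa$values), 5)
  expect_error(preprocess(matrix(1, 4, 3)), "MAD")
  # hand check backing the tie case: MAD of {1,1,5} is 0
  expect_equal(stats::mad(c(1, 1, 5)), 0)
})

test_that("nmf_run is seeded, monotone, exact on a noiseless low-rank instance", {
  set.seed(1)
  W0 <- matrix(runif(60, 0, 2), 30, 2)
  H0 <- matrix(runif(40, 0, 2), 2, 20)
  X <- W0 %*% H0
  r <- nmf_run(X, 2, seed = 5)
  expect_lt(r$objective, 1e-6 * norm(X, "F"))
  expect_true(all(r$W >= 0) && all(r$H >= 0))

  r2 <- nmf_run(X, 2, seed = 5)
  expect_identical(r$W, r2$W)
  expect_identical(r$H, r2$H)
  expect_false(identical(r$W, nmf_run(X, 2, seed = 6)$W))

  # objective is non-increasing along the iteration path (same seed,
  # growing iteration caps trace the same trajectory)
  objs <- vapply(c(20, 50, 100, 300), function(mi) {
    nmf_run(X, 2, seed = 7, max_iter = mi, tol = 0)$objective
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-10))

  expect_error(nmf_run(X, 25, seed = 1), "k must")
  expect_error(nmf_run(X, 1, seed = 1), "k must")
})

test_that("connectivity matrices encode shared dominant factors", {
  H <- rbind(F1 = c(5, 4, 0.1), F2 = c(1, 2, 3))
  colnames(H) <- paste0("s", 1:3)
  C <- connectivity_matrix(H)
  expect_equal(unname(diag(C)), rep(1, 3))
  expect_equal(C["s1", "s2"], 1)
  expect_equal(C["s1", "s3"], 0)
  # all samples on one factor: all-ones matrix
  Hone <- rbind(F1 = c(9, 9), F2 = c(1, 2))
  expect_true(all(connectivity_matrix(Hone) == 1))
  # tie goes to the lowest factor index
  Htie <- cbind(s1 = c(2, 2), s2 = c(2, 0.5))
  expect_equal(connectivity_matrix(Htie)["s1", "s2"], 1)
  Hzero <- cbind(s1 = c(1, 2), s2 = c(0, 0))
  expect_error(connectivity_matrix(Hzero), "s2")
})

test_that("consensus averaging and the cophenetic correlation behave at the extremes", {
  # helper to fabricate a run with a fixed assignment
  H_of <- function(assign) {
    H <- matrix(0.1, 2, length(assign),
                dimnames = list(NULL, paste0("s", seq_along(assign))))
    H[cbind(assign, seq_along(assign))] <- 1
    H
  }
  # pair co-assigned in 3 of 5 runs -> consensus entry 0.6
  runs <- lapply(list(c(1, 1, 2, 2), c(1, 1, 2, 2), c(1, 1, 2, 2),
                      c(1, 2, 1, 2), c(1, 2, 2, 1)), H_of)
  cc <- consensus_and_ccc(runs)
  expect_equal(cc$consensus["s1", "s2"], 0.6)
  expect_true(isSymmetric(cc$consensus))
  expect_equal(unname(diag(cc$consensus)), rep(1, 4))
  expect_true(all(cc$consensus >= 0 & cc$consensus <= 1))

  # perfectly stable partitions: binary consensus, CCC exactly 1
  stable <- lapply(rep(list(c(1, 1, 2, 2, 2)), 4), H_of)
  cs <- consensus_and_ccc(stable)
  expect_true(all(cs$consensus %in% c(0, 1)))
  expect_equal(cs$ccc, 1.0, tolerance = 1e-9)

  # all off-diagonal entries equal: CCC undefined
  flat <- lapply(list(c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 2, 2, 1)), H_of)
  expect_warning(cf <- consensus_and_ccc(flat), "degenerate")
  expect_true(is.na(cf$ccc))
})

test_that("candidate ranks are interior strict local maxima with leftmost-plateau rule", {
  lm <- tmecrossmap:::local_maxima
  expect_equal(lm(c(0.80, 0.95, 0.85, 0.90, 0.70)), c(2L, 4L))
  expect_equal(lm(c(0.9, 0.8, 0.7, 0.6)), integer(0))          # decreasing
  expect_equal(lm(c(0.5, 0.9, 0.9, 0.7, 0.8, 0.6)), c(2L, 5L)) # plateau -> leftmost
  expect_equal(lm(c(0.5, 0.6, 0.7)), integer(0))               # endpoint max excluded
})

test_that("the rank sweep flags invalid ranks and recovers structure on a tiny instance", {
  ds <- generate_planted_gep_dataset(tiny_gep_config(seed = 21))
  X <- log2(ds$expression_a + 1)
  expect_warning(
    prof <- rank_stability_sweep(X[1:30, 1:12], ranks = 3:14,
                                 runs_per_rank = 3, repeats = 2, seed = 4),
    "skipping")
  expect_true(all(prof$ranks < 12))
  expect_true(all(prof$median_ccc >= -1 & prof$median_ccc <= 1, na.rm = TRUE))
  expect_true(all(prof$candidate_ranks %in% prof$ranks))
  # determinism of the full profile
  suppressWarnings({
    prof2 <- rank_stability_sweep(X[1:30, 1:12], ranks = 3:14,
                                  runs_per_rank = 3, repeats = 2, seed = 4)
  })
  expect_identical(prof$ccc, prof2$ccc)
})

test_that("consensus factorization reduces to a single run when runs are identical", {
  set.seed(3)
  X <- matrix(runif(30 * 18, 0, 2), 30, 18,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:18)))
  r <- nmf_run(X, 3, seed = 2)
  g <- consensus_from_runs(rep(list(r), 10), 3, seed = 9)
  expect_equal(match_programs(g$W_Con, r$W)$mean_cosine, 1, tolerance = 1e-9)
  expect_equal(unname(sqrt(colSums(g$W_Con^2))), rep(1, 3), tolerance = 1e-9)
  expect_equal(g$cluster_sizes, rep(10L, 3))
  expect_equal(g$retained_counts, rep(6L, 3))  # 40% of 10 pruned
})

test_that("consensus factors recover a noiseless planted rank-3 basis", {
  cfg <- synthetic_cohort_config(n_genes = 90L, n_samples_a = 50L,
                                 n_samples_b = 10L, k_true = 3L,
                                 k_shared = 1L, n_markers = 10L,
                                 noise_scale = 0, seed = 13)
  ds <- generate_planted_gep_dataset(cfg)
  g <- consensus_factorization(ds$expression_a, 3, seed = 17)
  m <- match_programs(g$W_Con, ds$true_W_a)
  expect_gte(m$mean_cosine, 0.99)
  # Hungarian assignment agrees with the exhaustive-permutation oracle
  expect_equal(m$mean_cosine, perm_best_assignment(m$cosine),
               tolerance = 1e-12)
})

test_that("consensus weights are scale invariant (usages scale linearly)", {
  ds <- generate_planted_gep_dataset(tiny_gep_config(seed = 29))
  X <- ds$expression_a
  g1 <- consensus_factorization(X, 4, n_runs = 4, seed = 8)
  g2 <- consensus_factorization(X * 7, 4, n_runs = 4, seed = 8)
  expect_equal(g1$W_Con, g2$W_Con, tolerance = 1e-5)
  expect_equal(g2$H_Con, 7 * g1$H_Con, tolerance = 1e-4)
})

test_that("LOF scores isolate a gross outlier", {
  set.seed(12)
  pts <- rbind(matrix(rnorm(40, sd = 0.3), 20, 2), c(8, 8))
  lof <- lof_scores(pts, n_neighbors = 5)
  expect_equal(which.max(lof), 21L)
  expect_true(all(lof[1:20] < lof[21]))
  expect_error(lof_scores(pts, 0), "n_neighbors")
})
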