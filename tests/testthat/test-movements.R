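test_that("gene scores are fractional ranks averaged over the signature", {
  expr <- rbind(g1 = c(s1 = 5, s2 = 10))
  expect_equal(gene_score(expr, "g1"), c(s1 = 0.5, s2 = 1.0))

  # a sample maximal in every signature gene scores exactly 1
  expr2 <- rbind(g1 = c(1, 2, 9), g2 = c(0, 3, 7))
  colnames(expr2) <- paste0("s", 1:3)
  sc <- gene_score(expr2, c("g1", "g2"))
  expect_equal(unname(sc["s3"]), 1.0)

  # identical samples: every score is (n+1)/(2n) by the tie convention
  expr3 <- rbind(g1 = rep(4, 5), g2 = rep(1, 5))
  colnames(expr3) <- paste0("s", 1:5)
  expect_equal(unname(gene_score(expr3, c("g1", "g2"))), rep(6 / 10, 5))

  # rank-based: invariant under monotone per-gene transforms
  set.seed(2)
  expr4 <- matrix(rgamma(60, 2), 3, 20,
                  dimnames = list(paste0("g", 1:3), paste0("s", 1:20)))
  s_raw <- gene_score(expr4, paste0("g", 1:3))
  s_tr <- gene_score(log1p(expr4)^3, paste0("g", 1:3))
  expect_equal(s_raw, s_tr)

  expect_warning(gene_score(expr4, c("g1", "g2", "nope")), "missing")
  expect_error(gene_score(expr4, c("zz")), "no signature genes")
})

test_that("movement correlation joins samples and adjusts over the whole matrix", {
  set.seed(14)
  n <- 60
  base <- rnorm(n)
  t_sc <- cbind(T1 = base + rnorm(n, sd = 0.5), T2 = rnorm(n))
  my_sc <- cbind(My1 = base + rnorm(n, sd = 0.5), My2 = rnorm(n))
  rownames(t_sc) <- rownames(my_sc) <- paste0("p", 1:n)
  cm <- movement_correlation(t_sc, my_sc)
  expect_equal(dim(cm$pearson_r), c(2L, 2L))
  expect_gt(cm$pearson_r["T1", "My1"], 0.5)
  expect_lt(cm$p_adjusted["T1", "My1"], 0.01)
  expect_true(all(cm$p_adjusted >= cm$p_raw - 1e-15, na.rm = TRUE))
  # a score correlated with itself
  self <- movement_correlation(t_sc, t_sc)
  expect_equal(self$pearson_r["T1", "T1"], 1)
  # inner join on sample ids
  my_shift <- my_sc; rownames(my_shift) <- paste0("p", 3:(n + 2))
  cj <- movement_correlation(t_sc, my_shift)
  expect_equal(unique(as.vector(cj$n_used)), n - 2L)
  expect_error(movement_correlation(t_sc[1:2, ], my_sc[3:4, ]), "shared")
})

test_that("quantile binning yields the stated group sizes and joint labels", {
  s <- setNames(1:10, paste0("p", 1:10))
  b50 <- bin_by_quantile(s, 0.5, 0.5)
  expect_equal(sum(b50$bins == "high"), 5)
  expect_equal(sum(b50$bins == "low"), 5)
  b37 <- bin_by_quantile(s, 0.3, 0.7)
  expect_equal(unname(table(b37$bins)[c("high", "low", "excluded")]),
               c(3L, 3L, 4L), ignore_attr = TRUE)
  # crossing two programs at 0.5/0.5 partitions the cohort into 4 groups
  set.seed(5)
  two <- cbind(T1 = rnorm(40), My1 = rnorm(40))
  rownames(two) <- paste0("p", 1:40)
  bj <- bin_by_quantile(two, 0.5, 0.5)
  expect_false(anyNA(bj$joint))
  expect_equal(sort(unique(bj$joint)),
               sort(c("T1_high.My1_high", "T1_high.My1_low",
                      "T1_low.My1_high", "T1_low.My1_low")))
  expect_equal(sum(table(bj$joint)), 40)
  # ties at a threshold fall to the lower bin
  tied <- c(1, 2, 2, 2, 3, 4, 5, 6)
  bt <- bin_by_quantile(tied, 0.3, 0.7)
  expect_true(all(bt$bins[tied == 2] == "low"))
  expect_error(bin_by_quantile(s, 0, 0.5), "q_low")
  expect_error(bin_by_quantile(rep(1, 10), 0.5, 0.5), "empty")
})

test_that("Kaplan-Meier curves match the hand-computed product limit exactly", {
  # all events at 1, 2, 3
  km <- kaplan_meier(data.frame(time = 1:3, event = 1))
  expect_equal(km$curves$all$surv, c(2 / 3, 1 / 3, 0))
  # censoring removes a subject from later risk sets
  km2 <- kaplan_meier(data.frame(time = 1:3, event = c(0, 1, 1)))
  expect_equal(km2$curves$all$surv, c(1, 1 / 2, 0))
  # six-subject fixture with interleaved censoring, by hand:
  # t=1 (6 at risk, 1 event) 5/6; t=2 (5 at risk, 1 event, 1 censored)
  # 2/3; t=3 (3 at risk, 1 event) 4/9; t=4 censored; t=5 (1 at risk,
  # 1 event) 0
  km6 <- kaplan_meier(data.frame(time = c(1, 2, 2, 3, 4, 5),
                                 event = c(1, 1, 0, 1, 0, 1)))
  s <- km6$curves$all
  expect_equal(s$surv[s$time == 1], 5 / 6)
  expect_equal(s$surv[s$time == 2], 2 / 3)
  expect_equal(s$surv[s$time == 3], 4 / 9)
  expect_equal(s$surv[s$time == 5], 0)
  # no events: the curve never drops
  km0 <- kaplan_meier(data.frame(time = 1:4, event = 0))
  expect_true(all(km0$curves$all$surv == 1))
  expect_true(is.na(km0$median_survival))
  expect_error(kaplan_meier(data.frame(time = c(0, 1), event = 1)), "times")
})

test_that("log-rank testing matches its permutation oracle and degenerate contracts", {
  # duplicated identical group: no difference to detect
  df <- data.frame(time = rep(c(1, 3, 5, 7), 2), event = 1)
  lr <- logrank_test(df, rep(c("a", "b"), each = 4))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)

  # no events anywhere
  expect_warning(
    lr0 <- logrank_test(data.frame(time = 1:4, event = 0),
                        c("a", "a", "b", "b")),
    "no events")
  expect_equal(lr0$p, 1)

  # n = 12 fixture: asymptotic p within 0.02 of a permutation null
  set.seed(77)
  t12 <- c(rexp(6, 1), rexp(6, 2.5))
  e12 <- rbinom(12, 1, 0.8); e12[1] <- 1
  g12 <- rep(c("a", "b"), each = 6)
  lr12 <- logrank_test(data.frame(time = t12, event = e12), g12)
  p_perm <- perm_logrank_p(t12, e12, g12, B = 5000, seed = 3)
  expect_lt(abs(lr12$p - p_perm), 0.02)

  # complete separation is decisively significant
  sep <- data.frame(time = c(1:20 / 10, 21:40), event = 1)
  lrs <- logrank_test(sep, rep(c("early", "late"), each = 20))
  expect_lt(lrs$p, 0.001)
})

test_that("usage-score and gene-score routes feed identical downstream binning", {
  set.seed(21)
  h_usage <- matrix(rgamma(80, 2), 40, 2,
                    dimnames = list(paste0("p", 1:40), c("T1", "My1")))
  b1 <- bin_by_quantile(h_usage, 0.3, 0.7)
  expect_s3_class(b1, "binned_cohort")
  expect_equal(colnames(b1$bins), c("T1", "My1"))
  # identical labels when scores are replaced by any monotone transform
  b2 <- bin_by_quantile(sqrt(h_usage), 0.3, 0.7)
  expect_equal(b1$bins, b2$bins)
})
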