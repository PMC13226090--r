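test_that("combined z-scoring pools cohorts and uses population sd", {
  one <- matrix(c(0, 2), 2, 1, dimnames = list(NULL, "f"))
  z <- combined_zscore(one)
  expect_equal(unname(z$zscores[, "f"]), c(-1, 1))

  # pooling: two cohorts with different means share one global scale
  a <- matrix(rnorm(40, mean = 0), 20, 2, dimnames = list(NULL, c("x", "y")))
  b <- matrix(rnorm(40, mean = 3), 20, 2, dimnames = list(NULL, c("x", "y")))
  z2 <- combined_zscore(list(a, b))
  expect_true(all(abs(colMeans(z2$zscores)) < 1e-9))
  expect_gt(abs(mean(z2$zscores[z2$cohort == 1, "x"])), 0.5)

  # constant feature maps to zero with a warning
  cc <- cbind(a, const = 1)
  expect_warning(zc <- combined_zscore(cc), "zero-variance")
  expect_true(all(zc$zscores[, "const"] == 0))

  # mismatched features across cohorts is an error naming them
  b2 <- b; colnames(b2) <- c("x", "zz")
  expect_error(combined_zscore(list(a, b2)), "zz")
})

test_that("group aggregation applies the statistic feature-wise", {
  tab <- matrix(c(0.1, 0.2, 0.3, 0, 0, 0.9), 3, 2,
                dimnames = list(NULL, c("f1", "f2")))
  g <- rep("m1", 3)
  expect_equal(unname(aggregate_by_group(tab, g, "median")["m1", ]),
               c(0.2, 0))
  expect_equal(unname(aggregate_by_group(tab, g, "mean")["m1", ]),
               c(0.2, 0.3))
  # a single-sample group is its own row
  one <- aggregate_by_group(tab[1, , drop = FALSE], "solo")
  expect_equal(unname(one["solo", ]), unname(tab[1, ]))
})

test_that("cosine similarity matches hand values and the brute-force formula", {
  rows <- rbind(a = c(1, 1, 0), b = c(1, 0, 1), c = c(2, 2, 0))
  sm <- cosine_similarity_matrix(rows)
  expect_equal(sm$similarity["a", "b"], 0.5)
  expect_equal(sm$similarity["a", "c"], 1.0)  # identical direction
  expect_equal(unname(diag(sm$similarity)), rep(1, 3), tolerance = 1e-12)
  expect_equal(sm$distance, 1 - sm$similarity)
  expect_equal(sm$similarity, t(sm$similarity), tolerance = 1e-12)
  orth <- cosine_similarity_matrix(rbind(u = c(1, 0), v = c(0, 1)))
  expect_equal(orth$similarity["u", "v"], 0)

  set.seed(42)
  x <- matrix(runif(60, 0.1, 1), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("f", 1:10)))
  y <- matrix(runif(40, 0.1, 1), 4, 10,
              dimnames = list(paste0("h", 1:4), paste0("f", 1:10)))
  sm2 <- cosine_similarity_matrix(x, y)
  for (i in 1:6) for (j in 1:4) {
    expect_equal(sm2$similarity[i, j], cosine_brute(x[i, ], y[j, ]),
                 tolerance = 1e-12)
  }

  bad <- rbind(ok = c(1, 2), zero = c(0, 0))
  expect_error(cosine_similarity_matrix(bad), "zero")
})

test_that("relative variance is CV^2 on raw frequencies", {
  tab <- cbind(f1 = c(1, 3), f2 = c(5, 5), f3 = c(0, 0))
  rv <- relative_variance(tab, c("g", "g"))
  expect_equal(unname(rv["g", "f1"]), 0.25)   # pop var 1 / mean^2 4
  expect_equal(unname(rv["g", "f2"]), 0)      # constant feature
  expect_true(is.na(rv["g", "f3"]))           # zero mean undefined
  # scale invariance
  rv10 <- relative_variance(tab * 10, c("g", "g"))
  expect_equal(rv10["g", c("f1", "f2")], rv["g", c("f1", "f2")])
  expect_error(relative_variance(tab[1, , drop = FALSE], "g"), "fewer than 2")
})

test_that("pairwise Pearson/BH keeps invariants and matches a permutation oracle", {
  set.seed(7)
  n <- 15
  x1 <- rnorm(n)
  tab <- cbind(a = x1, b = -2 * x1, c = rnorm(n), d = rnorm(n))
  cm <- pairwise_pearson_bh(tab)
  expect_equal(unname(diag(cm$pearson_r)), rep(1, 4))
  expect_equal(cm$pearson_r["a", "b"], -1)
  expect_equal(cm$p_raw["a", "b"], 0)
  ok <- !is.na(cm$p_raw)
  expect_true(all(cm$p_adjusted[ok] >= cm$p_raw[ok] - 1e-15))
  expect_true(all(cm$n_used[upper.tri(cm$n_used)] == n))

  # BH is monotone in the raw-p ordering
  pr <- cm$p_raw[upper.tri(cm$p_raw)]
  pa <- cm$p_adjusted[upper.tri(cm$p_adjusted)]
  ord <- order(pr)
  expect_true(all(diff(pa[ord]) >= -1e-15))

  # t-transform p agrees with a label-permutation null for one pair
  r_obs <- abs(cm$pearson_r["c", "d"])
  set.seed(99)
  perm <- replicate(4000, abs(cor(tab[, "c"], sample(tab[, "d"]))))
  expect_lt(abs(mean(perm >= r_obs - 1e-12) - cm$p_raw["c", "d"]), 0.03)

  # constant feature: undefined pairs reported NA, excluded from BH
  tab2 <- cbind(tab, k = 1)
  cm2 <- pairwise_pearson_bh(tab2)
  expect_true(all(is.na(cm2$pearson_r["k", setdiff(colnames(tab2), "k")])))
  expect_true(all(is.na(cm2$p_adjusted["k", setdiff(colnames(tab2), "k")])))
})

test_that("mouse-like groups map onto their planted archetype by cosine argmax", {
  feats <- c("tumor", "stroma", "t_cell", "b_cell", "nk", "macrophage",
             "monocyte", "cdc1", "cdc2", "neutrophil")
  arche <- rbind(
    immune_rich  = c(0.20, 0.10, 0.30, 0.10, 0.05, 0.10, 0.05, 0.03, 0.04, 0.03),
    desert_mac   = c(0.45, 0.15, 0.03, 0.02, 0.02, 0.20, 0.08, 0.01, 0.02, 0.02),
    stroma_rich  = c(0.25, 0.40, 0.08, 0.04, 0.03, 0.08, 0.06, 0.02, 0.02, 0.02))
  colnames(arche) <- feats
  # mouse models: perturbed copies of the macrophage-rich desert
  mouse <- arche[c("desert_mac", "desert_mac"), ]
  rownames(mouse) <- c("B16", "MC38")
  mouse["B16", "macrophage"] <- mouse["B16", "macrophage"] + 0.05
  mouse["B16", "t_cell"] <- mouse["B16", "t_cell"] - 0.01
  mouse["B16", "tumor"] <- mouse["B16", "tumor"] - 0.04
  hits <- 0L
  for (rep_i in 1:20) {
    hum <- generate_frequency_cohort(arche, 20, 150, seed = 100 + rep_i)
    mus <- generate_frequency_cohort(mouse, 10, 150, seed = 200 + rep_i)
    med_h <- aggregate_by_group(hum$frequencies, hum$group_label, "median")
    med_m <- aggregate_by_group(mus$frequencies, mus$group_label, "median")
    sm <- cosine_similarity_matrix(med_m, med_h)
    best <- colnames(sm$similarity)[apply(sm$similarity, 1, which.max)]
    if (all(best == "desert_mac")) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.95)
})
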