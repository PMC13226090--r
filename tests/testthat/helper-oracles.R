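# Independent oracles used to cross-check the production paths.

# Two-sided Fisher p for gene-set overlap by explicit hypergeometric
# enumeration with binomial coefficients (independent of dhyper).
enum_fisher_two_sided <- function(n_a, n_b, overlap, universe) {
  support <- max(0L, n_a + n_b - universe):min(n_a, n_b)
  prob <- vapply(support, function(k) {
    choose(n_a, k) * choose(universe - n_a, n_b - k) / choose(universe, n_b)
  }, numeric(1))
  p_obs <- prob[support == overlap]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Unweighted two-group log-rank chi-square computed from first
# principles (risk sets and hypergeometric moments at each event time).
logrank_chisq_2g <- function(time, event, group) {
  g1 <- group == unique(group)[1]
  times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(0)
  (O1 - E1)^2 / V
}

# Permutation null of the log-rank statistic: p = fraction of label
# permutations with a statistic at least as large as observed.
perm_logrank_p <- function(time, event, group, B = 20000, seed = 1) {
  obs <- logrank_chisq_2g(time, event, group)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(B)) {
    if (logrank_chisq_2g(time, event, sample(group)) >= obs - 1e-12) {
      hits <- hits + 1L
    }
  }
  hits / B
}

# Scalar cosine similarity, evaluated pairwise for brute-force checks.
cosine_brute <- function(x, y) sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))

# Exhaustive-permutation optimal assignment (oracle for the Hungarian
# route in match_programs) - feasible for k <= 7.
perm_best_assignment <- function(cosine) {
  k <- nrow(cosine)
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), , drop = FALSE]
  best <- -Inf
  for (i in seq_len(nrow(perms))) {
    v <- mean(cosine[cbind(seq_len(k), perms[i, ])])
    if (v > best) best <- v
  }
  best
}

# Small planted dataset shared across unit tests (fast: ~120 genes).
tiny_gep_config <- function(seed = 1L, noise_scale = 0.25, ...) {
  synthetic_cohort_config(n_genes = 120L, n_samples_a = 60L,
                          n_samples_b = 60L, k_true = 4L, k_shared = 2L,
                          n_markers = 10L, noise_scale = noise_scale,
                          seed = seed, ...)
}
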