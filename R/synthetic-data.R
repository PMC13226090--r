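#' Configuration for a planted two-species GEP dataset
#'
#' Describes the stated world of the simulator: two species' expression
#' cohorts built from `k_true` gene expression programs (GEPs) of which
#' `k_shared` are planted in both species at ortholog-corresponding genes.
#' Each program owns an exclusive block of `n_markers` high-weight marker
#' genes on top of a low uniform background, so top-N gene signatures are
#' well defined; per-sample usages are sparse gamma draws in which 1-3
#' programs dominate, mirroring the program-dominance structure NMF assumes.
#'
#' @param n_genes number of genes per species.
#' @param n_samples_a,n_samples_b samples per species.
#' @param k_true number of planted programs per species.
#' @param k_shared number of programs shared between species
#'   (`k_shared <= k_true`).
#' @param noise_model `"gaussian-clipped"` (additive Gaussian noise clipped
#'   at zero, preserving the nonnegative input contract of NMF) or
#'   `"poisson"` (counts with the noiseless signal as the rate).
#' @param noise_scale for the Gaussian model, the noise standard deviation
#'   as a fraction of the mean signal; ignored for Poisson. The default
#'   0.25 is the "moderate" noise condition used throughout.
#' @param n_markers exclusive marker genes per program (default 20, the
#'   size of the top-gene signatures used downstream).
#' @param frac_unmapped fraction of non-marker genes left out of the
#'   ortholog map (exercises mapping policy).
#' @param frac_multi fraction of non-marker genes given a second,
#'   many-to-many ortholog partner (dropped by the one-to-one policy).
#' @param seed integer seed; the same config is bit-identical on rerun.
#' @return a `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(n_genes = 1000L,
                                    n_samples_a = 200L,
                                    n_samples_b = 200L,
                                    k_true = 6L,
                                    k_shared = 3L,
                                    noise_model = c("gaussian-clipped", "poisson"),
                                    noise_scale = 0.25,
                                    n_markers = 20L,
                                    frac_unmapped = 0.05,
                                    frac_multi = 0.02,
                                    seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (k_shared > k_true) {
    stop("invalid config: k_shared (", k_shared,
         ") must not exceed k_true (", k_true, ")", call. = FALSE)
  }
  if (any(c(n_genes, n_samples_a, n_samples_b, k_true, n_markers) <= 0)) {
    stop("invalid config: counts must be positive", call. = FALSE)
  }
  if (noise_scale < 0) stop("invalid config: noise_scale must be >= 0",
                            call. = FALSE)
  need <- k_shared * n_markers + 2L * (k_true - k_shared) * n_markers
  if (n_genes < need) {
    stop("invalid config: n_genes must be at least ", need,
         " to host disjoint marker blocks", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_samples_a = as.integer(n_samples_a),
                 n_samples_b = as.integer(n_samples_b),
                 k_true = as.integer(k_true),
                 k_shared = as.integer(k_shared),
                 noise_model = noise_model,
                 noise_scale = noise_scale,
                 n_markers = as.integer(n_markers),
                 frac_unmapped = frac_unmapped,
                 frac_multi = frac_multi,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_config")
}

# Draw a sparse nonnegative usage matrix (k x n): each sample gets 1-3
# dominant programs with gamma usages plus a small gamma background.
draw_usage <- function(k, n, program_ids) {
  H <- matrix(0.05 * stats::rgamma(k * n, shape = 0.3, rate = 1), k, n)
  for (j in seq_len(n)) {
    d <- sample.int(3L, 1L)
    dom <- sample.int(k, min(d, k))
    H[dom, j] <- stats::rgamma(length(dom), shape = 8, rate = 1)
  }
  dimnames(H) <- list(program_ids, paste0("s", seq_len(n)))
  H
}

# Gene-weight matrix with exclusive marker blocks: marker_idx[[p]] holds
# the row indices whose weight is drawn high for program p.
draw_weights <- function(n_genes, marker_idx, gene_ids, program_ids) {
  k <- length(marker_idx)
  W <- matrix(stats::runif(n_genes * k, 0, 0.05), n_genes, k)
  for (p in seq_len(k)) {
    W[marker_idx[[p]], p] <- stats::runif(length(marker_idx[[p]]), 1, 3)
  }
  dimnames(W) <- list(gene_ids, program_ids)
  W
}

#' Generate a two-species expression dataset with planted shared programs
#'
#' Builds `X = W H` for each species and adds noise clipped at zero.
#' Shared programs occupy the same marker-gene indices in both species, so
#' after ortholog mapping their top-`n_markers` gene sets have ground-truth
#' Jaccard index 1; species-specific programs use disjoint marker blocks.
#' The ortholog map names genes `g<i>_a` / `g<i>_b`; a configurable
#' fraction of non-marker genes is left unmapped and another fraction is
#' made many-to-many to exercise one-to-one filtering downstream.
#'
#' @param config a [synthetic_cohort_config()].
#' @return a `planted_gep_dataset` list with elements `expression_a`,
#'   `expression_b` (gene x sample), `true_W_a`, `true_W_b`, `true_H_a`,
#'   `true_H_b`, `shared_program_ids`, `ortholog_map` (data.frame with
#'   columns `gene_a`, `gene_b`), `config` and `seed`.
#' @export
generate_planted_gep_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  cfg <- config
  with_seed(cfg$seed, {
    nm <- cfg$n_markers
    k <- cfg$k_true
    ks <- cfg$k_shared
    genes_a <- sprintf("g%04d_a", seq_len(cfg$n_genes))
    genes_b <- sprintf("g%04d_b", seq_len(cfg$n_genes))
    progs <- paste0("P", seq_len(k))

    # marker blocks: shared programs first, then per-species blocks
    block <- function(i) ((i - 1L) * nm + 1L):(i * nm)
    marker_a <- marker_b <- vector("list", k)
    for (p in seq_len(ks)) marker_a[[p]] <- marker_b[[p]] <- block(p)
    off_a <- ks
    off_b <- ks + (k - ks)
    for (p in seq_len(k - ks)) {
      marker_a[[ks + p]] <- block(off_a + p)
      marker_b[[ks + p]] <- block(off_b + p)
    }

    W_a <- draw_weights(cfg$n_genes, marker_a, genes_a, progs)
    W_b <- draw_weights(cfg$n_genes, marker_b, genes_b, progs)
    H_a <- draw_usage(k, cfg$n_samples_a, progs)
    H_b <- draw_usage(k, cfg$n_samples_b, progs)
    colnames(H_a) <- paste0("a_s", seq_len(cfg$n_samples_a))
    colnames(H_b) <- paste0("b_s", seq_len(cfg$n_samples_b))

    add_noise <- function(X) {
      if (cfg$noise_model == "poisson") {
        matrix(stats::rpois(length(X), lambda = X), nrow(X), ncol(X),
               dimnames = dimnames(X))
      } else if (cfg$noise_scale == 0) {
        X
      } else {
        sd <- cfg$noise_scale * mean(X)
        pmax(X + matrix(stats::rnorm(length(X), 0, sd), nrow(X), ncol(X)), 0)
      }
    }
    X_a <- add_noise(W_a %*% H_a)
    X_b <- add_noise(W_b %*% H_b)

    # ortholog map: identity pairing, perturbed only on non-marker genes
    marker_rows <- unique(unlist(c(marker_a, marker_b)))
    free <- setdiff(seq_len(cfg$n_genes), marker_rows)
    n_unmap <- floor(cfg$frac_unmapped * cfg$n_genes)
    n_multi <- floor(cfg$frac_multi * cfg$n_genes)
    drop_idx <- if (n_unmap > 0) sample(free, min(n_unmap, length(free))) else integer(0)
    free2 <- setdiff(free, drop_idx)
    multi_idx <- if (n_multi > 0) sample(free2, min(n_multi, length(free2))) else integer(0)
    keep <- setdiff(seq_len(cfg$n_genes), drop_idx)
    map <- data.frame(gene_a = genes_a[keep], gene_b = genes_b[keep],
                      stringsAsFactors = FALSE)
    if (length(multi_idx) > 0) {
      # each selected a-gene also maps to its successor's b-gene
      partner <- (multi_idx %% cfg$n_genes) + 1L
      map <- rbind(map, data.frame(gene_a = genes_a[multi_idx],
                                   gene_b = genes_b[partner],
                                   stringsAsFactors = FALSE))
    }

    structure(list(expression_a = X_a, expression_b = X_b,
                   true_W_a = W_a, true_W_b = W_b,
                   true_H_a = H_a, true_H_b = H_b,
                   shared_program_ids = seq_len(ks),
                   ortholog_map = map,
                   config = cfg, seed = cfg$seed),
              class = "planted_gep_dataset")
  })
}

#' Generate an archetype-structured compartment-frequency cohort
#'
#' Samples compositional frequency vectors (10 immune/stromal compartments
#' by convention, any feature set accepted) around group centroids using a
#' Dirichlet draw with parameter `concentration * centroid`. Higher
#' concentration gives tighter groups; centroid entries of exactly zero
#' stay exactly zero in every draw.
#'
#' @param centroids group x feature matrix of valid compositions (rows sum
#'   to 1, entries in `[0,1]`); rownames are group labels.
#' @param n_per_group samples per group (recycled across groups).
#' @param concentration Dirichlet concentration (sum of alphas).
#' @param seed integer seed.
#' @return a `frequency_cohort` list with `frequencies` (sample x feature),
#'   `group_label`, `centroids` and `seed`.
#' @export
generate_frequency_cohort <- function(centroids, n_per_group = 20L,
                                      concentration = 100,
                                      seed = 1L) {
  centroids <- as.matrix(centroids)
  if (any(centroids < 0)) {
    stop("centroid rows must be valid compositions (negative entry found)",
         call. = FALSE)
  }
  if (any(abs(rowSums(centroids) - 1) > 1e-6)) {
    stop("centroid rows must sum to 1", call. = FALSE)
  }
  if (is.null(rownames(centroids))) {
    rownames(centroids) <- paste0("group", seq_len(nrow(centroids)))
  }
  groups <- rownames(centroids)
  n_per_group <- rep_len(as.integer(n_per_group), length(groups))
  with_seed(seed, {
    out <- vector("list", length(groups))
    for (g in seq_along(groups)) {
      alpha <- concentration * centroids[g, ]
      draws <- matrix(0, n_per_group[g], ncol(centroids))
      pos <- alpha > 0
      gam <- matrix(stats::rgamma(n_per_group[g] * sum(pos),
                                  shape = rep(alpha[pos], each = n_per_group[g])),
                    n_per_group[g], sum(pos))
      draws[, pos] <- gam / rowSums(gam)
      out[[g]] <- draws
    }
    freq <- do.call(rbind, out)
    colnames(freq) <- colnames(centroids)
    rownames(freq) <- paste0(rep(groups, n_per_group), "_",
                             unlist(lapply(n_per_group, seq_len)))
    structure(list(frequencies = freq,
                   group_label = rep(groups, n_per_group),
                   centroids = centroids, seed = as.integer(seed)),
              class = "frequency_cohort")
  })
}

#' Generate survival times whose hazard depends on planted program scores
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(sum(coefficients * scores))` per subject
#' (a proportional-hazards world). Censoring is independent exponential
#' with rate `baseline_hazard * censor_rate / (1 - censor_rate)`, so under
#' null covariates the expected censored fraction is `censor_rate`;
#' `censor_rate = 0` yields no censoring.
#'
#' @param scores subject x program matrix (or data.frame) of real-valued
#'   GEP scores.
#' @param coefficients log-hazard coefficient per score column.
#' @param baseline_hazard positive baseline event rate.
#' @param censor_rate target censored fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return a `survival_cohort` list with `time`, `event` (1 = death
#'   observed), `scores`, `true_log_hazard_coefficients` and `seed`.
#' @export
generate_survival_cohort <- function(scores, coefficients,
                                     baseline_hazard = 0.1,
                                     censor_rate = 0.3,
                                     seed = 1L) {
  scores <- as.matrix(scores)
  if (length(coefficients) != ncol(scores)) {
    stop("need one coefficient per score column", call. = FALSE)
  }
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("censor_rate must be in [0, 1)", call. = FALSE)
  }
  n <- nrow(scores)
  with_seed(seed, {
    rate <- baseline_hazard * exp(drop(scores %*% coefficients))
    t_event <- stats::rexp(n, rate = rate)
    if (censor_rate > 0) {
      c_rate <- baseline_hazard * censor_rate / (1 - censor_rate)
      t_cens <- stats::rexp(n, rate = c_rate)
    } else {
      t_cens <- rep(Inf, n)
    }
    structure(list(time = pmin(t_event, t_cens),
                   event = as.integer(t_event <= t_cens),
                   scores = scores,
                   true_log_hazard_coefficients = coefficients,
                   seed = as.integer(seed)),
              class = "survival_cohort")
  })
}
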