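#' Preprocess an expression matrix for NMF program discovery
#'
#' Applies `log2(x + 1)` to tame outliers, ranks genes by median absolute
#' deviation (MAD) descending, and keeps the top `n_top_genes` most
#' variable. Ties in MAD are broken by gene id so the selection is
#' deterministic.
#'
#' @param expression gene x sample matrix of nonnegative values (counts
#'   or TPM).
#' @param n_top_genes number of most-variable genes to keep (default
#'   5000).
#' @return a `preprocessed_matrix` list: `values` (log2-scale gene x
#'   sample matrix restricted to selected genes), `selected_genes`
#'   (ordered by variability), `provenance` (filter parameters).
#' @export
preprocess <- function(expression, n_top_genes = 5000L) {
  expression <- as.matrix(expression)
  stopifnot_nonneg(expression, "expression")
  if (is.null(rownames(expression))) {
    rownames(expression) <- paste0("gene", seq_len(nrow(expression)))
  }
  lg <- log2(expression + 1)
  mads <- apply(lg, 1, stats::mad)
  if (sum(mads > 0) < 2L) {
    stop("fewer than 2 genes with nonzero MAD", call. = FALSE)
  }
  if (n_top_genes > nrow(lg)) {
    warning("n_top_genes (", n_top_genes, ") exceeds available genes (",
            nrow(lg), "); keeping all", call. = FALSE)
    n_top_genes <- nrow(lg)
  }
  ord <- order(-mads, rownames(lg))
  sel <- rownames(lg)[ord[seq_len(n_top_genes)]]
  structure(list(values = lg[sel, , drop = FALSE],
                 selected_genes = sel,
                 provenance = list(n_top_genes = n_top_genes,
                                   transform = "log2(x+1)",
                                   ranking = "MAD descending, ties by gene id")),
            class = "preprocessed_matrix")
}

#' One seeded NMF run (multiplicative updates, Frobenius loss)
#'
#' Factorizes a nonnegative matrix `X ~ W H` at rank `k` by Lee-Seung
#' multiplicative updates. Initialization is uniform-random nonnegative,
#' deterministic in `seed`; the objective is non-increasing and iteration
#' stops at relative tolerance `tol` (checked every 10 iterations) or
#' `max_iter` iterations.
#'
#' @param matrix gene x sample nonnegative matrix (or a
#'   `preprocessed_matrix`).
#' @param k rank, `2 <= k < min(dim)`.
#' @param seed integer seed for the initialization.
#' @param max_iter,tol stopping rule (defaults 500, 1e-6).
#' @return an `nmf_run` list: `W` (gene x k), `H` (k x sample), `k`,
#'   `seed`, `objective` (final Frobenius reconstruction error),
#'   `iterations`, `converged`.
#' @export
nmf_run <- function(matrix, k, seed, max_iter = 500L, tol = 1e-6) {
  X <- if (inherits(matrix, "preprocessed_matrix")) matrix$values else as.matrix(matrix)
  stopifnot_nonneg(X, "matrix")
  m <- nrow(X); n <- ncol(X)
  if (k < 2L || k >= min(m, n)) {
    stop("k must satisfy 2 <= k < min(genes, samples) = ", min(m, n),
         call. = FALSE)
  }
  scale0 <- sqrt(mean(X) / k)
  init <- with_seed(seed, list(
    W = matrix(stats::runif(m * k, 0, 2 * scale0), m, k),
    H = matrix(stats::runif(k * n, 0, 2 * scale0), k, n)))
  fit <- nmf_mu_cpp(X, init$W, init$H, as.integer(max_iter), tol, 10L)
  W <- fit$W; H <- fit$H
  dimnames(W) <- list(rownames(X), paste0("F", seq_len(k)))
  dimnames(H) <- list(paste0("F", seq_len(k)), colnames(X))
  structure(list(W = W, H = H, k = as.integer(k), seed = as.integer(seed),
                 objective = fit$objective, iterations = fit$iterations,
                 converged = fit$converged),
            class = "nmf_run")
}

#' Connectivity matrix of one NMF run
#'
#' Assigns each sample to its dominant factor (argmax over its usage
#' column; ties go to the lowest factor index) and returns the binary
#' sample x sample matrix with entry 1 iff two samples share a factor.
#'
#' @param run an `nmf_run` (or a bare k x sample usage matrix).
#' @return binary sample x sample matrix with unit diagonal.
#' @export
connectivity_matrix <- function(run) {
  H <- if (inherits(run, "nmf_run")) run$H else as.matrix(run)
  zero <- colSums(H) == 0
  if (any(zero)) {
    bad <- colnames(H)[zero]
    if (is.null(bad)) bad <- which(zero)
    stop("all-zero usage column for sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  assign <- apply(H, 2, which.max)  # which.max takes the lowest index on ties
  C <- outer(assign, assign, "==") * 1
  dimnames(C) <- list(colnames(H), colnames(H))
  C
}

#' Consensus matrix and cophenetic correlation over repeated runs
#'
#' Averages the connectivity matrices of repeated same-rank runs into a
#' consensus matrix, then scores its stability by the cophenetic
#' correlation coefficient (CCC): Pearson correlation between the
#' consensus-derived distances `D = 1 - consensus` (upper triangle) and
#' the cophenetic distances of average-linkage hierarchical clustering of
#' `D`. A perfectly stable 0/1 block consensus is ultrametric and gives
#' CCC = 1; a degenerate `D` with zero variance gives `NA` with a
#' warning.
#'
#' @param runs list of `nmf_run`s at one rank over the same samples.
#' @return list with `consensus` (sample x sample, entries in `[0,1]`,
#'   symmetric, unit diagonal), `ccc`, `n_runs`.
#' @export
consensus_and_ccc <- function(runs) {
  if (length(runs) < 2L) stop("need at least 2 runs", call. = FALSE)
  conn <- lapply(runs, connectivity_matrix)
  n <- ncol(conn[[1]])
  if (!all(vapply(conn, ncol, 1L) == n)) {
    stop("runs cover different sample sets", call. = FALSE)
  }
  consensus <- Reduce(`+`, conn) / length(conn)
  D <- 1 - consensus
  dvec <- stats::as.dist(D)
  if (stats::sd(dvec) == 0) {
    warning("degenerate consensus (all off-diagonal entries equal); ",
            "CCC undefined", call. = FALSE)
    ccc <- NA_real_
  } else {
    hc <- stats::hclust(dvec, method = "average")
    ccc <- stats::cor(dvec, stats::cophenetic(hc))
  }
  list(consensus = consensus, ccc = ccc, n_runs = length(runs))
}

# Strict local maxima of a numeric sequence with plateau handling:
# a plateau counts once at its leftmost position; the first and last
# runs of the sequence are never candidates.
local_maxima <- function(x) {
  r <- rle(x)
  nrun <- length(r$values)
  if (nrun < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-nrun]))
  cand <- integer(0)
  for (j in 2:(nrun - 1L)) {
    if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L]) {
      cand <- c(cand, starts[j])
    }
  }
  cand
}

#' Rank-stability sweep: median CCC across a grid of ranks
#'
#' For each rank, performs `repeats` independent stability assessments,
#' each from `runs_per_rank` seeded NMF runs, and reports the median CCC.
#' Candidate ranks are the strict local maxima of the median-CCC profile
#' over the interior of the rank grid (plateaus count once at their
#' leftmost rank; endpoints are excluded). Per-run seeds are derived as
#' `mix_seed(seed, rank, repeat, run)` so the sweep is reproducible and
#' parallelizable.
#'
#' @param matrix gene x sample nonnegative matrix (or
#'   `preprocessed_matrix`).
#' @param ranks integer vector of ranks to sweep (default 3:30).
#' @param runs_per_rank NMF runs per stability assessment (default 50).
#' @param repeats independent assessments per rank (default 5).
#' @param seed global seed.
#' @param max_iter,tol passed to [nmf_run()].
#' @return a `rank_stability_profile` list: `ranks`, `median_ccc`,
#'   `ccc` (rank x repeat matrix), `repeats`, `candidate_ranks`.
#' @export
rank_stability_sweep <- function(matrix, ranks = 3:30, runs_per_rank = 50L,
                                 repeats = 5L, seed = 1L,
                                 max_iter = 500L, tol = 1e-6) {
  X <- if (inherits(matrix, "preprocessed_matrix")) matrix$values else as.matrix(matrix)
  lim <- min(dim(X))
  ok <- ranks >= 2L & ranks < lim
  if (any(!ok)) {
    warning("skipping rank(s) outside [2, ", lim - 1L, "]: ",
            paste(ranks[!ok], collapse = ", "), call. = FALSE)
    ranks <- ranks[ok]
  }
  if (length(ranks) == 0L) stop("no valid ranks to sweep", call. = FALSE)
  ccc <- matrix(NA_real_, length(ranks), repeats,
                dimnames = list(paste0("k", ranks), NULL))
  for (ri in seq_along(ranks)) {
    k <- ranks[ri]
    for (rep_i in seq_len(repeats)) {
      runs <- lapply(seq_len(runs_per_rank), function(run_i) {
        nmf_run(X, k, mix_seed(seed, k, rep_i, run_i),
                max_iter = max_iter, tol = tol)
      })
      ccc[ri, rep_i] <- consensus_and_ccc(runs)$ccc
    }
  }
  med <- apply(ccc, 1, stats::median, na.rm = TRUE)
  cand_idx <- local_maxima(med)
  candidates <- ranks[cand_idx]
  if (length(candidates) == 0L) {
    warning("no interior local maximum in the median CCC profile; ",
            "review the endpoints of the rank grid", call. = FALSE)
  }
  structure(list(ranks = ranks, median_ccc = stats::setNames(med, paste0("k", ranks)),
                 ccc = ccc, repeats = as.integer(repeats),
                 runs_per_rank = as.integer(runs_per_rank),
                 candidate_ranks = candidates, seed = as.integer(seed)),
            class = "rank_stability_profile")
}
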