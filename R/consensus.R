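#' Local outlier factor scores
#'
#' Density-based outlier scores (Breunig et al.): each point's local
#' reachability density is compared with that of its k-nearest
#' neighborhood; scores near 1 mean inlier, larger means more isolated
#' than its neighbors. Used to prune aberrant factor replicates before
#' the consensus medians. Implemented here because no installed package
#' provides it.
#'
#' @param x point x dimension matrix.
#' @param n_neighbors neighborhood size k (`1 <= k < nrow(x)`).
#' @return numeric vector of LOF scores, one per row of `x`.
#' @export
lof_scores <- function(x, n_neighbors) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- as.integer(n_neighbors)
  if (k < 1L || k >= n) stop("need 1 <= n_neighbors < nrow(x)", call. = FALSE)
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    kdist[i] <- sort(di, partial = k)[k]
    nbrs[[i]] <- which(di <= kdist[i])  # inclusive: ties enlarge the set
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    reach <- pmax(kdist[nbrs[[i]]], d[i, nbrs[[i]]])
    lrd[i] <- 1 / (mean(reach) + 1e-12)
  }
  vapply(seq_len(n), function(i) mean(lrd[nbrs[[i]]]) / lrd[i], numeric(1))
}

# L2-normalize each run's W columns and move the scale into H, removing
# the NMF scale ambiguity before replicates are pooled.
normalize_run <- function(run) {
  nrm <- l2_normalize_cols(run$W)
  W <- nrm$normalized
  H <- run$H * nrm$norms  # row i of H scaled by ||W[, i]||
  list(W = W, H = H)
}

#' Consensus factors from a list of NMF runs
#'
#' The replicate-pooling half of consensus factorization, exposed
#' separately so controlled corruption experiments can inject runs.
#' Steps: (1) each run's factors are column-L2-normalized (scale moved
#' into H); (2) the runs' W and H are concatenated into `W_big`
#' (gene x n_runs*k) and `H_big` (n_runs*k x sample); (3) the pooled
#' factor usage vectors (rows of `H_big`) are clustered by seeded k-means
#' into k clusters (10 restarts), labels transferred to `W_big`;
#' (4) within each cluster a `lof_contamination` fraction of members with
#' the highest LOF scores (on the usage vectors, `n_neighbors =
#' min(5, size - 1)`) is removed; clusters with fewer than 2 members skip
#' pruning with a warning; (5) element-wise medians of the retained
#' members form one consensus W column and H row per cluster; (6) W
#' columns are re-normalized to unit L2 with H rescaled accordingly.
#'
#' @param runs list of `nmf_run`s at the same rank.
#' @param k consensus rank (number of clusters).
#' @param lof_contamination fraction of each cluster flagged and removed
#'   (default 0.40).
#' @param seed seed for the k-means initialization.
#' @param cluster_on `"H"` (default: cluster usage vectors) or `"W"`
#'   (cluster gene-weight vectors).
#' @param prune set `FALSE` to skip LOF pruning (for comparison
#'   experiments).
#' @return a `gep_result`; see [consensus_factorization()].
#' @export
consensus_from_runs <- function(runs, k, lof_contamination = 0.40,
                                seed = 1L, cluster_on = c("H", "W"),
                                prune = TRUE) {
  cluster_on <- match.arg(cluster_on)
  if (length(runs) < 3L) stop("need n_runs >= 3", call. = FALSE)
  norm <- lapply(runs, normalize_run)
  W_big <- do.call(cbind, lapply(norm, `[[`, "W"))
  H_big <- do.call(rbind, lapply(norm, `[[`, "H"))
  feat <- if (cluster_on == "H") H_big else t(W_big)
  km <- with_seed(mix_seed(seed, k, 0L, 0L), {
    stats::kmeans(feat, centers = k, nstart = 10, iter.max = 100)
  })
  labels <- km$cluster
  W_con <- matrix(0, nrow(W_big), k,
                  dimnames = list(rownames(W_big), paste0("GEP", seq_len(k))))
  H_con <- matrix(0, k, ncol(H_big),
                  dimnames = list(paste0("GEP", seq_len(k)), colnames(H_big)))
  cluster_sizes <- retained_counts <- integer(k)
  for (cl in seq_len(k)) {
    members <- which(labels == cl)
    m <- length(members)
    cluster_sizes[cl] <- m
    if (m == 0L) {
      stop("cluster ", cl, " is empty; lower lof_contamination or n_runs",
           call. = FALSE)
    }
    retained <- members
    if (prune && m >= 2L) {
      n_out <- floor(lof_contamination * m)
      if (n_out > 0L) {
        lof <- lof_scores(H_big[members, , drop = FALSE],
                          n_neighbors = min(5L, m - 1L))
        retained <- members[order(lof)[seq_len(m - n_out)]]
      }
    } else if (prune && m < 2L) {
      warning("cluster ", cl, " has fewer than 2 members; pruning skipped",
              call. = FALSE)
    }
    if (length(retained) == 0L) {
      stop("cluster ", cl, " left empty after pruning; ",
           "lower lof_contamination", call. = FALSE)
    }
    retained_counts[cl] <- length(retained)
    W_con[, cl] <- apply(W_big[, retained, drop = FALSE], 1, stats::median)
    H_con[cl, ] <- apply(H_big[retained, , drop = FALSE], 2, stats::median)
  }
  nrm <- l2_normalize_cols(W_con)
  structure(list(W_Con = nrm$normalized,
                 H_Con = H_con * nrm$norms,
                 cluster_sizes = cluster_sizes,
                 retained_counts = retained_counts,
                 k = as.integer(k), n_runs = length(runs),
                 lof_contamination = lof_contamination,
                 cluster_on = cluster_on),
            class = "gep_result")
}

#' Consensus NMF factorization at a chosen rank
#'
#' Runs `n_runs` seeded NMF factorizations, pools them, clusters the
#' replicate factors by k-means, prunes outlier replicates by local
#' outlier factor (40% cutoff by default), and takes element-wise medians
#' to form the consensus matrices `W_Con` (gene weights, columns unit-L2)
#' and `H_Con` (sample usages). See [consensus_from_runs()] for the exact
#' pooling steps.
#'
#' @param matrix gene x sample nonnegative matrix (or
#'   `preprocessed_matrix`).
#' @param k consensus rank (a stable candidate from
#'   [rank_stability_sweep()]).
#' @param n_runs number of factorizations pooled (default 10).
#' @param lof_contamination fraction of each replicate cluster removed as
#'   outliers (default 0.40).
#' @param seed global seed; run seeds are `mix_seed(seed, k, 0, run)`.
#' @param cluster_on cluster replicate usage vectors (`"H"`, default) or
#'   gene-weight vectors (`"W"`).
#' @param max_iter,tol passed to [nmf_run()].
#' @return a `gep_result` list: `W_Con`, `H_Con`, `cluster_sizes`,
#'   `retained_counts`, `k`, `n_runs`.
#' @export
consensus_factorization <- function(matrix, k, n_runs = 10L,
                                    lof_contamination = 0.40, seed = 1L,
                                    cluster_on = c("H", "W"),
                                    max_iter = 500L, tol = 1e-6) {
  cluster_on <- match.arg(cluster_on)
  runs <- lapply(seq_len(n_runs), function(run_i) {
    nmf_run(matrix, k, mix_seed(seed, k, 0L, run_i),
            max_iter = max_iter, tol = tol)
  })
  consensus_from_runs(runs, k, lof_contamination = lof_contamination,
                      seed = seed, cluster_on = cluster_on)
}

#' Match estimated programs to reference programs by cosine similarity
#'
#' Builds the cosine-similarity matrix between the columns of two weight
#' matrices and solves the optimal one-to-one assignment (Hungarian
#' algorithm), returning the matched pairs and their mean cosine — the
#' recovery metric used to validate consensus factors against planted
#' ground truth.
#'
#' @param W_est,W_ref gene x k weight matrices over the same genes (equal
#'   k).
#' @return list with `assignment` (reference column matched to each
#'   estimated column), `pair_cosine`, `mean_cosine`, `cosine` (full
#'   k x k matrix).
#' @export
match_programs <- function(W_est, W_ref) {
  W_est <- as.matrix(W_est); W_ref <- as.matrix(W_ref)
  if (!is.null(rownames(W_est)) && !is.null(rownames(W_ref)) &&
      !identical(rownames(W_est), rownames(W_ref))) {
    if (!setequal(rownames(W_est), rownames(W_ref))) {
      stop("weight matrices cover different gene sets", call. = FALSE)
    }
    W_est <- W_est[rownames(W_ref), , drop = FALSE]
  }
  if (nrow(W_est) != nrow(W_ref) || ncol(W_est) != ncol(W_ref)) {
    stop("weight matrices must share gene rows and have equal rank",
         call. = FALSE)
  }
  ue <- l2_normalize_cols(W_est)$normalized
  ur <- l2_normalize_cols(W_ref)$normalized
  cosine <- crossprod(ue, ur)  # k x k
  sol <- clue::solve_LSAP(cosine - min(cosine) + 1e-9, maximum = TRUE)
  assignment <- as.integer(sol)
  pair_cosine <- cosine[cbind(seq_len(ncol(cosine)), assignment)]
  list(assignment = assignment, pair_cosine = pair_cosine,
       mean_cosine = mean(pair_cosine), cosine = cosine)
}
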