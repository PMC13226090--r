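#' Z-score compartment frequencies across pooled cohorts
#'
#' Pools one or more sample x feature frequency tables and standardizes
#' each feature over *all* samples jointly (not per cohort), so that
#' cohorts of different species land on a common scale before aggregation
#' or embedding. Standardization uses the population standard deviation
#' (divide by n), so a two-value feature `{0, 2}` maps to `{-1, +1}`.
#' Zero-variance features are mapped to all-zero columns with a warning.
#'
#' @param frequencies a sample x feature matrix/data.frame, or a list of
#'   them (one per cohort) sharing identical feature columns.
#' @return a `feature_zscores` list: `zscores` (pooled sample x feature
#'   matrix), `feature_means`, `feature_sds` (recorded for
#'   reproducibility), and `cohort` (the cohort index of each row).
#' @export
combined_zscore <- function(frequencies) {
  if (!is.list(frequencies) || is.data.frame(frequencies)) {
    frequencies <- list(frequencies)
  }
  tabs <- lapply(frequencies, function(x) as.matrix(x))
  feats <- colnames(tabs[[1]])
  if (is.null(feats)) stop("frequency tables need feature column names",
                           call. = FALSE)
  for (i in seq_along(tabs)) {
    if (!identical(sort(colnames(tabs[[i]])), sort(feats))) {
      only_a <- setdiff(feats, colnames(tabs[[i]]))
      only_b <- setdiff(colnames(tabs[[i]]), feats)
      stop("feature mismatch across cohorts: missing {",
           paste(only_a, collapse = ", "), "}; extra {",
           paste(only_b, collapse = ", "), "}", call. = FALSE)
    }
    tabs[[i]] <- tabs[[i]][, feats, drop = FALSE]
  }
  pooled <- do.call(rbind, tabs)
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2, pop_sd)
  z <- sweep(pooled, 2, mu, "-")
  const <- sdv == 0 | is.na(sdv)
  if (any(const)) {
    warning("zero-variance feature(s) mapped to 0: ",
            paste(feats[const], collapse = ", "), call. = FALSE)
    z[, const] <- 0
  }
  z[, !const] <- sweep(z[, !const, drop = FALSE], 2, sdv[!const], "/")
  structure(list(zscores = z, feature_means = mu, feature_sds = sdv,
                 cohort = rep(seq_along(tabs), vapply(tabs, nrow, 1L))),
            class = "feature_zscores")
}

#' Aggregate a sample x feature table by group
#'
#' One row per group, the chosen statistic applied feature-wise. The
#' median is the default used before cosine-similarity mapping of tumor
#' models onto archetypes; the mean serves the embedding path.
#'
#' @param table sample x feature matrix/data.frame.
#' @param group_labels one label per row of `table`.
#' @param statistic `"median"` or `"mean"`.
#' @return group x feature matrix with groups as rownames.
#' @export
aggregate_by_group <- function(table, group_labels,
                               statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  table <- as.matrix(table)
  if (length(group_labels) != nrow(table)) {
    stop("every sample needs a group label", call. = FALSE)
  }
  groups <- unique(group_labels)
  if (any(is.na(group_labels))) stop("missing group label", call. = FALSE)
  fun <- if (statistic == "median") stats::median else mean
  out <- t(vapply(groups, function(g) {
    rows <- table[group_labels == g, , drop = FALSE]
    if (nrow(rows) == 0L) stop("empty group: ", g, call. = FALSE)
    apply(rows, 2, fun)
  }, numeric(ncol(table))))
  rownames(out) <- groups
  colnames(out) <- colnames(table)
  out
}

#' Cosine similarity between the rows of two group x feature tables
#'
#' Each row vector is normalized to unit length; similarity is the matrix
#' product of the normalized rows, and distance is `1 - similarity`. With
#' `cols_table` omitted, the self-similarity matrix is symmetric with a
#' unit diagonal.
#'
#' @param rows_table,cols_table group x feature tables with identical
#'   feature columns.
#' @return a `similarity_matrix` list: `similarity` (rows of `rows_table`
#'   x rows of `cols_table`), `distance`, `rows`, `cols`.
#' @export
cosine_similarity_matrix <- function(rows_table, cols_table = rows_table) {
  a <- as.matrix(rows_table)
  b <- as.matrix(cols_table)
  if (!identical(colnames(a), colnames(b))) {
    stop("feature columns must match between the two tables", call. = FALSE)
  }
  norm_rows <- function(m, tag) {
    nrm <- sqrt(rowSums(m^2))
    if (any(nrm == 0)) {
      bad <- rownames(m)[nrm == 0]
      if (is.null(bad)) bad <- which(nrm == 0)
      stop("all-zero row(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    m / nrm
  }
  ua <- norm_rows(a)
  ub <- norm_rows(b)
  sim <- ua %*% t(ub)
  sim <- pmin(pmax(sim, -1), 1)
  structure(list(similarity = sim, distance = 1 - sim,
                 rows = rownames(a), cols = rownames(b)),
            class = "similarity_matrix")
}

#' Relative variance (squared coefficient of variation) per group
#'
#' For each group and feature, the population variance divided by the
#' squared group mean — a scale-free dispersion measure used to compare
#' compositional heterogeneity between cohorts. Features with group mean
#' zero are undefined and reported as `NA`.
#'
#' @param table sample x feature matrix/data.frame of raw frequencies.
#' @param group_labels one label per row.
#' @return group x feature matrix of CV^2 values.
#' @export
relative_variance <- function(table, group_labels) {
  table <- as.matrix(table)
  if (length(group_labels) != nrow(table)) {
    stop("every sample needs a group label", call. = FALSE)
  }
  groups <- unique(group_labels)
  out <- t(vapply(groups, function(g) {
    rows <- table[group_labels == g, , drop = FALSE]
    if (nrow(rows) < 2L) stop("group ", g, " has fewer than 2 samples",
                              call. = FALSE)
    v <- apply(rows, 2, pop_var)
    m <- colMeans(rows)
    ifelse(m == 0, NA_real_, v / m^2)
  }, numeric(ncol(table))))
  rownames(out) <- groups
  colnames(out) <- colnames(table)
  out
}

# Shared engine for Pearson + BH correlation matrices. Handles the square
# (single-table, all off-diagonal pairs form the BH family) and the
# rectangular (two tables, all cross pairs form the family) cases with
# pairwise-complete observations. p-values come from the t-distribution
# transform of r; pairs with undefined r (constant feature, n < 3) are
# reported NA and excluded from the BH family.
cor_bh_engine <- function(x, y = NULL) {
  x <- as.matrix(x)
  square <- is.null(y)
  y <- if (square) x else as.matrix(y)
  px <- ncol(x); py <- ncol(y)
  r <- p <- matrix(NA_real_, px, py,
                   dimnames = list(colnames(x), colnames(y)))
  n_used <- matrix(0L, px, py, dimnames = dimnames(r))
  for (i in seq_len(px)) {
    for (j in seq_len(py)) {
      if (square && j < i) next
      ok <- stats::complete.cases(x[, i], y[, j])
      n <- sum(ok)
      n_used[i, j] <- n
      if (square && i == j) { r[i, j] <- 1; next }
      if (n < 3L) next
      xi <- x[ok, i]; yj <- y[ok, j]
      if (pop_sd(xi) == 0 || pop_sd(yj) == 0) next
      rij <- stats::cor(xi, yj)
      r[i, j] <- rij
      if (abs(rij) >= 1) {
        p[i, j] <- 0
      } else {
        tt <- rij * sqrt((n - 2) / (1 - rij^2))
        p[i, j] <- 2 * stats::pt(-abs(tt), df = n - 2)
      }
      if (square) {
        r[j, i] <- r[i, j]; p[j, i] <- p[i, j]; n_used[j, i] <- n
      }
    }
  }
  # BH over the tested family: upper-triangle off-diagonal pairs (square)
  # or all pairs (rectangular), NA pairs excluded
  padj <- matrix(NA_real_, px, py, dimnames = dimnames(r))
  if (square) {
    idx <- which(upper.tri(p), arr.ind = TRUE)
  } else {
    idx <- as.matrix(expand.grid(seq_len(px), seq_len(py)))
  }
  pv <- p[idx]
  keep <- !is.na(pv)
  if (any(keep)) {
    adj <- stats::p.adjust(pv[keep], method = "BH")
    padj[idx[keep, , drop = FALSE]] <- adj
  }
  if (square) {
    padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  }
  structure(list(pearson_r = r, p_raw = p, p_adjusted = padj,
                 n_used = n_used),
            class = "correlation_matrix")
}

#' Pairwise Pearson correlations with Benjamini-Hochberg correction
#'
#' Computes the feature x feature Pearson correlation matrix of a sample
#' table with two-sided p-values from the t-distribution transform of r,
#' pairwise-complete observation handling (per-pair n recorded), and BH
#' adjustment over all tested off-diagonal pairs jointly. Constant
#' features give undefined r for their pairs; those are reported `NA` and
#' excluded from the BH family.
#'
#' @param table sample x feature matrix/data.frame.
#' @return a `correlation_matrix` list: `pearson_r`, `p_raw`,
#'   `p_adjusted`, `n_used`.
#' @export
pairwise_pearson_bh <- function(table) {
  cor_bh_engine(table)
}
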