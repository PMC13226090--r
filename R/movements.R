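#' Percentile-normalized gene score per sample
#'
#' For each signature gene, every sample's expression value is replaced
#' by its fractional rank across samples (`rank / n`, average ranks on
#' ties); the score is the mean of these normalized values over the
#' signature genes. Being rank-based, the score is invariant under any
#' monotone per-gene transformation of expression. Signature genes
#' missing from the matrix are dropped with a warning.
#'
#' @param expression gene x sample matrix.
#' @param signature a `gene_signature`, a character vector of genes, or a
#'   list of either (one score column per signature).
#' @return named numeric vector of scores in `(0, 1]` (one per sample),
#'   or a sample x program matrix when a list of signatures is given.
#' @export
gene_score <- function(expression, signature) {
  expression <- as.matrix(expression)
  if (ncol(expression) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (is.list(signature) && !inherits(signature, "gene_signature")) {
    cols <- lapply(signature, function(s) gene_score(expression, s))
    names(cols) <- vapply(seq_along(signature), function(i) {
      s <- signature[[i]]
      if (inherits(s, "gene_signature")) s$program else paste0("S", i)
    }, character(1))
    return(do.call(cbind, cols))
  }
  genes <- if (inherits(signature, "gene_signature")) signature$genes else signature
  present <- intersect(genes, rownames(expression))
  if (length(present) == 0L) {
    stop("no signature genes present in the expression matrix",
         call. = FALSE)
  }
  if (length(present) < length(genes)) {
    warning(length(genes) - length(present),
            " signature gene(s) missing from the expression matrix",
            call. = FALSE)
  }
  n <- ncol(expression)
  pct <- t(apply(expression[present, , drop = FALSE], 1,
                 function(x) rank(x, ties.method = "average") / n))
  colMeans(pct)
}

#' Correlate T-cell against myeloid program scores across samples
#'
#' Pearson correlation of every (T program, myeloid program) score pair
#' over the samples shared by the two score tables (inner join on sample
#' ids), with two-sided p-values and BH adjustment over all pairs of the
#' matrix jointly. A significant pair is a "movement": coordinated usage
#' of a T-cell and a myeloid program across tumors.
#'
#' @param t_scores,my_scores sample x program score matrices with sample
#'   ids as rownames.
#' @return a `correlation_matrix` (T programs x myeloid programs); see
#'   [pairwise_pearson_bh()].
#' @export
movement_correlation <- function(t_scores, my_scores) {
  t_scores <- as.matrix(t_scores)
  my_scores <- as.matrix(my_scores)
  if (is.null(rownames(t_scores)) || is.null(rownames(my_scores))) {
    stop("score tables need sample ids as rownames", call. = FALSE)
  }
  shared <- intersect(rownames(t_scores), rownames(my_scores))
  if (length(shared) < 3L) {
    stop("fewer than 3 shared samples between the score tables",
         call. = FALSE)
  }
  cor_bh_engine(t_scores[shared, , drop = FALSE],
                my_scores[shared, , drop = FALSE])
}

#' Bin subjects by score quantiles into high / low / excluded
#'
#' Per program: scores strictly above the `q_high` quantile are `high`,
#' scores at or below the `q_low` quantile are `low` (ties at a
#' threshold fall to the lower bin, deterministically), everything else
#' is `excluded`. With `q_low = q_high = 0.5` the cohort splits into
#' top/bottom halves; `0.3 / 0.7` gives the top-30%/bottom-30% design
#' with the middle excluded. When exactly two programs are binned, a
#' joint label (e.g. `"T3_high.My2_high"`) crosses the per-program bins;
#' subjects excluded in either program get `NA`.
#'
#' @param scores sample x program matrix (or a vector for one program).
#' @param q_low,q_high quantile thresholds, `0 < q_low <= q_high < 1`.
#' @return a `binned_cohort` list: `bins` (sample x program character
#'   matrix), `joint` (character vector or `NULL`), `thresholds`.
#' @export
bin_by_quantile <- function(scores, q_low = 0.5, q_high = 0.5) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1,
                                             dimnames = list(names(scores), "score"))
  scores <- as.matrix(scores)
  if (!(q_low > 0 && q_low <= q_high && q_high < 1)) {
    stop("need 0 < q_low <= q_high < 1", call. = FALSE)
  }
  if (is.null(colnames(scores))) colnames(scores) <- paste0("P", seq_len(ncol(scores)))
  bins <- matrix("excluded", nrow(scores), ncol(scores),
                 dimnames = dimnames(scores))
  thresholds <- matrix(NA_real_, 2, ncol(scores),
                       dimnames = list(c("low", "high"), colnames(scores)))
  for (p in seq_len(ncol(scores))) {
    s <- scores[, p]
    t_low <- stats::quantile(s, q_low, names = FALSE)
    t_high <- stats::quantile(s, q_high, names = FALSE)
    thresholds[, p] <- c(t_low, t_high)
    bins[s <= t_low, p] <- "low"
    bins[s > t_high, p] <- "high"
    if (!any(bins[, p] == "high") || !any(bins[, p] == "low")) {
      stop("empty high or low group for program ", colnames(scores)[p],
           call. = FALSE)
    }
  }
  joint <- NULL
  if (ncol(scores) == 2L) {
    joint <- ifelse(bins[, 1] == "excluded" | bins[, 2] == "excluded",
                    NA_character_,
                    paste0(colnames(scores)[1], "_", bins[, 1], ".",
                           colnames(scores)[2], "_", bins[, 2]))
    names(joint) <- rownames(scores)
  }
  structure(list(bins = bins, joint = joint,
                 thresholds = thresholds,
                 q_low = q_low, q_high = q_high),
            class = "binned_cohort")
}

# Coerce the cohort argument of the survival operations into a
# data.frame with time and event columns.
as_surv_df <- function(cohort) {
  if (inherits(cohort, "survival_cohort")) {
    data.frame(time = cohort$time, event = cohort$event)
  } else {
    df <- as.data.frame(cohort)
    stopifnot(all(c("time", "event") %in% names(df)))
    df[, c("time", "event")]
  }
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator with right censoring (deaths precede
#' censorings at tied times), one step function per group, with at-risk
#' counts and the median survival time (first time the curve reaches
#' 0.5 or below; `NA` if it never does). With two or more groups the
#' log-rank test is attached.
#'
#' @param cohort a `survival_cohort` or data.frame with `time` and
#'   `event` columns.
#' @param groups group label per subject (a single label is allowed).
#' @return a `survival_curves` list: `curves` (per group: data.frame
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`), `median_survival`
#'   (named vector), `logrank_statistic`, `logrank_p` (NA for a single
#'   group).
#' @export
kaplan_meier <- function(cohort, groups = NULL) {
  df <- as_surv_df(cohort)
  if (any(df$time <= 0)) stop("times must be > 0", call. = FALSE)
  if (is.null(groups)) groups <- rep("all", nrow(df))
  keep <- !is.na(groups)
  df <- df[keep, , drop = FALSE]
  groups <- as.character(groups[keep])
  if (any(table(groups) == 0L) || nrow(df) == 0L) {
    stop("empty group", call. = FALSE)
  }
  levs <- unique(groups)
  curves <- list()
  med <- stats::setNames(rep(NA_real_, length(levs)), levs)
  for (g in levs) {
    sub <- df[groups == g, , drop = FALSE]
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub)
    curves[[g]] <- data.frame(time = fit$time, n_risk = fit$n.risk,
                              n_event = fit$n.event,
                              n_censor = fit$n.censor, surv = fit$surv)
    hit <- which(fit$surv <= 0.5)
    if (length(hit) > 0) med[g] <- fit$time[min(hit)]
  }
  lr <- if (length(levs) >= 2L) logrank_test(df, groups) else
    list(statistic = NA_real_, p = NA_real_)
  structure(list(curves = curves, median_survival = med,
                 logrank_statistic = lr$statistic, logrank_p = lr$p,
                 groups = levs),
            class = "survival_curves")
}

#' Log-rank test across survival groups
#'
#' Standard (unweighted) log-rank chi-square across k groups with
#' `k - 1` degrees of freedom and the asymptotic two-sided p-value.
#' A cohort with no events at all returns statistic 0, p = 1 with a
#' warning.
#'
#' @param cohort a `survival_cohort` or data.frame with `time`, `event`.
#' @param groups group label per subject (>= 2 nonempty groups).
#' @return list with `statistic`, `df`, `p`.
#' @export
logrank_test <- function(cohort, groups) {
  df <- as_surv_df(cohort)
  keep <- !is.na(groups)
  df <- df[keep, , drop = FALSE]
  groups <- as.character(groups[keep])
  levs <- unique(groups)
  if (length(levs) < 2L) stop("need >= 2 nonempty groups", call. = FALSE)
  if (sum(df$event) == 0L) {
    warning("no events in any group; log-rank undefined, returning p = 1",
            call. = FALSE)
    return(list(statistic = 0, df = length(levs) - 1L, p = 1))
  }
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ g,
                               data = cbind(df, g = groups))
  k <- length(levs)
  list(statistic = unname(sd_fit$chisq), df = k - 1L,
       p = stats::pchisq(sd_fit$chisq, df = k - 1L, lower.tail = FALSE))
}
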