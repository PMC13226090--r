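#' TMM normalization factors and counts per million
#'
#' Between-sample normalization for count libraries via the trimmed mean
#' of M-values (reference sample = upper quartile closest to the mean
#' upper quartile; 30% M-trim, 5% A-trim, inverse-variance weights;
#' factors rescaled to geometric mean 1), followed by counts-per-million
#' on the factor-adjusted library sizes. Delegates to edgeR, whose
#' published defaults are exactly these parameters.
#'
#' @param counts gene x sample matrix of nonnegative counts.
#' @return list with `factors` (per-sample scaling factors) and `cpm`
#'   (gene x sample CPM table).
#' @export
tmm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot_nonneg(counts, "counts")
  if (ncol(counts) < 1L) stop("need at least one sample", call. = FALSE)
  zero <- colSums(counts) == 0
  if (any(zero)) {
    bad <- colnames(counts)[zero]
    if (is.null(bad)) bad <- which(zero)
    stop("all-zero sample(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (ncol(counts) == 1L) {
    f <- stats::setNames(1, colnames(counts))
    return(list(factors = f, cpm = counts / sum(counts) * 1e6))
  }
  dge <- edgeR::DGEList(counts = counts)
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  list(factors = stats::setNames(dge$samples$norm.factors,
                                 colnames(counts)),
       cpm = edgeR::cpm(dge, normalized.lib.sizes = TRUE))
}

#' Upper-quartile normalization with log2 transform
#'
#' Divides each sample's counts by its 75th percentile gene count and
#' applies `log2(x + 1)` (pseudocount 1, matching the log2 usage
#' elsewhere in the pipeline). A count equal to the sample's upper
#' quartile therefore maps to `log2(2) = 1`, and a zero count to 0.
#'
#' @param counts gene x sample matrix of nonnegative counts.
#' @return gene x sample matrix of normalized, log2-transformed values.
#' @export
upper_quartile_normalize <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot_nonneg(counts, "counts")
  q75 <- apply(counts, 2, stats::quantile, probs = 0.75, names = FALSE)
  if (any(q75 == 0)) {
    bad <- colnames(counts)[q75 == 0]
    if (is.null(bad)) bad <- which(q75 == 0)
    stop("75th-percentile count is zero for sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  log2(sweep(counts, 2, q75, "/") + 1)
}

#' Pseudobulk single-cell expression by (compartment, sample) group
#'
#' Arithmetic mean per gene within each (compartment, sample) group,
#' mimicking sorted-population bulk profiles. Expression is taken as
#' provided (already normalized per cell); no re-normalization happens
#' here.
#'
#' @param expression gene x cell matrix.
#' @param compartment,sample one label per cell.
#' @param species species tag recorded on the profile.
#' @return a `compartment_profile` list: `values` (gene x group matrix,
#'   columns named `compartment.sample`), `compartment`, `sample`,
#'   `species`, `normalization_state` (`"raw"`).
#' @export
pseudobulk_mean <- function(expression, compartment, sample,
                            species = NA_character_) {
  expression <- as.matrix(expression)
  if (length(compartment) != ncol(expression) ||
      length(sample) != ncol(expression)) {
    stop("every cell needs a (compartment, sample) label", call. = FALSE)
  }
  if (any(is.na(compartment)) || any(is.na(sample))) {
    stop("every cell needs a (compartment, sample) label", call. = FALSE)
  }
  key <- paste(compartment, sample, sep = ".")
  groups <- unique(key)
  vals <- vapply(groups, function(g) {
    rowMeans(expression[, key == g, drop = FALSE])
  }, numeric(nrow(expression)))
  vals <- matrix(vals, nrow = nrow(expression),
                 dimnames = list(rownames(expression), groups))
  ord <- match(groups, key)
  structure(list(values = vals,
                 compartment = compartment[ord],
                 sample = sample[ord],
                 species = species,
                 normalization_state = "raw"),
            class = "compartment_profile")
}

#' Z-score a compartment profile gene-wise across compartments
#'
#' For each gene, z-scores the (log-scale) values over all compartment
#' columns of the same species jointly, so a gene's value says how high
#' it is in one compartment relative to the other compartments of that
#' species — the scaling used before cross-species side-by-side display.
#' Uses the population standard deviation; zero-variance genes map to 0.
#'
#' @param profile a `compartment_profile` (log-scale values) or a plain
#'   gene x compartment matrix.
#' @return the profile with z-scored `values` and
#'   `normalization_state = "zscored"`.
#' @export
zscore_across_compartments <- function(profile) {
  plain <- !inherits(profile, "compartment_profile")
  vals <- if (plain) as.matrix(profile) else profile$values
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1, pop_sd)
  z <- (vals - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  if (plain) return(z)
  profile$values <- z
  profile$normalization_state <- "zscored"
  profile
}

#' Restrict two expression profiles to one-to-one ortholog pairs
#'
#' Filters the ortholog map to strictly one-to-one pairs (each gene at
#' most once on each side), restricts to pairs present in both profiles,
#' and returns the two tables on a shared gene axis (named by the
#' species-A gene ids). Unmapped and many-to-many genes are dropped and
#' counted in the report.
#'
#' @param profile_a,profile_b gene x column matrices (or
#'   `compartment_profile`s) for species A and B.
#' @param map data.frame with columns `gene_a`, `gene_b`.
#' @return list with `a`, `b` (row-aligned matrices), `pairs` (the
#'   surviving map) and `report` (counts: `total_a`, `retained`,
#'   `dropped_multi`, `dropped_unmapped`).
#' @export
map_orthologs <- function(profile_a, profile_b, map) {
  va <- if (inherits(profile_a, "compartment_profile")) profile_a$values else as.matrix(profile_a)
  vb <- if (inherits(profile_b, "compartment_profile")) profile_b$values else as.matrix(profile_b)
  if (nrow(map) == 0L) stop("ortholog map is empty", call. = FALSE)
  map <- unique(map[, c("gene_a", "gene_b")])
  multi <- map$gene_a %in% map$gene_a[duplicated(map$gene_a)] |
    map$gene_b %in% map$gene_b[duplicated(map$gene_b)]
  one2one <- map[!multi, , drop = FALSE]
  genes_a <- rownames(va)
  multi_genes_a <- intersect(genes_a, unique(map$gene_a[multi]))
  keep <- one2one$gene_a %in% genes_a & one2one$gene_b %in% rownames(vb)
  pairs <- one2one[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    stop("no genes survive one-to-one ortholog mapping", call. = FALSE)
  }
  a <- va[pairs$gene_a, , drop = FALSE]
  b <- vb[pairs$gene_b, , drop = FALSE]
  rownames(b) <- pairs$gene_a
  n_multi <- length(multi_genes_a)
  report <- c(total_a = length(genes_a),
              retained = nrow(pairs),
              dropped_multi = n_multi,
              dropped_unmapped = length(genes_a) - nrow(pairs) - n_multi)
  list(a = a, b = b, pairs = pairs, report = report)
}
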