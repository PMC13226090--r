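#' Top-weight gene signatures of a set of programs
#'
#' For each program (column of the consensus weight matrix), the top `n`
#' genes by descending weight, ties broken by gene id for determinism.
#' Zero-weight genes never enter a signature; if fewer than `n` genes
#' have nonzero weight the signature is shorter, with a warning.
#'
#' @param gep a `gep_result` (or a bare gene x program weight matrix).
#' @param n signature size (20 for T-cell programs, 50 for myeloid, by
#'   the conventions this pipeline follows).
#' @return list of `gene_signature`s: each has `program`, `genes`
#'   (ordered), `n`, `universe_size` (genes eligible, i.e. rows of W).
#' @export
top_genes <- function(gep, n) {
  W <- if (inherits(gep, "gep_result")) gep$W_Con else as.matrix(gep)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (is.null(rownames(W))) stop("weight matrix needs gene rownames",
                                 call. = FALSE)
  if (is.null(colnames(W))) colnames(W) <- paste0("GEP", seq_len(ncol(W)))
  lapply(seq_len(ncol(W)), function(p) {
    w <- W[, p]
    nz <- w > 0
    if (sum(nz) < n) {
      warning("program ", colnames(W)[p], ": only ", sum(nz),
              " nonzero-weight genes for a size-", n, " signature",
              call. = FALSE)
    }
    ord <- order(-w[nz], names(w)[nz])
    genes <- names(w)[nz][ord][seq_len(min(n, sum(nz)))]
    structure(list(program = colnames(W)[p], genes = genes,
                   n = length(genes), universe_size = nrow(W)),
              class = "gene_signature")
  })
}

#' Two-sided Fisher's exact test for gene-set overlap
#'
#' Exact hypergeometric test of the 2x2 table (in A and B / A only /
#' B only / neither) over a stated gene universe. The two-sided p-value
#' sums all hypergeometric outcomes whose probability does not exceed
#' that of the observed overlap.
#'
#' @param sig_a,sig_b gene signatures (`gene_signature`s or character
#'   vectors); duplicates are removed.
#' @param universe_size number of genes eligible in both analyses; must
#'   be at least `|A union B|`.
#' @param alternative `"two.sided"` (default) or `"greater"` (enrichment
#'   only).
#' @return the p-value.
#' @export
fisher_overlap_test <- function(sig_a, sig_b, universe_size,
                                alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  a <- unique(if (inherits(sig_a, "gene_signature")) sig_a$genes else sig_a)
  b <- unique(if (inherits(sig_b, "gene_signature")) sig_b$genes else sig_b)
  N <- as.integer(universe_size)
  if (length(union(a, b)) > N) {
    stop("inconsistent universe: |A union B| = ", length(union(a, b)),
         " exceeds universe_size = ", N, call. = FALSE)
  }
  x <- length(intersect(a, b))
  m <- length(a); nb <- length(b)
  support <- max(0L, m + nb - N):min(m, nb)
  dens <- stats::dhyper(support, m, N - m, nb)
  d_obs <- stats::dhyper(x, m, N - m, nb)
  if (alternative == "greater") {
    sum(dens[support >= x])
  } else {
    min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
  }
}

#' Jaccard / Fisher match table between two sets of gene signatures
#'
#' Translates the second set's genes through a one-to-one ortholog map
#' (many-to-many pairs are filtered out first), then computes, for every
#' program pair, the Jaccard index `|A n B| / |A u B|` and a Fisher's
#' exact p-value for the overlap over the stated universe. Signatures
#' that are empty after mapping give missing (`NA`) entries.
#'
#' @param signatures_a,signatures_b lists of `gene_signature`s (see
#'   [top_genes()]); set B is the one translated through the map.
#' @param ortholog_map optional data.frame with columns `gene_a`,
#'   `gene_b`; omit for same-namespace comparisons.
#' @param universe character vector of eligible genes (A namespace, after
#'   mapping) or a single count. Defaults, with a message, to the union
#'   of all (mapped) signature genes — the minimal consistent universe;
#'   pass the intersection of the two analyses' eligible gene sets for
#'   calibrated p-values.
#' @param alpha significance threshold for the `significant` flag.
#' @param p_adjust apply BH adjustment across all pairs (default off:
#'   raw Fisher significance is what gets annotated).
#' @param alternative passed to [fisher_overlap_test()].
#' @return a `match_table` list: `pairs` (long data.frame with
#'   `program_a`, `program_b`, `n_a`, `n_b`, `overlap`, `jaccard`,
#'   `fisher_p`, `significant`), `jaccard` and `fisher_p` matrices,
#'   `universe_size`.
#' @export
jaccard_matrix <- function(signatures_a, signatures_b, ortholog_map = NULL,
                           universe = NULL, alpha = 0.05, p_adjust = FALSE,
                           alternative = "two.sided") {
  get_genes <- function(s) unique(if (inherits(s, "gene_signature")) s$genes else s)
  genes_a <- lapply(signatures_a, get_genes)
  genes_b <- lapply(signatures_b, get_genes)
  name_of <- function(sigs, prefix) {
    vapply(seq_along(sigs), function(i) {
      s <- sigs[[i]]
      if (inherits(s, "gene_signature")) s$program else paste0(prefix, i)
    }, character(1))
  }
  names_a <- name_of(signatures_a, "A")
  names_b <- name_of(signatures_b, "B")
  if (!is.null(ortholog_map)) {
    map <- unique(ortholog_map[, c("gene_a", "gene_b")])
    multi <- map$gene_a %in% map$gene_a[duplicated(map$gene_a)] |
      map$gene_b %in% map$gene_b[duplicated(map$gene_b)]
    map <- map[!multi, , drop = FALSE]
    lut <- stats::setNames(map$gene_a, map$gene_b)
    genes_b <- lapply(genes_b, function(g) unname(lut[g][!is.na(lut[g])]))
  }
  if (is.null(universe)) {
    universe_size <- length(unique(unlist(c(genes_a, genes_b))))
    message("no universe supplied; using the union of signature genes (",
            universe_size, ")")
  } else if (is.character(universe)) {
    genes_a <- lapply(genes_a, intersect, universe)
    genes_b <- lapply(genes_b, intersect, universe)
    universe_size <- length(unique(universe))
  } else {
    universe_size <- as.integer(universe)
  }
  na <- length(genes_a); nb <- length(genes_b)
  J <- P <- matrix(NA_real_, na, nb, dimnames = list(names_a, names_b))
  OV <- matrix(NA_integer_, na, nb, dimnames = list(names_a, names_b))
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      A <- genes_a[[i]]; B <- genes_b[[j]]
      if (length(A) == 0L || length(B) == 0L) next
      ov <- length(intersect(A, B))
      OV[i, j] <- ov
      J[i, j] <- ov / length(union(A, B))
      P[i, j] <- fisher_overlap_test(A, B, universe_size,
                                     alternative = alternative)
    }
  }
  if (p_adjust) {
    P[] <- stats::p.adjust(as.vector(P), method = "BH")
  }
  pairs <- data.frame(
    program_a = rep(names_a, times = nb),
    program_b = rep(names_b, each = na),
    n_a = rep(lengths(genes_a), times = nb),
    n_b = rep(lengths(genes_b), each = na),
    overlap = as.vector(OV),
    jaccard = as.vector(J),
    fisher_p = as.vector(P),
    stringsAsFactors = FALSE)
  pairs$significant <- !is.na(pairs$fisher_p) & pairs$fisher_p <= alpha
  structure(list(pairs = pairs, jaccard = J, fisher_p = P,
                 overlap = OV, universe_size = universe_size),
            class = "match_table")
}
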