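#' Derive a reproducible stream seed from a global seed and indices
#'
#' Rank-stability sweeps and consensus factorizations need one independent,
#' reproducible seed per (rank, repeat, run) cell so that sweeps can be
#' rerun or parallelized without sharing RNG state. The mix is a fixed
#' linear-congruential hash; all arithmetic stays below 2^53 so the result
#' is exact in double precision, and the output is a valid positive
#' 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param a,b,c nonnegative integer indices (e.g. rank, repeat, run).
#' @return a positive integer < 2^31.
#' @export
mix_seed <- function(seed, a = 0L, b = 0L, c = 0L) {
  m <- 2147483647  # 2^31 - 1
  s <- (as.numeric(seed) %% m)
  s <- (s * 48271 + as.numeric(a) * 100003 +
          as.numeric(b) * 10007 + as.numeric(c) * 101) %% m
  as.integer(s %% 2147483646) + 1L
}

# Evaluate expr under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Population standard deviation (divide by n, not n - 1); the scaling
# conventions in this package follow z = (x - mean) / popsd so that a
# two-value feature {0, 2} maps to {-1, +1}.
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

pop_var <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

# Unit-L2-normalize the columns of a matrix; zero columns are left as zero.
l2_normalize_cols <- function(m) {
  nrm <- sqrt(colSums(m^2))
  nz <- nrm > 0
  m[, nz] <- sweep(m[, nz, drop = FALSE], 2, nrm[nz], "/")
  list(normalized = m, norms = nrm)
}

stopifnot_nonneg <- function(x, what = "matrix") {
  if (any(is.na(x))) stop(what, " contains missing values", call. = FALSE)
  if (any(x < 0)) stop(what, " must be nonnegative", call. = FALSE)
  invisible(x)
}
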