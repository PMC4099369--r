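#' Genomic relationship matrix from standardized genotypes
#'
#' The VanRaden-type estimator \eqn{\hat\Theta = WW'/m} where `W` holds
#' unit-variance standardized marker codes. The product is symmetrized by
#' averaging with its transpose to remove floating-point asymmetry.
#'
#' @param w a `"stdgeno"` object from [standardize_geno()], or a
#'   [geno_matrix()] (standardized on the fly).
#' @return An object of class `"grm"`: list with `theta` (n x n symmetric
#'   numeric matrix), `sample_ids`, `source = "marker"` and `n_markers`.
#' @examples
#' g <- geno_matrix(matrix(c(0L, 2L, 1L, 1L, 2L, 0L), 2, 3), "diploid")
#' compute_grm(g)
#' @export
compute_grm <- function(w) {
  if (inherits(w, "geno")) w <- standardize_geno(w)
  stopifnot(inherits(w, "stdgeno"))
  m <- ncol(w$w)
  theta <- tcrossprod(w$w) / m
  theta <- (theta + t(theta)) / 2
  new_grm(theta, w$sample_ids, source = "marker", n_markers = m)
}

new_grm <- function(theta, sample_ids, source, n_markers = NA_integer_) {
  dimnames(theta) <- list(sample_ids, sample_ids)
  structure(list(theta = theta, sample_ids = as.character(sample_ids),
                 source = source, n_markers = n_markers),
            class = "grm")
}

#' Theoretical AR1 relationship matrix
#'
#' Relatedness of a population ordered so that the genetic correlation
#' between individuals `i` and `j` is `theta_a^|i-j|`: each individual is
#' most related to its immediate neighbours, and relatedness decays
#' geometrically with index distance. The matrix is positive definite for
#' `|theta_a| < 1` and has a unit diagonal.
#'
#' @param n number of individuals.
#' @param theta_a nearest-neighbour correlation, `|theta_a| < 1`.
#' @param sample_ids optional identifiers.
#' @return A `"grm"` object with `source = "ar1_theoretical"`.
#' @export
ar1_grm <- function(n, theta_a, sample_ids = NULL) {
  stopifnot(n >= 1)
  if (!is.finite(theta_a) || abs(theta_a) >= 1)
    stop("|theta_a| must be < 1")
  idx <- seq_len(n)
  theta <- theta_a ^ abs(outer(idx, idx, "-"))
  diag(theta) <- 1
  new_grm(theta, sample_ids %||% paste0("ind", idx), source = "ar1_theoretical")
}

#' Pearson correlation between two relationship matrices
#'
#' Correlates the lower-triangle elements of two GRMs over the same
#' individuals in the same order. By default the diagonal is excluded
#' (strict lower triangle): a theoretical matrix has a constant unit
#' diagonal, which contributes zero-variance points. `diag = TRUE` includes
#' the diagonal, treating self-relatedness as ordinary elements of the
#' comparison; marker-estimated diagonals do vary, and the inclusive
#' correlation is what an element-wise comparison of the full matrices
#' measures.
#'
#' @param grm_hat,grm_true `"grm"` objects of equal dimension.
#' @param diag include the diagonal elements (default `FALSE`).
#' @return Pearson correlation coefficient.
#' @export
grm_cor <- function(grm_hat, grm_true, diag = FALSE) {
  stopifnot(inherits(grm_hat, "grm"), inherits(grm_true, "grm"))
  if (!identical(dim(grm_hat$theta), dim(grm_true$theta)))
    stop("GRMs have different dimensions")
  lt <- lower.tri(grm_hat$theta, diag = diag)
  a <- grm_hat$theta[lt]
  b <- grm_true$theta[lt]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance among lower-triangle elements")
  stats::cor(a, b)
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("GRM: %d individuals (source: %s", nrow(x$theta), x$source))
  if (!is.na(x$n_markers)) cat(sprintf(", %d markers", x$n_markers))
  cat(")\n")
  od <- x$theta[lower.tri(x$theta)]
  cat(sprintf("  diagonal mean %.4f; off-diagonal mean %.4f, range [%.4f, %.4f]\n",
              mean(diag(x$theta)), mean(od), min(od), max(od)))
  invisible(x)
}

#' @export
dim.grm <- function(x) dim(x$theta)

# subset a GRM (and keep class invariants); used by the bootstrap
grm_subset <- function(grm, idx) {
  new_grm(grm$theta[idx, idx, drop = FALSE], grm$sample_ids[idx],
          source = grm$source, n_markers = grm$n_markers)
}
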