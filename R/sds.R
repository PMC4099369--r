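#' Fit the symmetric-differences-squared similarity regression
#'
#' Estimates additive genetic variance and narrow-sense heritability by
#' least-squares regression of a pairwise phenotypic index on pairwise
#' genomic relatedness, optionally after equal-width binning of the
#' relatedness axis (the binned fit is the scalable estimator; the
#' un-binned fit is Ritland's classical procedure, see [ritland()]).
#'
#' Two model forms are available. Under the covariance form
#' (`model = "sds2"`) the index is the centered cross-product
#' \eqn{s_{ij} = (y_i-\bar y)(y_j-\bar y)}; its regression slope on
#' \eqn{\hat\theta_{ij}} estimates \eqn{\sigma^2_a}, and the slope of the
#' standardized index \eqn{s_{ij}/\hat\sigma^2_p} estimates \eqn{h^2}
#' directly (the two routes agree by linearity, and both are computed and
#' cross-checked internally). Under the difference form (`model = "sds1"`)
#' the index is the half squared difference \eqn{d_{ij} = (y_i-y_j)^2/2};
#' its intercept estimates \eqn{\sigma^2_p}, its slope estimates
#' \eqn{-\sigma^2_a}, and \eqn{\hat h^2 = -\beta/\alpha}.
#'
#' Estimates are reported unclamped: \eqn{\hat h^2} may be negative or
#' exceed 1, which is informative about sampling error and must not be
#' truncated before averaging over replicates.
#'
#' @param y numeric phenotype vector, optionally named by sample id.
#' @param grm a `"grm"` object (see [compute_grm()], [read_grm_gcta()]).
#' @param model `"sds2"` (covariance, default) or `"sds1"` (difference).
#' @param binned fit on bin averages (`TRUE`, default) or on all pairs.
#' @param n_bins number of equal-width bins (default 1000).
#' @param range_mode `"data"` (bins span the observed relatedness range,
#'   default) or `"unit"` (bins span \[0, 1\] with outside values clipped
#'   into the end bins).
#' @param double_diff for `model = "sds1"` only: regress the raw squared
#'   difference instead of its half; raw intercept/slope then estimate
#'   \eqn{2\sigma^2_p} and \eqn{-2\sigma^2_a} (the reported variance fields
#'   are rescaled accordingly; \eqn{\hat h^2} is unchanged).
#' @return An object of class `"sds_fit"` with components `sigma2_a`,
#'   `sigma2_p`, `h2`, `intercept`, `slope` (raw regression coefficients of
#'   the fitted index), `n_bins_used`, `n_pairs`, `method`, `h2_valid`,
#'   `bins` (the bin table, or `NULL` when un-binned) and `call`.
#' @seealso [ritland()], [greml()], [sds_boot()]
#' @examples
#' set.seed(1)
#' pop <- sim_ar1_population(n = 200, m = 500, h2 = 0.5)
#' fit <- sds(pop$y, compute_grm(pop$genotypes))
#' fit
#' coef(fit)
#' @export
sds <- function(y, grm, model = c("sds2", "sds1"), binned = TRUE,
                n_bins = 1000, range_mode = c("data", "unit"),
                double_diff = FALSE) {
  model <- match.arg(model)
  range_mode <- match.arg(range_mode)
  tab <- pair_table(y, grm, double_diff = double_diff && model == "sds1")
  s2p_plugin <- attr(tab, "sigma2_p")
  fit_index <- function(index) {
    if (binned) {
      b <- bin_pairs(tab, index = index, n_bins = n_bins,
                     range_mode = range_mode)
      list(coef = binned_regression(b), bins = b, nb = nrow(b))
    } else {
      list(coef = ols_fit(tab$theta_hat, tab[[index]]), bins = NULL,
           nb = NA_integer_)
    }
  }
  if (model == "sds2") {
    f <- fit_index("s")
    sigma2_a <- unname(f$coef["slope"])
    if (s2p_plugin <= 0) stop("zero phenotypic variance")
    h2 <- sigma2_a / s2p_plugin
    # standardized-index route must agree by linearity of the OLS slope
    f_std <- fit_index("s_std")
    h2_std <- unname(f_std$coef["slope"])
    if (abs(h2 - h2_std) > 1e-10 * max(1, abs(h2)))
      stop("internal inconsistency between similarity and standardized-similarity slopes")
    out <- list(sigma2_a = sigma2_a, sigma2_p = s2p_plugin, h2 = h2,
                intercept = unname(f$coef["intercept"]),
                slope = sigma2_a, h2_valid = TRUE)
  } else {
    f <- fit_index("d")
    k <- if (double_diff) 2 else 1
    intercept <- unname(f$coef["intercept"])
    slope <- unname(f$coef["slope"])
    sigma2_p <- intercept / k
    sigma2_a <- -slope / k
    h2_valid <- intercept > 0
    if (!h2_valid)
      warning("non-positive intercept in the difference regression; h2 estimate invalid",
              call. = FALSE)
    out <- list(sigma2_a = sigma2_a, sigma2_p = sigma2_p,
                h2 = if (intercept != 0) -slope / intercept else NA_real_,
                intercept = intercept, slope = slope, h2_valid = h2_valid)
  }
  out$method <- paste0(model, if (binned) "_binned" else "_unbinned")
  out$n_bins_used <- f$nb
  out$n_pairs <- nrow(tab)
  out$n <- length(grm$sample_ids)
  out$bins <- f$bins
  out$call <- match.call()
  class(out) <- "sds_fit"
  out
}

#' Ritland's un-binned similarity regression
#'
#' The classical procedure: ordinary least squares of the per-pair
#' similarity index on per-pair relatedness over all n(n-1)/2 pairs, with a
#' free intercept. Provided as the reference the binned estimator is
#' validated against; memory grows quadratically in n.
#'
#' @inheritParams sds
#' @return An `"sds_fit"` object (see [sds()]).
#' @export
ritland <- function(y, grm, model = c("sds2", "sds1"), double_diff = FALSE) {
  model <- match.arg(model)
  out <- sds(y, grm, model = model, binned = FALSE, double_diff = double_diff)
  out$call <- match.call()
  out
}

#' @export
print.sds_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Similarity regression (%s), n = %d (%d pairs",
              x$method, x$n, x$n_pairs))
  if (!is.na(x$n_bins_used)) cat(sprintf(", %d occupied bins", x$n_bins_used))
  cat(")\n")
  cat(sprintf("  sigma2_a = %.*f   sigma2_p = %.*f   h2 = %.*f%s\n",
              digits, x$sigma2_a, digits, x$sigma2_p, digits, x$h2,
              if (!x$h2_valid) " (invalid)" else ""))
  invisible(x)
}

#' @export
coef.sds_fit <- function(object, ...) {
  c(sigma2_a = object$sigma2_a, sigma2_p = object$sigma2_p, h2 = object$h2)
}

#' @export
summary.sds_fit <- function(object, ...) {
  out <- object
  if (!is.null(object$bins)) {
    r <- residuals(object)
    out$resid_summary <- summary(r)
    out$r_squared <- 1 - sum(r^2) /
      sum((object$bins$index_mean - mean(object$bins$index_mean))^2)
  }
  class(out) <- c("summary.sds_fit", class(object))
  out
}

#' @export
print.summary.sds_fit <- function(x, digits = 4, ...) {
  print.sds_fit(x, digits = digits, ...)
  cat(sprintf("  regression: intercept = %.*f, slope = %.*f\n",
              digits, x$intercept, digits, x$slope))
  cat("  (a non-zero intercept of the covariance regression flags departures\n",
      "  from the no-shared-environment assumption)\n", sep = "")
  if (!is.null(x$r_squared))
    cat(sprintf("  bin-level R^2 = %.3f\n", x$r_squared))
  invisible(x)
}

#' @export
fitted.sds_fit <- function(object, ...) {
  if (is.null(object$bins)) stop("fitted values are available for binned fits only")
  object$intercept + object$slope * object$bins$theta_mean
}

#' @export
residuals.sds_fit <- function(object, ...) {
  if (is.null(object$bins)) stop("residuals are available for binned fits only")
  object$bins$index_mean - fitted(object)
}

#' Plot a binned similarity regression
#'
#' Bin-mean index against bin-mean relatedness with the fitted least-squares
#' line; point area scales with the bin's pair count.
#'
#' @param x an `"sds_fit"` from a binned [sds()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sds_fit <- function(x, ...) {
  if (is.null(x$bins)) stop("plotting requires a binned fit")
  cx <- 0.3 + 1.7 * sqrt(x$bins$count / max(x$bins$count))
  graphics::plot(x$bins$theta_mean, x$bins$index_mean, cex = cx,
                 col = grDevices::adjustcolor("steelblue", 0.6), pch = 16,
                 xlab = "bin mean relatedness",
                 ylab = paste("bin mean", attr(x$bins, "index")), ...)
  graphics::abline(x$intercept, x$slope, col = "firebrick", lwd = 2)
  invisible(x)
}
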