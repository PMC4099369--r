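#' Delete-duplicate bootstrap for heritability estimates
#'
#' Nonparametric bootstrap over individuals: each resample draws `n`
#' individuals with replacement and then drops duplicates before
#' re-estimating, so the resampled GRM stays non-singular (a duplicated
#' individual makes two GRM rows identical, which breaks likelihood-based
#' fits). The phenotype vector and precomputed GRM are subset consistently;
#' trait centering is redone within every resample. SDS estimates are not
#' truncated, so negative interval bounds are legitimate; REML estimates
#' are boundary-constrained to \[0, 1\] by the fit itself.
#'
#' @param y phenotype vector; @param grm a `"grm"` object.
#' @param B number of bootstrap resamples (default 1000).
#' @param estimator `"sds2"`, `"sds1"`, `"ritland"` or `"reml"`.
#' @param seed optional integer seed.
#' @param n_bins,range_mode binning controls for SDS estimators.
#' @return An object of class `"sds_boot"`: `estimates` (successful
#'   resample h2 values), `sd`, `ci95` (2.5th and 97.5th percentiles),
#'   `resample_sizes` (unique-individual counts), `B`, `n_failed`,
#'   `estimator`.
#' @examples
#' set.seed(2)
#' pop <- sim_ar1_population(n = 80, m = 120, h2 = 0.5)
#' sds_boot(pop$y, compute_grm(pop$genotypes), B = 20, estimator = "ritland",
#'          seed = 3)
#' @export
sds_boot <- function(y, grm, B = 1000,
                     estimator = c("sds2", "sds1", "ritland", "reml"),
                     seed = NULL, n_bins = 1000, range_mode = "data") {
  stopifnot(B >= 1)
  estimator <- match.arg(estimator)
  y <- align_pheno(y, grm)
  n <- length(y)
  if (!is.null(seed)) set.seed(seed)
  est <- numeric(B)
  sizes <- integer(B)
  failed <- logical(B)
  for (b in seq_len(B)) {
    idx <- sort(unique(sample.int(n, n, replace = TRUE)))
    sizes[b] <- length(idx)
    est[b] <- tryCatch(
      estimate_h2(y[idx], grm_subset(grm, idx), estimator,
                  n_bins = n_bins, range_mode = range_mode),
      error = function(e) NA_real_)
    failed[b] <- is.na(est[b])
  }
  if (any(failed))
    warning(sprintf("%d of %d bootstrap resamples failed and were skipped",
                    sum(failed), B), call. = FALSE)
  if (mean(failed) > 0.5)
    stop("more than half of the bootstrap resamples failed")
  ok <- est[!failed]
  structure(list(estimates = ok, sd = stats::sd(ok),
                 ci95 = stats::quantile(ok, c(0.025, 0.975), names = FALSE),
                 resample_sizes = sizes, B = B, n_failed = sum(failed),
                 estimator = estimator),
            class = "sds_boot")
}

#' @export
print.sds_boot <- function(x, digits = 4, ...) {
  cat(sprintf("Delete-duplicate bootstrap (%s), %d resamples (%d failed)\n",
              x$estimator, x$B, x$n_failed))
  cat(sprintf("  sd = %.*f   95%% CI = %.*f to %.*f\n",
              digits, x$sd, digits, x$ci95[1], digits, x$ci95[2]))
  cat(sprintf("  mean unique individuals per resample = %.1f\n",
              mean(x$resample_sizes)))
  invisible(x)
}
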