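#' Replicated simulation study of heritability estimators
#'
#' Runs `reps` independent simulation replicates at one parameter setting;
#' in each replicate the population is simulated, the all-marker GRM is
#' built (causal and irrelevant markers together, as an analyst would), and
#' every requested estimator is applied. Per method the replicate estimates
#' are summarized by their mean, SD, 90% range (5th and 95th percentiles,
#' linear interpolation) and a two-sided one-sample t-test of the mean
#' against the true `h2` at the 5% level. The realized heritabilities are
#' summarized the same way.
#'
#' @param h2,n,m,theta_a,causal_fraction,rescale simulation parameters
#'   passed to [sim_ar1_population()].
#' @param reps number of replicates (>= 2).
#' @param methods character subset of `"sds2"`, `"sds1"`, `"ritland"`,
#'   `"reml"`; may be empty (`character(0)`) to summarize realized
#'   heritability only (no GRM is then built).
#' @param n_bins,range_mode binning controls for the SDS fits.
#' @param seed integer seed; per-replicate seeds are derived from it so the
#'   study is reproducible as a whole.
#' @return An object of class `"sds_sim_study"`: `estimates` (reps x
#'   methods matrix), `realized` (vector), `summary` (data frame with one
#'   row per method plus one for realized), `config`.
#' @examples
#' st <- sim_study(h2 = 0.5, n = 120, m = 100, reps = 5, seed = 1)
#' st$summary
#' @export
sim_study <- function(h2, n, m, reps = 100,
                      methods = "sds2", n_bins = 1000,
                      range_mode = c("data", "unit"),
                      theta_a = 0.95, causal_fraction = 0.1,
                      rescale = FALSE, seed = NULL) {
  stopifnot(reps >= 2)
  range_mode <- match.arg(range_mode)
  methods <- as.character(methods)
  bad <- setdiff(methods, c("sds2", "sds1", "ritland", "reml"))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, reps)
  est <- matrix(NA_real_, reps, length(methods),
                dimnames = list(NULL, methods))
  realized <- numeric(reps)
  for (r in seq_len(reps)) {
    pop <- sim_ar1_population(n, m, h2, theta_a = theta_a,
                              causal_fraction = causal_fraction,
                              seed = rep_seeds[r], rescale = rescale)
    realized[r] <- pop$realized_h2
    if (!length(methods)) next
    grm <- compute_grm(pop$genotypes)
    for (meth in methods) {
      est[r, meth] <- tryCatch(
        estimate_h2(pop$y, grm, meth, n_bins = n_bins,
                    range_mode = range_mode),
        error = function(e)
          stop(sprintf("replicate %d, method %s: %s", r, meth,
                       conditionMessage(e)), call. = FALSE))
    }
  }
  summ <- do.call(rbind, c(
    lapply(methods, function(meth) summarize_estimates(est[, meth], meth, h2)),
    list(summarize_estimates(realized, "realized", h2))))
  structure(list(estimates = est, realized = realized, summary = summ,
                 config = list(h2 = h2, n = n, m = m, reps = reps,
                               methods = methods, n_bins = n_bins,
                               range_mode = range_mode, theta_a = theta_a,
                               causal_fraction = causal_fraction,
                               rescale = rescale, seed = seed)),
            class = "sds_sim_study")
}

# dispatch one estimator, returning its h2 estimate
estimate_h2 <- function(y, grm, method, n_bins = 1000, range_mode = "data") {
  switch(method,
         sds2 = sds(y, grm, model = "sds2", binned = TRUE, n_bins = n_bins,
                    range_mode = range_mode)$h2,
         sds1 = sds(y, grm, model = "sds1", binned = TRUE, n_bins = n_bins,
                    range_mode = range_mode)$h2,
         ritland = ritland(y, grm)$h2,
         reml = withCallingHandlers(
           greml(y, grm)$h2,
           sdsreg_singular_grm = function(w) invokeRestart("muffleWarning")),
         stop("unknown method: ", method))
}

summarize_estimates <- function(x, label, h2_true) {
  q <- stats::quantile(x, c(0.05, 0.95), names = FALSE)  # type 7: linear interp.
  tt <- stats::t.test(x, mu = h2_true)
  data.frame(method = label, mean = mean(x), sd = stats::sd(x),
             q05 = q[1], q95 = q[2],
             t_stat = unname(tt$statistic), p_value = tt$p.value,
             sig_05 = tt$p.value < 0.05)
}

#' @export
print.sds_sim_study <- function(x, digits = 3, ...) {
  cfg <- x$config
  cat(sprintf("Simulation study: h2 = %.3g, n = %d, m = %d, %d replicates\n",
              cfg$h2, cfg$n, cfg$m, cfg$reps))
  s <- x$summary
  for (k in seq_len(nrow(s)))
    cat(sprintf("  %-8s mean %.*f  sd %.*f  90%% range %.*f-%.*f%s\n",
                s$method[k], digits, s$mean[k], digits, s$sd[k],
                digits, s$q05[k], digits, s$q95[k],
                if (s$sig_05[k]) "  (mean deviates from h2, p<0.05)" else ""))
  invisible(x)
}

#' Agreement between marker-estimated and theoretical relatedness
#'
#' Simulates one AR1 population, builds the all-marker GRM, and returns the
#' Pearson correlation of its strict lower triangle with the theoretical
#' AR1 matrix — the accuracy of realized relatedness as a function of
#' sample size and marker density.
#'
#' @param n,m,theta_a population parameters; @param seed optional seed;
#' @param diag include the diagonal in the correlation (see [grm_cor()]).
#' @return Scalar correlation.
#' @export
grm_accuracy <- function(n, m, theta_a = 0.95, seed = NULL, diag = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  latent <- sample_ar1_latent(n, m, theta_a)
  grm_hat <- compute_grm(latent_to_genotypes(latent))
  grm_cor(grm_hat, ar1_grm(n, theta_a), diag = diag)
}

#' Grid of relatedness-accuracy correlations
#'
#' Runs [grm_accuracy()] over all combinations of sample sizes and marker
#' densities.
#'
#' @param n_grid,m_grid integer vectors; @param theta_a correlation;
#' @param seed optional seed (per-cell seeds derived from it).
#' @return Data frame with columns `n`, `m`, `r`.
#' @export
grm_accuracy_grid <- function(n_grid, m_grid, theta_a = 0.95, seed = NULL,
                              diag = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(n = n_grid, m = m_grid)
  cells$r <- NA_real_
  cell_seeds <- sample.int(.Machine$integer.max, nrow(cells))
  for (k in seq_len(nrow(cells)))
    cells$r[k] <- grm_accuracy(cells$n[k], cells$m[k], theta_a,
                               seed = cell_seeds[k], diag = diag)
  cells
}
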