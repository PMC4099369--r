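# AR1 population and quantitative-trait simulator.
#
# The design emulates a breeding-like population whose individuals, ordered
# by descent, have genetic correlation theta_a^|i-j| (a full spectrum of
# relatedness within one sample). Marker genotypes arise by thresholding a
# latent Gaussian at the standard-normal quartiles, giving 1:2:1 genotype
# proportions at every locus; markers are mutually independent.

# standard-normal upper quartile used to cut the latent scale into 0/1/2
geno_threshold <- function() stats::qnorm(0.75)

#' Latent Gaussian sample under the AR1 relatedness model
#'
#' Draws an n x m matrix whose rows are marginally standard normal with
#' inter-row correlation `theta_a^|i-j|`, by the stationary recursion
#' `z_i = theta_a * z_(i-1) + sqrt(1 - theta_a^2) * eps_i` (the unique
#' linear recursion with standard-normal marginals and nearest-neighbour
#' correlation `theta_a`). Columns are independent.
#'
#' @param n individuals (rows); @param m markers (columns);
#' @param theta_a nearest-neighbour correlation, `|theta_a| < 1`.
#' @return n x m numeric matrix.
#' @export
sample_ar1_latent <- function(n, m, theta_a) {
  if (!is.finite(theta_a) || abs(theta_a) >= 1) stop("|theta_a| must be < 1")
  z <- matrix(0, n, m)
  z[1L, ] <- stats::rnorm(m)
  if (n > 1L) {
    sc <- sqrt(1 - theta_a^2)
    for (i in 2:n) z[i, ] <- theta_a * z[i - 1L, ] + sc * stats::rnorm(m)
  }
  z
}

#' Convert latent Gaussian values to diploid genotype codes
#'
#' Thresholds each latent value at the standard-normal quartiles
#' (+/- 0.67449): values below the lower quartile code 0, between the
#' quartiles 1, above the upper quartile 2, so genotypes occur in 1:2:1
#' proportions. Values equal to a threshold (measure zero) map upward.
#'
#' @param latent numeric matrix from [sample_ar1_latent()].
#' @param sample_ids,marker_ids optional identifiers.
#' @return A diploid [geno_matrix()].
#' @export
latent_to_genotypes <- function(latent, sample_ids = NULL, marker_ids = NULL) {
  if (anyNA(latent) || any(!is.finite(latent))) stop("non-finite latent values")
  thr <- geno_threshold()
  codes <- (latent >= -thr) + (latent >= thr)
  storage.mode(codes) <- "integer"
  geno_matrix(codes, ploidy = "diploid",
              sample_ids = sample_ids, marker_ids = marker_ids)
}

#' Sample causal marker positions
#'
#' Draws `round(causal_fraction * m)` distinct marker indices uniformly
#' without replacement.
#'
#' @param m total marker count; @param causal_fraction fraction in (0, 1].
#' @return Sorted integer vector of causal indices.
#' @export
assign_qtl <- function(m, causal_fraction = 0.1) {
  if (causal_fraction <= 0 || causal_fraction > 1)
    stop("causal_fraction must be in (0, 1]")
  k <- round(causal_fraction * m)
  if (k < 1L) stop("causal_fraction * m rounds to zero causal markers")
  sort(sample.int(m, k))
}

#' Simulate an AR1-related population with a quantitative trait
#'
#' Simulates `n` individuals genotyped at `m` independent markers under the
#' AR1 relatedness model, assigns a random `causal_fraction` of markers as
#' QTL, and generates the trait `y = mu + a + e`: causal effects
#' `u ~ N(0, I)` act through the standardized causal genotypes,
#' `a = sqrt(h2) W_c u / sqrt(m_c)` (so that `Var(a) = h2 * Theta_c` with a
#' unit phenotypic variance), and `e ~ N(0, (1 - h2) I)`. With
#' `rescale = TRUE` the genetic effects are instead rescaled so the sample
#' variance of `a` equals `h2` exactly in every replicate. The default
#' (`rescale = FALSE`) leaves genetic sampling variation in place, which is
#' what the realized heritability is designed to gauge: under strong
#' relatedness the sample variance of `a` is systematically below
#' `sigma2_a`, so realized values fall slightly below `h2` in small
#' samples.
#'
#' All randomness flows from `seed` (when supplied): latent genotypes,
#' causal positions, causal effects, residuals, in that order. Identical
#' arguments give bit-identical output.
#'
#' @param n individuals; @param m markers; @param h2 true narrow-sense
#'   heritability in \[0, 1\];
#' @param theta_a nearest-neighbour genetic correlation (default 0.95);
#' @param causal_fraction fraction of markers that are causal (default 0.1);
#' @param mu population mean (default 0);
#' @param seed optional integer seed;
#' @param rescale force the realized genetic variance to equal `h2` exactly.
#' @return An object of class `"sds_sim"`: `genotypes` (a [geno_matrix()]),
#'   `y` (named phenotype vector), `causal_idx`, `u` (causal effects), `a`,
#'   `e`, `realized_h2`, `config`.
#' @examples
#' pop <- sim_ar1_population(n = 100, m = 200, h2 = 0.5, seed = 1)
#' pop$realized_h2
#' @export
sim_ar1_population <- function(n, m, h2, theta_a = 0.95,
                               causal_fraction = 0.1, mu = 0,
                               seed = NULL, rescale = FALSE) {
  stopifnot(n >= 2, m >= 1, h2 >= 0, h2 <= 1)
  if (!is.null(seed)) set.seed(seed)
  latent <- sample_ar1_latent(n, m, theta_a)
  g <- latent_to_genotypes(latent)
  causal_idx <- assign_qtl(m, causal_fraction)
  gc_ <- geno_matrix(g$codes[, causal_idx, drop = FALSE], ploidy = "diploid",
                     sample_ids = g$sample_ids,
                     marker_ids = g$marker_ids[causal_idx])
  if (h2 > 0) {
    wc <- standardize_geno(gc_)
    mc <- ncol(wc$w)
    u <- stats::rnorm(mc)
    a_star <- as.vector(wc$w %*% u) / sqrt(mc)
    if (rescale) {
      v <- stats::var(a_star)
      if (v == 0) stop("degenerate causal genotypes: zero genetic variance")
      a <- a_star * sqrt(h2 / v)
    } else {
      a <- sqrt(h2) * a_star
    }
  } else {
    u <- numeric(0)
    a <- numeric(n)
  }
  e <- if (h2 < 1) stats::rnorm(n, 0, sqrt(1 - h2)) else numeric(n)
  y <- mu + a + e
  names(y) <- g$sample_ids
  structure(list(genotypes = g, y = y, causal_idx = causal_idx, u = u,
                 a = a, e = e, realized_h2 = realized_h2(a, e),
                 config = list(n = n, m = m, h2 = h2, theta_a = theta_a,
                               causal_fraction = causal_fraction, mu = mu,
                               sigma2_p = 1, seed = seed,
                               rescale = rescale)),
            class = "sds_sim")
}

#' @export
print.sds_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Simulated AR1 population: n = %d, m = %d, h2 = %.3g, theta_a = %.3g\n",
              cfg$n, cfg$m, cfg$h2, cfg$theta_a))
  cat(sprintf("  %d causal markers; realized h2 = %.4f\n",
              length(x$causal_idx), x$realized_h2))
  invisible(x)
}

#' Realized heritability of a simulated replicate
#'
#' The variance ratio computed directly from the drawn genetic and residual
#' effect vectors, `var(a) / (var(a) + var(e))` with divisor n-1; it gauges
#' genetic sampling variation across replicates.
#'
#' @param a genetic effects; @param e residual effects (equal length).
#' @return Scalar in \[0, 1\].
#' @export
realized_h2 <- function(a, e) {
  stopifnot(length(a) == length(e), length(a) >= 2)
  va <- stats::var(a)
  ve <- stats::var(e)
  if (va + ve == 0) stop("both variance components are zero")
  va / (va + ve)
}
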