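#' Single-GRM restricted maximum likelihood by spectral decomposition
#'
#' Fits the intercept-only linear mixed model
#' \eqn{y = \mu 1 + a + e}, \eqn{a \sim N(0, \Theta\sigma^2_a)},
#' \eqn{e \sim N(0, I\sigma^2_e)}, the likelihood baseline against which the
#' similarity regression is compared. The GRM is eigendecomposed once,
#' \eqn{\Theta = U\Lambda U'}; in the rotated basis the covariance is
#' diagonal, \eqn{\sigma^2_p(h^2\lambda_i + 1 - h^2)}, so \eqn{\mu} and the
#' total variance profile out in closed form and the restricted likelihood
#' is maximized over the single ratio \eqn{h^2 \in [0,1]} by bounded scalar
#' optimization (tolerance 1e-8). The variance constraint of REML is
#' enforced by the parameterization itself; solutions pinned at 0 or 1 are
#' flagged `at_boundary`.
#'
#' Eigenvalues below 1e-8 (rank-deficient GRMs arise whenever markers are
#' fewer than individuals, and round-off can produce small negatives) are
#' clipped to 1e-8 with a warning of class `"sdsreg_singular_grm"`.
#'
#' If all eigenvalues are equal (e.g. \eqn{\Theta = I}) the likelihood
#' depends on \eqn{(\sigma^2_a, \sigma^2_e)} only through their sum: the fit
#' is returned with `identifiable = FALSE` and `NA` component estimates
#' rather than an arbitrary interior split.
#'
#' @param y numeric phenotype vector, optionally named by sample id.
#' @param grm a `"grm"` object.
#' @param tol convergence tolerance on \eqn{h^2}.
#' @return An object of class `"greml_fit"`: `sigma2_a`, `sigma2_e`, `h2`,
#'   `loglik` (restricted log-likelihood at the optimum), `at_boundary`,
#'   `identifiable`, `converged`, `evaluations`, `n`, `call`.
#' @seealso [greml_direct()] for the dense-likelihood reference
#'   implementation, [restricted_loglik()] to evaluate the criterion.
#' @examples
#' set.seed(1)
#' pop <- sim_ar1_population(n = 150, m = 400, h2 = 0.5)
#' greml(pop$y, compute_grm(pop$genotypes))
#' @export
greml <- function(y, grm, tol = 1e-8) {
  y <- align_pheno(y, grm)
  n <- length(y)
  if (n < 3L) stop("need at least 3 individuals")
  eg <- eigen(grm$theta, symmetric = TRUE)
  lam <- eg$values
  if (min(lam) < 1e-8) {
    warning(warningCondition(
      sprintf("GRM is near-singular (smallest eigenvalue %.3g); clipping to 1e-8",
              min(lam)),
      class = "sdsreg_singular_grm"))
    lam <- pmax(lam, 1e-8)
  }
  yt <- as.vector(crossprod(eg$vectors, y))
  xt <- as.vector(crossprod(eg$vectors, rep(1, n)))
  if (max(lam) - min(lam) < 1e-10) {
    # V = c*I up to scale: only sigma2_a + sigma2_e is identified
    s2 <- sum((y - mean(y))^2) / (n - 1)
    return(structure(list(sigma2_a = NA_real_, sigma2_e = NA_real_,
                          h2 = NA_real_, sigma2_total = s2,
                          loglik = reml_ll_rotated(0, lam, yt, xt)$ll,
                          at_boundary = FALSE, identifiable = FALSE,
                          converged = TRUE, evaluations = 1L, n = n,
                          call = match.call()),
                     class = "greml_fit"))
  }
  nll <- function(h) -reml_ll_rotated(h, lam, yt, xt)$ll
  opt <- stats::optimize(nll, c(0, 1), tol = tol)
  cand_h <- c(opt$minimum, 0, 1)
  cand_v <- c(opt$objective, nll(0), nll(1))
  if (any(!is.finite(cand_v))) {
    cand_h <- cand_h[is.finite(cand_v)]
    cand_v <- cand_v[is.finite(cand_v)]
  }
  if (!length(cand_v)) stop("non-finite restricted likelihood")
  h2 <- cand_h[which.min(cand_v)]
  at_boundary <- h2 <= tol || h2 >= 1 - tol
  if (at_boundary) h2 <- round(h2)
  fit <- reml_ll_rotated(h2, lam, yt, xt)
  structure(list(sigma2_a = h2 * fit$sigma2_total,
                 sigma2_e = (1 - h2) * fit$sigma2_total,
                 h2 = h2, sigma2_total = fit$sigma2_total,
                 loglik = fit$ll, at_boundary = at_boundary,
                 identifiable = TRUE, converged = TRUE,
                 evaluations = length(cand_v) + 1L, n = n,
                 call = match.call()),
            class = "greml_fit")
}

# profiled restricted log-likelihood in the eigenbasis.
# delta_i = h2*lambda_i + (1-h2); mu and sigma2_total profiled out;
# REML divisor n - 1 (one fixed effect).
reml_ll_rotated <- function(h2, lam, yt, xt) {
  n <- length(yt)
  d <- h2 * lam + (1 - h2)
  if (any(d <= 0)) return(list(ll = -Inf, sigma2_total = NA_real_))
  xdx <- sum(xt^2 / d)
  bhat <- sum(xt * yt / d) / xdx
  r <- yt - xt * bhat
  s2 <- sum(r^2 / d) / (n - 1)
  ll <- -0.5 * ((n - 1) * (log(2 * pi * s2) + 1) + sum(log(d)) + log(xdx))
  list(ll = ll, sigma2_total = s2, mu = bhat)
}

#' Evaluate the restricted log-likelihood
#'
#' The restricted log-likelihood of the intercept-only single-GRM mixed
#' model at a given heritability ratio, with the total variance either
#' profiled out (`sigma2_total = NULL`) or fixed. `method = "spectral"`
#' computes it in the GRM eigenbasis as [greml()] does; `method = "direct"`
#' forms \eqn{V = h^2\Theta + (1-h^2)I} densely and uses explicit
#' factorizations — the two must agree to numerical precision, which is the
#' identity the test suite asserts.
#'
#' @param y phenotype vector; @param grm a `"grm"`; @param h2 ratio in
#'   \[0,1\]; @param sigma2_total optional fixed total variance;
#' @param method `"spectral"` or `"direct"`.
#' @return The restricted log-likelihood (a scalar).
#' @export
restricted_loglik <- function(y, grm, h2, sigma2_total = NULL,
                              method = c("spectral", "direct")) {
  method <- match.arg(method)
  y <- align_pheno(y, grm)
  n <- length(y)
  if (method == "spectral") {
    eg <- eigen(grm$theta, symmetric = TRUE)
    lam <- pmax(eg$values, 1e-8)
    yt <- as.vector(crossprod(eg$vectors, y))
    xt <- as.vector(crossprod(eg$vectors, rep(1, n)))
    if (is.null(sigma2_total)) return(reml_ll_rotated(h2, lam, yt, xt)$ll)
    d <- sigma2_total * (h2 * lam + (1 - h2))
    xdx <- sum(xt^2 / d)
    bhat <- sum(xt * yt / d) / xdx
    r <- yt - xt * bhat
    -0.5 * ((n - 1) * log(2 * pi) + sum(log(d)) + log(xdx) + sum(r^2 / d))
  } else {
    V1 <- h2 * grm$theta + (1 - h2) * diag(n)
    x <- rep(1, n)
    if (is.null(sigma2_total)) {
      ch <- chol(V1)
      Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
      Vi_x <- backsolve(ch, forwardsolve(t(ch), x))
      xdx <- sum(x * Vi_x)
      bhat <- sum(x * Vi_y) / xdx
      r <- y - bhat
      Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
      s2 <- sum(r * Vi_r) / (n - 1)
      return(-0.5 * ((n - 1) * (log(2 * pi * s2) + 1) +
                       2 * sum(log(diag(ch))) + log(xdx)))
    }
    V <- sigma2_total * V1
    ch <- chol(V)
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_x <- backsolve(ch, forwardsolve(t(ch), x))
    xdx <- sum(x * Vi_x)
    bhat <- sum(x * Vi_y) / xdx
    r <- y - bhat
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    -0.5 * ((n - 1) * log(2 * pi) + 2 * sum(log(diag(ch))) + log(xdx) +
              sum(r * Vi_r))
  }
}

#' Dense-likelihood REML reference (grid plus refinement)
#'
#' Maximizes the restricted likelihood written with the explicit dense
#' covariance \eqn{V = h^2\Theta + (1-h^2)I} over a grid on \eqn{h^2}
#' followed by local refinement. Intended as an independent cross-check of
#' [greml()] on small problems (dense factorizations at every grid point);
#' not for production use.
#'
#' @inheritParams greml
#' @param grid_step spacing of the initial grid on \eqn{h^2}.
#' @return A `"greml_fit"` object.
#' @export
greml_direct <- function(y, grm, grid_step = 1e-3) {
  y <- align_pheno(y, grm)
  n <- length(y)
  if (n > 200L) stop("dense reference restricted to n <= 200")
  lam <- eigen(grm$theta, symmetric = TRUE, only.values = TRUE)$values
  if (max(lam) - min(lam) < 1e-10) {
    s2 <- sum((y - mean(y))^2) / (n - 1)
    return(structure(list(sigma2_a = NA_real_, sigma2_e = NA_real_,
                          h2 = NA_real_, sigma2_total = s2,
                          loglik = restricted_loglik(y, grm, 0, method = "direct"),
                          at_boundary = FALSE, identifiable = FALSE,
                          converged = TRUE, evaluations = 1L, n = n,
                          call = match.call()),
                     class = "greml_fit"))
  }
  hs <- seq(0, 1, by = grid_step)
  ll <- vapply(hs, function(h)
    tryCatch(restricted_loglik(y, grm, h, method = "direct"),
             error = function(e) -Inf), 0)
  k <- which.max(ll)
  lo <- hs[max(1L, k - 1L)]
  hi <- hs[min(length(hs), k + 1L)]
  opt <- stats::optimize(function(h)
    -restricted_loglik(y, grm, h, method = "direct"),
    c(lo, hi), tol = 1e-9)
  h2 <- opt$minimum
  if (-opt$objective < ll[k]) h2 <- hs[k]
  at_boundary <- h2 <= 1e-8 || h2 >= 1 - 1e-8
  if (at_boundary) h2 <- round(h2)
  # recover total variance at the optimum via the GLS profile
  eg <- eigen(grm$theta, symmetric = TRUE)
  fit <- reml_ll_rotated(h2, pmax(eg$values, 1e-8),
                         as.vector(crossprod(eg$vectors, y)),
                         as.vector(crossprod(eg$vectors, rep(1, n))))
  structure(list(sigma2_a = h2 * fit$sigma2_total,
                 sigma2_e = (1 - h2) * fit$sigma2_total,
                 h2 = h2, sigma2_total = fit$sigma2_total,
                 loglik = restricted_loglik(y, grm, h2, method = "direct"),
                 at_boundary = at_boundary, identifiable = TRUE,
                 converged = TRUE, evaluations = length(hs) + 2L, n = n,
                 call = match.call()),
            class = "greml_fit")
}

#' @export
print.greml_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Single-GRM REML fit, n = %d\n", x$n))
  if (!x$identifiable) {
    cat("  variance split unidentifiable (GRM proportional to identity);\n")
    cat(sprintf("  total variance = %.*f\n", digits, x$sigma2_total))
  } else {
    cat(sprintf("  sigma2_a = %.*f   sigma2_e = %.*f   h2 = %.*f%s\n",
                digits, x$sigma2_a, digits, x$sigma2_e, digits, x$h2,
                if (x$at_boundary) " (at boundary)" else ""))
  }
  cat(sprintf("  restricted log-likelihood = %.*f\n", digits, x$loglik))
  invisible(x)
}

#' @export
coef.greml_fit <- function(object, ...) {
  c(sigma2_a = object$sigma2_a, sigma2_e = object$sigma2_e, h2 = object$h2)
}

#' @export
logLik.greml_fit <- function(object, ...) {
  structure(object$loglik, df = 3, class = "logLik")
}

#' @export
summary.greml_fit <- function(object, ...) object
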