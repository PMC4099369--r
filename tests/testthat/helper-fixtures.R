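# Fixtures are generated in code; nothing is stored on disk.

# small deterministic diploid genotype matrix with both common and rare
# alleles (no monomorphic columns unless asked for)
fixture_geno <- function(n = 8, m = 6, seed = 101, monomorphic = FALSE) {
  set.seed(seed)
  codes <- matrix(sample(0:2, n * m, replace = TRUE, prob = c(0.3, 0.4, 0.3)),
                  n, m)
  codes[1, ] <- c(0L, 1L, 2L)[1 + (seq_len(m) %% 3)]  # guard polymorphism
  codes[2, ] <- 2L - codes[1, ]
  if (monomorphic) codes[, m] <- 1L  # p = 0.5 is fine; use all-0 instead
  if (monomorphic) codes[, m] <- 0L
  geno_matrix(codes, ploidy = "diploid")
}

# phenotype + GRM pair with an exactly linear similarity-relatedness
# relationship: s_ij = h2_true * theta_ij by construction.
# Build theta from the observed centered cross-products of an arbitrary y.
fixture_exact_linear <- function(n = 12, h2_true = 0.7, seed = 7) {
  set.seed(seed)
  y <- rnorm(n)
  yc <- y - mean(y)
  # s_ij = h2_true * var(y) * theta_ij, so the standardized-index slope
  # (the h2 estimate) is exactly h2_true
  theta <- tcrossprod(yc) / (h2_true * var(y))
  diag(theta) <- 1
  list(y = y, grm = sdsreg:::new_grm(theta, paste0("ind", 1:n),
                                     source = "marker"))
}

# simulated population + GRM, cached per test file run
fixture_pop <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 150, m = 200, h2 = 0.5, seed = 11) {
    key <- paste(n, m, h2, seed, sep = "_")
    if (is.null(cache[[key]])) {
      pop <- suppressWarnings(sim_ar1_population(n, m, h2, seed = seed))
      cache[[key]] <- list(pop = pop,
                           grm = suppressWarnings(compute_grm(pop$genotypes)))
    }
    cache[[key]]
  }
})
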