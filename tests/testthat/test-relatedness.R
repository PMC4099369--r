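test_that("allele frequencies count reference alleles per ploidy", {
  g <- geno_matrix(cbind(rep(1L, 3), c(0L, 2L, 2L)), "diploid")
  p <- allele_freq(g)
  expect_equal(unname(p[1]), 0.5)       # all heterozygotes
  expect_equal(unname(p[2]), 4 / 6)     # hand count of reference alleles
  gh <- geno_matrix(cbind(c(0L, 0L, 0L), c(1L, 0L, 1L)), "haploid")
  expect_equal(unname(allele_freq(gh)), c(0, 2 / 3))
})

test_that("genotype validation rejects illegal codes and duplicates", {
  expect_error(geno_matrix(matrix(c(0L, 3L, 1L, 2L), 2), "diploid"),
               "illegal diploid code 3")
  expect_error(geno_matrix(matrix(c(0L, 2L, 1L, 1L), 2), "haploid"),
               "illegal haploid code")
  expect_error(geno_matrix(matrix(c(0L, NA, 1L, 2L), 2), "diploid"),
               "missing")
  expect_error(geno_matrix(matrix(0:1, 2, 2), "haploid",
                           sample_ids = c("a", "a")),
               "duplicate")
})

test_that("standardization matches the unit-variance coding and drops monomorphic markers", {
  # diploid z = 2 at p = 0.25: w = 1.5 / sqrt(0.375)
  g <- geno_matrix(rbind(c(2L, 1L, 0L), c(0L, 1L, 0L),
                         c(0L, 1L, 0L), c(0L, 1L, 0L)), "diploid")
  # marker 1: p = 2/8 = 0.25; marker 2 all het p = 0.5 -> w = 0; marker 3 monomorphic
  expect_warning(w <- standardize_geno(g), "monomorphic")
  expect_equal(ncol(w$w), 2)
  expect_equal(w$n_dropped, 1)
  expect_equal(w$w[1, 1], 1.5 / sqrt(0.375), tolerance = 1e-12)
  expect_true(all(w$w[, 2] == 0))
  expect_true(all(abs(colMeans(w$w)) < 1e-12))  # exact centering
  # haploid z = 1 at p = 0.5 -> w = 1
  gh <- geno_matrix(cbind(c(1L, 0L), c(0L, 1L)), "haploid")
  wh <- standardize_geno(gh)
  expect_equal(wh$w[1, 1], 1)
  expect_error(suppressWarnings(
    standardize_geno(geno_matrix(matrix(0L, 3, 2), "diploid"))),
    "monomorphic")
})

test_that("compute_grm equals the brute-force per-pair oracle", {
  g <- fixture_geno(n = 7, m = 9, seed = 3)
  w <- standardize_geno(g)
  K <- compute_grm(w)
  m <- ncol(w$w)
  oracle <- matrix(0, 7, 7)
  for (i in 1:7) for (j in 1:7) {
    acc <- 0
    for (l in 1:m) acc <- acc + w$w[i, l] * w$w[j, l]
    oracle[i, j] <- acc / m
  }
  expect_lt(max(abs(K$theta - oracle)), 1e-12)
  expect_identical(K$theta, t(K$theta))  # exact symmetry
  # orthogonal-rows example: identity GRM
  w2 <- structure(list(w = rbind(c(1, -1), c(1, 1)), freqs = c(0.5, 0.5),
                       ploidy = "diploid", sample_ids = c("a", "b"),
                       marker_ids = c("m1", "m2"), n_dropped = 0L),
                  class = "stdgeno")
  expect_equal(compute_grm(w2)$theta, diag(2), ignore_attr = TRUE)
})

test_that("duplicated individuals share diagonal and off-diagonal GRM entries", {
  g <- fixture_geno(n = 6, m = 8, seed = 5)
  codes <- rbind(g$codes, g$codes[1, , drop = FALSE])
  g2 <- geno_matrix(codes, "diploid", sample_ids = c(g$sample_ids, "dup"))
  K <- suppressWarnings(compute_grm(g2))
  expect_equal(K$theta[7, 1], K$theta[1, 1])
  expect_equal(K$theta[7, 7], K$theta[1, 1])
})

test_that("ar1_grm has geometric decay, unit diagonal, positive spectrum", {
  A <- ar1_grm(5, 0.95)
  expect_equal(A$theta[1, 3], 0.9025)
  expect_equal(unname(diag(A$theta)), rep(1, 5))
  expect_equal(ar1_grm(4, 0)$theta, diag(4),
               ignore_attr = TRUE)
  # translation invariance: entries depend only on |i - j|
  A2 <- ar1_grm(10, 0.6)
  for (t in 1:4)
    expect_equal(unname(A2$theta[cbind(1:(10 - t), (1 + t):10)]),
                 rep(0.6^t, 10 - t))
  # positive definite for |theta_a| < 1 (eigen oracle)
  for (ta in c(0.3, 0.95, 0.999, -0.9))
    expect_gt(min(eigen(ar1_grm(40, ta)$theta, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  expect_error(ar1_grm(5, 1), "theta_a")
})

test_that("grm_cor is symmetric, shift-invariant, and excludes the diagonal by default", {
  K1 <- suppressWarnings(compute_grm(fixture_geno(n = 9, m = 12, seed = 8)))
  K2 <- ar1_grm(9, 0.8)
  expect_equal(grm_cor(K1, K2), grm_cor(K2, K1))
  K3 <- K1
  K3$theta <- K3$theta + 5
  expect_equal(grm_cor(K3, K2), grm_cor(K1, K2))
  expect_equal(grm_cor(K1, K1), 1)
  # constant theoretical diagonal must not affect the default comparison
  K4 <- K1
  diag(K4$theta) <- 99
  expect_equal(grm_cor(K4, K2), grm_cor(K1, K2))
  expect_false(isTRUE(all.equal(grm_cor(K4, K2, diag = TRUE),
                                grm_cor(K4, K2))))
  expect_error(grm_cor(K1, ar1_grm(9, 0)), "zero variance")
  expect_error(grm_cor(sdsreg:::new_grm(matrix(1, 3, 3), letters[1:3], "file"),
                       ar1_grm(3, 0.5)),
               "zero variance")
})

test_that("marker GRM concentrates on identity for unrelated individuals", {
  set.seed(20)
  m <- 4000
  lat <- sample_ar1_latent(60, m, 0)   # theta_a = 0: unrelated
  K <- compute_grm(latent_to_genotypes(lat))
  off <- K$theta[lower.tri(K$theta)]
  expect_lt(abs(mean(off)), 3 / sqrt(m))
  expect_lt(abs(mean(diag(K$theta)) - 1), 3 / sqrt(m))
})
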