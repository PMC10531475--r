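test_that("phenotypes have the configured residual variance", {
  set.seed(41)
  colonies <- data.frame(id = seq_len(1e5), bv_m = 0, bv_d = 0)
  recs <- simulate_phenotypes(colonies, n_apiaries = 1, sigma2_e = 4,
                              apiary_effects = 0)
  expect_lt(abs(var(recs$y) - 4), 0.1)
  # no noise: the phenotype is exactly the performance criterion
  col2 <- data.frame(id = 1:5, bv_m = 1:5, bv_d = 0.5)
  r2 <- simulate_phenotypes(col2, 1, sigma2_e = 0, apiary_effects = 0)
  expect_equal(r2$y, col2$bv_m + col2$bv_d)
  # constant apiary effect, zero genetics
  r3 <- simulate_phenotypes(data.frame(id = 1:5, bv_m = 0, bv_d = 0),
                            1, sigma2_e = 0, apiary_effects = 3.5)
  expect_equal(r3$y, rep(3.5, 5))
})

test_that("BLUP solvers agree with each other and a naive GLS oracle", {
  set.seed(43)
  G0 <- matrix(c(1, -0.3, -0.3, 2), 2)
  for (r in 1:5) {
    n <- sample(8:15, 1)
    ids <- paste0("q", seq_len(n))
    ped <- pedigree_table(
      id = ids, kind = "queen",
      dam = c(NA, NA, NA, sample(ids[1:3], n - 3, TRUE)),
      sire = c(rep(NA, 3), sample(ids[1:2], n - 3, TRUE)),
      mated = c(NA, ids[1], sample(ids[1:2], n - 2, TRUE)))
    A <- relationship_matrix(accessible_kinship(ped, include_workers = TRUE))
    recs <- data.frame(id = ids, apiary = sample(c("a", "b"), n, TRUE),
                       y = rnorm(n, 5, 2))
    gls <- estimate_breeding_values(recs, A, G0, 4, method = "gls")
    mme <- estimate_breeding_values(recs, A, G0, 4, method = "mme")
    ora <- gls_oracle(recs, A, G0, 4)
    expect_equal(gls$ebv_m, mme$ebv_m, tolerance = 1e-8)
    expect_equal(gls$ebv_d, mme$ebv_d, tolerance = 1e-8)
    expect_equal(mme$ebv_m, unname(ora$ebv_m[mme$id]), tolerance = 1e-8)
    expect_equal(mme$ebv_d, unname(ora$ebv_d[mme$id]), tolerance = 1e-8)
  }
})

test_that("breeding values shrink to zero as residual variance explodes", {
  set.seed(47)
  ids <- paste0("q", 1:6)
  ped <- pedigree_table(ids, "queen", dam = NA, sire = NA,
                        mated = c(NA, NA, ids[1], ids[1], ids[2], ids[2]))
  A <- relationship_matrix(accessible_kinship(ped, include_workers = TRUE))
  recs <- data.frame(id = ids, apiary = rep(c("a", "b"), 3), y = rnorm(6, 2))
  eb <- estimate_breeding_values(recs, A, diag(c(1, 2)), 1e12)
  expect_lt(max(abs(c(eb$ebv_m, eb$ebv_d))), 1e-8)
})

test_that("a single corrected record regresses by heritability", {
  # direct-only reduction: one record on an unrelated non-inbred entity,
  # fixed effects known and removed => EBV = h^2 * y
  A <- diag(2)
  dimnames(A) <- list(c("q1", "W:q1"), c("q1", "W:q1"))
  G0 <- matrix(c(1e-12, 0, 0, 2), 2)   # maternal variance negligible
  recs <- data.frame(id = "q1", apiary = "a", y = 3)
  eb <- estimate_breeding_values(recs, A, G0, 4, method = "gls",
                                 fixed_effects = FALSE)
  h2 <- 2 / (2 + 4)
  expect_equal(eb$ebv_d[eb$id == "W:q1"], h2 * 3, tolerance = 1e-9)
})

test_that("breeding values are invariant to apiary-level shifts", {
  set.seed(53)
  ids <- paste0("q", 1:10)
  ped <- pedigree_table(ids, "queen",
                        dam = c(rep(NA, 4), sample(ids[1:4], 6, TRUE)),
                        sire = c(rep(NA, 4), sample(ids[1:2], 6, TRUE)),
                        mated = c(NA, NA, NA, NA, sample(ids[1:3], 6, TRUE)))
  A <- relationship_matrix(accessible_kinship(ped, include_workers = TRUE))
  recs <- data.frame(id = ids, apiary = rep(c("a", "b"), 5), y = rnorm(10))
  e1 <- estimate_breeding_values(recs, A, diag(c(1, 2)), 4)
  recs2 <- recs
  recs2$y[recs2$apiary == "a"] <- recs2$y[recs2$apiary == "a"] + 100
  e2 <- estimate_breeding_values(recs2, A, diag(c(1, 2)), 4)
  expect_equal(e1$ebv_m, e2$ebv_m, tolerance = 1e-7)
  expect_equal(e1$ebv_d, e2$ebv_d, tolerance = 1e-7)
})

test_that("variance reassessment tracks the cohort covariance", {
  set.seed(59)
  pars <- trait_params(n_loci = 400)
  p <- sample_founder_frequencies(400)
  eff <- sample_allele_effects(pars, p)
  # large base cohort: empirical covariance near the calibrated targets
  H <- matrix(as.integer(runif(400 * 4000) < p), 400)
  dos <- H[, 1:2000] + H[, 2001:4000]
  bv <- t(true_breeding_values(dos, eff))
  G <- reassess_variances(bv)
  expect_lt(abs(G[1, 1] - 1), 0.15)
  expect_lt(abs(G[2, 2] - 2), 0.3)
  expect_lt(abs(G[1, 2] - (-0.18 * sqrt(2))), 0.15)
  # identical genotypes: degenerate, floored
  Gd <- reassess_variances(matrix(1, 10, 2))
  expect_true(attr(Gd, "degenerate"))
  expect_true(all(eigen(Gd)$values >= 1e-9))
  # halving the direct values quarters the direct variance
  bv2 <- bv; bv2[, 2] <- bv2[, 2] / 2
  expect_equal(reassess_variances(bv2)[2, 2], G[2, 2] / 4, tolerance = 1e-9)
  expect_error(reassess_variances(bv[1, , drop = FALSE]), "at least 2")
})

test_that("EBV accuracy is positive and improves with less noise", {
  set.seed(61)
  accs <- vapply(c(16, 4, 0.5), function(s2e) {
    pop <- toy_population(n_queens = 60, sigma2_e = s2e)
    eb <- estimate_breeding_values(pop$records, pop$A, pop$G0, s2e,
                                   targets = pop$ids)
    cor(eb$ebv_m + eb$ebv_d, pop$true_crit)
  }, numeric(1))
  expect_true(all(accs > 0))
  expect_true(all(diff(accs) > 0))
})
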