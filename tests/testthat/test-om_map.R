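test_that("natural mortality leaves 1% of a cohort at the maximum age", {
  expect_equal(naturalMortality(60), 0.0767528, tolerance = 1e-6)
  expect_equal(naturalMortality(5), 0.9210340, tolerance = 1e-6)
  for (A in c(7, 23, 55)) expect_equal(exp(-naturalMortality(A) * A), 0.01)
  expect_error(naturalMortality(0))
})

test_that("growth rate is the von Bertalanffy inversion at maturity", {
  expect_equal(growthK(100, 50, 5), -log(0.5) / 5)
  expect_error(growthK(100, 120, 5))
})

test_that("Euler-Lotka root matches its closed forms", {
  # exact replacement
  phi <- c(0, 0.4, 0.6)
  expect_equal(eulerLotkaRate(phi, 1:3), 0, tolerance = 1e-8)
  # single reproductive age: r = log(phi)/a
  expect_equal(eulerLotkaRate(c(0, 0, 2), 1:3), log(2) / 3, tolerance = 1e-8)
  expect_equal(eulerLotkaRate(c(0.5, 0, 0), 1:3), log(0.5), tolerance = 1e-8)
})

test_that("intrinsic rate equals the Leslie-matrix dominant eigenvalue", {
  for (h in c(0.3, 0.6, 0.9)) {
    for (A in c(12, 40)) {
      life <- midLife(h = h, A_max = A, age_mat = 0.2 * A, Linf = 150,
                      Lmat = 70)
      expect_equal(intrinsicRate(life), leslieLogLambda(life),
                   tolerance = 1e-6)
    }
  }
})

test_that("intrinsic rate increases with steepness and net fecundity", {
  r_h <- vapply(c(0.3, 0.5, 0.7, 0.9),
                function(h) intrinsicRate(midLife(h = h)), numeric(1))
  expect_true(all(diff(r_h) > 0))
  # higher survival raises r when the low-density compensation is held fixed
  phi <- c(0, 0.2, 0.5, 0.8) * exp(-0.4 * (1:4))
  phi_hi <- c(0, 0.2, 0.5, 0.8) * exp(-0.3 * (1:4))
  expect_gt(eulerLotkaRate(phi_hi, 1:4), eulerLotkaRate(phi, 1:4))
  # and scaling the whole schedule up always raises r
  expect_gt(eulerLotkaRate(1.5 * phi, 1:4), eulerLotkaRate(phi, 1:4))
})

test_that("sampled operating models honour their scored intervals", {
  atts <- psaAttributes("sPSA")
  all1 <- setNames(rep(1L, 9), atts$name)
  all1[c("SizeMaturity", "MaxSize")] <- c(1L, 1L)
  for (seed in 1:5) {
    om <- sampleOperatingModel(all1, "sPSA", "Medium", seed = seed)
    l <- lifeHistory(om)
    expect_true(l$age_mat >= 1 && l$age_mat <= 5)
    expect_true(l$A_max >= 5 && l$A_max <= 10)
    expect_true(l$h >= 0.6 && l$h <= 0.95)
    expect_true(l$M / l$K >= 0.3 && l$M / l$K <= 4)
  }
  s3 <- setNames(rep(2L, 9), atts$name); s3["Steepness"] <- 3L
  om <- sampleOperatingModel(s3, "sPSA", "High", seed = 2)
  expect_true(lifeHistory(om)$h >= 0.21 && lifeHistory(om)$h <= 0.4)
  expect_true(om@depletion >= 0.4 && om@depletion <= 0.8)
  # bit-reproducible under a fixed seed
  om2 <- sampleOperatingModel(s3, "sPSA", "High", seed = 2)
  expect_identical(lifeHistory(om), lifeHistory(om2))
  expect_identical(fleetDynamics(om), fleetDynamics(om2))
})

test_that("ePSA sampling lands the derived r and K in their scored bins", {
  atts <- psaAttributes("ePSA")
  sc <- setNames(rep(2L, 12), atts$name)
  om <- sampleOperatingModel(sc, "ePSA", seed = 4)
  l <- lifeHistory(om)
  expect_true(l$r >= 0.16 && l$r <= 0.5)
  expect_true(l$K >= 0.15 && l$K <= 0.25)
  expect_true(om@depletion >= 0.25 && om@depletion <= 0.4)
  sc["Depletion"] <- 1L
  om1 <- sampleOperatingModel(sc, "ePSA", seed = 4)
  expect_true(om1@depletion > 0.4 && om1@depletion < 0.8)
})

test_that("operating models round-trip through JSON", {
  sc <- setNames(rep(2L, 9), psaAttributes("sPSA")$name)
  om <- sampleOperatingModel(sc, "sPSA", "Low", seed = 13)
  f <- tempfile(fileext = ".json")
  writeOperatingModel(om, f)
  om2 <- readOperatingModel(f)
  expect_equal(lifeHistory(om2), lifeHistory(om))
  expect_equal(fleetDynamics(om2), fleetDynamics(om))
  expect_identical(om2@scores, om@scores)
  expect_equal(om2@depletion, om@depletion)
  # the reconstructed model simulates equivalently (JSON text round-trip
  # is not bit-exact for doubles)
  expect_equal(ssbTrajectories(simulatePopulation(om2, n_sim = 3)),
               ssbTrajectories(simulatePopulation(om, n_sim = 3)),
               tolerance = 1e-8)
})

test_that("infeasible combinations exhaust the resampling budget", {
  base <- setNames(rep(2L, 9), psaAttributes("sPSA")$name)
  base["MaxAge"] <- 1L; base["AgeMaturity"] <- 3L
  expect_error(sampleOperatingModel(base, "sPSA", seed = 1,
                                    max_draws = 400L), "infeasible")
})
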