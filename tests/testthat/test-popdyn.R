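test_that("unfished equilibrium follows exponential survivorship", {
  om <- midOM()
  eq <- unfishedEquilibrium(om)
  M <- lifeHistory(om)$M
  expect_equal(eq$N0[2] / eq$N0[1], exp(-M))
  # direct summation oracle for ssb0, plus group accumulated explicitly
  life <- lifeHistory(om)
  A <- ceiling(life$A_max)
  a <- 0:A
  L <- life$Linf * (1 - exp(-life$K * a))
  w <- life$lw_a * L^life$lw_b
  mat <- 1 / (1 + exp(-log(19) * (L - life$Lmat) / (0.1 * life$Lmat)))
  l <- exp(-M * a)
  l[A + 1] <- l[A + 1] / (1 - exp(-M))
  expect_equal(eq$ssb0, sum(l * w * mat), tolerance = 1e-12)
})

test_that("Beverton-Holt equilibrium matches its closed form", {
  eq <- bhEquilibrium(0.6, 0.5)
  expect_equal(eq$relR, 0.8)
  expect_equal(eq$depletion, 0.4)
  # collapse below the replacement spawning-potential ratio
  h <- 0.45
  p_crit <- (1 - h) / (4 * h)
  expect_equal(bhEquilibrium(h, p_crit * 0.99)$depletion, 0)
  expect_gt(bhEquilibrium(h, p_crit * 1.01)$depletion, 0)
  expect_equal(bhEquilibrium(0.7, 1)$depletion, 1)
  om <- midOM()
  expect_equal(equilibriumDepletion(om, 0), 1, tolerance = 1e-12)
})

test_that("unfished projections hold the population at equilibrium", {
  om <- midOM()
  eq <- unfishedEquilibrium(om)
  pr <- projectForward(om, U = 0, n_years = 30, n_sim = 2)
  expect_equal(unname(pr$ssb), matrix(eq$ssb0, 2, 30), tolerance = 1e-10)
  # zero availability is equivalent to no fishing under proportional spatial
  om0 <- midOM(fleet = midFleet(availability = 0))
  pr0 <- projectForward(om0, U = 0.6, n_years = 30, n_sim = 1,
                        spatial = "proportional")
  expect_equal(unname(pr0$ssb[1, ]), rep(eq$ssb0, 30), tolerance = 1e-10)
  # under full mixing, availability does not alter the dynamics
  omA <- midOM(fleet = midFleet(availability = 0.15))
  omB <- midOM(fleet = midFleet(availability = 0.95))
  prA <- projectForward(omA, U = 0.4, n_years = 20, n_sim = 1)
  prB <- projectForward(omB, U = 0.4, n_years = 20, n_sim = 1)
  expect_equal(prA$ssb, prB$ssb)
})

test_that("deterministic projections converge to the closed-form equilibrium", {
  for (h in c(0.35, 0.6, 0.85)) {
    om <- midOM(life = midLife(h = h))
    for (U in c(0.1, 0.3, 0.5)) {
      ny <- 3000L   # near-collapse equilibria approach slowly
      pr <- projectForward(om, U = U, n_years = ny, n_sim = 1)
      got <- pr$ssb[1, ny] / unfishedEquilibrium(om)$ssb0
      expect_lt(abs(got - equilibriumDepletion(om, U)), 1e-3)
    }
  }
})

test_that("history conditioning hits the depletion target", {
  for (target in c(0.1, 0.3, 0.6)) {
    om <- midOM(depletion = target)
    cond <- conditionHistory(om, n_sim = 1)          # deterministic deviates
    expect_lt(abs(cond$depletion - target), 0.005)
    expect_false(any(cond$flag))
  }
  # lower targets require harder fishing
  s_low <- conditionHistory(midOM(depletion = 0.1), n_sim = 1)$scaler
  s_high <- conditionHistory(midOM(depletion = 0.6), n_sim = 1)$scaler
  expect_gt(s_low, s_high)
  # stochastic conditioning: each replicate's own deviates are honoured
  om <- midOM(depletion = 0.3)
  dev <- withr::with_seed(8, matrix(exp(rnorm(20 * 50, 0, 0.4) - 0.08),
                                    20, 50))
  cond <- conditionHistory(om, dev)
  expect_true(mean(abs(cond$depletion - 0.3) < 0.005) >= 0.95)
})

test_that("unreachable targets are flagged, not fabricated", {
  om <- midOM(fleet = midFleet(dome_sel = 0, Lc = 1200), depletion = 0.05)
  cond <- conditionHistory(om, n_sim = 1)
  expect_true(all(cond$flag))
  expect_equal(cond$depletion, 1, tolerance = 1e-9)
})

test_that("MSY reference points agree with a brute-force grid", {
  om <- midOM()
  msy <- msyReference(om)
  sc <- psasim:::.schedules(om@life, om@fleet)
  spr0 <- psasim:::.sprYpr(sc, 0)$spr
  grid <- seq(0, 0.9, by = 1e-4)
  yg <- vapply(grid, function(u) {
    pr <- psasim:::.sprYpr(sc, u)
    bhEquilibrium(om@life$h, pr$spr / spr0)$relR * pr$ypr
  }, numeric(1))
  expect_lt(abs(msy$u_msy - grid[which.max(yg)]), 2e-4)
  expect_gte(msy$msy, max(yg) - 1e-8)
  expect_lt(msy$ssb_msy, msy$ssb0)
  expect_equal(yg[1], 0)  # no yield without fishing
})

test_that("risk probabilities count replicate-years below the reference", {
  ssb <- matrix(1, 4, 50)
  expect_equal(riskProbability(ssb, reference = 0.5), 0)
  expect_equal(riskProbability(ssb, reference = 2), 1)
  half <- ssb; half[1:2, 41:50] <- 0.1
  expect_equal(riskProbability(half, reference = 0.5), 0.5)
  # averaging-rule options
  mixed <- ssb; mixed[1, 41] <- 0.1
  expect_equal(riskProbability(mixed, 0.5, rule = "any"), 0.25)
  expect_equal(riskProbability(mixed, 0.5, rule = "all"), 0)
  expect_equal(riskProbability(mixed, 0.5, rule = "peryear"), 1 / 40)
})

test_that("full simulation satisfies its structural invariants", {
  om <- midOM(seed = 21L)
  pr <- simulatePopulation(om, n_sim = 30)
  expect_true(all(ssbTrajectories(pr) >= 0))
  rk <- riskProbability(pr)
  expect_true(all(rk$p_01_b0 <= rk$p_02_b0 + 1e-12))     # nested thresholds
  expect_true(all(unlist(rk[, -1]) >= 0 & unlist(rk[, -1]) <= 1))
  # monotone risk in exploitation (median terminal SSB decreases)
  med <- apply(ssbTrajectories(pr)[, 50, ], 2, median)
  expect_true(all(diff(med) <= 1e-9))
  # deterministic single replicate: probabilities are multiples of 1/10
  pr1 <- simulatePopulation(om, n_sim = 1, deviates = FALSE)
  rk1 <- unlist(riskProbability(pr1)[, -1])
  expect_true(all(abs(rk1 * 10 - round(rk1 * 10)) < 1e-9))
  # determinism contract
  pr2 <- simulatePopulation(om, n_sim = 30)
  expect_identical(ssbTrajectories(pr), ssbTrajectories(pr2))
})
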