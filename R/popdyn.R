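#' Unfished equilibrium age structure
#'
#' Numbers-at-age decline exponentially with natural mortality from a
#' normalized recruitment of R0 = 1, with a plus group accumulating at the
#' maximum age. Unfished spawning biomass per recruit (SPR0) is the sum of
#' survivorship times maturity times weight over ages.
#'
#' @param om an \linkS4class{OperatingModel}.
#' @return list with \code{N0} (numbers-at-age, ages 0..A_max), \code{ssb0},
#'   and \code{spr0} (equal to \code{ssb0} since R0 = 1).
#' @export
unfishedEquilibrium <- function(om) {
  sc <- .schedules(om@life, om@fleet)
  l <- exp(-sc$M * sc$ages)
  l[sc$A + 1L] <- l[sc$A + 1L] / (1 - exp(-sc$M))  # plus group
  spr0 <- sum(l * sc$w * sc$mat)
  list(N0 = l, ssb0 = spr0, spr0 = spr0)
}

# Spawning biomass and yield per recruit under a fixed annual exploitation
# rate U. Removals (fraction U * vulnerability, clamped below 1) are taken
# before natural survival within the year; spawning is at the start of the
# year, before removals.
.sprYpr <- function(sched, U) {
  A <- sched$A
  hfrac <- pmin(U * sched$vul, 0.999)
  s <- (1 - hfrac) * exp(-sched$M)
  l <- numeric(A + 1L)
  l[1L] <- 1
  for (a in seq_len(A)) l[a + 1L] <- l[a] * s[a]
  l[A + 1L] <- l[A + 1L] / (1 - s[A + 1L])
  list(spr = sum(l * sched$w * sched$mat), ypr = sum(l * hfrac * sched$w))
}

.bhParams <- function(h, spr0, R0 = 1) {
  list(alpha = 4 * h / ((1 - h) * spr0),
       beta = (5 * h - 1) / ((1 - h) * spr0 * R0))
}

#' Beverton-Holt equilibrium recruitment and depletion
#'
#' Closed-form equilibrium of the Beverton-Holt stock-recruitment
#' relationship parameterized by steepness h, given the spawning potential
#' ratio p = SPR(U)/SPR(0): relative recruitment
#' R/R0 = (4 h p - (1 - h)) / ((5 h - 1) p), clamped at zero (the stock
#' collapses when p < (1-h)/(4h)), and equilibrium depletion
#' SSB/SSB0 = (R/R0) * p.
#'
#' @param h Beverton-Holt steepness in (0.2, 1].
#' @param p spawning potential ratio in (0, 1].
#' @return list with \code{relR} and \code{depletion}.
#' @examples
#' bhEquilibrium(0.6, 0.5)  # relR 0.8, depletion 0.4
#' @export
bhEquilibrium <- function(h, p) {
  stopifnot(h > 0.2, h <= 1, p > 0, p <= 1 + 1e-9)
  relR <- pmax(0, (4 * h * p - (1 - h)) / ((5 * h - 1) * p))
  list(relR = relR, depletion = relR * p)
}

#' Deterministic equilibrium depletion under a fixed exploitation rate
#'
#' @param om an \linkS4class{OperatingModel}.
#' @param U annual exploitation rate(s) in [0, 1).
#' @param spatial availability treatment: \code{"mixed"} (fully mixed
#'   two-area stock: the stock-level exploitation is realized regardless of
#'   the fished-area fraction) or \code{"proportional"} (removals scale
#'   with availability).
#' @return equilibrium SSB/SSB0 for each U.
#' @export
equilibriumDepletion <- function(om, U, spatial = "mixed") {
  stopifnot(all(U >= 0), all(U < 1))
  sc <- .schedules(om@life, om@fleet, spatial)
  spr0 <- .sprYpr(sc, 0)$spr
  vapply(U, function(u) {
    p <- .sprYpr(sc, u)$spr / spr0
    bhEquilibrium(om@life$h, p)$depletion
  }, numeric(1))
}

#' MSY reference points
#'
#' Finds the exploitation rate maximizing deterministic equilibrium yield
#' (equilibrium recruitment times yield per recruit) given the fleet's
#' selectivity, availability and discard mortality, by a coarse grid search
#' refined with golden-section optimization (tolerance 1e-4 on U).
#'
#' @param om an \linkS4class{OperatingModel}.
#' @param spatial availability treatment (see
#'   \code{\link{equilibriumDepletion}}).
#' @return list with \code{u_msy}, \code{ssb_msy}, \code{msy} (equilibrium
#'   yield) and \code{ssb0}.
#' @export
msyReference <- function(om, spatial = "mixed") {
  sc <- .schedules(om@life, om@fleet, spatial)
  spr0 <- .sprYpr(sc, 0)$spr
  yield <- function(u) {
    pr <- .sprYpr(sc, u)
    bhEquilibrium(om@life$h, pr$spr / spr0)$relR * pr$ypr
  }
  grid <- seq(0, 0.995, length.out = 120L)
  yg <- vapply(grid, yield, numeric(1))
  if (max(yg) <= 1e-12)
    stop("degenerate operating model: equilibrium yield is zero")
  i <- which.max(yg)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(yield, c(lo, hi), maximum = TRUE, tol = 1e-5)
  u_msy <- opt$maximum
  p <- .sprYpr(sc, u_msy)$spr / spr0
  ssb0 <- spr0
  ssb_msy <- bhEquilibrium(om@life$h, p)$depletion * ssb0
  if (ssb_msy <= 0 || ssb_msy >= ssb0)
    stop("degenerate operating model: no interior MSY")
  list(u_msy = u_msy, ssb_msy = ssb_msy, msy = opt$objective, ssb0 = ssb0)
}

# Autocorrelated lognormal recruitment deviates, bias-corrected to mean 1:
# eps_t = rho * eps_(t-1) + sqrt(1 - rho^2) * eta_t with stationary SD
# sigma = sqrt(log(1 + CV^2)); deviate = exp(eps_t - sigma^2 / 2).
.recDeviates <- function(n_sim, n_years, cv, rho) {
  sigma <- sqrt(log(1 + cv^2))
  eps <- matrix(0, n_sim, n_years)
  eps[, 1L] <- stats::rnorm(n_sim, 0, sigma)
  if (n_years > 1L) for (t in 2:n_years)
    eps[, t] <- rho * eps[, t - 1L] +
      sqrt(1 - rho^2) * stats::rnorm(n_sim, 0, sigma)
  exp(eps - sigma^2 / 2)
}

# Advance all replicates one year: spawn (SSB from start-of-year numbers),
# recruit (Beverton-Holt x deviate), remove the harvested fraction, apply
# natural survival, shift ages with a plus group. `surv` is (A+1) x n_sim
# (or a vector recycled across replicates).
.stepYear <- function(N, sw, alpha, beta, dev_t, surv, A1) {
  ssb <- colSums(N * sw)
  N[1L, ] <- alpha * ssb / (1 + beta * ssb) * dev_t
  Np <- N * surv
  N[2:A1, ] <- Np[1:(A1 - 1L), ]
  N[A1, ] <- N[A1, ] + Np[A1, ]
  list(N = N, ssb = ssb)
}

# Simulate n_hist years under a linearly increasing exploitation ramp
# U_t = scaler * t / n_hist (scaler per replicate); per-age removal
# fractions are clamped at 0.99.
.simulateRamp <- function(N, sched, bh, dev, scaler, n_hist) {
  A1 <- sched$A + 1L
  n <- ncol(N)
  ssb <- matrix(0, n, n_hist)
  eM <- exp(-sched$M)
  sw <- sched$w * sched$mat
  for (t in seq_len(n_hist)) {
    H <- pmin(outer(sched$vul, scaler * t / n_hist), 0.99)
    st <- .stepYear(N, sw, bh$alpha, bh$beta, dev[, t], (1 - H) * eM, A1)
    N <- st$N
    ssb[, t] <- st$ssb
  }
  list(N = N, ssb = ssb)
}

# Simulate n_years at a fixed exploitation rate U (scalar).
.simulateFixed <- function(N, sched, bh, dev, U, n_years) {
  A1 <- sched$A + 1L
  ssb <- matrix(0, ncol(N), n_years)
  surv <- (1 - pmin(U * sched$vul, 0.999)) * exp(-sched$M)
  sw <- sched$w * sched$mat
  for (t in seq_len(n_years)) {
    st <- .stepYear(N, sw, bh$alpha, bh$beta, dev[, t], surv, A1)
    N <- st$N
    ssb[, t] <- st$ssb
  }
  list(N = N, ssb = ssb)
}

#' Condition the historical period to a target depletion
#'
#' Simulates 50 historical years from the unfished state under a linearly
#' increasing exploitation trajectory U_t = scaler * t / 50 and solves the
#' scaler per replicate by bisection so that terminal-year SSB/SSB0 is
#' within +/- \code{tol} of the operating model's depletion target, holding
#' the replicate's recruitment deviates fixed. If the target is unreachable
#' (the effective vulnerability is too small to deplete the stock even at
#' the maximum ramp), the replicate keeps the closest achievable depletion
#' and is counted in \code{n_unconditioned}.
#'
#' @param om an \linkS4class{OperatingModel}.
#' @param rec_devs n_sim x n_hist matrix of multiplicative recruitment
#'   deviates, or \code{NULL} for deterministic conditioning (deviates 1).
#' @param n_sim replicates (used when \code{rec_devs} is NULL).
#' @param n_hist historical years.
#' @param tol depletion tolerance.
#' @param spatial availability treatment (see
#'   \code{\link{equilibriumDepletion}}).
#' @return list with \code{scaler} (per replicate), \code{ssb} (n_sim x
#'   n_hist historical SSB), \code{N} (terminal numbers-at-age matrix),
#'   \code{depletion} (achieved terminal SSB/SSB0), \code{flag} (logical,
#'   TRUE when off target), and \code{ssb0}.
#' @export
conditionHistory <- function(om, rec_devs = NULL, n_sim = 100L,
                             n_hist = 50L, tol = 0.005, spatial = "mixed") {
  sched <- .schedules(om@life, om@fleet, spatial)
  eq <- unfishedEquilibrium(om)
  bh <- .bhParams(om@life$h, eq$spr0)
  if (is.null(rec_devs)) rec_devs <- matrix(1, n_sim, n_hist)
  n <- nrow(rec_devs)
  N0 <- matrix(eq$N0, sched$A + 1L, n)
  target <- om@depletion

  vmax <- max(sched$vul)
  smax <- if (vmax < 1e-8) 0 else min(4 * 0.99 / vmax, 1e6)
  lo <- rep(0, n); hi <- rep(smax, n)
  run <- NULL
  for (it in seq_len(20L)) {
    mid <- (lo + hi) / 2
    run <- .simulateRamp(N0, sched, bh, rec_devs, mid, n_hist)
    depl <- run$ssb[, n_hist] / eq$ssb0
    over <- depl > target           # still above target: fish harder
    lo[over] <- mid[over]
    hi[!over] <- mid[!over]
  }
  scaler <- (lo + hi) / 2
  run <- .simulateRamp(N0, sched, bh, rec_devs, scaler, n_hist)
  depl <- run$ssb[, n_hist] / eq$ssb0
  list(scaler = scaler, ssb = run$ssb, N = run$N, depletion = depl,
       flag = abs(depl - target) > tol, ssb0 = eq$ssb0)
}

#' Project a conditioned population forward at a fixed exploitation rate
#'
#' Annual dynamics: the removal fraction per age is U times the effective
#' vulnerability (availability x selectivity-at-age x discard-survival
#' factor); removals are taken before natural survival; recruitment is
#' Beverton-Holt on start-of-year spawning biomass with the supplied
#' multiplicative deviates.
#'
#' @param om an \linkS4class{OperatingModel}.
#' @param N starting numbers-at-age matrix (ages x replicates), e.g. the
#'   \code{N} component of \code{\link{conditionHistory}}; \code{NULL}
#'   starts from the unfished state.
#' @param U annual exploitation rate.
#' @param n_years projection years.
#' @param rec_devs n_sim x n_years deviate matrix, or \code{NULL} for
#'   deterministic projection.
#' @param n_sim replicates when \code{N} and \code{rec_devs} are NULL.
#' @param spatial availability treatment (see
#'   \code{\link{equilibriumDepletion}}).
#' @return list with \code{ssb} (replicates x years) and terminal \code{N}.
#' @export
projectForward <- function(om, N = NULL, U = 0.2, n_years = 50L,
                           rec_devs = NULL, n_sim = 1L, spatial = "mixed") {
  sched <- .schedules(om@life, om@fleet, spatial)
  eq <- unfishedEquilibrium(om)
  bh <- .bhParams(om@life$h, eq$spr0)
  if (is.null(N)) {
    n <- if (is.null(rec_devs)) n_sim else nrow(rec_devs)
    N <- matrix(eq$N0, sched$A + 1L, n)
  }
  if (is.null(rec_devs)) rec_devs <- matrix(1, ncol(N), n_years)
  .simulateFixed(N, sched, bh, rec_devs, U, n_years)
}

#' Simulate a full replicate set: history, projection and reference points
#'
#' Runs the complete per-model simulation: draws autocorrelated lognormal
#' recruitment deviates, conditions every replicate's 50-year history to the
#' depletion target, projects 50 years at each requested exploitation rate
#' (sharing the replicate's projection deviates across rates), and computes
#' the unfished and MSY reference points.
#'
#' @param om an \linkS4class{OperatingModel}.
#' @param n_sim replicates.
#' @param U exploitation rates for the projection scenarios.
#' @param n_hist,n_proj years in the historical and projection periods.
#' @param deviates apply recruitment process error (TRUE) or run
#'   deterministically (FALSE).
#' @param seed RNG seed (defaults to the operating model's own seed).
#' @param tol conditioning tolerance on depletion.
#' @param spatial availability treatment (see
#'   \code{\link{equilibriumDepletion}}).
#' @return a \linkS4class{PopProjection}.
#' @examples
#' sc <- setNames(rep(2L, 9), psaAttributes("sPSA")$name)
#' om <- sampleOperatingModel(sc, "sPSA", "Medium", seed = 7)
#' pr <- simulatePopulation(om, n_sim = 5)
#' riskProbability(pr)
#' @export
simulatePopulation <- function(om, n_sim = 100L, U = c(0.2, 0.4, 0.6),
                               n_hist = 50L, n_proj = 50L, deviates = TRUE,
                               seed = om@seed, tol = 0.005,
                               spatial = "mixed") {
  msy <- msyReference(om, spatial)
  dev <- if (deviates) {
    withSeed(seed, .recDeviates(n_sim, n_hist + n_proj, om@sigmaR, om@rho))
  } else matrix(1, n_sim, n_hist + n_proj)
  cond <- conditionHistory(om, dev[, seq_len(n_hist), drop = FALSE],
                           n_hist = n_hist, tol = tol, spatial = spatial)
  sched <- .schedules(om@life, om@fleet, spatial)
  bh <- .bhParams(om@life$h, msy$ssb0)
  pdev <- dev[, n_hist + seq_len(n_proj), drop = FALSE]
  ssb <- array(0, dim = c(n_sim, n_proj, length(U)))
  for (k in seq_along(U))
    ssb[, , k] <- .simulateFixed(cond$N, sched, bh, pdev, U[k], n_proj)$ssb
  new("PopProjection", ssb = ssb, ssbHist = cond$ssb, U = U,
      ssb0 = msy$ssb0, ssbMsy = msy$ssb_msy, uMsy = msy$u_msy,
      depletionAchieved = cond$depletion,
      nUnconditioned = sum(cond$flag))
}

#' Probability of breaching a biomass reference point
#'
#' The risk metric: the fraction of simulations in which spawning biomass
#' falls below the reference point during projection years 41-50 (by
#' default a simulation counts as failed if any window year is below the
#' reference). The \code{rule} argument exposes the alternative readings:
#' \code{"peryear"} averages the indicator over replicate-years,
#' \code{"all"} requires every window year below the reference.
#'
#' @param x a \linkS4class{PopProjection}, or a replicates x years SSB
#'   matrix.
#' @param reference for the matrix method, the numeric reference biomass.
#' @param years projection years over which risk is evaluated.
#' @param rule averaging rule (see Details).
#' @param ... passed between methods.
#' @return for a \code{PopProjection}: a data.frame with one row per
#'   exploitation rate and columns \code{U}, \code{p_half_bmsy} (P(SSB <
#'   0.5 BMSY)), \code{p_02_b0} (P(SSB < 0.2 SSB0)) and \code{p_01_b0}
#'   (P(SSB < 0.1 SSB0)); for a matrix: a single probability.
#' @export
setGeneric("riskProbability",
           function(x, ...) standardGeneric("riskProbability"))

#' @rdname riskProbability
#' @export
setMethod("riskProbability", "matrix",
  function(x, reference, years = 41:50, rule = c("any", "peryear", "all")) {
    rule <- match.arg(rule)
    years <- years[years <= ncol(x)]
    below <- x[, years, drop = FALSE] < reference
    switch(rule,
           peryear = mean(below),
           any = mean(apply(below, 1L, any)),
           all = mean(apply(below, 1L, all)))
  })

#' @rdname riskProbability
#' @export
setMethod("riskProbability", "PopProjection",
  function(x, years = 41:50, rule = c("any", "peryear", "all")) {
    rule <- match.arg(rule)
    refs <- c(p_half_bmsy = 0.5 * x@ssbMsy, p_02_b0 = 0.2 * x@ssb0,
              p_01_b0 = 0.1 * x@ssb0)
    out <- data.frame(U = x@U)
    for (m in names(refs)) out[[m]] <- vapply(seq_along(x@U), function(k) {
      s <- x@ssb[, , k, drop = FALSE]
      dim(s) <- dim(s)[1:2]
      riskProbability(s, refs[[m]], years, rule)
    }, numeric(1))
    out
  })
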