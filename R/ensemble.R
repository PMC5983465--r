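#' @include popdyn.R
NULL

#' EnsembleProjection: simulations with per-replicate parameter draws
#'
#' Like \linkS4class{PopProjection}, but every replicate carries its own
#' operating-model parameter set (drawn from the scored category intervals),
#' its own depletion target and recruitment-variability regime, and its own
#' unfished and MSY reference points. The risk probability for a scoring
#' combination then integrates over both parameter uncertainty within the
#' scored categories and recruitment process error, which is what the
#' "fraction of simulations below the reference point" metric measures.
#'
#' @slot ssb numeric array [replicate, projection year, exploitation rate].
#' @slot U exploitation rates.
#' @slot ssb0,ssbMsy,uMsy per-replicate reference points.
#' @slot depletionAchieved terminal historical depletion per replicate.
#' @slot nUnconditioned replicates off their depletion target.
#' @slot params the per-replicate parameter draws.
#' @export
setClass("EnsembleProjection",
  representation(ssb = "array", U = "numeric", ssb0 = "numeric",
                 ssbMsy = "numeric", uMsy = "numeric",
                 depletionAchieved = "numeric", nUnconditioned = "integer",
                 params = "data.frame"),
  validity = function(object) {
    msg <- NULL
    n <- dim(object@ssb)[1]
    if (length(object@ssb0) != n || length(object@ssbMsy) != n)
      msg <- c(msg, "per-replicate reference points must match replicates")
    if (any(object@ssb < 0)) msg <- c(msg, "ssb must be non-negative")
    if (any(object@ssbMsy <= 0 | object@ssbMsy >= object@ssb0))
      msg <- c(msg, "ssbMsy must satisfy 0 < ssbMsy < ssb0 per replicate")
    if (dim(object@ssb)[3] != length(object@U))
      msg <- c(msg, "third ssb dimension must match U")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "EnsembleProjection", function(object) {
  d <- dim(object@ssb)
  cat("EnsembleProjection:", d[1], "parameter draws x", d[2],
      "projection years x", d[3], "exploitation rates\n")
  cat(sprintf("  median ssb0=%.3f ssbMsy=%.3f uMsy=%.3f\n",
              stats::median(object@ssb0), stats::median(object@ssbMsy),
              stats::median(object@uMsy)))
  cat(sprintf("  conditioning: %d replicate(s) off-target\n",
              object@nUnconditioned))
})

#' Draw an ensemble of operating-model parameter sets for one combination
#'
#' Samples \code{n_sim} parameter sets for a scored combination, each drawn
#' uniformly within its scored category intervals subject to the joint
#' life-history constraints (and, for the ePSA, the derived r and K
#' categories), mirroring \code{\link{sampleOperatingModel}} but one draw
#' per simulation replicate. If fewer than \code{n_sim} acceptable sets are
#' found within the draw budget, the accepted sets are recycled (replicates
#' still receive independent recruitment deviates).
#'
#' @param scores named score vector or 1-row data.frame.
#' @param variant "sPSA" or "ePSA".
#' @param scenario sPSA initial-status scenario; ignored for ePSA.
#' @param n_sim parameter sets to draw.
#' @param seed RNG seed.
#' @param max_draws total candidate budget.
#' @return data.frame with one row per replicate: life history (A_max,
#'   age_mat, Linf, Lmat, h, M, K, r), fleet (availability, dome_sel, Lc,
#'   discard_rate, discard_mortality), depletion, sigmaR, rho.
#' @export
sampleEnsemble <- function(scores, variant = c("sPSA", "ePSA"),
                           scenario = c("Medium", "Low", "High"),
                           n_sim = 100L, seed = 1L, max_draws = 60000L) {
  variant <- match.arg(variant)
  scenario <- match.arg(scenario)
  if (is.data.frame(scores)) scores <- unlist(scores[1, , drop = TRUE])
  atts <- psaAttributes(variant)
  if (!all(atts$name %in% names(scores)))
    stop("scores must name every ", variant, " attribute")
  scores <- vapply(scores[atts$name], as.integer, integer(1))
  .checkScores(scores)

  withSeed(seed, {
    hits <- list()
    got <- 0L; drawn <- 0L
    while (got < n_sim && drawn < max_draws) {
      batch <- .lifeDrawBatch(400L, scores, variant)
      drawn <- drawn + 400L
      acc <- batch[batch$ok, , drop = FALSE]
      if (nrow(acc)) {
        hits[[length(hits) + 1L]] <- acc
        got <- got + nrow(acc)
      }
    }
    if (got == 0L)
      stop("resampling budget exhausted: score combination appears infeasible")
    life <- do.call(rbind, hits)
    idx <- if (got >= n_sim) seq_len(n_sim) else
      sample.int(got, n_sim, replace = TRUE)
    life <- life[idx, c("A_max", "age_mat", "Linf", "Lmat", "h", "M", "K",
                        "r")]

    n <- n_sim
    avail <- runifIn(n, attributeInterval("Availability", scores[["Availability"]]))
    dome <- runifIn(n, attributeInterval("Encounterability", scores[["Encounterability"]]))
    rel <- attributeInterval("Selectivity", scores[["Selectivity"]])
    lc_hi <- if (scores[["Selectivity"]] == 1L)
      0.95 * life$Linf else rel[2] * life$Lmat
    Lc <- stats::runif(n, rel[1] * life$Lmat,
                       pmax(lc_hi, rel[1] * life$Lmat + 1e-6))
    depl <- if (variant == "ePSA") {
      runifIn(n, attributeInterval("Depletion", scores[["Depletion"]], "ePSA"))
    } else {
      runifIn(n, switch(scenario, Low = c(0.025, 0.25),
                        Medium = c(0.25, 0.4), High = c(0.4, 0.8)))
    }
    data.frame(life,
               availability = avail, dome_sel = dome, Lc = Lc,
               discard_rate = runifIn(n, attributeInterval("Discard", scores[["Discard"]])),
               discard_mortality = runifIn(n, attributeInterval("Discard", scores[["Discard"]], what = "mortality")),
               depletion = depl,
               sigmaR = stats::runif(n, 0.3, 0.9),
               rho = stats::runif(n, 0, 0.9),
               row.names = NULL)
  })
}

# Per-replicate age schedules as (max age + 1) x n matrices, with an alive
# mask up to each replicate's own plus-group age.
.ensSchedules <- function(params, spatial = c("mixed", "proportional")) {
  spatial <- match.arg(spatial)
  n <- nrow(params)
  Ai <- ceiling(params$A_max)             # per-replicate plus-group age
  A <- max(Ai)
  ages <- 0:A
  amat <- matrix(ages, A + 1L, n)
  alive <- sweep(amat, 2L, Ai, `<=`)
  adv <- sweep(amat, 2L, Ai, `<`)         # may advance to the next age
  L <- sweep(1 - exp(amat * rep(-params$K, each = A + 1L)), 2L,
             params$Linf, `*`)
  w <- 1e-5 * L^3
  mat <- 1 / (1 + exp(-log(19) * sweep(sweep(L, 2L, params$Lmat, `-`), 2L,
                                       0.1 * params$Lmat, `/`)))
  asc <- 1 / (1 + exp(-log(19) * sweep(sweep(L, 2L, params$Lc, `-`), 2L,
                                       0.1 * params$Lc, `/`)))
  Lpeak <- 1.1 * params$Lc
  f <- clamp(sweep(sweep(L, 2L, Lpeak, `-`), 2L,
                   pmax(params$Linf - Lpeak, 1e-9), `/`), 0, 1)
  dome <- 1 - sweep(f^2, 2L, 1 - params$dome_sel, `*`)
  dfac <- 1 - params$discard_rate * (1 - params$discard_mortality)
  scale <- if (spatial == "proportional") params$availability * dfac else dfac
  vul <- sweep(asc * dome, 2L, scale, `*`)
  eM <- sweep(alive, 2L, exp(-params$M), `*`)   # natural survival, masked
  plusIdx <- cbind(Ai + 1L, seq_len(n))
  list(A1 = A + 1L, n = n, alive = alive, adv = adv,
       advTrim = adv[seq_len(A), , drop = FALSE], w = w,
       sw = w * mat, vul = vul, eM = eM, plusIdx = plusIdx)
}

# Per-recruit survivorship under per-replicate exploitation rates Uvec.
.ensPerRecruit <- function(sc, Uvec) {
  hfrac <- pmin(sc$vul * rep(Uvec, each = sc$A1), 0.999) * sc$alive
  surv <- (1 - hfrac) * sc$eM
  sa <- surv * sc$adv
  l <- matrix(0, sc$A1, sc$n)
  l[1L, ] <- 1
  for (a in seq_len(sc$A1 - 1L)) l[a + 1L, ] <- l[a, ] * sa[a, ]
  l[sc$plusIdx] <- l[sc$plusIdx] / (1 - surv[sc$plusIdx])
  list(spr = colSums(l * sc$sw), ypr = colSums(l * hfrac * sc$w), l = l)
}

.ensBh <- function(h, spr0) {
  list(alpha = 4 * h / ((1 - h) * spr0),
       beta = (5 * h - 1) / ((1 - h) * spr0))
}

# Equilibrium yield per replicate at per-replicate U.
.ensYield <- function(sc, h, spr0, Uvec) {
  pr <- .ensPerRecruit(sc, Uvec)
  p <- pr$spr / spr0
  relR <- pmax(0, (4 * h * p - (1 - h)) / ((5 * h - 1) * p))
  relR * pr$ypr
}

# Per-replicate MSY by a shared coarse grid plus shrinking local grids.
.ensMsy <- function(sc, h, spr0) {
  grid <- seq(0, 0.995, length.out = 48L)
  best <- rep(0, sc$n); besty <- rep(-Inf, sc$n)
  for (u in grid) {
    y <- .ensYield(sc, h, spr0, rep(u, sc$n))
    imp <- y > besty
    best[imp] <- u; besty[imp] <- y[imp]
  }
  step <- diff(grid[1:2])
  for (stage in 1:3) {
    for (d in seq(-1, 1, length.out = 9L)) {
      u <- clamp(best + d * step, 0, 0.999)
      y <- .ensYield(sc, h, spr0, u)
      imp <- y > besty
      best[imp] <- u[imp]; besty[imp] <- y[imp]
    }
    step <- step / 4
  }
  if (any(besty <= 1e-12))
    stop("degenerate operating model: equilibrium yield is zero")
  p <- .ensPerRecruit(sc, best)$spr / spr0
  relR <- pmax(0, (4 * h * p - (1 - h)) / ((5 * h - 1) * p))
  list(u_msy = best, ssb_msy = relR * p * spr0)
}

# One year for all replicates with per-replicate survival matrix. The age
# shift and per-replicate plus group are done with preallocated row
# assignments (this is the innermost loop of the whole package).
.ensStep <- function(N, sc, bh, dev_t, surv) {
  A1 <- sc$A1
  ssb <- colSums(N * sc$sw)
  N[1L, ] <- bh$alpha * ssb / (1 + bh$beta * ssb) * dev_t
  Np <- N * surv
  plusN <- Np[sc$plusIdx]
  N[2:A1, ] <- Np[1:(A1 - 1L), ] * sc$advTrim
  N[sc$plusIdx] <- N[sc$plusIdx] + plusN
  N[1L, ] <- 0
  list(N = N, ssb = ssb)
}

.ensRamp <- function(N, sc, bh, dev, scaler, n_hist) {
  ssb <- matrix(0, sc$n, n_hist)
  Vs <- sc$vul * rep(scaler, each = sc$A1)     # harvest at full ramp height
  for (t in seq_len(n_hist)) {
    surv <- (1 - pmin(Vs * (t / n_hist), 0.99)) * sc$eM
    st <- .ensStep(N, sc, bh, dev[, t], surv)
    N <- st$N; ssb[, t] <- st$ssb
  }
  list(N = N, ssb = ssb)
}

.ensFixed <- function(N, sc, bh, dev, U, n_years) {
  surv <- (1 - pmin(U * sc$vul, 0.999)) * sc$eM
  ssb <- matrix(0, sc$n, n_years)
  for (t in seq_len(n_years)) {
    st <- .ensStep(N, sc, bh, dev[, t], surv)
    N <- st$N; ssb[, t] <- st$ssb
  }
  list(N = N, ssb = ssb)
}

#' Simulate an ensemble of per-replicate operating models
#'
#' The ensemble analogue of \code{\link{simulatePopulation}}: every
#' replicate runs its own parameter set from \code{\link{sampleEnsemble}}
#' through the same annual dynamics (50-year depletion-conditioned history,
#' 50-year projections at each exploitation rate), with per-replicate
#' unfished and MSY reference points.
#'
#' @param params data.frame from \code{\link{sampleEnsemble}}.
#' @param U exploitation rates.
#' @param n_hist,n_proj years in each period.
#' @param deviates recruitment process error on/off.
#' @param seed RNG seed for the deviates.
#' @param tol conditioning tolerance on depletion.
#' @param spatial availability treatment (see
#'   \code{\link{equilibriumDepletion}}): under the default fully-mixed
#'   two-area stock, availability does not scale removals.
#' @return an \linkS4class{EnsembleProjection}.
#' @export
simulateEnsemble <- function(params, U = c(0.2, 0.4, 0.6), n_hist = 50L,
                             n_proj = 50L, deviates = TRUE, seed = 1L,
                             tol = 0.005, spatial = "mixed") {
  sc <- .ensSchedules(params, spatial)
  # drop degenerate draws (effectively unfishable fleet: zero vulnerability
  # at every age) rather than failing the whole combination
  vmax0 <- apply(sc$vul, 2L, max)
  if (any(vmax0 < 1e-4)) {
    keep <- vmax0 >= 1e-4
    if (!any(keep))
      stop("degenerate operating model: equilibrium yield is zero")
    warning(sum(!keep), " degenerate parameter draw(s) dropped",
            call. = FALSE)
    params <- params[keep, , drop = FALSE]
    sc <- .ensSchedules(params, spatial)
  }
  n <- sc$n
  pr0 <- .ensPerRecruit(sc, rep(0, n))
  spr0 <- pr0$spr
  bh <- .ensBh(params$h, spr0)
  msy <- .ensMsy(sc, params$h, spr0)
  dev <- if (deviates) {
    withSeed(seed, {
      sigma <- sqrt(log(1 + params$sigmaR^2))
      eps <- matrix(0, n, n_hist + n_proj)
      eps[, 1L] <- stats::rnorm(n, 0, sigma)
      for (t in 2:(n_hist + n_proj))
        eps[, t] <- params$rho * eps[, t - 1L] +
          sqrt(1 - params$rho^2) * stats::rnorm(n, 0, sigma)
      exp(eps - sigma^2 / 2)
    })
  } else matrix(1, n, n_hist + n_proj)

  # condition each replicate's ramp scaler to its own depletion target
  N0 <- pr0$l
  vmax <- pmax(apply(sc$vul, 2L, max), 1e-8)
  lo <- rep(0, n); hi <- pmin(4 * 0.99 / vmax, 1e6)
  hi[vmax <= 1e-7] <- 0
  hdev <- dev[, seq_len(n_hist), drop = FALSE]
  for (it in seq_len(20L)) {
    mid <- (lo + hi) / 2
    depl <- .ensRamp(N0, sc, bh, hdev, mid, n_hist)$ssb[, n_hist] / spr0
    over <- depl > params$depletion
    lo[over] <- mid[over]
    hi[!over] <- mid[!over]
  }
  scaler <- (lo + hi) / 2
  run <- .ensRamp(N0, sc, bh, hdev, scaler, n_hist)
  depl <- run$ssb[, n_hist] / spr0

  pdev <- dev[, n_hist + seq_len(n_proj), drop = FALSE]
  ssb <- array(0, dim = c(n, n_proj, length(U)))
  for (k in seq_along(U))
    ssb[, , k] <- .ensFixed(run$N, sc, bh, pdev, U[k], n_proj)$ssb
  new("EnsembleProjection", ssb = ssb, U = U, ssb0 = spr0,
      ssbMsy = msy$ssb_msy, uMsy = msy$u_msy, depletionAchieved = depl,
      nUnconditioned = sum(abs(depl - params$depletion) > tol),
      params = params)
}

#' @rdname riskProbability
#' @export
setMethod("riskProbability", "EnsembleProjection",
  function(x, years = 41:50, rule = c("any", "peryear", "all")) {
    rule <- match.arg(rule)
    refs <- list(p_half_bmsy = 0.5 * x@ssbMsy, p_02_b0 = 0.2 * x@ssb0,
                 p_01_b0 = 0.1 * x@ssb0)
    out <- data.frame(U = x@U)
    for (m in names(refs)) out[[m]] <- vapply(seq_along(x@U), function(k) {
      s <- x@ssb[, , k, drop = FALSE]
      dim(s) <- dim(s)[1:2]
      below <- sweep(s[, years, drop = FALSE], 1L, refs[[m]], `<`)
      switch(rule, peryear = mean(below),
             any = mean(apply(below, 1L, any)),
             all = mean(apply(below, 1L, all)))
    }, numeric(1))
    out
  })
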