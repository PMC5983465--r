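#' Natural mortality from maximum age
#'
#' Assumes 1% of a cohort survives to the maximum observed age, so
#' M = -log(0.01) / Amax.
#'
#' @param A_max maximum age in years (> 0), vectorized.
#' @return instantaneous natural mortality rate per year.
#' @examples
#' naturalMortality(60)
#' @export
naturalMortality <- function(A_max) {
  if (any(A_max <= 0)) stop("A_max must be positive")
  -log(0.01) / A_max
}

#' von Bertalanffy growth rate implied by maturity schedule
#'
#' The growth coefficient K is never sampled directly: it is determined
#' analytically from the asymptotic length, the length at maturity and the
#' age at maturity by inverting the von Bertalanffy curve (with t0 = 0), so
#' that length-at-age reaches Lmat exactly at the age of maturity:
#' K = -log(1 - Lmat/Linf) / age_mat.
#'
#' @param Linf asymptotic length (cm).
#' @param Lmat length at 50\% maturity (cm), must be below Linf.
#' @param age_mat age at 50\% maturity (years).
#' @return growth rate K per year.
#' @export
growthK <- function(Linf, Lmat, age_mat) {
  if (any(Lmat >= Linf)) stop("Lmat must be below Linf")
  if (any(age_mat <= 0)) stop("age_mat must be positive")
  -log(1 - Lmat / Linf) / age_mat
}

#' Intrinsic rate of increase from the Euler-Lotka balance
#'
#' Solves 1 = sum_a phi_a exp(-r a) for r, where phi_a combines survivorship
#' l_a = exp(-M a), maturity, weight-at-age (relative fecundity is taken
#' proportional to mature weight) and the maximum recruits-per-spawning-unit
#' implied by Beverton-Holt steepness: alpha0 = 4h / ((1 - h) * SPR0), the
#' compensation ratio 4h/(1-h) scaled by unfished spawners-per-recruit. The
#' demographic calculation truncates at the maximum age (no plus group), so
#' r equals the log of the dominant eigenvalue of the corresponding Leslie
#' matrix. A negative r (lifetime low-density reproduction below
#' replacement) is returned, not clamped.
#'
#' @param life named list with \code{A_max}, \code{M}, \code{K},
#'   \code{Linf}, \code{Lmat}, \code{h} (see \linkS4class{OperatingModel}).
#' @return intrinsic rate of increase r per year.
#' @seealso \code{\link{eulerLotkaRate}} for the root finder on an explicit
#'   net-fecundity schedule.
#' @export
intrinsicRate <- function(life) {
  stopifnot(all(c("A_max", "M", "K", "Linf", "Lmat", "h") %in% names(life)))
  with(life, .intrinsicRateVec(A_max, M, K, Linf, Lmat, h))
}

#' Solve the Euler-Lotka equation for a net fecundity schedule
#'
#' Finds the real root r of 1 = sum_a phi[a] * exp(-r * ages[a]) by
#' bracketing and bisection. phi is the expected number of age-0 recruits
#' produced (at low density) by a newborn when it reaches each age,
#' i.e. survivorship times per-capita fecundity.
#'
#' @param phi non-negative net fecundity schedule.
#' @param ages ages corresponding to \code{phi} (default \code{seq_along}).
#' @return the growth rate r (negative when lifetime reproduction < 1).
#' @examples
#' eulerLotkaRate(c(0, 0, 2), ages = 1:3)  # log(2)/3
#' @export
eulerLotkaRate <- function(phi, ages = seq_along(phi)) {
  stopifnot(length(phi) == length(ages), all(phi >= 0), sum(phi) > 0,
            all(ages > 0))
  g <- function(r) sum(phi * exp(-r * ages)) - 1
  lo <- -1; hi <- 1
  while (g(lo) < 0 && lo > -50) lo <- lo * 2
  while (g(hi) > 0 && hi < 50) hi <- hi * 2
  stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
}

# Vectorized intrinsic rate over parallel draws (bisection on a matrix of
# net-fecundity schedules); used by feasibility screening and OM sampling.
.intrinsicRateVec <- function(A_max, M, K, Linf, Lmat, h, max_age = 60L) {
  n <- length(A_max)
  a <- seq_len(max_age)                                  # ages 1..60
  amat <- matrix(a, max_age, n)
  alive <- sweep(amat, 2L, A_max, `<=`)
  l <- exp(-sweep(amat, 2L, M, `*`)) * alive             # survivorship
  L <- sweep(1 - exp(-sweep(amat, 2L, K, `*`)), 2L, Linf, `*`)
  w <- L^3                                               # length-weight scale cancels
  mat <- 1 / (1 + exp(-log(19) * sweep(sweep(L, 2L, Lmat, `-`), 2L,
                                       0.1 * Lmat, `/`)))
  sw <- mat * w
  spr0 <- colSums(l * sw)
  alpha0 <- 4 * h / ((1 - h) * spr0)
  phi <- sweep(l * sw, 2L, alpha0, `*`)
  # g(0) = 4h/(1-h) - 1 > 0 for h > 0.2, g decreasing in r
  rlo <- rep(-0.5, n); rhi <- rep(5, n)
  for (i in 1:50) {
    rmid <- (rlo + rhi) / 2
    gpos <- colSums(phi * exp(-rmid * amat)) > 1
    rlo[gpos] <- rmid[gpos]
    rhi[!gpos] <- rmid[!gpos]
  }
  (rlo + rhi) / 2
}

# Maturity ogive at length: logistic with L50 = Lmat, L95 = 1.1 * Lmat.
.maturityAtLength <- function(L, Lmat) {
  1 / (1 + exp(-log(19) * (L - Lmat) / (0.1 * Lmat)))
}

# Fishery selectivity at length: ascending logistic with L50 = Lc
# (L95 = 1.1 * Lc), and a descending limb declining quadratically from full
# selection at 1.1 * Lc down to dome_sel (the encounterability of the
# largest individuals) at Linf.
.selectivityAtLength <- function(L, Lc, dome_sel, Linf) {
  asc <- 1 / (1 + exp(-log(19) * (L - Lc) / (0.1 * Lc)))
  Lpeak <- 1.1 * Lc
  dome <- rep(1, length(L))
  if (Linf > Lpeak) {
    f <- clamp((L - Lpeak) / (Linf - Lpeak), 0, 1)
    dome <- 1 - (1 - dome_sel) * f^2
  }
  asc * dome
}

#' Serialize an operating model to JSON
#'
#' Writes (or reads back) every slot of an \linkS4class{OperatingModel} as
#' a JSON record, so that the exact model behind any design row can be
#' archived and re-simulated in isolation.
#'
#' @param om an \linkS4class{OperatingModel}.
#' @param path JSON file path.
#' @return \code{writeOperatingModel} returns \code{path} invisibly;
#'   \code{readOperatingModel} returns the reconstructed
#'   \linkS4class{OperatingModel}.
#' @export
writeOperatingModel <- function(om, path) {
  rec <- list(variant = om@variant, scores = as.list(om@scores),
              life = om@life, fleet = om@fleet, depletion = om@depletion,
              sigmaR = om@sigmaR, rho = om@rho, seed = om@seed)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeOperatingModel
#' @export
readOperatingModel <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("OperatingModel", variant = rec$variant,
      scores = vapply(rec$scores, as.integer, integer(1)),
      life = as.list(rec$life), fleet = as.list(rec$fleet),
      depletion = rec$depletion, sigmaR = rec$sigmaR, rho = rec$rho,
      seed = as.integer(rec$seed))
}

# Age schedules for an operating model: length, weight, maturity, fishery
# selectivity and effective vulnerability (selectivity x discard survival
# factor, times availability in the proportional reading) over ages
# 0..A_max.
.schedules <- function(life, fleet, spatial = c("mixed", "proportional")) {
  spatial <- match.arg(spatial)
  A <- ceiling(life$A_max)
  ages <- 0:A
  L <- life$Linf * (1 - exp(-life$K * (ages - life$t0)))
  w <- life$lw_a * L^life$lw_b
  mat <- .maturityAtLength(L, life$Lmat)
  sel <- .selectivityAtLength(L, fleet$Lc, fleet$dome_sel, life$Linf)
  dfac <- 1 - fleet$discard_rate * (1 - fleet$discard_mortality)
  # under full mixing an area closure gives no protection: the stock-level
  # exploitation is realized regardless of the fished-area fraction, so
  # availability scales removals only in the "proportional" reading
  scale <- if (spatial == "proportional") fleet$availability * dfac else dfac
  list(ages = ages, A = A, L = L, w = w, mat = mat, sel = sel,
       vul = scale * sel, M = life$M)
}

# One vectorized batch of candidate life histories for a productivity score
# combination; returns the draws with derived M, K and joint-constraint flag.
.lifeDrawBatch <- function(n, pscores, variant) {
  age_mat <- runifIn(n, attributeInterval("AgeMaturity", pscores[["AgeMaturity"]]))
  A_max <- runifIn(n, attributeInterval("MaxAge", pscores[["MaxAge"]]))
  Linf <- runifIn(n, attributeInterval("MaxSize", pscores[["MaxSize"]]))
  Lmat <- runifIn(n, attributeInterval("SizeMaturity", pscores[["SizeMaturity"]]))
  h <- runifIn(n, attributeInterval("Steepness", pscores[["Steepness"]]))
  ratio <- Lmat / Linf
  ok <- age_mat <= 0.6 * A_max & ratio >= 0.3 & ratio <= 0.9
  M <- naturalMortality(A_max)
  K <- rep(NA_real_, n)
  K[ok] <- -log(1 - ratio[ok]) / age_mat[ok]
  ok[ok] <- M[ok] / K[ok] >= 0.3 & M[ok] / K[ok] <= 4
  if (variant == "ePSA") {
    kint <- attributeInterval("VonBK", pscores[["VonBK"]], "ePSA")
    ok[ok] <- K[ok] >= kint[1] & K[ok] <= kint[2]
  }
  r <- rep(NA_real_, n)
  if (any(ok)) {
    r[ok] <- .intrinsicRateVec(A_max[ok], M[ok], K[ok], Linf[ok], Lmat[ok],
                               h[ok])
    if (variant == "ePSA") {
      rint <- attributeInterval("RateIncrease", pscores[["RateIncrease"]], "ePSA")
      ok[ok] <- r[ok] >= rint[1] & r[ok] <= rint[2]
    }
  }
  data.frame(age_mat = age_mat, A_max = A_max, Linf = Linf, Lmat = Lmat,
             h = h, M = M, K = K, r = r, ok = ok)
}

#' Sample an operating model for a PSA score vector
#'
#' Draws every operating-model parameter uniformly within the interval of
#' its scored risk category (Table-style registry; see
#' \code{\link{psaAttributes}}), enforcing the joint life-history
#' constraints (M/K in [0.3, 4], Lmat/Linf in [0.3, 0.9], age at maturity
#' below 60\% of maximum age) by resampling, and for the ePSA additionally
#' requiring the derived von Bertalanffy K and intrinsic rate r to land in
#' their scored categories. The fleet is parameterized from the
#' susceptibility scores: availability as the mixed-area exposed fraction,
#' encounterability as the selectivity of the largest individuals (dome
#' height), the selectivity score as the length at 50\% selectivity relative
#' to the length at maturity, and the discard score as a (discard rate,
#' discard mortality) pair. Depletion at the end of the history is drawn
#' from the initial-status scenario interval for the sPSA (Low 0.025-0.25,
#' Medium 0.25-0.4, High 0.4-0.8) or from the scored depletion category for
#' the ePSA. Recruitment variability: CV ~ U(0.3, 0.9), autocorrelation
#' ~ U(0, 0.9).
#'
#' @param scores named vector (or 1-row data.frame) of attribute scores.
#' @param variant "sPSA" or "ePSA".
#' @param scenario initial stock status for the sPSA ("Low", "Medium",
#'   "High"); ignored for the ePSA, where depletion is a scored attribute.
#' @param seed integer seed; sampling is bit-reproducible given the seed.
#' @param max_draws resampling budget for the joint constraints.
#' @return an \linkS4class{OperatingModel}.
#' @examples
#' sc <- setNames(rep(2L, 9), psaAttributes("sPSA")$name)
#' om <- sampleOperatingModel(sc, "sPSA", "Medium", seed = 1)
#' @export
sampleOperatingModel <- function(scores, variant = c("sPSA", "ePSA"),
                                 scenario = c("Medium", "Low", "High"),
                                 seed = 1L, max_draws = 10000L) {
  variant <- match.arg(variant)
  scenario <- match.arg(scenario)
  if (is.data.frame(scores)) scores <- unlist(scores[1, , drop = TRUE])
  atts <- psaAttributes(variant)
  if (!all(atts$name %in% names(scores)))
    stop("scores must name every ", variant, " attribute")
  scores <- vapply(scores[atts$name], as.integer, integer(1))
  .checkScores(scores)

  withSeed(seed, {
    hit <- NULL
    drawn <- 0L
    while (is.null(hit) && drawn < max_draws) {
      batch <- .lifeDrawBatch(200L, scores, variant)
      drawn <- drawn + 200L
      if (any(batch$ok)) hit <- batch[which(batch$ok)[1], ]
    }
    if (is.null(hit))
      stop("resampling budget exhausted: score combination appears infeasible")

    life <- list(A_max = hit$A_max, age_mat = hit$age_mat, Linf = hit$Linf,
                 Lmat = hit$Lmat, h = hit$h, M = hit$M, K = hit$K,
                 t0 = 0, lw_a = 1e-5, lw_b = 3, r = hit$r)
    avail <- runifIn(1L, attributeInterval("Availability", scores[["Availability"]]))
    dome <- runifIn(1L, attributeInterval("Encounterability", scores[["Encounterability"]]))
    rel <- attributeInterval("Selectivity", scores[["Selectivity"]])
    # low-risk selectivity means capture only above maturity, anywhere up
    # to (nearly) the asymptotic length
    lc_hi <- if (scores[["Selectivity"]] == 1L)
      0.95 * life$Linf else rel[2] * life$Lmat
    Lc <- stats::runif(1L, rel[1] * life$Lmat, max(lc_hi, rel[1] * life$Lmat + 1e-6))
    drate <- runifIn(1L, attributeInterval("Discard", scores[["Discard"]]))
    dmort <- runifIn(1L, attributeInterval("Discard", scores[["Discard"]],
                                           what = "mortality"))
    fleet <- list(availability = avail, dome_sel = dome, Lc = Lc,
                  discard_rate = drate, discard_mortality = dmort)
    depl <- if (variant == "ePSA") {
      runifIn(1L, attributeInterval("Depletion", scores[["Depletion"]], "ePSA"))
    } else {
      runifIn(1L, switch(scenario, Low = c(0.025, 0.25),
                         Medium = c(0.25, 0.4), High = c(0.4, 0.8)))
    }
    new("OperatingModel", variant = variant, scores = scores, life = life,
        fleet = fleet, depletion = depl,
        sigmaR = stats::runif(1L, 0.3, 0.9), rho = stats::runif(1L, 0, 0.9),
        seed = as.integer(seed))
  })
}
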