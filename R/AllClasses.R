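#' @import methods
NULL

#' PsaDesign: a sampled experimental design over the PSA scoring space
#'
#' Holds the outcome of the four-step design procedure: enumerate every
#' scoring permutation of a PSA variant, drop biologically implausible
#' combinations, bin the overall productivity and susceptibility scores into
#' an 8 x 8 grid of equal-width classes (1-1.25, 1.25-1.5, ..., 2.75-3.0),
#' and sample up to \code{nPerCell} combinations per cell without
#' replacement.
#'
#' @slot variant "sPSA" or "ePSA".
#' @slot method susceptibility aggregation used for binning ("additive" or
#'   "multiplicative").
#' @slot scores data.frame of sampled combinations: one column per
#'   attribute, plus \code{P}, \code{S}, \code{V}, \code{category},
#'   \code{p_bin}, \code{s_bin}.
#' @slot cellCounts 8 x 8 integer matrix of feasible enumeration members per
#'   cell (before sampling).
#' @slot nPerCell target sample size per cell.
#' @slot seed integer seed the sampling was drawn under.
#' @export
setClass("PsaDesign",
  representation(variant = "character", method = "character",
                 scores = "data.frame", cellCounts = "matrix",
                 nPerCell = "integer", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@variant %in% c("sPSA", "ePSA"))
      msg <- c(msg, "variant must be 'sPSA' or 'ePSA'")
    if (!object@method %in% c("additive", "multiplicative"))
      msg <- c(msg, "method must be 'additive' or 'multiplicative'")
    if (!identical(dim(object@cellCounts), c(8L, 8L)))
      msg <- c(msg, "cellCounts must be 8 x 8")
    if (nrow(object@scores) > 64L * object@nPerCell)
      msg <- c(msg, "more sampled rows than 64 * nPerCell")
    need <- c("P", "S", "V", "p_bin", "s_bin")
    if (!all(need %in% names(object@scores)))
      msg <- c(msg, "scores must carry P, S, V, p_bin, s_bin")
    if (is.null(msg)) TRUE else msg
  })

#' OperatingModel: an age-structured operating model for one scored stock
#'
#' A fully parameterized fishery system sampled from the parameter intervals
#' of a PSA score vector: life history (growth, maturity, mortality,
#' Beverton-Holt steepness, derived intrinsic rate of increase), fleet
#' dynamics (availability, dome-shaped selectivity, length at capture,
#' discarding), the target depletion at the end of the historical period,
#' and the recruitment variability regime.
#'
#' @slot variant "sPSA" or "ePSA".
#' @slot scores named integer vector of the attribute scores the model was
#'   sampled from.
#' @slot life named list: \code{A_max}, \code{age_mat}, \code{Linf},
#'   \code{Lmat}, \code{h}, \code{M}, \code{K}, \code{t0}, \code{lw_a},
#'   \code{lw_b}, \code{r}.
#' @slot fleet named list: \code{availability}, \code{dome_sel}, \code{Lc},
#'   \code{discard_rate}, \code{discard_mortality}.
#' @slot depletion target SSB/SSB0 at the end of the 50-year history.
#' @slot sigmaR recruitment coefficient of variation (sampled U(0.3, 0.9)).
#' @slot rho recruitment deviate autocorrelation (sampled U(0, 0.9)).
#' @slot seed integer seed for the simulation RNG stream.
#' @export
setClass("OperatingModel",
  representation(variant = "character", scores = "integer", life = "list",
                 fleet = "list", depletion = "numeric", sigmaR = "numeric",
                 rho = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    l <- object@life; f <- object@fleet
    needL <- c("A_max", "age_mat", "Linf", "Lmat", "h", "M", "K")
    needF <- c("availability", "dome_sel", "Lc", "discard_rate",
               "discard_mortality")
    if (!all(needL %in% names(l))) {
      msg <- c(msg, "incomplete life history")
    } else {
      if (l$M / l$K < 0.3 - 1e-9 || l$M / l$K > 4 + 1e-9)
        msg <- c(msg, "M/K outside [0.3, 4]")
      if (l$Lmat / l$Linf < 0.3 - 1e-9 || l$Lmat / l$Linf > 0.9 + 1e-9)
        msg <- c(msg, "Lmat/Linf outside [0.3, 0.9]")
      if (l$age_mat > 0.6 * l$A_max + 1e-9)
        msg <- c(msg, "age at maturity above 60% of maximum age")
      if (l$h <= 0.2 || l$h > 1) msg <- c(msg, "steepness must be in (0.2, 1]")
    }
    if (!all(needF %in% names(f))) {
      msg <- c(msg, "incomplete fleet dynamics")
    } else {
      pr <- unlist(f[c("availability", "dome_sel", "discard_rate",
                       "discard_mortality")])
      if (any(pr < 0 | pr > 1)) msg <- c(msg, "fleet proportions outside [0, 1]")
    }
    if (object@depletion <= 0 || object@depletion >= 1)
      msg <- c(msg, "depletion target must be in (0, 1)")
    if (object@sigmaR < 0.3 - 1e-9 || object@sigmaR > 0.9 + 1e-9)
      msg <- c(msg, "sigmaR outside [0.3, 0.9]")
    if (object@rho < 0 || object@rho > 0.9 + 1e-9)
      msg <- c(msg, "rho outside [0, 0.9]")
    if (is.null(msg)) TRUE else msg
  })

#' PopProjection: simulated spawning-biomass trajectories for one model
#'
#' Output of \code{\link{simulatePopulation}}: replicate spawning-biomass
#' trajectories over the 50-year conditioning history and the 50-year
#' projection under each exploitation rate, together with the unfished and
#' MSY reference points needed for the risk metrics.
#'
#' @slot ssb numeric array [replicate, projection year, exploitation rate].
#' @slot ssbHist numeric matrix [replicate, historical year].
#' @slot U exploitation rates of the projection scenarios.
#' @slot ssb0 unfished spawning biomass (per recruit scale, R0 = 1).
#' @slot ssbMsy equilibrium spawning biomass at MSY.
#' @slot uMsy exploitation rate giving maximum sustainable yield.
#' @slot depletionAchieved terminal historical depletion per replicate.
#' @slot nUnconditioned replicates whose conditioning missed the target by
#'   more than the tolerance (unreachable targets; kept at the closest
#'   achievable depletion).
#' @export
setClass("PopProjection",
  representation(ssb = "array", ssbHist = "matrix", U = "numeric",
                 ssb0 = "numeric", ssbMsy = "numeric", uMsy = "numeric",
                 depletionAchieved = "numeric", nUnconditioned = "integer"),
  validity = function(object) {
    msg <- NULL
    if (any(object@ssb < 0) || any(object@ssbHist < 0))
      msg <- c(msg, "ssb must be non-negative")
    if (object@ssb0 <= 0) msg <- c(msg, "ssb0 must be positive")
    if (object@ssbMsy <= 0 || object@ssbMsy >= object@ssb0)
      msg <- c(msg, "ssbMsy must satisfy 0 < ssbMsy < ssb0")
    if (dim(object@ssb)[3] != length(object@U))
      msg <- c(msg, "third ssb dimension must match U")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "PsaDesign", function(object) {
  cat("PsaDesign:", object@variant, "/", object@method, "aggregation\n")
  cat("  sampled combinations:", nrow(object@scores),
      sprintf("(target %d per cell, %d non-empty cells)\n",
              object@nPerCell, sum(object@cellCounts > 0)))
  cat("  feasible enumeration members: ", sum(object@cellCounts),
      " (median per non-empty cell ",
      stats::median(object@cellCounts[object@cellCounts > 0]), ")\n", sep = "")
})

setMethod("show", "OperatingModel", function(object) {
  l <- object@life; f <- object@fleet
  cat("OperatingModel (", object@variant, ")\n", sep = "")
  cat(sprintf("  life: Amax=%.0f ageMat=%.1f Linf=%.0f Lmat=%.0f h=%.2f M=%.3f K=%.3f r=%.3f\n",
              l$A_max, l$age_mat, l$Linf, l$Lmat, l$h, l$M, l$K,
              if (is.null(l$r)) NA_real_ else l$r))
  cat(sprintf("  fleet: avail=%.2f dome=%.2f Lc=%.0f discRate=%.2f discMort=%.2f\n",
              f$availability, f$dome_sel, f$Lc, f$discard_rate,
              f$discard_mortality))
  cat(sprintf("  depletion target=%.3f sigmaR=%.2f rho=%.2f\n",
              object@depletion, object@sigmaR, object@rho))
})

setMethod("show", "PopProjection", function(object) {
  d <- dim(object@ssb)
  cat("PopProjection:", d[1], "replicates x", d[2], "projection years x",
      d[3], "exploitation rates\n")
  cat(sprintf("  ssb0=%.3f ssbMsy=%.3f uMsy=%.3f\n",
              object@ssb0, object@ssbMsy, object@uMsy))
  cat(sprintf("  conditioning: mean terminal depletion %.3f, %d replicate(s) off-target\n",
              mean(object@depletionAchieved), object@nUnconditioned))
})

#' Accessors for design and projection objects
#'
#' @param object a \code{PsaDesign} or \code{PopProjection}.
#' @return \code{designScores}: the sampled score table;
#'   \code{cellCounts}: the 8 x 8 feasible member counts;
#'   \code{ssbTrajectories}: the [replicate, year, U] projection array;
#'   \code{referencePoints}: named vector of ssb0, ssbMsy, uMsy.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("designScores", function(object) standardGeneric("designScores"))
#' @rdname accessors
#' @export
setMethod("designScores", "PsaDesign", function(object) object@scores)

#' @rdname accessors
#' @export
setGeneric("cellCounts", function(object) standardGeneric("cellCounts"))
#' @rdname accessors
#' @export
setMethod("cellCounts", "PsaDesign", function(object) object@cellCounts)

#' @rdname accessors
#' @export
setGeneric("ssbTrajectories", function(object) standardGeneric("ssbTrajectories"))
#' @rdname accessors
#' @export
setMethod("ssbTrajectories", "PopProjection", function(object) object@ssb)

#' @rdname accessors
#' @export
setGeneric("referencePoints", function(object) standardGeneric("referencePoints"))
#' @rdname accessors
#' @export
setMethod("referencePoints", "PopProjection", function(object)
  c(ssb0 = object@ssb0, ssbMsy = object@ssbMsy, uMsy = object@uMsy))

#' @rdname accessors
#' @export
setGeneric("lifeHistory", function(object) standardGeneric("lifeHistory"))
#' @rdname accessors
#' @export
setMethod("lifeHistory", "OperatingModel", function(object) object@life)

#' @rdname accessors
#' @export
setGeneric("fleetDynamics", function(object) standardGeneric("fleetDynamics"))
#' @rdname accessors
#' @export
setMethod("fleetDynamics", "OperatingModel", function(object) object@fleet)
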