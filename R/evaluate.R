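#' Expected additive risk surface
#'
#' The risk surface the PSA implies on the 8 x 8 grid of binned
#' productivity and susceptibility scores: risk increases linearly and
#' additively with the two bin centers, standardized so the (1, 1) cell is
#' 0 and the (8, 8) cell is 1. The surface is symmetric in its two axes.
#'
#' @return 8 x 8 matrix (rows = productivity bins, cols = susceptibility
#'   bins).
#' @export
expectedMatrix <- function() {
  centers <- seq(1.125, 2.875, by = 0.25)
  tot <- outer(centers, centers, `+`)
  m <- (tot - min(tot)) / (max(tot) - min(tot))
  dimnames(m) <- list(p_bin = 1:8, s_bin = 1:8)
  m
}

#' Observed risk surface on the productivity x susceptibility grid
#'
#' Averages the simulated risk over the design combinations in each cell
#' of the 8 x 8 grid, then min-max standardizes the non-missing cells to
#' [0, 1]. Cells with no simulated combinations are NA and are excluded
#' pairwise from the Frobenius distance. A constant surface standardizes to
#' all zeros and is flagged with the attribute \code{degenerate}.
#'
#' @param risk numeric vector of simulated risk probabilities, one per
#'   design row.
#' @param design a \linkS4class{PsaDesign} (or a data.frame with
#'   \code{p_bin} and \code{s_bin} columns matching \code{risk}).
#' @return 8 x 8 matrix with attributes \code{counts} (contributing
#'   combinations per cell) and \code{degenerate}.
#' @export
observedMatrix <- function(risk, design) {
  df <- if (is(design, "PsaDesign")) designScores(design) else design
  stopifnot(length(risk) == nrow(df))
  if (all(is.na(risk))) stop("no risk estimates to aggregate")
  f <- list(factor(df$p_bin, levels = 1:8), factor(df$s_bin, levels = 1:8))
  m <- tapply(risk, f, mean)
  counts <- tapply(rep(1L, length(risk)), f, sum)
  counts[is.na(counts)] <- 0L
  rng <- range(m, na.rm = TRUE)
  degenerate <- diff(rng) < .Machine$double.eps^0.5
  m <- if (degenerate) m * 0 else (m - rng[1]) / (rng[2] - rng[1])
  dimnames(m) <- dimnames(counts) <- list(p_bin = 1:8, s_bin = 1:8)
  structure(m, counts = counts, degenerate = degenerate)
}

#' Frobenius distance between risk surfaces
#'
#' sqrt(trace(A A*)) with A = E - O, equal to the square root of the sum of
#' squared elementwise differences; missing cells are excluded pairwise.
#'
#' @param E,O matrices of identical shape.
#' @return non-negative distance.
#' @export
frobeniusDistance <- function(E, O) {
  if (!identical(dim(E), dim(O))) stop("matrices must have the same shape")
  d <- E - O
  sqrt(sum(d[!is.na(d)]^2))
}

#' Similarity of an observed surface to the expected additive surface
#'
#' Rescales a Frobenius distance so that 1 means the observed surface is
#' identical to the expected additive pattern and 0 means it is as far from
#' it as the average of \code{n_random} matrices with cells drawn uniformly
#' on [0, 1] (same shape and missing-cell mask). Scores below 0 are
#' possible and indicate a surface worse than random.
#'
#' @param F_obs observed Frobenius distance (or an observed matrix, in
#'   which case the distance to \code{expected} is computed first).
#' @param expected the expected surface (default \code{\link{expectedMatrix}}).
#' @param mask logical matrix of cells to include (default: non-missing
#'   cells of \code{F_obs} when it is a matrix, else all).
#' @param n_random random baseline matrices.
#' @param seed RNG seed for the baseline.
#' @return similarity score (<= 1).
#' @examples
#' similarityScore(0)  # 1 by construction
#' @export
similarityScore <- function(F_obs, expected = expectedMatrix(), mask = NULL,
                            n_random = 1000L, seed = 1L) {
  if (is.matrix(F_obs)) {
    if (is.null(mask)) mask <- !is.na(F_obs)
    F_obs <- frobeniusDistance(expected, F_obs)
  }
  stopifnot(F_obs >= 0)
  if (is.null(mask)) mask <- !is.na(expected)
  Fr <- withSeed(seed, vapply(seq_len(n_random), function(i) {
    R <- expected
    R[] <- NA_real_
    R[mask] <- stats::runif(sum(mask))
    frobeniusDistance(expected, R)
  }, numeric(1)))
  1 - F_obs / mean(Fr)
}

#' LMG relative importance of the PSA attributes
#'
#' Fits a linear model of simulated risk on the individual attribute scores
#' (numeric 1-3) and decomposes the model R-squared into per-attribute
#' shares by the LMG method: each attribute's share is its sequential
#' R-squared contribution averaged over all orderings of the predictors,
#' computed exactly by enumerating all predictor subsets. Shares are
#' non-negative and sum to the model R-squared.
#'
#' @param attribute_scores data.frame or matrix of predictor scores (one
#'   column per attribute).
#' @param risk numeric response, one value per row.
#' @return list with \code{shares} (named, summing to \code{R2}) and
#'   \code{R2}.
#' @export
relativeImportance <- function(attribute_scores, risk) {
  X <- as.matrix(attribute_scores)
  p <- ncol(X)
  stopifnot(length(risk) == nrow(X), nrow(X) > p, p <= 20L)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant predictor column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  Xc <- scale(X, scale = FALSE)
  yc <- risk - mean(risk)
  Cxx <- crossprod(Xc)
  Cxy <- drop(crossprod(Xc, yc))
  tss <- sum(yc^2)
  nmask <- 2^p
  r2 <- numeric(nmask)                 # r2[mask + 1]
  bits <- function(mask) which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1L))) > 0L)
  for (mask in seq_len(nmask - 1L)) {
    s <- bits(mask)
    b <- solve(Cxx[s, s, drop = FALSE], Cxy[s])
    r2[mask + 1L] <- sum(b * Cxy[s]) / tss
  }
  w <- factorial(0:(p - 1L)) * factorial((p - 1L):0) / factorial(p)
  shares <- numeric(p)
  for (mask in seq_len(nmask - 1L)) {
    s <- bits(mask)
    for (k in s) {
      prev <- mask - bitwShiftL(1L, k - 1L)
      shares[k] <- shares[k] + w[length(s)] * (r2[mask + 1L] - r2[prev + 1L])
    }
  }
  names(shares) <- colnames(X)
  list(shares = shares, R2 = r2[nmask])
}

#' Mean risk per pair of attribute scores
#'
#' The two-way interaction surface between two attributes: the mean
#' simulated risk in each of the 9 (score_a, score_b) cells. Cells with no
#' simulated combinations (infeasible pairings) are NA.
#'
#' @param risk numeric risk per design row.
#' @param design a \linkS4class{PsaDesign} or score data.frame.
#' @param attr_a,attr_b attribute names.
#' @return 3 x 3 matrix with a \code{counts} attribute.
#' @export
interactionGrid <- function(risk, design, attr_a, attr_b) {
  df <- if (is(design, "PsaDesign")) designScores(design) else design
  stopifnot(attr_a %in% names(df), attr_b %in% names(df),
            length(risk) == nrow(df))
  f <- list(factor(df[[attr_a]], levels = 1:3),
            factor(df[[attr_b]], levels = 1:3))
  m <- tapply(risk, f, mean)
  counts <- tapply(rep(1L, length(risk)), f, sum)
  counts[is.na(counts)] <- 0L
  dimnames(m) <- dimnames(counts) <- list(a = 1:3, b = 1:3)
  names(dimnames(m)) <- c(attr_a, attr_b)
  structure(m, counts = counts)
}

#' Classification performance of the PSA against simulated risk
#'
#' Compares the three PSA vulnerability categories (thresholds 2.64 / 3.18
#' on V) with three equal categories of the simulated risk probability
#' (Low: P <= 0.33, Medium: 0.33 < P <= 0.66, High: P > 0.66; boundary
#' values fall in the lower category). Returns the 3 x 3 confusion matrix
#' (predicted category x simulated category), the overall accuracy
#' (trace / total) and the per-class sensitivity (diagonal over the true
#' class total).
#'
#' @param psa_category factor of predicted categories (Low/Medium/High), or
#'   numeric V scores (then classified with \code{v_thresholds}).
#' @param risk numeric simulated risk probabilities.
#' @param risk_terciles the two risk-category boundaries.
#' @param v_thresholds vulnerability thresholds when \code{psa_category} is
#'   numeric.
#' @return list with \code{counts}, \code{accuracy}, \code{sensitivity},
#'   \code{n}.
#' @examples
#' classificationStats(c(2, 3, 4), c(0.1, 0.5, 0.9))
#' @export
classificationStats <- function(psa_category, risk,
                                risk_terciles = c(0.33, 0.66),
                                v_thresholds = c(2.64, 3.18)) {
  if (is.numeric(psa_category))
    psa_category <- classifyVulnerability(psa_category, v_thresholds)
  lev <- c("Low", "Medium", "High")
  psa_category <- factor(psa_category, levels = lev)
  true <- cut(risk, breaks = c(-Inf, risk_terciles, Inf), labels = lev,
              right = TRUE)
  counts <- table(predicted = psa_category, simulated = true)
  acc <- sum(diag(counts)) / sum(counts)
  sens <- diag(counts) / colSums(counts)
  list(counts = counts, accuracy = acc, sensitivity = sens, n = sum(counts))
}

#' Re-score the PSA with a subset of attributes
#'
#' Recomputes P, S, V and the risk category using only the given attribute
#' subset (which must contain at least one productivity and one
#' susceptibility attribute), then re-derives the classification statistics
#' against the unchanged simulated risk. Used to ask whether a leaner
#' scoring system with only the most informative attributes predicts risk
#' better than the full set.
#'
#' @param design a \linkS4class{PsaDesign}.
#' @param risk numeric simulated risk per design row.
#' @param attribute_subset character vector of attribute names.
#' @param method susceptibility aggregation for the re-scoring (defaults to
#'   the design's method).
#' @param risk_terciles,v_thresholds category boundaries, as in
#'   \code{\link{classificationStats}}.
#' @return as \code{\link{classificationStats}}, plus \code{V} (the
#'   recomputed vulnerability scores) and \code{attributes}.
#' @export
subsetRescoring <- function(design, risk, attribute_subset,
                            method = design@method,
                            risk_terciles = c(0.33, 0.66),
                            v_thresholds = c(2.64, 3.18)) {
  atts <- psaAttributes(design@variant)
  stopifnot(all(attribute_subset %in% atts$name))
  pn <- intersect(attribute_subset, atts$name[atts$axis == "productivity"])
  sn <- intersect(attribute_subset, atts$name[atts$axis == "susceptibility"])
  if (length(pn) == 0L || length(sn) == 0L)
    stop("subset must contain at least one attribute from each axis")
  df <- designScores(design)
  P <- rowMeans(as.matrix(df[, pn, drop = FALSE]))
  S <- if (method == "additive") rowMeans(as.matrix(df[, sn, drop = FALSE]))
       else clamp(exp(rowMeans(log(as.matrix(df[, sn, drop = FALSE])))), 1, 3)
  V <- vulnerability(P, S)
  out <- classificationStats(V, risk, risk_terciles, v_thresholds)
  out$V <- V
  out$attributes <- attribute_subset
  out
}
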