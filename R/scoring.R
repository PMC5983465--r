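#' Aggregate productivity scores
#'
#' The overall productivity score P is the arithmetic mean of the ordinal
#' productivity-attribute scores, so P lies in [1, 3].
#'
#' @param scores numeric vector of ordinal scores, each in \{1, 2, 3\}.
#' @return mean score in [1, 3].
#' @examples
#' aggregateProductivity(c(1, 2, 3, 2, 1))
#' @export
aggregateProductivity <- function(scores) {
  .checkScores(scores)
  mean(scores)
}

#' Aggregate susceptibility scores
#'
#' The overall susceptibility score S is either the arithmetic mean
#' (\code{"additive"}, as in the extended PSA with equal weights) or the
#' geometric mean (\code{"multiplicative"}, as in the standard PSA, where a
#' single low-susceptibility attribute can render a stock nearly
#' invulnerable) of the attribute scores. By the AM-GM inequality the
#' additive aggregate is never below the multiplicative one.
#'
#' @param scores numeric vector of ordinal scores, each in \{1, 2, 3\}.
#' @param method \code{"additive"} or \code{"multiplicative"}.
#' @return aggregated score in [1, 3].
#' @examples
#' aggregateSusceptibility(c(1, 3, 3, 3), "multiplicative")
#' @export
aggregateSusceptibility <- function(scores,
                                    method = c("additive", "multiplicative")) {
  .checkScores(scores)
  method <- match.arg(method)
  if (method == "additive") mean(scores)
  else min(3, max(1, exp(mean(log(scores)))))
}

.checkScores <- function(scores) {
  if (length(scores) == 0L || !all(scores %in% 1:3))
    stop("scores must be a non-empty vector with elements in {1, 2, 3}")
  invisible(TRUE)
}

#' Vulnerability score
#'
#' Combines the overall productivity (P) and susceptibility (S) scores into
#' a single vulnerability score V. Under consistent scoring (1 = lowest
#' risk on both axes, the convention used throughout this package) V is the
#' Euclidean distance from the origin, \code{sqrt(P^2 + S^2)}, ranging from
#' sqrt(2) = 1.41 (all attributes scored 1) to sqrt(18) = 4.24 (all scored
#' 3). The \code{"reversed"} formula, \code{sqrt((P-3)^2 + (S-1)^2)}, is the
#' conversion used by scoring systems where 3 denotes the most productive
#' (lowest-risk) stocks; it is provided as a utility only.
#'
#' @param P,S overall scores in [1, 3] (vectorized).
#' @param formula \code{"origin"} (default) or \code{"reversed"}.
#' @return vulnerability score(s).
#' @examples
#' vulnerability(1, 1)  # 1.414
#' vulnerability(3, 3)  # 4.243
#' @export
vulnerability <- function(P, S, formula = c("origin", "reversed")) {
  formula <- match.arg(formula)
  if (any(P < 1 | P > 3 | S < 1 | S > 3))
    stop("P and S must lie in [1, 3]")
  if (formula == "origin") sqrt(P^2 + S^2) else sqrt((P - 3)^2 + (S - 1)^2)
}

#' Categorize a vulnerability score
#'
#' Assigns Low / Medium / High risk by comparing V with two thresholds
#' (defaults 2.64 and 3.18, the published terciles of V under uniformly
#' distributed scores; see \code{\link{tercileThresholds}}). A score exactly
#' equal to a threshold falls in the lower category.
#'
#' @param V vulnerability score(s), non-negative.
#' @param thresholds strictly increasing pair \code{c(lower, upper)}.
#' @return factor with levels \code{Low}, \code{Medium}, \code{High}.
#' @examples
#' classifyVulnerability(c(2, 3, 4))
#' @export
classifyVulnerability <- function(V, thresholds = c(2.64, 3.18)) {
  stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2],
            all(V >= 0))
  cut(V, breaks = c(-Inf, thresholds, Inf),
      labels = c("Low", "Medium", "High"), right = TRUE)
}

#' Monte-Carlo tercile thresholds of the vulnerability score
#'
#' If every attribute score were equally likely, the overall P and S scores
#' are treated as independent uniform on [1, 3]; the 1/3 and 2/3 quantiles
#' of V = sqrt(P^2 + S^2) then split stocks evenly into the three risk
#' categories. With a million samples these reproduce the published
#' thresholds 2.64 and 3.18 to two decimals.
#'
#' @param n_samples number of Monte-Carlo draws (>= 1e5).
#' @param seed integer seed for reproducibility.
#' @return named numeric vector \code{c(lower = ..., upper = ...)}.
#' @export
tercileThresholds <- function(n_samples = 1e6, seed = 1L) {
  stopifnot(n_samples >= 1e5)
  v <- withSeed(seed, {
    P <- stats::runif(n_samples, 1, 3)
    S <- stats::runif(n_samples, 1, 3)
    sqrt(P^2 + S^2)
  })
  q <- stats::quantile(v, c(1 / 3, 2 / 3), names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Score a table of PSA attribute ratings
#'
#' Batch interface: one row per stock (or scoring combination), one column
#' per attribute of the variant, values in \{1, 2, 3\}. Returns the input
#' with the overall productivity, susceptibility, vulnerability and risk
#' category appended. Missing attribute scores are handled by the
#' \code{missing} policy: \code{"error"} (default; the simulation design
#' always has full scores), \code{"high"} (precautionary: score as 3), or
#' \code{"drop"} (exclude from the aggregate).
#'
#' @param scores data.frame (or file path to a CSV) of ordinal scores.
#' @param variant PSA variant.
#' @param method susceptibility aggregation method.
#' @param missing missing-score policy.
#' @param thresholds vulnerability category thresholds.
#' @param file optional path; when given, the result is also written as CSV.
#' @return data.frame with columns \code{P}, \code{S}, \code{V},
#'   \code{category} appended.
#' @examples
#' sc <- enumerateScores("sPSA")[1:3, ]
#' scorePsa(sc, "sPSA")
#' @export
scorePsa <- function(scores, variant = c("sPSA", "ePSA"),
                     method = c("additive", "multiplicative"),
                     missing = c("error", "high", "drop"),
                     thresholds = c(2.64, 3.18), file = NULL) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  missing <- match.arg(missing)
  if (is.character(scores)) scores <- utils::read.csv(scores)
  atts <- psaAttributes(variant)
  need <- atts$name
  if (!all(need %in% names(scores)))
    stop("missing attribute columns: ",
         paste(setdiff(need, names(scores)), collapse = ", "))
  m <- as.matrix(scores[, need, drop = FALSE])
  if (anyNA(m)) {
    if (missing == "error") stop("NA scores present (see 'missing' policy)")
    if (missing == "high") m[is.na(m)] <- 3
  }
  pn <- atts$name[atts$axis == "productivity"]
  sn <- atts$name[atts$axis == "susceptibility"]
  P <- apply(m[, pn, drop = FALSE], 1L, function(x) mean(x, na.rm = TRUE))
  S <- if (method == "additive") {
    apply(m[, sn, drop = FALSE], 1L, function(x) mean(x, na.rm = TRUE))
  } else {
    pmin(3, pmax(1, apply(m[, sn, drop = FALSE], 1L,
                          function(x) exp(mean(log(x), na.rm = TRUE)))))
  }
  out <- cbind(scores, P = P, S = S, V = vulnerability(P, S))
  out$category <- classifyVulnerability(out$V, thresholds)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
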