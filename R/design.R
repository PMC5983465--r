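#' Enumerate all PSA scoring permutations
#'
#' Generates every assignment of ordinal scores \{1, 2, 3\} to the
#' attributes of a variant: 3^9 = 19,683 combinations for the sPSA and
#' 3^12 = 531,441 for the ePSA.
#'
#' @param variant "sPSA" or "ePSA".
#' @param attributes optional character vector of attribute names to
#'   enumerate over (mainly for small illustrative variants); defaults to
#'   the variant's registry attributes.
#' @return data.frame of integer scores, one column per attribute.
#' @examples
#' nrow(enumerateScores("sPSA"))  # 19683
#' @export
enumerateScores <- function(variant = c("sPSA", "ePSA"), attributes = NULL) {
  variant <- match.arg(variant)
  if (is.null(attributes)) attributes <- psaAttributes(variant)$name
  g <- expand.grid(rep(list(1:3), length(attributes)),
                   KEEP.OUT.ATTRS = FALSE)
  names(g) <- attributes
  g
}

#' Bin an overall score into the 8-class grid
#'
#' Total productivity and susceptibility scores in [1, 3] are categorized
#' into 8 classes of equal width (1-1.25, 1.25-1.50, ..., 2.75-3.0). Bins
#' are half-open [lo, hi) except the last, which is closed at 3.
#'
#' @param total_score numeric score(s) in [1, 3].
#' @return integer bin index in 1..8.
#' @examples
#' binIndex(c(1, 1.8, 3))  # 1, 4, 8
#' @export
binIndex <- function(total_score) {
  if (any(total_score < 1 | total_score > 3))
    stop("total score must lie in [1, 3]")
  findInterval(total_score, seq(1, 3, by = 0.25), rightmost.closed = TRUE)
}

#' Biological feasibility of score combinations
#'
#' A scoring combination is feasible if at least one operating-model
#' parameter set exists with every parameter inside its scored category
#' interval that jointly satisfies the empirical life-history constraints:
#' M/K in [0.3, 4], Lmat/Linf in [0.3, 0.9], age at maturity at most 60\%
#' of the maximum age, and (ePSA) the derived von Bertalanffy K and
#' intrinsic rate of increase r inside their scored categories. Feasibility
#' is decided by bounded rejection sampling (up to \code{n_draws} uniform
#' draws per combination) under a fixed internal RNG substream, so the
#' predicate is deterministic, order-independent, and depends only on the
#' productivity-attribute scores (results are memoised per
#' productivity-score combination).
#'
#' @param scores a data.frame of score vectors (one per row) or a single
#'   named vector; \code{feasibleScore} is the single-vector convenience
#'   wrapper.
#' @param variant "sPSA" or "ePSA".
#' @param n_draws rejection-sampling budget per combination.
#' @return logical vector, one element per score vector.
#' @examples
#' feasibleScore(c(AgeMaturity = 3, MaxAge = 1, MaxSize = 2, SizeMaturity = 2,
#'                 Steepness = 2, Availability = 2, Encounterability = 2,
#'                 Selectivity = 2, Discard = 2), "sPSA")  # FALSE
#' @export
feasibleScores <- function(scores, variant = c("sPSA", "ePSA"),
                           n_draws = 1000L) {
  variant <- match.arg(variant)
  atts <- psaAttributes(variant)
  pn <- atts$name[atts$axis == "productivity"]
  m <- as.matrix(scores[, pn, drop = FALSE])
  keys <- apply(m, 1L, paste, collapse = "")
  uk <- unique(keys)
  feas <- vapply(uk, function(k) {
    ps <- as.integer(strsplit(k, "")[[1]])
    names(ps) <- pn
    .feasibleKey(ps, variant, n_draws)
  }, logical(1))
  unname(feas[keys])
}

#' @rdname feasibleScores
#' @export
feasibleScore <- function(scores, variant = c("sPSA", "ePSA"),
                          n_draws = 1000L) {
  if (!is.data.frame(scores)) scores <- as.data.frame(as.list(scores))
  feasibleScores(scores, variant, n_draws)[1L]
}

# Memoised per-productivity-combination feasibility check. Runs under its
# own RNG substream (seeded from a stable hash of the key) so that the
# predicate is pure.
.feasibleKey <- function(pscores, variant, n_draws) {
  key <- paste0(variant, ":", paste(pscores, collapse = ""), ":", n_draws)
  cache <- .psasim_env$feasible
  if (is.null(cache)) cache <- .psasim_env$feasible <- new.env(parent = emptyenv())
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- withSeed(hashSeed(990001L, key), {
    found <- FALSE
    drawn <- 0L
    while (!found && drawn < n_draws) {
      chunk <- min(250L, n_draws - drawn)
      found <- any(.lifeDrawBatch(chunk, pscores, variant)$ok)
      drawn <- drawn + chunk
    }
    found
  })
  cache[[key]] <- res
  res
}

#' Build the sampled experimental design
#'
#' The four-step design procedure: enumerate all scoring permutations,
#' compute the overall productivity and susceptibility scores with the
#' chosen aggregation method, drop infeasible combinations, bin (P, S) into
#' the 8 x 8 grid, and sample up to \code{n_per_cell} combinations per cell
#' uniformly without replacement (cells with fewer feasible members
#' contribute all of them). With 10 per cell and all 64 cells populated the
#' design holds 640 combinations spread evenly over the score space.
#'
#' @param variant "sPSA" or "ePSA".
#' @param method susceptibility aggregation ("additive" or
#'   "multiplicative"); also used for the binning, so the design is
#'   self-consistent with the downstream scoring.
#' @param n_per_cell target combinations per cell.
#' @param seed integer seed (sampling is deterministic given the seed).
#' @param n_draws feasibility rejection-sampling budget.
#' @return a \linkS4class{PsaDesign}.
#' @export
buildDesign <- function(variant = c("sPSA", "ePSA"),
                        method = c("additive", "multiplicative"),
                        n_per_cell = 10L, seed = 1L, n_draws = 1000L) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  stopifnot(n_per_cell >= 1L)
  enum <- enumerateScores(variant)
  atts <- psaAttributes(variant)
  pn <- atts$name[atts$axis == "productivity"]
  sn <- atts$name[atts$axis == "susceptibility"]
  pm <- as.matrix(enum[, pn, drop = FALSE])
  sm <- as.matrix(enum[, sn, drop = FALSE])
  P <- rowMeans(pm)
  # clamp guards against floating-point drift just outside [1, 3]
  S <- if (method == "additive") rowMeans(sm)
       else clamp(exp(rowMeans(log(sm))), 1, 3)

  ok <- feasibleScores(enum, variant, n_draws)
  p_bin <- binIndex(P)
  s_bin <- binIndex(S)
  cell <- (p_bin - 1L) * 8L + s_bin

  tab <- table(factor(cell[ok], levels = 1:64))
  counts <- matrix(as.integer(tab), 8L, 8L, byrow = TRUE,
                   dimnames = list(p_bin = 1:8, s_bin = 1:8))

  idx_ok <- which(ok)
  take <- withSeed(hashSeed(seed, "design", variant, method), {
    unlist(lapply(split(idx_ok, cell[idx_ok]), function(members) {
      if (length(members) <= n_per_cell) members
      else sample(members, n_per_cell)
    }), use.names = FALSE)
  })
  take <- sort(take)
  out <- enum[take, , drop = FALSE]
  out$P <- P[take]
  out$S <- S[take]
  out$V <- vulnerability(out$P, out$S)
  out$category <- classifyVulnerability(out$V)
  out$p_bin <- p_bin[take]
  out$s_bin <- s_bin[take]
  rownames(out) <- NULL
  new("PsaDesign", variant = variant, method = method, scores = out,
      cellCounts = counts, nPerCell = as.integer(n_per_cell),
      seed = as.integer(seed))
}

#' Serialize a design to CSV (+ JSON sidecar)
#'
#' Writes one row per sampled score vector (attribute scores, P, S, V,
#' category, bins) and a JSON sidecar recording the variant, aggregation
#' method, seed and per-cell feasible counts.
#'
#' @param design a \linkS4class{PsaDesign}.
#' @param file CSV path; the sidecar is written next to it as
#'   \code{<file>.json}.
#' @return \code{file}, invisibly.
#' @export
writeDesign <- function(design, file) {
  utils::write.csv(designScores(design), file, row.names = FALSE)
  meta <- list(variant = design@variant, method = design@method,
               seed = design@seed, n_per_cell = design@nPerCell,
               cell_counts = design@cellCounts)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}
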