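#' PSA attribute registry
#'
#' The Productivity Susceptibility Analysis (PSA) rates a stock on a set of
#' life-history ("productivity") and fishery-interaction ("susceptibility")
#' attributes, each scored into one of three ordinal risk categories
#' (1 = low risk, 2 = medium, 3 = high). Every attribute is backed by a
#' closed numeric interval of an operating-model parameter per score, so a
#' scored stock can be translated into a simulable population model. The
#' registry ships as a human-editable YAML table
#' (\code{system.file("extdata", "attributes.yaml", package = "psasim")}).
#'
#' The standard PSA (sPSA) uses 9 attributes (5 productivity, 4
#' susceptibility); the extended PSA (ePSA) adds the intrinsic rate of
#' increase, the von Bertalanffy growth rate (both derived from the other
#' life-history parameters, never sampled directly) and current depletion,
#' for 12 attributes (7 productivity, 5 susceptibility).
#'
#' @param variant \code{"sPSA"} or \code{"ePSA"}.
#' @param registry a registry list as returned by
#'   \code{\link{readAttributeRegistry}}; defaults to the packaged table.
#' @return \code{psaAttributes} returns a data.frame with one row per
#'   attribute (columns \code{name}, \code{axis}, \code{units},
#'   \code{derived}, \code{composite}, and \code{lo1}..\code{hi3} interval
#'   bounds per score).
#' @examples
#' psaAttributes("sPSA")$name
#' @export
psaAttributes <- function(variant = c("sPSA", "ePSA"), registry = NULL) {
  variant <- match.arg(variant)
  if (is.null(registry)) registry <- .defaultRegistry()
  keep <- vapply(registry$attributes, function(a) variant %in% a$variants,
                 logical(1))
  atts <- registry$attributes[keep]
  df <- do.call(rbind, lapply(atts, function(a) {
    rng <- a$ranges
    data.frame(
      name = a$name, axis = a$axis, units = a$units,
      derived = isTRUE(a$derived), composite = isTRUE(a$composite),
      lo1 = rng[["1"]][1], hi1 = rng[["1"]][2],
      lo2 = rng[["2"]][1], hi2 = rng[["2"]][2],
      lo3 = rng[["3"]][1], hi3 = rng[["3"]][2],
      stringsAsFactors = FALSE)
  }))
  rownames(df) <- df$name
  # productivity attributes first, matching the published table layout
  df[order(df$axis == "susceptibility"), ]
}

# registry cache: parsed once per session
.psasim_env <- new.env(parent = emptyenv())

.defaultRegistry <- function() {
  if (is.null(.psasim_env$registry)) {
    path <- system.file("extdata", "attributes.yaml", package = "psasim")
    .psasim_env$registry <- readAttributeRegistry(path)
  }
  .psasim_env$registry
}

#' Read or write an attribute registry
#'
#' @param path YAML file path.
#' @return \code{readAttributeRegistry} returns the parsed registry list
#'   after validation; \code{writeAttributeRegistry} writes it and returns
#'   \code{path} invisibly.
#' @seealso \code{\link{psaAttributes}}
#' @export
readAttributeRegistry <- function(path) {
  reg <- yaml::read_yaml(path)
  .validateRegistry(reg)
  reg
}

#' @rdname readAttributeRegistry
#' @param registry registry list to serialize.
#' @export
writeAttributeRegistry <- function(registry, path) {
  .validateRegistry(registry)
  yaml::write_yaml(registry, path)
  invisible(path)
}

.validateRegistry <- function(reg) {
  stopifnot(is.list(reg), !is.null(reg$attributes))
  for (a in reg$attributes) {
    stopifnot(!is.null(a$name), a$axis %in% c("productivity", "susceptibility"),
              all(a$variants %in% c("sPSA", "ePSA")))
    rng <- a$ranges
    if (!identical(sort(names(rng)), c("1", "2", "3")))
      stop("attribute '", a$name, "': exactly three score levels required")
    for (k in names(rng)) {
      iv <- rng[[k]]
      if (length(iv) != 2L || !all(is.finite(iv)) || iv[1] >= iv[2])
        stop("attribute '", a$name, "': score ", k,
             " interval must be finite with lo < hi")
    }
    if (!isTRUE(a$composite)) {
      # interiors must not overlap and the union must cover the domain
      ivs <- rng[order(vapply(rng, `[`, numeric(1), 1L))]
      for (i in 1:2) {
        if (ivs[[i]][2] != ivs[[i + 1]][1])
          stop("attribute '", a$name,
               "': intervals must tile the sampling domain")
      }
    }
  }
  invisible(TRUE)
}

#' Interval of the operating-model parameter for a scored attribute
#'
#' @param name attribute name (a row of \code{\link{psaAttributes}}).
#' @param score ordinal score in \{1, 2, 3\}.
#' @param variant PSA variant.
#' @param what for the composite Discard attribute, which sub-interval:
#'   \code{"primary"} (discard rate) or \code{"mortality"}.
#' @return numeric length-2 vector \code{c(lo, hi)}.
#' @export
attributeInterval <- function(name, score, variant = "sPSA",
                              what = c("primary", "mortality")) {
  what <- match.arg(what)
  stopifnot(score %in% 1:3)
  reg <- .defaultRegistry()
  idx <- which(vapply(reg$attributes, function(a) a$name == name, logical(1)))
  if (length(idx) != 1L) stop("unknown attribute: ", name)
  a <- reg$attributes[[idx]]
  if (!variant %in% a$variants)
    stop("attribute '", name, "' is not part of the ", variant)
  rng <- if (what == "mortality") {
    if (!isTRUE(a$composite)) stop("'", name, "' has no mortality interval")
    a$mortality_ranges
  } else a$ranges
  as.numeric(rng[[as.character(score)]])
}
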