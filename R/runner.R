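#' Experiment configuration
#'
#' Bundles every knob of a full PSA evaluation experiment. The defaults
#' reproduce the published evaluation grid: for the sPSA, 2 aggregation
#' methods x 3 initial-status scenarios x 3 exploitation rates x 3 risk
#' metrics = 54 analysis cells; for the ePSA (where initial depletion is a
#' scored attribute, so there is a single "Scored" scenario), 2 x 3 x 3 =
#' 18 cells.
#'
#' @param variant "sPSA" or "ePSA".
#' @param methods susceptibility aggregation methods to run.
#' @param scenarios initial-status scenarios (sPSA only).
#' @param U future exploitation rates.
#' @param metrics risk metrics (columns of \code{\link{riskProbability}}).
#' @param n_per_cell design combinations per grid cell.
#' @param n_sim replicates per operating model.
#' @param seed master seed; all stage seeds are derived from it by stable
#'   hashing of the cell labels, so adding scenarios never perturbs
#'   existing cells.
#' @param deviates recruitment process error on/off.
#' @param outdir optional output directory for CSV/JSON artifacts.
#' @return a validated config list of class \code{psasimConfig}.
#' @export
experimentConfig <- function(variant = c("sPSA", "ePSA"),
                             methods = c("additive", "multiplicative"),
                             scenarios = NULL,
                             U = c(0.2, 0.4, 0.6),
                             metrics = c("p_half_bmsy", "p_02_b0", "p_01_b0"),
                             n_per_cell = 10L, n_sim = 100L, seed = 1L,
                             deviates = TRUE, outdir = NULL) {
  variant <- match.arg(variant)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(scenarios))
    scenarios <- if (variant == "sPSA") c("Low", "Medium", "High") else "Scored"
  if (variant == "ePSA") scenarios <- "Scored"
  stopifnot(all(U > 0 & U < 1), length(U) >= 1,
            all(metrics %in% c("p_half_bmsy", "p_02_b0", "p_01_b0")),
            n_per_cell >= 1, n_sim >= 1)
  structure(list(variant = variant, methods = methods, scenarios = scenarios,
                 U = U, metrics = metrics, n_per_cell = as.integer(n_per_cell),
                 n_sim = as.integer(n_sim), seed = as.integer(seed),
                 deviates = isTRUE(deviates), outdir = outdir),
            class = "psasimConfig")
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file with fields matching the arguments of
#'   \code{\link{experimentConfig}}.
#' @return a \code{psasimConfig}.
#' @export
readExperimentConfig <- function(path) {
  do.call(experimentConfig, yaml::read_yaml(path))
}

#' Simulate every operating model of a design
#'
#' Maps each sampled score combination to an operating model, simulates it
#' (history conditioning + projections at each exploitation rate) and
#' returns the risk probabilities in long format. Failures (degenerate
#' models with zero equilibrium yield) are logged and the affected rows
#' carry NA risk.
#'
#' @param design a \linkS4class{PsaDesign}.
#' @param scenario initial-status scenario (sPSA) or "Scored" (ePSA).
#' @param n_sim replicates per operating model.
#' @param U exploitation rates.
#' @param seed master seed (per-row substreams are derived from it).
#' @param deviates recruitment process error on/off.
#' @param param_uncertainty draw a fresh parameter set per replicate
#'   (default; see \code{\link{simulateEnsemble}}) rather than one fixed
#'   parameter set per combination.
#' @param spatial availability treatment (see
#'   \code{\link{equilibriumDepletion}}).
#' @return data.frame with columns \code{row}, \code{U},
#'   \code{p_half_bmsy}, \code{p_02_b0}, \code{p_01_b0},
#'   \code{n_unconditioned}.
#' @export
simulateDesign <- function(design, scenario = "Medium", n_sim = 100L,
                           U = c(0.2, 0.4, 0.6), seed = 1L,
                           deviates = TRUE, param_uncertainty = TRUE,
                           spatial = "mixed") {
  df <- designScores(design)
  om_scenario <- if (design@variant == "ePSA") "Medium" else scenario
  res <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    s_om <- hashSeed(seed, design@variant, design@method, scenario, "om", i)
    s_sim <- hashSeed(seed, design@variant, design@method, scenario, "sim", i)
    res[[i]] <- tryCatch({
      pr <- if (param_uncertainty) {
        ens <- sampleEnsemble(df[i, , drop = FALSE], design@variant,
                              om_scenario, n_sim = n_sim, seed = s_om)
        simulateEnsemble(ens, U = U, deviates = deviates, seed = s_sim,
                         spatial = spatial)
      } else {
        om <- sampleOperatingModel(df[i, , drop = FALSE], design@variant,
                                   om_scenario, seed = s_om)
        simulatePopulation(om, n_sim = n_sim, U = U, deviates = deviates,
                           seed = s_sim, spatial = spatial)
      }
      cbind(row = i, riskProbability(pr),
            n_unconditioned = pr@nUnconditioned)
    }, error = function(e) {
      warning("design row ", i, " failed: ", conditionMessage(e),
              call. = FALSE)
      data.frame(row = i, U = U, p_half_bmsy = NA_real_, p_02_b0 = NA_real_,
                 p_01_b0 = NA_real_, n_unconditioned = NA_integer_)
    })
  }
  do.call(rbind, res)
}

#' Run a full PSA evaluation experiment
#'
#' Executes the complete pipeline for every analysis cell of the
#' configuration: build the sampled design per aggregation method, map each
#' combination to an operating model, simulate it under every exploitation
#' rate, and collect the risk probabilities. All randomness derives from
#' the master seed through per-stage substreams, so the same configuration
#' and seed reproduce identical outputs.
#'
#' @param config a \code{psasimConfig} (see \code{\link{experimentConfig}}).
#' @param progress print per-stage progress messages.
#' @return a result bundle: list with \code{config}, \code{designs} (one
#'   \linkS4class{PsaDesign} per method), \code{risk} (long data.frame:
#'   method, scenario, row, U, one column per metric), and \code{manifest}.
#' @seealso \code{\link{report}} for the summary tables.
#' @export
runExperiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "psasimConfig"))
  designs <- list()
  risk <- list()
  for (method in config$methods) {
    if (progress) message("building ", config$variant, " / ", method, " design")
    des <- buildDesign(config$variant, method, config$n_per_cell, config$seed)
    designs[[method]] <- des
    for (scenario in config$scenarios) {
      if (progress) message("  simulating scenario ", scenario)
      r <- simulateDesign(des, scenario, config$n_sim, config$U, config$seed,
                          config$deviates)
      risk[[paste(method, scenario, sep = ":")]] <-
        cbind(method = method, scenario = scenario, r)
    }
  }
  risk <- do.call(rbind, risk)
  rownames(risk) <- NULL
  manifest <- list(
    package = as.character(utils::packageVersion("psasim")),
    variant = config$variant, seed = config$seed,
    n_per_cell = config$n_per_cell, n_sim = config$n_sim,
    U = config$U, metrics = config$metrics,
    design_rows = vapply(designs, function(d) nrow(designScores(d)),
                         integer(1)),
    median_cell_members = vapply(designs, function(d) {
      cc <- cellCounts(d)
      stats::median(cc[cc > 0])
    }, numeric(1)))
  bundle <- list(config = config, designs = designs, risk = risk,
                 manifest = manifest)
  if (!is.null(config$outdir)) .writeBundle(bundle, config$outdir)
  bundle
}

.writeBundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (m in names(bundle$designs))
    writeDesign(bundle$designs[[m]],
                file.path(outdir, paste0("design_", bundle$config$variant,
                                         "_", m, ".csv")))
  utils::write.csv(bundle$risk, file.path(outdir, "risk.csv"),
                   row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Summary tables for a result bundle
#'
#' Produces the evaluation tables for every completed analysis cell
#' (method x scenario x exploitation rate x metric): the similarity of the
#' observed risk surface to the expected additive surface, the
#' classification accuracy and per-class sensitivity, and optionally the
#' LMG relative-importance shares of the attributes. Cells whose
#' simulations failed are reported as gaps (NA rows).
#'
#' @param bundle result of \code{\link{runExperiment}}.
#' @param importance also compute the LMG decomposition per cell (slower).
#' @param n_random random matrices for the similarity baseline.
#' @return list of data.frames: \code{similarity}, \code{accuracy},
#'   \code{importance} (optional), and \code{scatter} (per-combination V
#'   and risk, the raw material of the vulnerability-risk relationship).
#' @export
report <- function(bundle, importance = FALSE, n_random = 1000L) {
  cfg <- bundle$config
  sim_rows <- list(); acc_rows <- list(); imp_rows <- list()
  scatter <- list()
  for (method in cfg$methods) {
    des <- bundle$designs[[method]]
    df <- designScores(des)
    atts <- psaAttributes(cfg$variant)$name
    for (scenario in cfg$scenarios) {
      sub <- bundle$risk[bundle$risk$method == method &
                         bundle$risk$scenario == scenario, ]
      for (u in cfg$U) {
        cell <- sub[sub$U == u, ]
        cell <- cell[order(cell$row), ]
        for (metric in cfg$metrics) {
          rk <- cell[[metric]][match(seq_len(nrow(df)), cell$row)]
          key <- data.frame(variant = cfg$variant, method = method,
                            scenario = scenario, U = u, metric = metric)
          if (all(is.na(rk))) {
            sim_rows[[length(sim_rows) + 1L]] <-
              cbind(key, similarity = NA_real_)
            acc_rows[[length(acc_rows) + 1L]] <- cbind(
              key, accuracy = NA_real_, sens_low = NA_real_,
              sens_medium = NA_real_, sens_high = NA_real_, n = 0L)
            next
          }
          keep <- !is.na(rk)
          O <- observedMatrix(rk[keep], df[keep, ])
          sim_rows[[length(sim_rows) + 1L]] <- cbind(
            key, similarity = similarityScore(
              O, n_random = n_random, seed = hashSeed(cfg$seed, "simbase")))
          cs <- classificationStats(df$V[keep], rk[keep])
          acc_rows[[length(acc_rows) + 1L]] <- cbind(
            key, accuracy = cs$accuracy, sens_low = cs$sensitivity[["Low"]],
            sens_medium = cs$sensitivity[["Medium"]],
            sens_high = cs$sensitivity[["High"]], n = cs$n)
          if (importance) {
            li <- relativeImportance(df[keep, atts], rk[keep])
            imp_rows[[length(imp_rows) + 1L]] <- cbind(
              key, as.data.frame(as.list(li$shares)), R2 = li$R2)
          }
          scatter[[length(scatter) + 1L]] <-
            cbind(key, V = df$V[keep], risk = rk[keep])
        }
      }
    }
  }
  out <- list(similarity = do.call(rbind, sim_rows),
              accuracy = do.call(rbind, acc_rows),
              scatter = do.call(rbind, scatter))
  if (importance) out$importance <- do.call(rbind, imp_rows)
  if (!is.null(cfg$outdir)) {
    for (nm in setdiff(names(out), "scatter"))
      utils::write.csv(out[[nm]],
                       file.path(cfg$outdir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  out
}
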