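## Pipeline orchestration: simulate -> screen -> quantify -> eqs -> risk
## -> stats from one validated config, with deterministic outputs, a
## human-readable report and a machine-readable run manifest.

#' Default pipeline configuration
#'
#' All stage parameters in one validated list: matching tolerances, EQS
#' thresholds, risk-category cut points and the simulation seed.
#'
#' @param seed Integer seed for the synthetic study.
#' @param outDir Output directory for stage CSVs, the report and the
#'   manifest.
#' @return Named list of class `"fluorscreenConfig"`.
#' @export
defaultPipelineConfig <- function(seed = 1L, outDir = tempfile("fluorscreen")) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = outDir,
    tolerances = list(ppm = 5, rt_tol = 0.2, kmd_tol = 0.002,
                      blank_ratio = 5, isotope_threshold = 80,
                      ms2_ppm = 10),
    eqs = list(group = 4.4, pfos_aa = 0.65, pfos_mac = 36000,
               include_ssa = FALSE),
    risk = list(thresholds = c(high = 0.1, medium = 0.01, low = 0.001))
  )
  class(cfg) <- "fluorscreenConfig"
  validatePipelineConfig(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config Config list, or path to a YAML file holding one.
#' @return The validated config (invisibly a list).
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  tol <- config$tolerances
  if (any(unlist(tol) <= 0)) stop("all tolerances must be > 0")
  th <- unlist(config$risk$thresholds)
  if (length(th) != 3L || any(diff(th) >= 0)) {
    stop("risk thresholds must be three descending values")
  }
  if (is.null(config$seed)) stop("a simulation seed is mandatory")
  invisible(config)
}

#' Run the full workflow
#'
#' Executes every stage on the synthetic study defined by the config
#' seed: data simulation, suspect screening, (semi-)quantification, EQS
#' compliance screening, risk prioritization and paired
#' upstream/downstream statistics. All stage outputs are written as CSVs
#' under `config$out_dir` together with `report.md` and `manifest.json`;
#' outputs are byte-identical across runs with the same config.
#'
#' @param config A [defaultPipelineConfig()] list or YAML path.
#' @return Invisibly, a list of all stage results.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  config <- validatePipelineConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tol <- config$tolerances
  outcsv <- function(x, name) {
    utils::write.csv(x, file.path(config$out_dir, name), row.names = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  design <- defaultStudyDesign(seed = config$seed)
  study <- stage("simulate", simulateStudy(design))
  outcsv(study$features, "features.csv")
  outcsv(study$blanks, "blanks.csv")

  scr <- stage("screen", screenStudy(
    study$features, study$blanks, study$suspects, study$spectra,
    tolPpm = tol$ppm, ms2TolPpm = tol$ms2_ppm, rtTol = tol$rt_tol,
    blankRatio = tol$blank_ratio))
  outcsv(scr$annotations, "annotations.csv")

  rrf <- stage("quantify", fitRrf(study$calibration))
  records <- stage("quantify", semiQuantify(
    scr$annotations, scr$groups$features, rrf, study$suspects))
  outcsv(records, "concentrations.csv")

  eqs <- stage("eqs", eqsScreen(study$experiment,
                                includeSsa = config$eqs$include_ssa))
  rivers <- stage("eqs", riverSummary(
    eqs, sampleInfo(study$experiment)$water_body))
  outcsv(eqs, "eqs.csv")
  outcsv(rivers, "river_summary.csv")

  risk <- stage("risk", prioritizeRisk(study$experiment, study$hazard))
  outcsv(risk, "risk.csv")

  tests <- stage("stats", upstreamDownstreamTests(study$experiment))
  outcsv(tests, "tests.csv")

  report <- c(
    "# PFAS screening pipeline report", "",
    sprintf("Seed: %d; samples: %d; compounds quantified: %d.",
            config$seed, ncol(study$experiment), nrow(study$experiment)), "",
    "## Confidence levels",
    sprintf("- L%d: %d annotations", 1:5, as.integer(scr$level_counts)), "",
    "## EQS exceedances",
    sprintf("- group EQS (> %.1f ng/L PFOA-eq): %d of %d samples",
            config$eqs$group, sum(eqs$exceeds_group_eqs), nrow(eqs)),
    sprintf("- PFOS AA-EQS (> %.2f ng/L): %d of %d samples",
            config$eqs$pfos_aa, sum(eqs$exceeds_pfos_aa), nrow(eqs)),
    sprintf("- PFOS MAC-EQS (> %.0f ng/L): %d of %d samples",
            config$eqs$pfos_mac, sum(eqs$exceeds_pfos_mac), nrow(eqs)), "",
    "## Per-river summary (ng/L)",
    sprintf("- %s: mean %.3g, sd %.3g, range %.3g-%.3g (n = %d)",
            rivers$water_body, rivers$mean, rivers$sd, rivers$min,
            rivers$max, rivers$n), "",
    "## Risk ranking (top 5)",
    sprintf("- %s: RI = %.4f (%s)", utils::head(risk$compound_id, 5),
            utils::head(risk$ri, 5), utils::head(risk$category, 5)), "",
    "## Paired upstream/downstream tests",
    sprintf("- compounds with FDR-adjusted p < 0.05: %d of %d",
            sum(tests$p_adjusted < 0.05, na.rm = TRUE), nrow(tests)))
  writeLines(report, file.path(config$out_dir, "report.md"))

  manifest <- list(
    package = "fluorscreen",
    version = as.character(utils::packageVersion("fluorscreen")),
    seed = config$seed,
    config_hash = sum(strtoi(charToRaw(paste(
      deparse(unclass(config)[setdiff(names(config), "out_dir")]),
      collapse = "")), 16L)),
    stages = c("simulate", "screen", "quantify", "eqs", "risk", "stats"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(study = study, screening = scr, rrf = rrf,
                 concentrations = records, eqs = eqs, rivers = rivers,
                 risk = risk, tests = tests, config = config))
}
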