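## Isotope-dilution quantification of targets, surrogate-RRF
## semi-quantification of suspect-screening compounds, QC gating, blank
## correction and method-quantification-limit estimation.

#' Fit relative response factors from a calibration set
#'
#' For each native/labeled pair the RRF is the slope of the
#' origin-constrained least-squares fit of `area_native/area_is` against
#' `conc_native/conc_is`; the coefficient of determination of the fit is
#' reported.
#'
#' @param calibration Long `data.frame` with columns `native_id`,
#'   `labeled_id`, `conc_native`, `conc_is`, `area_native`, `area_is`
#'   (see [simulateCalibration()]); at least 3 levels per pair.
#' @return `data.frame` with `native_id`, `labeled_id`, `rrf`, `fit_r2`.
#' @export
fitRrf <- function(calibration) {
  out <- lapply(split(calibration, calibration$native_id), function(d) {
    if (nrow(d) < 3L) stop("need >= 3 calibration levels for ", d$native_id[1])
    y <- d$area_native / d$area_is
    x <- d$conc_native / d$conc_is
    if (all(y == 0)) stop("degenerate calibration (all-zero areas) for ",
                          d$native_id[1])
    fit <- stats::lm(y ~ 0 + x)
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum(y^2)
    data.frame(native_id = d$native_id[1], labeled_id = d$labeled_id[1],
               rrf = unname(stats::coef(fit)[1]), fit_r2 = r2,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Quantify a compound by isotope dilution
#'
#' `conc = (area / area_is) * conc_is / rrf`, in ng/L.
#'
#' @param area Native peak area (>= 0).
#' @param isArea Internal-standard peak area (> 0).
#' @param isConc Internal-standard concentration (ng/L).
#' @param rrf Relative response factor (> 0).
#' @return Concentration in ng/L.
#' @export
quantifyTarget <- function(area, isArea, isConc, rrf) {
  if (any(isArea <= 0)) stop("internal-standard area must be > 0")
  if (any(rrf <= 0)) stop("rrf must be > 0")
  (area / isArea) * isConc / rrf
}

#' Assign a surrogate target to a suspect-screening compound
#'
#' Chooses the target whose retention time is closest to the
#' suspect-screening compound's; ties are broken by same subclass
#' (PFCA/PFSA/...), then by smallest neutral-mass difference. The chosen
#' target's RRF is used for semi-quantification.
#'
#' @param ssaCompound List/one-row `data.frame` with `rt`, `class`,
#'   `neutral_mass`.
#' @param targets `data.frame` with `compound_id`, `rt`, `class`,
#'   `neutral_mass` for targets with fitted RRFs (>= 1 row).
#' @return The chosen target's `compound_id`; the RT, class and mass
#'   distances of the choice are attached as attribute `"distances"`.
#' @export
assignSurrogate <- function(ssaCompound, targets) {
  if (is.null(targets) || nrow(targets) < 1L) {
    stop("no targets with RRFs available")
  }
  dRt <- abs(targets$rt - ssaCompound$rt)
  sameClass <- targets$class == ssaCompound$class
  dMass <- abs(targets$neutral_mass - ssaCompound$neutral_mass)
  ord <- order(dRt, !sameClass, dMass)
  pick <- ord[1]
  structure(targets$compound_id[pick],
            distances = list(rt = dRt[pick], same_class = sameClass[pick],
                             mass = dMass[pick]))
}

#' Quality-control gate for a quantified record
#'
#' A record fails when S/N is not greater than 3, when the uncertainty of
#' the qualifier-to-quantifier ion ratio is not below 30%, or (for targets
#' quantified with authentic standards) when the retention-time deviation
#' exceeds 0.1 min. Each violated rule contributes a named flag.
#'
#' @param snr Signal-to-noise ratio.
#' @param ionRatioUncertainty Relative uncertainty of the
#'   qualifier/quantifier ion ratio (fraction).
#' @param rtDev Retention-time deviation in minutes.
#' @param isTarget Whether the compound has an authentic standard (the RT
#'   gate only applies to targets).
#' @return List with `pass` (logical) and `flags` (character vector among
#'   `"low_snr"`, `"ion_ratio"`, `"rt_drift"`).
#' @export
qcGate <- function(snr, ionRatioUncertainty = 0, rtDev = 0, isTarget = TRUE) {
  stopifnot(is.finite(snr), is.finite(ionRatioUncertainty), is.finite(rtDev))
  flags <- character(0)
  if (!(snr > 3)) flags <- c(flags, "low_snr")
  if (!(ionRatioUncertainty < 0.30)) flags <- c(flags, "ion_ratio")
  if (isTarget && abs(rtDev) > 0.1) flags <- c(flags, "rt_drift")
  list(pass = length(flags) == 0L, flags = flags)
}

#' Estimate method quantification limits
#'
#' The MQL is anchored at S/N = 10: assuming S/N scales linearly with
#' concentration, each accepted record extrapolates to `conc * 10/snr`
#' and the per-compound MQL is the minimum of these.
#'
#' @param records `data.frame` with `conc` (ng/L) and `snr` (> 0)
#'   columns; optionally `compound_id` for a per-compound result.
#' @return Named numeric vector of MQLs (single unnamed value when no
#'   `compound_id` column is present); `NA` for compounds without usable
#'   records.
#' @export
estimateMql <- function(records) {
  if (is.null(records) || nrow(records) == 0L) return(NA_real_)
  ok <- records$snr > 0 & records$conc > 0
  mqlOf <- function(d) if (!nrow(d)) NA_real_ else min(d$conc * 10 / d$snr)
  if (!"compound_id" %in% names(records)) {
    return(mqlOf(records[ok, , drop = FALSE]))
  }
  vapply(split(records[ok, , drop = FALSE],
               factor(records$compound_id[ok],
                      levels = unique(records$compound_id))),
         mqlOf, numeric(1))
}

#' Blank-correct a concentration
#'
#' Subtracts the procedural-blank concentration, floored at zero.
#'
#' @param conc,blankConc Concentrations in ng/L, `>= 0`.
#' @return `max(conc - blankConc, 0)`.
#' @export
blankCorrect <- function(conc, blankConc) {
  stopifnot(all(conc >= 0), all(blankConc >= 0))
  pmax(conc - blankConc, 0)
}

#' Semi-quantify screened annotations
#'
#' Converts retained annotations plus per-sample feature areas into
#' concentration records: targets are quantified with their own RRF,
#' suspect-screening compounds with the RRF of their assigned surrogate
#' target ([assignSurrogate()]); QC gating, blank correction and MQL
#' assignment produce the final status
#' (`quantified`/`semi_quantified`/`below_mql`/`not_detected`).
#'
#' @param annotations Retained annotation `data.frame` from
#'   [screenStudy()] (one row per group x suspect).
#' @param memberFeatures Feature `data.frame` with `group_id` column (from
#'   [screenStudy()]`$groups$features`).
#' @param rrf RRF table from [fitRrf()].
#' @param suspects Suspect list (provides class/mass/RT for surrogate
#'   assignment and the `is_target` split via non-`NA` `expected_rt`).
#' @param isConc,isArea Internal-standard concentration (ng/L) and area
#'   applied to every sample.
#' @param blankConc Optional named vector of blank concentrations per
#'   compound (ng/L).
#' @return `data.frame` of concentration records: `sample_id`,
#'   `compound_id`, `conc`, `mql`, `status`, `qc_flags`, `surrogate`.
#' @export
semiQuantify <- function(annotations, memberFeatures, rrf, suspects,
                         isConc = 2, isArea = 1e5, blankConc = NULL) {
  if (!nrow(annotations)) return(data.frame())
  suspects$is_target <- !is.na(suspects$expected_rt)
  targets <- merge(rrf, suspects, by.x = "native_id", by.y = "name")
  targets <- data.frame(compound_id = targets$native_id,
                        rt = targets$expected_rt, class = targets$class,
                        neutral_mass = targets$neutral_mass,
                        rrf = targets$rrf, stringsAsFactors = FALSE)
  recs <- list()
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    isTarget <- a$name %in% targets$compound_id
    if (isTarget) {
      useRrf <- targets$rrf[targets$compound_id == a$name]
      surrogate <- a$name
    } else {
      surrogate <- assignSurrogate(
        list(rt = a$rt, class = a$class,
             neutral_mass = suspects$neutral_mass[suspects$name == a$name][1]),
        targets)
      useRrf <- targets$rrf[targets$compound_id == surrogate]
    }
    mem <- memberFeatures[memberFeatures$group_id == a$group_id, , drop = FALSE]
    for (j in seq_len(nrow(mem))) {
      conc <- quantifyTarget(mem$area[j], isArea, isConc, useRrf)
      rtDev <- if (isTarget) mem$rt[j] - a$expected_rt else 0
      qc <- qcGate(mem$snr[j], 0, rtDev, isTarget)
      if (!is.null(blankConc) && a$name %in% names(blankConc)) {
        conc <- blankCorrect(conc, blankConc[[a$name]])
      }
      recs[[length(recs) + 1L]] <- data.frame(
        sample_id = mem$sample_id[j], compound_id = a$name, conc = conc,
        snr = mem$snr[j], qc_pass = qc$pass,
        qc_flags = paste(qc$flags, collapse = ";"),
        surrogate = as.character(surrogate), is_target = isTarget,
        stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, recs)
  mql <- estimateMql(rec[rec$qc_pass, c("compound_id", "conc", "snr")])
  rec$mql <- unname(mql[rec$compound_id])
  rec$status <- ifelse(!rec$qc_pass, "not_detected",
                ifelse(!is.na(rec$mql) & rec$conc < rec$mql, "below_mql",
                ifelse(rec$is_target, "quantified", "semi_quantified")))
  rec$conc[rec$status == "not_detected"] <- 0
  rownames(rec) <- NULL
  rec
}
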