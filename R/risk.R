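## Three-step risk prioritization: min-max normalization of the 18 PBT
## hazard attributes, weighted ToxPi aggregation, exposure from detection
## frequency x concentration magnitude, risk index and categorization.

#' ToxPi attribute weights
#'
#' The weight of each of the 18 attributes: 1/9 per persistence attribute,
#' 1/6 per bioaccumulation attribute, 1/18 per ecotoxicity attribute and
#' 1/60 per human-toxicity endpoint. With the 3/2/3/10 group sizes the
#' weights sum exactly to 1, so ToxPi scores lie in `[0, 1]`.
#'
#' @return Named numeric vector of length 18.
#' @export
toxpiWeights <- function() {
  sch <- hazardAttributeSchema()
  w <- c(persistence = 1 / 9, bioaccumulation = 1 / 6,
         ecotoxicity = 1 / 18, human = 1 / 60)
  stats::setNames(w[sch$group], sch$attribute)
}

#' Normalize hazard attributes to [0, 1]
#'
#' Per-attribute min-max scaling across compounds after direction
#' alignment: attributes where a lower raw value means more hazardous
#' (e.g. aerobic biodegradation probability) are reflected first, so that
#' 1 is always the most hazardous observed value. An attribute constant
#' across compounds normalizes to all zeros (degenerate rule, so
#' downstream scores never become NaN).
#'
#' @param hazard Numeric compounds x attributes matrix (>= 2 compounds).
#' @param schema Attribute schema with `attribute` and `direction`
#'   columns; defaults to [hazardAttributeSchema()].
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
normalizeAttributes <- function(hazard, schema = hazardAttributeSchema()) {
  if (nrow(hazard) < 2L) {
    stop("normalization undefined for a single compound")
  }
  miss <- setdiff(schema$attribute, colnames(hazard))
  if (length(miss)) stop("hazard matrix missing attribute(s): ",
                         paste(miss, collapse = ", "))
  out <- hazard[, schema$attribute, drop = FALSE]
  for (k in seq_len(ncol(out))) {
    v <- out[, k]
    if (schema$direction[k] == "lower") v <- -v
    rng <- range(v)
    out[, k] <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else 0
  }
  out
}

#' Weighted ToxPi hazard score
#'
#' `toxpi = sum_a w_a * normalized_a` over the 18 attributes; since the
#' weights sum to 1 the score lies in `[0, 1]`.
#'
#' @param normalized Normalized compounds x attributes matrix from
#'   [normalizeAttributes()].
#' @param weights Named weight vector matching the attribute columns
#'   (default [toxpiWeights()]).
#' @return Named numeric vector of ToxPi scores in `[0, 1]`.
#' @export
toxpiScore <- function(normalized, weights = toxpiWeights()) {
  if (!setequal(colnames(normalized), names(weights))) {
    stop("weights do not match the attribute columns")
  }
  drop(normalized[, names(weights), drop = FALSE] %*% weights)
}

#' Concentration magnitude
#'
#' `(c_i - c_min) / (c_max - c_min)` where `c_i` is the maximum observed
#' concentration of compound i and `c_min`/`c_max` are the smallest and
#' largest of these maxima over compounds. When all maxima are equal the
#' magnitudes are defined as 0 with a warning.
#'
#' @param cI Numeric vector of per-compound maximum concentrations (ng/L).
#' @param cMin,cMax Extremes over compounds; default computed from `cI`.
#' @return Magnitudes in `[0, 1]`.
#' @export
concentrationMagnitude <- function(cI, cMin = min(cI), cMax = max(cI)) {
  if (cMax <= cMin) {
    if (cMax < cMin) stop("cMax must be >= cMin")
    warning("degenerate concentration range; magnitudes set to 0")
    return(rep(0, length(cI)))
  }
  (cI - cMin) / (cMax - cMin)
}

#' Exposure and its normalization
#'
#' `exposure = DF x magnitude` with the detection frequency DF as a
#' fraction in `[0, 1]`, then min-max normalized over compounds to
#' `[0, 1]`. A degenerate all-equal exposure vector normalizes to zeros
#' with a warning.
#'
#' @param df Detection frequencies in `[0, 1]`.
#' @param magnitude Concentration magnitudes in `[0, 1]`.
#' @return `exposureScore`: the raw products; `normalizeExposure`: values
#'   rescaled to `[0, 1]`.
#' @export
exposureScore <- function(df, magnitude) {
  stopifnot(all(df >= 0 & df <= 1))
  df * magnitude
}

#' @rdname exposureScore
#' @param values Raw exposure values.
#' @export
normalizeExposure <- function(values) {
  rng <- range(values)
  if (rng[2] <= rng[1]) {
    warning("degenerate exposure range; normalized exposures set to 0")
    return(rep(0, length(values)))
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Risk index and category
#'
#' `RI = ToxPi x normalized exposure`, classified into high (RI > 0.1),
#' medium (0.01 < RI <= 0.1), low (0.001 < RI <= 0.01) and negligible
#' (RI <= 0.001); boundary values belong to the lower category.
#'
#' @param toxpi ToxPi scores in `[0, 1]`.
#' @param exposureNorm Normalized exposures in `[0, 1]`.
#' @return `riskIndex`: numeric RI in `[0, 1]`.
#' @export
riskIndex <- function(toxpi, exposureNorm) {
  if (any(toxpi < 0 | toxpi > 1) || any(exposureNorm < 0 | exposureNorm > 1)) {
    stop("toxpi and exposureNorm must lie in [0, 1]")
  }
  toxpi * exposureNorm
}

#' @rdname riskIndex
#' @param ri Risk-index values.
#' @return `classifyRisk`: factor with levels `high`, `medium`, `low`,
#'   `negligible`.
#' @export
classifyRisk <- function(ri) {
  if (any(ri < 0 | ri > 1)) stop("ri must lie in [0, 1]")
  cut(ri, breaks = c(-Inf, 0.001, 0.01, 0.1, Inf),
      labels = c("negligible", "low", "medium", "high"),
      right = TRUE)
}

#' Full risk prioritization of a study
#'
#' Combines the hazard side (normalized 18-attribute ToxPi) with the
#' exposure side (detection frequency x concentration magnitude computed
#' from the study's concentration matrix) into risk indices and
#' categories, ranked by RI.
#'
#' @param experiment A [PfasExperiment-class].
#' @param hazard Compounds x 18-attribute matrix covering (at least) the
#'   experiment's compounds.
#' @param schema Attribute schema (default [hazardAttributeSchema()]).
#' @return `data.frame` sorted by decreasing RI: `compound_id`, `toxpi`,
#'   `df`, `c_i`, `magnitude`, `exposure`, `exposure_norm`, `ri`,
#'   `category`.
#' @export
prioritizeRisk <- function(experiment, hazard,
                           schema = hazardAttributeSchema()) {
  ids <- compoundInfo(experiment)$compound_id
  miss <- setdiff(ids, rownames(hazard))
  if (length(miss)) stop("hazard table missing compound(s): ",
                         paste(miss, collapse = ", "))
  hz <- hazard[ids, , drop = FALSE]
  toxpi <- toxpiScore(normalizeAttributes(hz, schema))
  df <- detectionFrequency(experiment)
  cI <- apply(concentrations(experiment), 1, max)
  mag <- concentrationMagnitude(cI)
  expo <- exposureScore(df, mag)
  expoN <- normalizeExposure(expo)
  ri <- riskIndex(toxpi, expoN)
  out <- data.frame(compound_id = ids, toxpi = unname(toxpi[ids]),
                    df = unname(df[ids]), c_i = unname(cI[ids]),
                    magnitude = unname(mag), exposure = unname(expo),
                    exposure_norm = unname(expoN), ri = unname(ri),
                    category = classifyRisk(unname(ri)),
                    stringsAsFactors = FALSE)
  out[order(-out$ri), , drop = FALSE]
}
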