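## PFOA-equivalent EQS compliance screening: lower-bound PFAS sums,
## RPF-weighted PFOA equivalents, exceedance flags against the proposed
## 4.4 ng/L group EQS and the PFOS AA-/MAC-EQS, and per-river summaries.

# EQS thresholds in ng/L (MAC-EQS 36 ug/L stored as 36000 ng/L)
.EQS <- c(group = 4.4, pfos_aa = 0.65, pfos_mac = 36000)

#' Lower-bound sum of PFAS concentrations in one sample
#'
#' Sums concentrations over compounds, with non-detected and below-MQL
#' records contributing zero (lower-bound aggregation).
#'
#' @param conc Numeric vector of concentrations (ng/L) for one sample.
#' @param status Optional character vector of quantification statuses;
#'   `"not_detected"` and `"below_mql"` entries are zeroed.
#' @return Sum in ng/L.
#' @export
sumPfas <- function(conc, status = NULL) {
  stopifnot(all(conc >= 0, na.rm = TRUE))
  if (!is.null(status)) conc[status %in% c("not_detected", "below_mql")] <- 0
  sum(conc, na.rm = TRUE)
}

#' PFOA equivalents of a concentration profile
#'
#' Multiplies each compound's concentration by its relative potency factor
#' (RPF; PFOA anchored at 1) and sums; per-compound fractional
#' contributions to the sum are reported. Compounds without an RPF are
#' excluded with a warning.
#'
#' @param conc Named numeric vector of concentrations (ng/L).
#' @param rpfTable `data.frame` with `compound_id` and `rpf` (see
#'   [readRpfTable()]).
#' @return List with `per_compound` (ng/L PFOA-eq), `total` (ng/L) and
#'   `contributions` (fractions summing to 1 when `total > 0`).
#' @export
pfoaEquivalents <- function(conc, rpfTable) {
  rpf <- stats::setNames(rpfTable$rpf, rpfTable$compound_id)
  missing <- setdiff(names(conc), names(rpf))
  missing <- c(missing, names(conc)[names(conc) %in% names(rpf) &
                                      is.na(rpf[names(conc)])])
  if (length(missing)) {
    warning("no RPF for: ", paste(unique(missing), collapse = ", "),
            "; excluded from PFOA-equivalents")
    conc <- conc[!names(conc) %in% missing]
  }
  eq <- conc * rpf[names(conc)]
  total <- sum(eq)
  list(per_compound = eq, total = total,
       contributions = if (total > 0) eq / total else eq * 0)
}

#' EQS exceedance flags for one sample
#'
#' Strict `>` comparisons: the PFOA-equivalent sum against the proposed
#' 4.4 ng/L group EQS, and the PFOS concentration against the 0.65 ng/L
#' annual-average and 36000 ng/L maximum-allowable-concentration EQS for
#' inland surface waters. A value exactly at a standard does not exceed
#' it.
#'
#' @param sumPfoaEq PFOA-equivalent sum (ng/L).
#' @param pfosConc PFOS concentration (ng/L, default 0).
#' @param thresholds Named vector `c(group=, pfos_aa=, pfos_mac=)` in
#'   ng/L.
#' @return Named logical vector `exceeds_group_eqs`, `exceeds_pfos_aa`,
#'   `exceeds_pfos_mac`.
#' @export
checkEqs <- function(sumPfoaEq, pfosConc = 0, thresholds = .EQS) {
  c(exceeds_group_eqs = unname(sumPfoaEq > thresholds[["group"]]),
    exceeds_pfos_aa = unname(pfosConc > thresholds[["pfos_aa"]]),
    exceeds_pfos_mac = unname(pfosConc > thresholds[["pfos_mac"]]))
}

#' Site-level EQS compliance screen
#'
#' Computes, for every sample of a study, the lower-bound PFAS sum, the
#' RPF-weighted PFOA-equivalent sum and the EQS exceedance flags.
#'
#' @param experiment A [PfasExperiment-class].
#' @param rpfTable RPF table; defaults to the table stored in the
#'   experiment's `rowData` (`rpf` column).
#' @param includeSsa Include semi-quantified suspect-screening compounds
#'   (e.g. TFA) in the PFOA-equivalent sum (default `FALSE`: quantified
#'   targets only, mirroring the two-tier reporting of group-EQS work).
#' @return `data.frame` with one row per sample: `sample_id`,
#'   `sum_pfas_quant`, `sum_pfoa_eq`, `pfos_conc` and the three exceedance
#'   flags.
#' @export
eqsScreen <- function(experiment, rpfTable = NULL, includeSsa = FALSE) {
  conc <- concentrations(experiment)
  st <- quantStatus(experiment)
  ri <- compoundInfo(experiment)
  if (is.null(rpfTable)) {
    rpfTable <- data.frame(compound_id = ri$compound_id, rpf = ri$rpf)
  }
  useRow <- if (includeSsa) rep(TRUE, nrow(conc)) else ri$is_target
  out <- lapply(colnames(conc), function(s) {
    v <- conc[, s]; vs <- st[, s]
    v[vs %in% c("not_detected", "below_mql")] <- 0
    total <- sumPfas(v[ri$is_target])
    eq <- suppressWarnings(
      pfoaEquivalents(v[useRow], rpfTable))
    pfos <- if ("PFOS" %in% names(v)) v[["PFOS"]] else 0
    flags <- checkEqs(eq$total, pfos)
    data.frame(sample_id = s, sum_pfas_quant = total,
               sum_pfoa_eq = eq$total, pfos_conc = pfos,
               exceeds_group_eqs = flags[["exceeds_group_eqs"]],
               exceeds_pfos_aa = flags[["exceeds_pfos_aa"]],
               exceeds_pfos_mac = flags[["exceeds_pfos_mac"]],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-water-body summary of PFAS burdens
#'
#' Arithmetic mean, sample standard deviation, minimum and maximum of the
#' per-sample PFAS sum (and, when present, the PFOA-equivalent sum) over
#' the samples of each water body. Means are over samples, not
#' settlements. A single-sample water body reports sd 0 with
#' `single_sample = TRUE`. Values are full precision; round only at the
#' presentation layer (conventionally 3 significant figures).
#'
#' @param values Numeric vector of per-sample sums (ng/L), or the result
#'   of [eqsScreen()] (its `sum_pfas_quant` column is used).
#' @param waterBody Character vector mapping each sample to a water body.
#' @return `data.frame` with `water_body`, `n`, `mean`, `sd`, `min`,
#'   `max`, `single_sample`.
#' @export
riverSummary <- function(values, waterBody) {
  if (is.data.frame(values)) values <- values$sum_pfas_quant
  stopifnot(length(values) == length(waterBody))
  out <- lapply(split(seq_along(values), waterBody), function(idx) {
    v <- values[idx]
    data.frame(water_body = waterBody[idx[1]], n = length(v),
               mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
               min = min(v), max = max(v),
               single_sample = length(v) == 1L, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
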