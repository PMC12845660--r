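## Central data container: a compound x sample concentration study with
## sample metadata (settlement, water body, upstream/downstream position)
## and per-compound annotation, built on SummarizedExperiment.

#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' PfasExperiment: a PFAS concentration study
#'
#' An S4 container (extending
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class])
#' holding a compound x sample matrix of concentrations in ng/L (assay
#' `"concentration"`), a parallel character matrix of quantification
#' statuses (assay `"status"`: `"quantified"`, `"semi_quantified"`,
#' `"below_mql"` or `"not_detected"`), per-compound annotation in
#' `rowData` (at least `compound_id`, `class`, `is_target`) and sample
#' metadata in `colData` (`sample_id`, `site_number`, `settlement`,
#' `water_body`, `position`).
#'
#' The survey design encoded in `colData` follows a paired scheme: each
#' settlement contributes one upstream and one downstream sample, and
#' odd site numbers are upstream while even site numbers are downstream.
#'
#' @name PfasExperiment-class
#' @aliases PfasExperiment-class
#' @exportClass PfasExperiment
setClass("PfasExperiment", contains = "SummarizedExperiment")

setValidity("PfasExperiment", function(object) {
  msg <- character(0)
  if (!"concentration" %in% names(assays(object))) {
    msg <- c(msg, "assay 'concentration' is required")
  } else {
    conc <- assay(object, "concentration")
    if (any(conc < 0, na.rm = TRUE)) {
      msg <- c(msg, "concentrations must be >= 0")
    }
  }
  if ("status" %in% names(assays(object))) {
    st <- assay(object, "status")
    ok <- c("quantified", "semi_quantified", "below_mql", "not_detected")
    if (!all(st %in% ok)) {
      msg <- c(msg, paste("status values must be one of:",
                          paste(ok, collapse = ", ")))
    }
  }
  cd <- colData(object)
  need <- c("sample_id", "site_number", "settlement", "water_body", "position")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    msg <- c(msg, paste("colData is missing:", paste(miss, collapse = ", ")))
  } else {
    if (!all(cd$position %in% c("upstream", "downstream"))) {
      msg <- c(msg, "position must be 'upstream' or 'downstream'")
    } else {
      odd <- cd$site_number %% 2 == 1
      if (any(odd & cd$position != "upstream") ||
          any(!odd & cd$position != "downstream")) {
        msg <- c(msg,
          "odd site numbers must be upstream, even site numbers downstream")
      }
    }
  }
  if (!"compound_id" %in% colnames(rowData(object))) {
    msg <- c(msg, "rowData is missing 'compound_id'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PfasExperiment
#'
#' @param concentration Numeric compound x sample matrix, ng/L, `>= 0`.
#' @param status Optional character matrix of the same shape with
#'   quantification statuses; defaults to `"quantified"` where
#'   `concentration > 0` and `"not_detected"` elsewhere.
#' @param compoundInfo `data.frame`/`DataFrame` with one row per compound;
#'   must contain `compound_id`.
#' @param sampleInfo `data.frame`/`DataFrame` with one row per sample;
#'   must contain `sample_id`, `site_number`, `settlement`, `water_body`,
#'   `position` (`"upstream"`/`"downstream"`).
#' @param metadata Optional named list stored in the object's metadata.
#' @return A [PfasExperiment-class] object.
#' @examples
#' study <- simulateStudy(defaultStudyDesign(seed = 1))
#' study$experiment
#' @export
PfasExperiment <- function(concentration, status = NULL, compoundInfo,
                           sampleInfo, metadata = list()) {
  concentration <- as.matrix(concentration)
  if (is.null(status)) {
    status <- ifelse(concentration > 0, "quantified", "not_detected")
  }
  rd <- DataFrame(compoundInfo)
  cd <- DataFrame(sampleInfo)
  rownames(rd) <- rd$compound_id
  rownames(cd) <- cd$sample_id
  se <- SummarizedExperiment(
    assays = list(concentration = concentration, status = status),
    rowData = rd, colData = cd, metadata = metadata)
  methods::new("PfasExperiment", se)
}

#' @describeIn PfasExperiment Concentration matrix (ng/L), compounds in
#'   rows, samples in columns.
#' @param object,x A `PfasExperiment`.
#' @export
concentrations <- function(object) assay(object, "concentration")

#' @describeIn PfasExperiment Quantification status matrix.
#' @export
quantStatus <- function(object) assay(object, "status")

#' @describeIn PfasExperiment Sample metadata as a `data.frame`.
#' @export
sampleInfo <- function(object) as.data.frame(colData(object))

#' @describeIn PfasExperiment Compound annotation as a `data.frame`.
#' @export
compoundInfo <- function(object) as.data.frame(rowData(object))

#' Detection frequency per compound
#'
#' Fraction of (non-blank) samples in which each compound was quantified or
#' semi-quantified.
#'
#' @param object A [PfasExperiment-class].
#' @return Named numeric vector in `[0, 1]`.
#' @export
detectionFrequency <- function(object) {
  st <- quantStatus(object)
  det <- matrix(st %in% c("quantified", "semi_quantified"),
                nrow = nrow(st), dimnames = dimnames(st))
  rowMeans(det)
}

setMethod("show", "PfasExperiment", function(object) {
  cd <- colData(object)
  cat("PfasExperiment:", nrow(object), "compounds x", ncol(object),
      "samples\n")
  cat("  water bodies:", paste(unique(cd$water_body), collapse = ", "), "\n")
  cat("  settlements: ", length(unique(cd$settlement)),
      " (paired upstream/downstream)\n", sep = "")
  dt <- detectionFrequency(object)
  cat("  detection frequency: ",
      sprintf("%.0f%%-%.0f%%", 100 * min(dt), 100 * max(dt)), "\n", sep = "")
  invisible(NULL)
})
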