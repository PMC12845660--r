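## Readers/writers for the tabular and spectral formats the workflow
## touches. CSV dialect: UTF-8, comma separator, "." decimal, mandatory
## header. Retention times are minutes, concentrations ng/L throughout.

.schemaError <- function(path, what, row = NULL) {
  loc <- if (is.null(row)) "" else sprintf(" (row %d)", row)
  stop(sprintf("%s: %s%s", path, what, loc), call. = FALSE)
}

.readCsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    .schemaError(path, paste("missing column(s):", paste(miss, collapse = ", ")))
  }
  x
}

.requireNumeric <- function(x, cols, path) {
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(x[[cl]]))
    bad <- which(is.na(v) & !is.na(x[[cl]]))
    if (length(bad)) {
      .schemaError(path, paste0("non-numeric value in '", cl, "'"), bad[1])
    }
    x[[cl]] <- v
  }
  x
}

#' Read a feature table
#'
#' Columns: `feature_id`, `sample_id`, `mz` (Da, `[M-H]-`), `rt` (minutes),
#' `area` (> 0), `snr` (>= 0) and optional `ms2_ref`. Row order is
#' preserved; duplicate feature ids, non-numeric or non-positive values
#' raise schema errors naming the offending row.
#'
#' @param path CSV path.
#' @return Validated `data.frame` of features.
#' @export
readFeatureTable <- function(path) {
  x <- .readCsv(path, c("feature_id", "sample_id", "mz", "rt", "area", "snr"))
  x <- .requireNumeric(x, c("mz", "rt", "area", "snr"), path)
  if (anyDuplicated(x$feature_id)) {
    .schemaError(path, "duplicate feature_id",
                 which(duplicated(x$feature_id))[1])
  }
  if (any(bad <- !(x$mz > 0))) .schemaError(path, "mz must be > 0", which(bad)[1])
  if (any(bad <- x$rt < 0)) .schemaError(path, "rt must be >= 0", which(bad)[1])
  if (any(bad <- !(x$area > 0))) {
    .schemaError(path, "area must be > 0", which(bad)[1])
  }
  if (is.null(x$ms2_ref)) x$ms2_ref <- NA_character_
  x
}

#' @rdname readFeatureTable
#' @param features Feature `data.frame` to write.
#' @export
writeFeatureTable <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a suspect list
#'
#' Columns: `name`, `formula`, `neutral_mass` (Da), `suspect_id`, `class`,
#' optional `expected_rt` (minutes) and `in_library` (logical). Each row's
#' `neutral_mass` must agree with the monoisotopic mass computed from its
#' formula to within 0.001 Da, otherwise the row is rejected.
#'
#' @param path CSV path.
#' @param massTol Formula/mass consistency tolerance in Da (default 0.001).
#' @return Validated suspect-list `data.frame`.
#' @export
readSuspectList <- function(path, massTol = 0.001) {
  x <- .readCsv(path, c("name", "formula", "neutral_mass", "suspect_id",
                        "class"))
  x <- .requireNumeric(x, "neutral_mass", path)
  calc <- vapply(x$formula, monoisotopicMass, numeric(1))
  off <- which(abs(calc - x$neutral_mass) > massTol)
  if (length(off)) {
    .schemaError(path, sprintf(
      "neutral_mass inconsistent with formula '%s' (|delta| = %.4f Da)",
      x$formula[off[1]], abs(calc - x$neutral_mass)[off[1]]), off[1])
  }
  if (is.null(x$expected_rt)) x$expected_rt <- NA_real_
  if (is.null(x$in_library)) x$in_library <- FALSE
  x$in_library <- as.logical(x$in_library)
  x
}

#' @rdname readSuspectList
#' @param suspects Suspect-list `data.frame` to write.
#' @export
writeSuspectList <- function(suspects, path) {
  utils::write.csv(suspects, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read/write MGF fragment spectra
#'
#' Minimal Mascot generic format support: `BEGIN IONS`/`END IONS` blocks
#' with `TITLE=` (spectrum id) and `PEPMASS=` (precursor m/z) headers and
#' `mz intensity` peak lines. Peaks are returned sorted by m/z; empty
#' blocks are rejected.
#'
#' @param path MGF path.
#' @return List of spectra; each a list with `spectrum_id`, `precursor_mz`
#'   and a `peaks` data.frame (`mz`, `intensity`).
#' @export
readMgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends)) {
    .schemaError(path, "unbalanced BEGIN IONS/END IONS")
  }
  out <- list()
  for (k in seq_along(starts)) {
    block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    title <- sub("^TITLE=", "", grep("^TITLE=", block, value = TRUE)[1])
    pm <- grep("^PEPMASS=", block, value = TRUE)[1]
    if (is.na(pm)) .schemaError(path, "missing PEPMASS", starts[k])
    precursor <- as.numeric(strsplit(sub("^PEPMASS=", "", pm), "[ \t]")[[1]][1])
    peakLines <- block[!grepl("=", block) & nzchar(trimws(block))]
    if (!length(peakLines)) .schemaError(path, "empty spectrum", starts[k])
    pk <- do.call(rbind, lapply(peakLines, function(l) {
      v <- as.numeric(strsplit(trimws(l), "[ \t]+")[[1]])
      if (length(v) < 2 || anyNA(v[1:2])) {
        .schemaError(path, paste("malformed peak line:", l))
      }
      v[1:2]
    }))
    pk <- pk[order(pk[, 1]), , drop = FALSE]
    if (any(pk[, 2] < 0)) .schemaError(path, "negative peak intensity")
    out[[title]] <- list(spectrum_id = title, precursor_mz = precursor,
                         peaks = data.frame(mz = pk[, 1], intensity = pk[, 2]))
  }
  out
}

#' @rdname readMgf
#' @param spectra List of spectra as returned by [readMgf()].
#' @export
writeMgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", sp$spectrum_id),
                 paste0("PEPMASS=", format(sp$precursor_mz, digits = 10)),
                 paste(format(sp$peaks$mz, digits = 10, trim = TRUE),
                       format(sp$peaks$intensity, digits = 10, trim = TRUE)),
                 "END IONS", ""), con)
  }
  invisible(path)
}

#' Read a relative-potency-factor table
#'
#' Columns: `compound_id`, `rpf` (dimensionless, >= 0). When PFOA is
#' present its RPF must equal 1 (it is the anchor of the equivalency
#' scale).
#'
#' @param path CSV path.
#' @return Validated `data.frame`.
#' @export
readRpfTable <- function(path) {
  x <- .readCsv(path, c("compound_id", "rpf"))
  x <- .requireNumeric(x, "rpf", path)
  if (any(bad <- x$rpf < 0)) .schemaError(path, "rpf must be >= 0", which(bad)[1])
  if ("PFOA" %in% x$compound_id && x$rpf[x$compound_id == "PFOA"] != 1) {
    .schemaError(path, "PFOA rpf must be 1 (equivalency anchor)")
  }
  x
}

#' Read a compound x attribute hazard table
#'
#' Wide CSV with a `compound_id` column followed by the 18 attribute
#' columns of [hazardAttributeSchema()].
#'
#' @param path CSV path.
#' @return Numeric matrix, compounds x attributes.
#' @export
readHazardTable <- function(path) {
  sch <- hazardAttributeSchema()
  x <- .readCsv(path, c("compound_id", sch$attribute))
  x <- .requireNumeric(x, sch$attribute, path)
  m <- as.matrix(x[, sch$attribute])
  rownames(m) <- x$compound_id
  m
}

#' @rdname readHazardTable
#' @param hazard Hazard matrix to write.
#' @export
writeHazardTable <- function(hazard, path) {
  utils::write.csv(data.frame(compound_id = rownames(hazard), hazard,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Columns: `sample_id`, `site_number` (1-24), `settlement`, `water_body`,
#' `position` (`upstream`/`downstream`), optional `is_blank`. Enforces the
#' survey convention that odd site numbers are upstream and even numbers
#' downstream.
#'
#' @param path CSV path.
#' @return Validated `data.frame`.
#' @export
readSampleMeta <- function(path) {
  x <- .readCsv(path, c("sample_id", "site_number", "settlement",
                        "water_body", "position"))
  x <- .requireNumeric(x, "site_number", path)
  if (!all(x$position %in% c("upstream", "downstream"))) {
    .schemaError(path, "position must be 'upstream' or 'downstream'",
                 which(!x$position %in% c("upstream", "downstream"))[1])
  }
  odd <- x$site_number %% 2 == 1
  bad <- which((odd & x$position != "upstream") |
                 (!odd & x$position != "downstream"))
  if (length(bad)) {
    .schemaError(path, "odd sites must be upstream, even sites downstream",
                 bad[1])
  }
  if (is.null(x$is_blank)) x$is_blank <- FALSE
  x$is_blank <- as.logical(x$is_blank)
  x
}

#' Default diagnostic fragment and neutral-loss databases
#'
#' Small curated tables of diagnostic PFAS fragment anions (e.g. CF3-,
#' C2F5-, SO3-) and PFAS-typical neutral losses (CO2, HF, CF2, ...), with
#' m/z computed from atomic masses at load time.
#'
#' @return `data.frame` with `name` and `mz` columns.
#' @export
defaultFragmentDb <- function() {
  frags <- c(CF3 = "CF3", C2F5 = "C2F5", C3F7 = "C3F7", C4F9 = "C4F9",
             SO3 = "SO3", FSO3 = "FSO3", C2F5O = "C2F5O", HF2 = "HF2")
  data.frame(name = paste0(names(frags), "-"),
             mz = vapply(frags, fragmentAnionMz, numeric(1)),
             row.names = NULL)
}

#' @rdname defaultFragmentDb
#' @export
defaultNeutralLossDb <- function() {
  losses <- c(CO2 = "CO2", HF = "HF", CF2 = "CF2", C2F4 = "C2F4",
              H2O = "H2O", SO3 = "SO3", CO2HF = "CHFO2")
  data.frame(name = names(losses),
             mass = vapply(losses, monoisotopicMass, numeric(1)),
             row.names = NULL)
}
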