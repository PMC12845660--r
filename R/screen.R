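## Suspect-screening core: cross-sample feature grouping, blank
## subtraction, suspect matching, isotope-pattern scoring, diagnostic
## fragment / neutral-loss matching and confidence-level assignment.

#' Group features across samples
#'
#' Transitive-closure grouping of features from all samples: two features
#' are linked when their retention times differ by at most `rtTol` minutes
#' and their m/z by at most `mzTolPpm` ppm (of the larger m/z). Every
#' feature ends up in exactly one group; the group consensus m/z is the
#' intensity(area)-weighted mean of its members.
#'
#' @param features Feature `data.frame` (see [readFeatureTable()]).
#' @param rtTol Retention-time tolerance in minutes (default 0.2).
#' @param mzTolPpm m/z tolerance in ppm (default 5).
#' @return List with `features` (input plus `group_id`) and `groups`
#'   (per-group consensus: `group_id`, `mz`, `rt`, `n_features`,
#'   `n_samples`, `max_area`, `ms2_ref`).
#' @export
groupAcrossSamples <- function(features, rtTol = 0.2, mzTolPpm = 5) {
  stopifnot(nrow(features) >= 1L)
  f <- features[order(features$mz), , drop = FALSE]
  n <- nrow(f)
  edges <- list()
  j0 <- 1L
  for (i in seq_len(n)) {
    if (i == n) break
    for (j in (i + 1L):n) {
      dmz <- f$mz[j] - f$mz[i]
      if (dmz > mzTolPpm * 1e-6 * f$mz[j]) break
      if (abs(f$rt[j] - f$rt[i]) <= rtTol) {
        edges[[length(edges) + 1L]] <- c(i, j)
      }
    }
  }
  em <- if (length(edges)) do.call(rbind, edges) else matrix(integer(0), ncol = 2)
  comp <- .unionFind(n, em)
  gid <- as.integer(factor(comp, levels = unique(comp)))
  f$group_id <- gid
  groups <- do.call(rbind, lapply(split(f, gid), function(g) {
    ms2 <- g$ms2_ref[!is.na(g$ms2_ref)]
    data.frame(group_id = g$group_id[1],
               mz = sum(g$mz * g$area) / sum(g$area),
               rt = mean(g$rt),
               n_features = nrow(g),
               n_samples = length(unique(g$sample_id)),
               max_area = max(g$area),
               ms2_ref = if (length(ms2)) ms2[1] else NA_character_,
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  list(features = f, groups = groups)
}

#' Remove blank-borne background groups
#'
#' A sample group is matched to a blank group using the same tolerances as
#' cross-sample grouping; when the ratio of its maximum sample area to the
#' maximum matched blank area is at most `maxRatio` (default 5) the group
#' is classified as background and removed. Groups without a matched blank
#' feature are retained.
#'
#' @param groups Consensus group `data.frame` from [groupAcrossSamples()].
#' @param blankGroups Consensus groups built from blank injections.
#' @param maxRatio Maximum sample/blank area ratio still considered
#'   background (default 5; the boundary ratio is removed).
#' @param rtTol,mzTolPpm Matching tolerances (defaults as for grouping).
#' @return List with `retained` and `background` group `data.frame`s; the
#'   background table carries the matched `blank_ratio`.
#' @export
blankSubtract <- function(groups, blankGroups, maxRatio = 5,
                          rtTol = 0.2, mzTolPpm = 5) {
  if (is.null(blankGroups) || nrow(blankGroups) == 0L) {
    return(list(retained = groups,
                background = groups[integer(0), , drop = FALSE]))
  }
  ratio <- rep(NA_real_, nrow(groups))
  for (i in seq_len(nrow(groups))) {
    hit <- abs(blankGroups$rt - groups$rt[i]) <= rtTol &
      abs(blankGroups$mz - groups$mz[i]) <=
        mzTolPpm * 1e-6 * pmax(blankGroups$mz, groups$mz[i])
    if (any(hit)) {
      ratio[i] <- groups$max_area[i] / max(blankGroups$max_area[hit])
    }
  }
  isBg <- !is.na(ratio) & ratio <= maxRatio
  bg <- groups[isBg, , drop = FALSE]
  bg$blank_ratio <- ratio[isBg]
  list(retained = groups[!isBg, , drop = FALSE], background = bg)
}

#' Match feature groups against a suspect list
#'
#' A candidate annotation is produced for every (group, suspect) pair whose
#' measured consensus m/z lies within `tolPpm` of the suspect's theoretical
#' `[M-H]-` m/z; the signed ppm error is recorded.
#'
#' @param groups Consensus group `data.frame`.
#' @param suspects Suspect list (see [readSuspectList()]).
#' @param tolPpm Precursor mass tolerance in ppm (default 5).
#' @return `data.frame` of candidates: group columns plus `suspect_id`,
#'   `name`, `formula`, `class`, `expected_rt`, `in_library`, `theo_mz`,
#'   `ppm_error`.
#' @export
matchSuspects <- function(groups, suspects, tolPpm = 5) {
  theo <- deprotonatedMz(suspects$neutral_mass)
  out <- list()
  for (i in seq_len(nrow(groups))) {
    err <- ppmError(groups$mz[i], theo)
    hit <- which(abs(err) <= tolPpm)
    for (h in hit) {
      out[[length(out) + 1L]] <- cbind(
        groups[i, , drop = FALSE],
        data.frame(suspect_id = suspects$suspect_id[h],
                   name = suspects$name[h],
                   formula = suspects$formula[h],
                   class = suspects$class[h],
                   expected_rt = suspects$expected_rt[h],
                   in_library = suspects$in_library[h],
                   theo_mz = theo[h], ppm_error = err[h],
                   stringsAsFactors = FALSE))
    }
  }
  if (!length(out)) {
    return(data.frame())
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  # report candidates ranked by |ppm error| within each group
  res[order(res$group_id, abs(res$ppm_error)), , drop = FALSE]
}

# aggregated isotopologue envelope of a formula: relative abundance at
# nucleon shifts 0..maxShift, from per-element isotope distributions
.ISOTOPE_DIST <- list(
  C  = c("0" = 0.9893,   "1" = 0.0107),
  H  = c("0" = 0.999885, "1" = 0.000115),
  N  = c("0" = 0.99636,  "1" = 0.00364),
  O  = c("0" = 0.99757,  "1" = 0.00038, "2" = 0.00205),
  F  = c("0" = 1),
  P  = c("0" = 1),
  S  = c("0" = 0.9499,   "1" = 0.0075, "2" = 0.0425),
  Cl = c("0" = 0.7576,   "2" = 0.2424),
  Br = c("0" = 0.5069,   "2" = 0.4931)
)

.convolveShift <- function(a, b, maxShift) {
  out <- numeric(maxShift + 1L)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      s <- (i - 1L) + (j - 1L)
      if (s <= maxShift) out[s + 1L] <- out[s + 1L] + a[i] * b[j]
    }
  }
  out
}

#' Theoretical isotope envelope of a formula
#'
#' Aggregated-isotopologue envelope: relative intensities (base peak = 1)
#' at nucleon shifts 0, +1, +2, ... computed by convolving per-element
#' isotope distributions; peak m/z values are placed at the monoisotopic
#' ion mass plus multiples of the 13C-12C spacing.
#'
#' @param formula Formula string or named count vector.
#' @param charge `-1` (default, `[M-H]-`) or 0 (neutral).
#' @param maxShift Highest shift reported (default 3).
#' @return `data.frame` with `shift`, `mz`, `intensity` (relative, max 1).
#' @export
theoreticalIsotopePattern <- function(formula, charge = -1L, maxShift = 3L) {
  counts <- parseFormula(formula)
  dist <- c(1, numeric(maxShift))
  for (el in names(counts)) {
    d <- .ISOTOPE_DIST[[el]]
    v <- numeric(maxShift + 1L)
    v[as.integer(names(d)) + 1L] <- d
    for (k in seq_len(counts[[el]])) dist <- .convolveShift(dist, v, maxShift)
  }
  mono <- if (charge == -1L) deprotonatedMz(monoisotopicMass(counts))
          else monoisotopicMass(counts)
  data.frame(shift = 0:maxShift,
             mz = mono + (0:maxShift) * .ISOTOPE_SPACING,
             intensity = dist / max(dist))
}

#' Score an observed isotope envelope against a formula
#'
#' The theoretical envelope is computed from the formula (the M+1/M+2
#' signatures of C, S, Cl and Br dominate); observed peaks are matched
#' within `matchTolPpm`. For every theoretical isotopologue above 5%
#' relative abundance the relative intensity deviation is computed
#' (a missing expected peak counts as full deviation); deviations within
#' the instrument intensity tolerance `intensityTol` score zero and the
#' excess is rescaled to (0, 1]. The score is
#' `100 * (1 - mean deviation)`; envelopes from the correct formula score
#' 100 and a >= 80 score is the conventional acceptance threshold.
#'
#' @param observed `data.frame` with `mz` and `intensity` columns (>= 1
#'   peak).
#' @param formula Candidate formula.
#' @param intensityTol Relative intensity tolerance (default 0.30).
#' @param charge Ion charge convention for the envelope (default -1).
#' @param matchTolPpm Peak matching tolerance in ppm (default 10).
#' @return Score in `[0, 100]`.
#' @export
scoreIsotopePattern <- function(observed, formula, intensityTol = 0.30,
                                charge = -1L, matchTolPpm = 10) {
  if (is.null(observed) || nrow(observed) == 0L) {
    stop("observed isotope envelope is empty")
  }
  theo <- theoreticalIsotopePattern(formula, charge)
  theo <- theo[theo$intensity >= 0.05, , drop = FALSE]
  obsInt <- observed$intensity / max(observed$intensity)
  dev <- vapply(seq_len(nrow(theo)), function(k) {
    hit <- which(abs(ppmError(observed$mz, theo$mz[k])) <= matchTolPpm)
    if (!length(hit)) return(1)
    d <- abs(max(obsInt[hit]) - theo$intensity[k]) / theo$intensity[k]
    if (d <= intensityTol) 0 else min(1, (d - intensityTol) / (1 - intensityTol))
  }, numeric(1))
  100 * (1 - mean(dev))
}

#' Match MS2 peaks against diagnostic fragments and neutral losses
#'
#' A fragment hit is recorded when any spectrum peak matches a database
#' fragment m/z within `tolPpm`; a neutral-loss hit when
#' `precursor - peak` matches a database loss within `tolPpm` of the
#' precursor m/z.
#'
#' @param spectrum Spectrum list (`precursor_mz`, `peaks`), as read by
#'   [readMgf()].
#' @param fragmentDb `data.frame` with `name`, `mz` (see
#'   [defaultFragmentDb()]).
#' @param neutralLossDb `data.frame` with `name`, `mass`.
#' @param tolPpm MS2 tolerance in ppm (default 10).
#' @return List with `fragments` and `losses` hit `data.frame`s.
#' @export
matchFragments <- function(spectrum, fragmentDb = defaultFragmentDb(),
                           neutralLossDb = defaultNeutralLossDb(),
                           tolPpm = 10) {
  stopifnot(nrow(fragmentDb) > 0L, nrow(neutralLossDb) > 0L)
  pk <- spectrum$peaks
  fhits <- lhits <- list()
  for (i in seq_len(nrow(fragmentDb))) {
    err <- ppmError(pk$mz, fragmentDb$mz[i])
    h <- which(abs(err) <= tolPpm)
    if (length(h)) {
      fhits[[length(fhits) + 1L]] <- data.frame(
        name = fragmentDb$name[i], db_mz = fragmentDb$mz[i],
        peak_mz = pk$mz[h[1]], ppm_error = err[h[1]])
    }
  }
  losses <- spectrum$precursor_mz - pk$mz
  tolDa <- tolPpm * 1e-6 * spectrum$precursor_mz
  for (i in seq_len(nrow(neutralLossDb))) {
    h <- which(abs(losses - neutralLossDb$mass[i]) <= tolDa)
    if (length(h)) {
      lhits[[length(lhits) + 1L]] <- data.frame(
        name = neutralLossDb$name[i], db_mass = neutralLossDb$mass[i],
        observed_loss = losses[h[1]])
    }
  }
  emptyF <- data.frame(name = character(0), db_mz = numeric(0),
                       peak_mz = numeric(0), ppm_error = numeric(0))
  emptyL <- data.frame(name = character(0), db_mass = numeric(0),
                       observed_loss = numeric(0))
  list(fragments = if (length(fhits)) do.call(rbind, fhits) else emptyF,
       losses = if (length(lhits)) do.call(rbind, lhits) else emptyL)
}

#' Assign identification confidence levels
#'
#' Implements the five-tier identification-confidence framework used in
#' nontarget screening as a decision table over evidence flags, returning
#' the best (lowest) applicable level:
#' * L1 - retention-time match to an authentic standard plus accurate mass
#'   plus MS2 evidence (library or diagnostic-fragment);
#' * L2 - accurate mass plus curated spectral-library MS2 match;
#' * L3 - unequivocal formula plus at least one diagnostic/in-silico
#'   fragment hit;
#' * L4 - unequivocal molecular formula only;
#' * L5 - accurate-mass match to a suspect list only.
#'
#' @param evidence `data.frame` (or single-row list) with logical columns
#'   `mass_match`, `formula_assigned`, `ms2_library_match`,
#'   `ms2_insilico_fragment_match`, `rt_standard_match`.
#' @return Integer vector of levels 1-5; `NA` when MS2-only evidence
#'   cannot support any level. All-`FALSE` rows raise an error.
#' @export
assignConfidence <- function(evidence) {
  ev <- as.data.frame(evidence)
  need <- c("mass_match", "formula_assigned", "ms2_library_match",
            "ms2_insilico_fragment_match", "rt_standard_match")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("missing evidence flag(s): ",
                         paste(miss, collapse = ", "))
  if (any(rowSums(ev[, need]) == 0)) {
    stop("unannotatable: no evidence flag set")
  }
  if (any(ev$rt_standard_match & !ev$mass_match)) {
    stop("inconsistent evidence: rt_standard_match requires mass_match")
  }
  level <- rep(NA_integer_, nrow(ev))
  ms2 <- ev$ms2_library_match | ev$ms2_insilico_fragment_match
  level[ev$mass_match] <- 5L
  level[ev$formula_assigned] <- 4L
  level[ev$formula_assigned & ev$ms2_insilico_fragment_match] <- 3L
  level[ev$mass_match & ev$ms2_library_match] <- 2L
  level[ev$rt_standard_match & ev$mass_match & ms2] <- 1L
  level
}

#' Retain confident annotations
#'
#' Keeps annotations at or below `maxLevel` (default 3: confirmed,
#' probable and tentative structures); the per-level tally of the input is
#' attached as attribute `"level_counts"`.
#'
#' @param annotations `data.frame` with a `confidence` column.
#' @param maxLevel Worst level retained (default 3).
#' @return Filtered `data.frame`.
#' @export
retainConfident <- function(annotations, maxLevel = 3L) {
  counts <- table(factor(annotations$confidence, levels = 1:5))
  out <- annotations[!is.na(annotations$confidence) &
                       annotations$confidence <= maxLevel, , drop = FALSE]
  attr(out, "level_counts") <- counts
  out
}

#' Screen a feature study against a suspect list
#'
#' End-to-end screening: cross-sample grouping, blank subtraction, suspect
#' matching, evidence collection (formula enumeration within the suspect's
#' element bounds, spectral-library membership, diagnostic fragment /
#' neutral-loss matching, retention-time comparison against authentic
#' standards) and confidence-level assignment.
#'
#' @param features,blanks Feature `data.frame`s (samples and procedural
#'   blanks).
#' @param suspects Suspect list.
#' @param spectra Named list of MS2 spectra (`ms2_ref` values).
#' @param fragmentDb,neutralLossDb Diagnostic databases.
#' @param tolPpm Precursor tolerance in ppm (default 5).
#' @param ms2TolPpm MS2 tolerance in ppm (default 10).
#' @param rtTol Grouping RT tolerance in minutes (default 0.2).
#' @param rtStandardTol RT window for authentic-standard confirmation in
#'   minutes (default 0.1).
#' @param blankRatio Blank-subtraction ratio threshold (default 5).
#' @param maxLevel Confidence retention threshold (default 3).
#' @return List with `annotations` (retained, one row per group x suspect
#'   candidate with evidence flags and `confidence`), `all_annotations`,
#'   `groups`, `background` and `level_counts`.
#' @export
screenStudy <- function(features, blanks, suspects, spectra = list(),
                        fragmentDb = defaultFragmentDb(),
                        neutralLossDb = defaultNeutralLossDb(),
                        tolPpm = 5, ms2TolPpm = 10, rtTol = 0.2,
                        rtStandardTol = 0.1, blankRatio = 5,
                        maxLevel = 3L) {
  grp <- groupAcrossSamples(features, rtTol = rtTol, mzTolPpm = tolPpm)
  bgrp <- if (!is.null(blanks) && nrow(blanks)) {
    groupAcrossSamples(blanks, rtTol = rtTol, mzTolPpm = tolPpm)$groups
  } else NULL
  bs <- blankSubtract(grp$groups, bgrp, maxRatio = blankRatio,
                      rtTol = rtTol, mzTolPpm = tolPpm)
  cand <- matchSuspects(bs$retained, suspects, tolPpm = tolPpm)
  if (!nrow(cand)) {
    return(list(annotations = cand, all_annotations = cand,
                groups = grp, background = bs$background,
                level_counts = table(factor(integer(0), levels = 1:5))))
  }
  ev <- data.frame(mass_match = rep(TRUE, nrow(cand)),
                   formula_assigned = FALSE, ms2_library_match = FALSE,
                   ms2_insilico_fragment_match = FALSE,
                   rt_standard_match = FALSE)
  for (i in seq_len(nrow(cand))) {
    bounds <- parseFormula(cand$formula[i])
    fml <- enumerateFormulas(cand$mz[i], charge = -1L, tolPpm = tolPpm,
                             elements = names(bounds), maxCounts = bounds)
    ev$formula_assigned[i] <- formatFormula(cand$formula[i]) %in% fml$formula
    sp <- if (!is.na(cand$ms2_ref[i])) spectra[[cand$ms2_ref[i]]] else NULL
    if (!is.null(sp)) {
      hits <- matchFragments(sp, fragmentDb, neutralLossDb,
                             tolPpm = ms2TolPpm)
      ev$ms2_insilico_fragment_match[i] <-
        nrow(hits$fragments) > 0 || nrow(hits$losses) > 0
      ev$ms2_library_match[i] <- isTRUE(cand$in_library[i])
    }
    ev$rt_standard_match[i] <- !is.na(cand$expected_rt[i]) &&
      abs(cand$rt[i] - cand$expected_rt[i]) <= rtStandardTol
  }
  ann <- cbind(cand, ev)
  ann$confidence <- assignConfidence(ev)
  retained <- retainConfident(ann, maxLevel)
  list(annotations = retained, all_annotations = ann, groups = grp,
       background = bs$background,
       level_counts = attr(retained, "level_counts"))
}
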