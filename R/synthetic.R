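## Synthetic-data generators: a paired upstream/downstream river survey with
## known ground truth for every stage (concentrations, HRMS feature tables
## with planted homologous series, MS2 spectra, calibration series, hazard
## attributes). All generators are deterministic given (design, seed).

#' Built-in compound roster
#'
#' Twenty PFAS and fluorinated pesticides emulating a surface-water survey:
#' ten quantified targets (C4-C9 carboxylates and sulfonates plus 6:2 FTS)
#' and ten suspect-screening compounds including the ultra-short-chain acids
#' TFA, PFPrA and TFMS, the ether acid ADONA, two hydrogen-substituted
#' acids and four fluorinated pesticides. TFA is flagged dominant: its mean
#' concentration sits two orders of magnitude above the other compounds.
#' Detection probabilities mirror the detection frequencies reported for
#' this kind of survey (from ~17% up to 100%). `rpf` holds placeholder
#' relative potency factors (PFOA anchored at 1) for the PFOA-equivalent
#' screen; they are user-editable inputs, not measured values.
#'
#' @return `data.frame` with columns `compound_id`, `formula`, `class`,
#'   `true_rt` (minutes), `mean_conc` (ng/L), `detect_prob`, `rpf`,
#'   `is_target`, `quantifiable`, `dominant`, `in_library`.
#' @export
pfasCompoundRoster <- function() {
  r <- function(id, formula, class, rt, conc, dp, rpf, target,
                quant = TRUE, dominant = FALSE, lib = FALSE) {
    data.frame(compound_id = id, formula = formula, class = class,
               true_rt = rt, mean_conc = conc, detect_prob = dp, rpf = rpf,
               is_target = target, quantifiable = quant, dominant = dominant,
               in_library = lib, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    ## targets quantified with authentic standards
    r("PFBA",  "C4HF7O2",    "PFCA", 1.6, 1.8,  1.000, 0.05,  TRUE),
    r("PFPeA", "C5HF9O2",    "PFCA", 2.4, 1.5,  0.958, 0.03,  TRUE),
    r("PFHxA", "C6HF11O2",   "PFCA", 3.2, 0.5,  0.333, 0.01,  TRUE),
    r("PFHpA", "C7HF13O2",   "PFCA", 4.0, 0.3,  0.167, 0.505, TRUE),
    r("PFOA",  "C8HF15O2",   "PFCA", 4.8, 1.0,  1.000, 1,     TRUE),
    r("PFNA",  "C9HF17O2",   "PFCA", 5.6, 0.5,  0.750, 10,    TRUE),
    r("PFBS",  "C4HF9O3S",   "PFSA", 2.0, 0.7,  1.000, 0.001, TRUE),
    r("PFHxS", "C6HF13O3S",  "PFSA", 3.6, 0.4,  1.000, 0.6,   TRUE),
    r("PFOS",  "C8HF17O3S",  "PFSA", 5.2, 1.2,  1.000, 2,     TRUE),
    r("FTS_6_2", "C8H5F13O3S", "FTS", 4.4, 1.5, 1.000, 0.02,  TRUE),
    ## suspect-screening compounds
    r("TFA",   "C2HF3O2",    "PFCA", 0.8, 513,  1.000, 0.002, FALSE,
      dominant = TRUE),
    r("PFPrA", "C3HF5O2",    "PFCA", 1.2, 17.9, 1.000, 0.03,  FALSE),
    r("TFMS",  "CHF3O3S",    "PFSA", 1.0, 3.83, 1.000, 0.001, FALSE),
    r("ADONA", "C7H2F12O4",  "ether", 4.2, 11.2, 0.750, 0.06, FALSE,
      lib = TRUE),
    r("9H-PFNA",  "C9H2F16O2", "H-PFCA", 5.4, 1.11, 0.333, 0.1, FALSE),
    r("7H-PFHpA", "C7H2F12O2", "H-PFCA", 3.8, 0.63, 1.000, 0.1, FALSE),
    r("Flupropanate", "C3H2F4O2", "pesticide", 1.4, 5.95, 0.875, 0.002,
      FALSE, lib = TRUE),
    r("Fluxapyroxad", "C18H12F5N3O", "pesticide", 6.5, 0, 0.5, NA,
      FALSE, quant = FALSE, lib = TRUE),
    r("Isoxaflutole", "C15H12F3NO4S", "pesticide", 6.0, 0, 0.5, NA,
      FALSE, quant = FALSE, lib = TRUE),
    r("Fluometuron", "C10H11F3N2O", "pesticide", 5.8, 0, 0.5, NA,
      FALSE, quant = FALSE, lib = TRUE)
  ))
}

#' Default study design
#'
#' Encodes the survey layout the generators emulate: 12 settlements over
#' five water bodies (six on the Danube, three on the Great Backa Canal and
#' one each on the Tisa, Tamis and Sava), each sampled once upstream (odd
#' site numbers) and once downstream (even), giving 24 samples.
#'
#' @param seed Integer seed driving all randomness derived from the design.
#' @param compounds Compound roster (see [pfasCompoundRoster()]).
#' @param cv Lognormal coefficient of variation of site-level
#'   concentrations around the compound mean (default 0.30; positive-only,
#'   right-skewed noise typical of environmental concentration data).
#' @param sigmaPpm Standard deviation of relative m/z error in ppm for
#'   generated features (default 1, well inside the 5 ppm matching window).
#' @param settlementEffect Multiplicative downstream/upstream concentration
#'   ratio; 1 (default) plants no systematic settlement effect.
#' @return A list of class `"StudyDesign"`.
#' @export
defaultStudyDesign <- function(seed = 1L, compounds = pfasCompoundRoster(),
                               cv = 0.30, sigmaPpm = 1,
                               settlementEffect = 1) {
  settlements <- data.frame(
    settlement = c("Backo Novo Selo", "Backa Palanka", "Novi Sad", "Zemun",
                   "Belgrade", "Smederevo", "Kula", "Vrbas", "Srbobran",
                   "Becej", "Pancevo", "Novi Beograd"),
    water_body = c(rep("Danube", 6), rep("Great Backa Canal", 3),
                   "Tisa", "Tamis", "Sava"),
    stringsAsFactors = FALSE)
  design <- list(settlements = settlements, compounds = compounds,
                 n_samples = 2L * nrow(settlements), cv = cv,
                 sigma_ppm = sigmaPpm, settlement_effect = settlementEffect,
                 seed = as.integer(seed))
  class(design) <- "StudyDesign"
  validateDesign(design)
  design
}

#' Validate a study design
#'
#' @param design A `"StudyDesign"` list.
#' @return The design, invisibly; errors on violation.
#' @export
validateDesign <- function(design) {
  stopifnot(is.list(design))
  if (is.null(design$compounds) || nrow(design$compounds) < 1L) {
    stop("design must contain at least one compound")
  }
  if (length(unique(design$settlements$water_body)) < 2L) {
    stop("design needs >= 2 water bodies")
  }
  if (design$n_samples != 2L * nrow(design$settlements)) {
    stop("n_samples must be 2 x number of settlements")
  }
  cp <- design$compounds
  if (any(cp$mean_conc < 0)) stop("mean_conc must be >= 0")
  if (any(cp$detect_prob < 0 | cp$detect_prob > 1)) {
    stop("detect_prob must lie in [0, 1]")
  }
  dom <- cp$dominant & cp$quantifiable
  if (any(dom)) {
    others <- cp$mean_conc[!dom & cp$quantifiable]
    if (any(cp$mean_conc[dom] < 100 * stats::median(others))) {
      stop("dominant compound mean must be >= 100 x median of the others")
    }
  }
  invisible(design)
}

# sample metadata for a design; odd sites upstream, even downstream
.designSampleInfo <- function(design) {
  st <- design$settlements
  data.frame(
    sample_id = sprintf("S%02d", seq_len(design$n_samples)),
    site_number = seq_len(design$n_samples),
    settlement = rep(st$settlement, each = 2),
    water_body = rep(st$water_body, each = 2),
    position = rep(c("upstream", "downstream"), times = nrow(st)),
    is_blank = FALSE,
    stringsAsFactors = FALSE)
}

#' Simulate the concentration study
#'
#' Draws a compound x sample concentration matrix: lognormal site-level
#' noise (CV `design$cv`) around each compound's mean, zeroed where a
#' Bernoulli(`detect_prob`) draw fails. A `settlement_effect != 1`
#' multiplies downstream samples to plant a systematic paired effect.
#'
#' @param design A [defaultStudyDesign()] list.
#' @param seed Optional seed overriding `design$seed`.
#' @return List with `experiment` (a [PfasExperiment-class]) and
#'   `ground_truth` (planted concentrations, detection draws, realized
#'   detection frequencies).
#' @export
simulateConcentrations <- function(design = defaultStudyDesign(),
                                   seed = design$seed) {
  validateDesign(design)
  set.seed(seed)
  cp <- design$compounds[design$compounds$quantifiable, , drop = FALSE]
  si <- .designSampleInfo(design)
  n <- nrow(cp); m <- nrow(si)
  sdlog <- sqrt(log(1 + design$cv^2))
  conc <- matrix(0, n, m, dimnames = list(cp$compound_id, si$sample_id))
  detected <- matrix(FALSE, n, m, dimnames = dimnames(conc))
  for (i in seq_len(n)) {
    det <- stats::runif(m) < cp$detect_prob[i]
    v <- cp$mean_conc[i] * exp(stats::rnorm(m, -sdlog^2 / 2, sdlog))
    v[si$position == "downstream"] <-
      v[si$position == "downstream"] * design$settlement_effect
    conc[i, det] <- v[det]
    detected[i, ] <- det & cp$mean_conc[i] > 0
  }
  conc[conc > 0 & !detected] <- 0 # mean_conc 0 rows stay absent
  status <- ifelse(conc > 0, "quantified", "not_detected")
  rowinfo <- cp[, c("compound_id", "formula", "class", "true_rt",
                    "rpf", "is_target")]
  pe <- PfasExperiment(conc, status, rowinfo, si,
                       metadata = list(seed = seed, cv = design$cv))
  gt <- list(concentration = conc, detected = detected,
             detect_prob = stats::setNames(cp$detect_prob, cp$compound_id),
             realized_df = rowMeans(conc > 0))
  list(experiment = pe, ground_truth = gt)
}

# group compounds into exact-CF2 homologous families from their formulas:
# two compounds are homologues when their counts differ only in C and F
# with dF = 2 dC
.formulaFamilies <- function(formulas) {
  key <- vapply(formulas, function(f) {
    cnt <- parseFormula(f)
    full <- stats::setNames(integer(length(supportedElements())),
                            supportedElements())
    full[names(cnt)] <- cnt
    if (full["F"] < 2 * 1) return(paste("nonpfas", f)) # no CF2 backbone
    resid <- full
    k <- min(full["C"], full["F"] %/% 2)
    resid["C"] <- full["C"] - k
    resid["F"] <- full["F"] - 2 * k
    paste(names(resid), resid, collapse = " ")
  }, character(1))
  as.integer(factor(key, levels = unique(key)))
}

#' Simulate per-sample HRMS feature tables with ground truth
#'
#' Generates feature tables (m/z, RT, area, S/N) for every sample and for
#' procedural blanks. Planted PFAS appear as `[M-H]-` ions with relative
#' m/z error drawn as N(0, `sigma_ppm`); peak area follows the
#' isotope-dilution response model `area = conc/isConc * isArea` (unit
#' response factor) and S/N scales linearly
#' with concentration, anchored so that S/N = 10 at 0.1 ng/L. Three kinds
#' of interferents are planted and labeled in the ground truth:
#' `"decoy"` non-fluorinated features (positive mass defects, rejected if
#' they could link into a planted CF2 series), and `"background"` features
#' present in blanks at >= 1/`blank ratio` of their sample intensity.
#' MS2 spectra carrying one class-diagnostic fragment and the CO2 neutral
#' loss are attached to planted acid features.
#'
#' @param design A [defaultStudyDesign()] list.
#' @param seed Optional seed overriding `design$seed`.
#' @param concResult Optional result of [simulateConcentrations()] to reuse
#'   (so areas match planted concentrations); generated if `NULL`.
#' @param nDecoys Number of decoy features across the study (default 30).
#' @param nBackground Number of blank-borne background compounds
#'   (default 5), planted at a sample/blank intensity ratio of 3.
#' @return List with `features` (data.frame over all samples), `blanks`,
#'   `spectra` (list of MS2 spectra), and `ground_truth` (per-feature
#'   roles, compound identities, CF2 family ids, true m/z).
#' @export
simulateFeatureTables <- function(design = defaultStudyDesign(),
                                  seed = design$seed, concResult = NULL,
                                  nDecoys = 30L, nBackground = 5L,
                                  isConc = 2, isArea = 1e5) {
  validateDesign(design)
  if (is.null(concResult)) concResult <- simulateConcentrations(design, seed)
  set.seed(seed + 1000L)
  conc <- concResult$ground_truth$concentration
  cp <- design$compounds
  quant <- cp[cp$quantifiable, , drop = FALSE]
  si <- .designSampleInfo(design)
  # response model matched to isotope dilution: area = conc/conc_IS * area_IS
  # (unit RRF), so quantification recovers planted values exactly
  areaPerNgL <- isArea / isConc
  snrAnchor <- 0.1 # ng/L at which S/N = 10

  theo <- vapply(quant$formula, function(f) deprotonatedMz(f), numeric(1))
  fam <- .formulaFamilies(quant$formula)

  feats <- list(); gt <- list(); spectra <- list()
  fid <- 0L
  addFeature <- function(sample_id, mz, rt, area, snr, ms2 = NA_character_,
                         role, compound = NA_character_, family = NA_integer_,
                         true_mz = NA_real_) {
    fid <<- fid + 1L
    id <- sprintf("F%05d", fid)
    feats[[length(feats) + 1L]] <<- data.frame(
      feature_id = id, sample_id = sample_id, mz = mz, rt = rt,
      area = area, snr = snr, ms2_ref = ms2, stringsAsFactors = FALSE)
    gt[[length(gt) + 1L]] <<- data.frame(
      feature_id = id, sample_id = sample_id, role = role,
      compound_id = compound, family = family, true_mz = true_mz,
      stringsAsFactors = FALSE)
    id
  }

  ## planted PFAS features
  for (j in seq_len(nrow(si))) {
    sid <- si$sample_id[j]
    for (i in seq_len(nrow(quant))) {
      cij <- conc[quant$compound_id[i], sid]
      if (cij <= 0) next
      mz <- theo[i] * (1 + stats::rnorm(1, 0, design$sigma_ppm) * 1e-6)
      rt <- quant$true_rt[i] + stats::rnorm(1, 0, 0.02)
      area <- cij * areaPerNgL
      snr <- 10 * cij / snrAnchor
      specId <- sprintf("MS2_%s_%s", quant$compound_id[i], sid)
      spectra[[specId]] <- .plantedMs2(quant$formula[i], quant$class[i],
                                       theo[i], specId)
      addFeature(sid, mz, rt, area, snr, specId, "planted",
                 quant$compound_id[i], fam[i], theo[i])
    }
  }

  ## decoy features: CHNO-like positive mass defects, KMD-separated from
  ## every planted PFAS and from each other so they can never link into a
  ## CF2 series (or share an m/z) at the screening tolerances
  kmdTaken <- kendrickCoords(theo, "CF2")$kmd
  nd <- 0L
  while (nd < nDecoys) {
    nominal <- sample(100:600, 1L)
    mz <- nominal + stats::runif(1, 0.05, 0.45)
    if (any(abs(kendrickCoords(mz, "CF2")$kmd - kmdTaken) < 0.004)) next
    kmdTaken <- c(kmdTaken, kendrickCoords(mz, "CF2")$kmd)
    sid <- sample(si$sample_id, 1L)
    area <- stats::runif(1, 1e3, 1e6)
    addFeature(sid, mz, stats::runif(1, 0.5, 10), area, area / 1e3, role = "decoy")
    nd <- nd + 1L
  }

  ## blank-borne background compounds: present in every sample and in the
  ## blanks at 1/3 of the sample intensity (ratio 3 <= 5 => background)
  blankFeats <- list()
  bgRatio <- 3
  for (b in seq_len(nBackground)) {
    repeat {
      nominal <- sample(100:600, 1L)
      mz0 <- nominal + stats::runif(1, 0.05, 0.45)
      if (all(abs(kendrickCoords(mz0, "CF2")$kmd - kmdTaken) >= 0.004)) break
    }
    kmdTaken <- c(kmdTaken, kendrickCoords(mz0, "CF2")$kmd)
    rt0 <- stats::runif(1, 0.5, 10)
    areaS <- stats::runif(1, 1e4, 1e5)
    for (j in seq_len(nrow(si))) {
      addFeature(si$sample_id[j],
                 mz0 * (1 + stats::rnorm(1, 0, design$sigma_ppm) * 1e-6),
                 rt0 + stats::rnorm(1, 0, 0.02), areaS, areaS / 1e3,
                 role = "background", compound = sprintf("BG%02d", b))
    }
    blankFeats[[b]] <- data.frame(
      feature_id = sprintf("B%05d", b), sample_id = "BLANK1",
      mz = mz0 * (1 + stats::rnorm(1, 0, design$sigma_ppm) * 1e-6),
      rt = rt0 + stats::rnorm(1, 0, 0.02),
      area = areaS / bgRatio, snr = areaS / bgRatio / 1e3,
      ms2_ref = NA_character_, stringsAsFactors = FALSE)
  }

  features <- do.call(rbind, feats)
  groundTruth <- do.call(rbind, gt)
  list(features = features,
       blanks = do.call(rbind, blankFeats),
       spectra = spectra,
       ground_truth = groundTruth)
}

# MS2 spectrum for a planted acid/sulfonate: one class-diagnostic fragment
# plus the CO2 (carboxylates) or SO3-related loss, at exact masses
.plantedMs2 <- function(formula, class, precursorMz, spectrumId) {
  peaks <- NULL
  if (class %in% c("PFCA", "H-PFCA", "ether", "pesticide", "FTS")) {
    peaks <- rbind(peaks,
                   c(fragmentAnionMz("CF3"), 60),
                   c(precursorMz - monoisotopicMass("CO2"), 100))
  }
  if (class %in% c("PFSA", "FTS")) {
    peaks <- rbind(peaks, c(fragmentAnionMz("SO3"), 100))
  }
  peaks <- peaks[order(peaks[, 1]), , drop = FALSE]
  list(spectrum_id = spectrumId, precursor_mz = precursorMz,
       peaks = data.frame(mz = peaks[, 1], intensity = peaks[, 2]))
}

#' Simulate an isotope-dilution calibration set
#'
#' For each native/labeled pair, areas are generated as
#' `area = RRF_true * (conc/conc_IS) * area_IS * (1 + eps)` with
#' `eps ~ N(0, sigma)`; the generating RRFs are recorded as ground truth.
#'
#' @param compounds Character vector of native compound ids.
#' @param levels Numeric calibration concentrations (ng/L); at least 3,
#'   spanning at least one order of magnitude.
#' @param seed Integer seed.
#' @param sigma Relative area noise (default 0).
#' @param rrfTrue Named numeric vector of generating RRFs; defaults to 1.
#' @param isConc Internal-standard concentration (ng/L, default 2).
#' @param isArea Internal-standard area (default 1e5).
#' @return List with `calibration` (long data.frame) and `ground_truth`
#'   (named RRF vector).
#' @export
simulateCalibration <- function(compounds, levels = c(0.5, 1, 2, 5, 10, 20, 50),
                                seed = 1L, sigma = 0, rrfTrue = NULL,
                                isConc = 2, isArea = 1e5) {
  if (length(levels) < 3L) stop("need >= 3 calibration levels")
  if (max(levels) / min(levels) < 10) {
    stop("calibration levels must span >= 1 order of magnitude")
  }
  set.seed(seed)
  if (is.null(rrfTrue)) rrfTrue <- stats::setNames(rep(1, length(compounds)),
                                                   compounds)
  rows <- list()
  for (cmp in compounds) {
    eps <- stats::rnorm(length(levels), 0, sigma)
    rows[[cmp]] <- data.frame(
      native_id = cmp, labeled_id = paste0("M-", cmp),
      conc_native = levels, conc_is = isConc,
      area_native = rrfTrue[[cmp]] * (levels / isConc) * isArea * (1 + eps),
      area_is = isArea, stringsAsFactors = FALSE)
  }
  list(calibration = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       ground_truth = rrfTrue)
}

#' Hazard attribute schema
#'
#' The 18 persistence/bioaccumulation/toxicity attributes used by the
#' ToxPi hazard score: 3 persistence (aerobic biodegradation probabilities),
#' 2 bioaccumulation (log BCF, log Kow), 3 ecotoxicity (fish, Daphnia and
#' algae acute potencies as -log10 mg/L) and 10 human-health endpoints.
#' `direction` records whether a larger raw value means more hazardous
#' (`"higher"`) or less (`"lower"`, e.g. biodegradation probability).
#'
#' @return `data.frame` with columns `attribute`, `group`, `direction`.
#' @export
hazardAttributeSchema <- function() {
  data.frame(
    attribute = c("biowin1", "biowin3", "biowin5",
                  "log_bcf", "log_kow",
                  "fish_lc50_96h", "daphnia_lc50_48h", "algae_ec50_96h",
                  "carcinogenicity", "developmental_toxicity", "mutagenicity",
                  "endocrine_disruption", "hepatotoxicity", "skin_irritation",
                  "eye_irritation", "sensitization", "repeated_dose_toxicity",
                  "oral_rat_ld50"),
    group = c(rep("persistence", 3), rep("bioaccumulation", 2),
              rep("ecotoxicity", 3), rep("human", 10)),
    direction = c(rep("lower", 3), rep("higher", 15)),
    stringsAsFactors = FALSE)
}

#' Simulate a compound x 18-attribute hazard table
#'
#' Generates plausible QSAR-style attribute values: biodegradation
#' probabilities in (0, 0.4) (PFAS are poorly biodegradable), log BCF in
#' (0, 4), log Kow in (1, 7), acute aquatic potencies as -log10(mg/L) in
#' (-3, 2), human-endpoint probabilities in (0, 1) and an oral rat LD50
#' potency. Ground truth retains the generating draw.
#'
#' @param compoundIds Character vector of compound ids (>= 2).
#' @param seed Integer seed.
#' @return Numeric matrix, compounds x 18 attributes.
#' @export
simulateHazardTable <- function(compoundIds, seed = 1L) {
  if (length(compoundIds) < 2L) stop("need >= 2 compounds")
  set.seed(seed)
  sch <- hazardAttributeSchema()
  n <- length(compoundIds)
  draw <- function(attr) {
    switch(attr,
      biowin1 = , biowin3 = , biowin5 = stats::runif(n, 0.0, 0.4),
      log_bcf = stats::runif(n, 0, 4),
      log_kow = stats::runif(n, 1, 7),
      fish_lc50_96h = , daphnia_lc50_48h = , algae_ec50_96h =
        stats::runif(n, -3, 2),
      oral_rat_ld50 = stats::runif(n, -4, 0),
      stats::runif(n, 0, 1))
  }
  m <- vapply(sch$attribute, draw, numeric(n))
  rownames(m) <- compoundIds
  m
}

#' Simulate the complete synthetic study
#'
#' Runs every generator with seeds derived from the design seed and
#' returns all pipeline inputs plus exhaustive ground truth.
#'
#' @param design A [defaultStudyDesign()] list.
#' @param calibSigma Relative noise of calibration areas (default 0).
#' @return List: `experiment`, `features`, `blanks`, `spectra`,
#'   `calibration`, `rrf_truth`, `hazard`, `suspects`, `ground_truth`.
#' @export
simulateStudy <- function(design = defaultStudyDesign(), calibSigma = 0) {
  concRes <- simulateConcentrations(design)
  featRes <- simulateFeatureTables(design, concResult = concRes)
  targets <- design$compounds$compound_id[design$compounds$is_target]
  calib <- simulateCalibration(targets, seed = design$seed + 2000L,
                               sigma = calibSigma)
  quantIds <- design$compounds$compound_id[design$compounds$quantifiable]
  hazard <- simulateHazardTable(quantIds, seed = design$seed + 3000L)
  list(experiment = concRes$experiment,
       features = featRes$features,
       blanks = featRes$blanks,
       spectra = featRes$spectra,
       calibration = calib$calibration,
       rrf_truth = calib$ground_truth,
       hazard = hazard,
       suspects = suspectList(design$compounds),
       ground_truth = c(concRes$ground_truth,
                        list(features = featRes$ground_truth)))
}

#' Build a suspect list from a compound roster
#'
#' Computes neutral monoisotopic masses from the formulas and assigns
#' suspect ids; targets carry their reference retention time.
#'
#' @param compounds Roster `data.frame` (see [pfasCompoundRoster()]).
#' @return Suspect-list `data.frame` with columns `name`, `formula`,
#'   `neutral_mass`, `suspect_id`, `class`, `expected_rt`, `in_library`.
#' @export
suspectList <- function(compounds = pfasCompoundRoster()) {
  data.frame(
    name = compounds$compound_id,
    formula = compounds$formula,
    neutral_mass = vapply(compounds$formula, monoisotopicMass, numeric(1)),
    suspect_id = sprintf("SL%04d", seq_len(nrow(compounds))),
    class = compounds$class,
    expected_rt = ifelse(compounds$is_target, compounds$true_rt, NA_real_),
    in_library = compounds$in_library,
    stringsAsFactors = FALSE, row.names = NULL)
}
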