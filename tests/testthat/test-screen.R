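test_that("cross-sample grouping respects both tolerances", {
  f2 <- data.frame(feature_id = c("a", "b"), sample_id = c("S1", "S2"),
                   mz = c(400.0000, 400.0008), rt = c(5.0, 5.1),
                   area = c(1, 1), snr = c(10, 10), ms2_ref = NA)
  g <- groupAcrossSamples(f2)
  expect_equal(nrow(g$groups), 1L)
  f2$rt <- c(5.0, 5.5)
  expect_equal(nrow(groupAcrossSamples(f2)$groups), 2L)
  # consensus m/z is intensity-weighted
  f2$rt <- c(5.0, 5.1); f2$area <- c(100, 300)
  g <- groupAcrossSamples(f2)
  expect_equal(g$groups$mz, (400.0000 * 100 + 400.0008 * 300) / 400)
})

test_that("grouping equals brute-force transitive closure", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 30
    f <- data.frame(feature_id = paste0("f", 1:n), sample_id = "S1",
                    mz = runif(n, 100, 101), rt = runif(n, 0, 2),
                    area = runif(n, 1, 10), snr = 10, ms2_ref = NA)
    got <- groupAcrossSamples(f)$features
    gotPart <- split(got$feature_id, got$group_id)
    wantLab <- oracleGrouping(f)
    wantPart <- split(f$feature_id, wantLab)
    expect_equal(membershipPairs(gotPart), membershipPairs(wantPart))
  }
})

test_that("blank subtraction applies the sample/blank ratio-of-5 rule", {
  g <- data.frame(group_id = 1:3, mz = c(200.1, 300.1, 400.1),
                  rt = c(1, 2, 3), n_features = 1, n_samples = 1,
                  max_area = c(1000, 1000, 1000), ms2_ref = NA)
  bl <- data.frame(group_id = 1:2, mz = c(200.1, 300.1), rt = c(1, 2),
                   n_features = 1, n_samples = 1, max_area = c(250, 100),
                   ms2_ref = NA)
  bs <- blankSubtract(g, bl)
  expect_equal(bs$background$group_id, 1L)  # ratio 4 -> background
  expect_setequal(bs$retained$group_id, c(2L, 3L)) # ratio 10, no match
  # boundary: ratio exactly 5 is removed
  bl$max_area <- c(200, 100)
  expect_true(1L %in% blankSubtract(g, bl)$background$group_id)
})

test_that("suspect matching applies a signed 5 ppm window", {
  sus <- data.frame(name = "PFOA", formula = "C8HF15O2",
                    neutral_mass = monoisotopicMass("C8HF15O2"),
                    suspect_id = "SL1", class = "PFCA",
                    expected_rt = NA_real_, in_library = FALSE)
  g <- data.frame(group_id = 1L, mz = 412.96800, rt = 4.8, n_features = 1,
                  n_samples = 1, max_area = 1, ms2_ref = NA)
  m <- matchSuspects(g, sus)
  expect_equal(nrow(m), 1L)
  expect_equal(m$ppm_error, 3.9, tolerance = 0.04) # 3.8-3.9 ppm window
  g$mz <- 412.97100
  expect_equal(nrow(matchSuspects(g, sus)), 0L)
  g$mz <- deprotonatedMz("C8HF15O2")
  expect_equal(matchSuspects(g, sus, tolPpm = 0.001)$ppm_error, 0,
               tolerance = 1e-6)
})

test_that("isotope-pattern scoring separates correct from halogen-shifted formulas", {
  theo <- theoreticalIsotopePattern("C8HF17O3S")
  obs <- data.frame(mz = theo$mz, intensity = theo$intensity)
  expect_equal(scoreIsotopePattern(obs, "C8HF17O3S"), 100, tolerance = 1e-9)
  # a chlorine-free envelope scored against a one-Cl formula misses the
  # large M+2 and fails the 80% threshold
  obsC <- theoreticalIsotopePattern("C10H10O2")
  expect_lt(scoreIsotopePattern(
    data.frame(mz = obsC$mz, intensity = obsC$intensity),
    c(C = 10, H = 9, Cl = 1, O = 2)), 80)
  # uniform +30% perturbation renormalizes away
  pert <- data.frame(mz = theo$mz, intensity = theo$intensity * 1.3)
  expect_gte(scoreIsotopePattern(pert, "C8HF17O3S"), 80)
  expect_error(scoreIsotopePattern(obs[0, ], "C2HF3O2"), "empty")
})

test_that("diagnostic fragment and neutral-loss matching hit at 10 ppm", {
  sp <- list(spectrum_id = "t", precursor_mz = 412.9664,
             peaks = data.frame(mz = c(68.9952, 368.9766),
                                intensity = c(60, 100)))
  hits <- matchFragments(sp)
  expect_true("CF3-" %in% hits$fragments$name)
  expect_true("CO2" %in% hits$losses$name)
  far <- list(spectrum_id = "t2", precursor_mz = 500,
              peaks = data.frame(mz = c(123.4567), intensity = 1))
  empty <- matchFragments(far)
  expect_equal(nrow(empty$fragments), 0L)
  expect_equal(nrow(empty$losses), 0L)
})

test_that("confidence assignment equals the 32-case truth-table oracle", {
  flags <- expand.grid(mass_match = c(FALSE, TRUE),
                       formula_assigned = c(FALSE, TRUE),
                       ms2_library_match = c(FALSE, TRUE),
                       ms2_insilico_fragment_match = c(FALSE, TRUE),
                       rt_standard_match = c(FALSE, TRUE))
  for (i in seq_len(nrow(flags))) {
    fl <- flags[i, ]
    want <- tryCatch(oracleConfidence(fl$mass_match, fl$formula_assigned,
                                      fl$ms2_library_match,
                                      fl$ms2_insilico_fragment_match,
                                      fl$rt_standard_match),
                     error = function(e) "error")
    got <- tryCatch(assignConfidence(fl), error = function(e) "error")
    expect_equal(got, want, info = paste(unlist(fl), collapse = ","))
  }
})

test_that("confidence is monotone: more evidence never worsens the level", {
  flags <- expand.grid(mass_match = c(FALSE, TRUE),
                       formula_assigned = c(FALSE, TRUE),
                       ms2_library_match = c(FALSE, TRUE),
                       ms2_insilico_fragment_match = c(FALSE, TRUE),
                       rt_standard_match = c(FALSE, TRUE))
  lvl <- function(fl) tryCatch(assignConfidence(fl),
                               error = function(e) NA_integer_)
  for (i in seq_len(nrow(flags))) {
    base <- flags[i, ]
    l0 <- lvl(base)
    if (is.na(l0)) next
    for (fn in names(base)) {
      if (base[[fn]]) next
      more <- base; more[[fn]] <- TRUE
      if (fn == "rt_standard_match") more$mass_match <- TRUE
      l1 <- lvl(more)
      expect_true(is.na(l1) || l1 <= l0)
    }
  }
})

test_that("retention keeps levels 1-3 and tallies the rest", {
  ann <- data.frame(feature = letters[1:5], confidence = 1:5)
  kept <- retainConfident(ann)
  expect_equal(kept$confidence, 1:3)
  expect_equal(as.integer(attr(kept, "level_counts")), rep(1L, 5))
  expect_equal(nrow(retainConfident(data.frame(confidence = c(5, 5)))), 0L)
  expect_equal(nrow(retainConfident(ann, maxLevel = 5)), 5L)
})

test_that("screening the synthetic study recovers the planted truth", {
  study <- simulateStudy(defaultStudyDesign(seed = 17))
  scr <- screenStudy(study$features, study$blanks, study$suspects,
                     study$spectra)
  gt <- study$ground_truth$features
  feats <- scr$groups$features
  # blank subtraction removes exactly the generator-labeled background
  bgGroups <- unique(feats$group_id[feats$feature_id %in%
                                      gt$feature_id[gt$role == "background"]])
  expect_setequal(scr$background$group_id, bgGroups)
  # every planted quantifiable suspect reaches confidence <= 3
  planted <- unique(gt$compound_id[gt$role == "planted"])
  expect_setequal(scr$annotations$name, planted)
  expect_true(all(scr$annotations$confidence <= 3))
  # decoys are never annotated at all (mass-only L5 at worst)
  decoyGroups <- feats$group_id[feats$feature_id %in%
                                  gt$feature_id[gt$role == "decoy"]]
  expect_false(any(scr$all_annotations$group_id %in% decoyGroups))
})
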