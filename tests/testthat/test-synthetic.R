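test_that("detection probability boundaries behave deterministically", {
  roster <- pfasCompoundRoster()[1:4, ]
  roster$detect_prob <- 1
  d <- defaultStudyDesign(seed = 2, compounds = roster)
  res <- simulateConcentrations(d)
  expect_true(all(concentrations(res$experiment) > 0))
  expect_equal(unname(res$ground_truth$realized_df), rep(1, 4))

  roster$detect_prob[2] <- 0
  d0 <- defaultStudyDesign(seed = 2, compounds = roster)
  res0 <- simulateConcentrations(d0)
  expect_true(all(concentrations(res0$experiment)[2, ] == 0))
})

test_that("realized detection frequency converges to detect_prob", {
  d <- defaultStudyDesign(seed = 42)
  p <- d$compounds$detect_prob[d$compounds$quantifiable]
  nRep <- 1000L
  hits <- 0
  for (r in seq_len(nRep)) {
    res <- simulateConcentrations(d, seed = 42L + r)
    hits <- hits + rowSums(res$ground_truth$detected)
  }
  df <- hits / (nRep * 24)
  se <- sqrt(p * (1 - p) / (nRep * 24))
  expect_true(all(abs(df - p) <= pmax(3 * se, 1e-12)))
})

test_that("the generated study matches its design invariants", {
  d <- defaultStudyDesign(seed = 5)
  res <- simulateConcentrations(d)
  si <- sampleInfo(res$experiment)
  expect_equal(nrow(si), 24L)
  expect_equal(as.integer(table(si$settlement)), rep(2L, 12))
  expect_equal(length(unique(si$water_body)), 5L)
  # determinism given (design, seed)
  res2 <- simulateConcentrations(d)
  expect_identical(concentrations(res$experiment),
                   concentrations(res2$experiment))
  # dominant compound (TFA analogue) sits >= 100x the median of the others
  conc <- compoundInfo(res$experiment)
  expect_error(
    defaultStudyDesign(seed = 1, compounds = transform(
      pfasCompoundRoster(), mean_conc = ifelse(dominant, 5, mean_conc))),
    "dominant")
  expect_error(defaultStudyDesign(
    seed = 1, compounds = pfasCompoundRoster()[0, ]), "at least one")
})

test_that("feature generator plants exact masses and labels ground truth", {
  d <- defaultStudyDesign(seed = 9, sigmaPpm = 1e-12)
  ft <- simulateFeatureTables(d)
  gt <- ft$ground_truth
  planted <- gt[gt$role == "planted", ]
  f <- ft$features[match(planted$feature_id, ft$features$feature_id), ]
  expect_equal(f$mz, planted$true_mz, tolerance = 1e-9)
  # the C2-C9 PFCA family shares one ground-truth series id
  pfcaIds <- planted$compound_id %in% c("TFA", "PFPrA", "PFBA", "PFPeA",
                                        "PFHxA", "PFHpA", "PFOA", "PFNA")
  expect_equal(length(unique(planted$family[pfcaIds])), 1L)
  # background features are labeled and present in blanks at ratio <= 5
  expect_true(all(c("planted", "decoy", "background") %in% gt$role))
  bg <- gt[gt$role == "background", ]
  expect_gt(nrow(ft$blanks), 0L)
  for (b in seq_len(nrow(ft$blanks))) {
    ids <- bg$feature_id[bg$compound_id == sprintf("BG%02d", b)]
    sampleArea <- ft$features$area[match(ids, ft$features$feature_id)]
    expect_equal(unique(sampleArea) / ft$blanks$area[b], 3, tolerance = 1e-9)
  }
})

test_that("calibration generator recovers planted response factors", {
  cal <- simulateCalibration(c("PFOA", "PFOS"), seed = 1, sigma = 0,
                             rrfTrue = c(PFOA = 1, PFOS = 0.5))
  fit <- fitRrf(cal$calibration)
  expect_equal(fit$rrf[fit$native_id == "PFOA"], 1, tolerance = 1e-12)
  expect_equal(fit$rrf[fit$native_id == "PFOS"], 0.5, tolerance = 1e-12)
  expect_equal(fit$fit_r2, c(1, 1), tolerance = 1e-9)
  expect_error(simulateCalibration("PFOA", levels = c(1, 2)), ">= 3")
})

test_that("noisy calibration is unbiased in the median over seeds", {
  fits <- vapply(1:200, function(s) {
    cal <- simulateCalibration("PFOA", seed = s, sigma = 0.05,
                               rrfTrue = c(PFOA = 0.8))
    fitRrf(cal$calibration)$rrf
  }, numeric(1))
  # the median fitted RRF recovers the planted value within 2%
  expect_lte(abs(median(fits) - 0.8) / 0.8, 0.02)
  # spread of individual fits under 5% multiplicative area noise: the
  # origin-constrained slope is dominated by the top calibration level,
  # giving a median relative error near 2.8% (Monte-Carlo value frozen
  # with margin)
  expect_lte(median(abs(fits - 0.8) / 0.8), 0.04)
})

test_that("hazard generator follows the 18-attribute schema", {
  sch <- hazardAttributeSchema()
  expect_equal(nrow(sch), 18L)
  expect_equal(as.integer(table(factor(sch$group, levels = c(
    "persistence", "bioaccumulation", "ecotoxicity", "human")))),
    c(3L, 2L, 3L, 10L))
  h <- simulateHazardTable(c("A", "B", "C"), seed = 2)
  expect_equal(dim(h), c(3L, 18L))
  expect_identical(h, simulateHazardTable(c("A", "B", "C"), seed = 2))
  expect_error(simulateHazardTable("A"), ">= 2")
})
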