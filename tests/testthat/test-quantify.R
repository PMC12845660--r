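test_that("isotope-dilution arithmetic is exact", {
  expect_equal(quantifyTarget(200, 100, 2, 1), 4.0)
  expect_equal(quantifyTarget(0, 100, 2, 1), 0)
  expect_equal(quantifyTarget(100, 100, 7.3, 1), 7.3) # identity
  expect_error(quantifyTarget(1, 0, 2, 1), "area")
  expect_error(quantifyTarget(1, 1, 2, 0), "rrf")
})

test_that("degenerate calibrations are rejected", {
  cal <- simulateCalibration("X", seed = 1, rrfTrue = c(X = 1))$calibration
  cal$area_native <- 0
  expect_error(fitRrf(cal), "degenerate")
})

test_that("surrogate assignment minimizes RT, then class, then mass", {
  targets <- data.frame(compound_id = c("T1", "T2"),
                        rt = c(1.9, 3.5), class = c("PFSA", "PFCA"),
                        neutral_mass = c(300, 250))
  pick <- assignSurrogate(list(rt = 2.0, class = "PFCA",
                               neutral_mass = 114), targets)
  expect_equal(as.character(pick), "T1") # nearest RT wins
  targets$rt <- c(2.5, 1.5) # both 0.5 min away -> class tie-break
  pick <- assignSurrogate(list(rt = 2.0, class = "PFCA",
                               neutral_mass = 114), targets)
  expect_equal(as.character(pick), "T2")
  expect_error(assignSurrogate(list(rt = 1, class = "PFCA",
                                    neutral_mass = 1), targets[0, ]),
               "no targets")
})

test_that("surrogate choice equals brute-force lexicographic minimization", {
  set.seed(31)
  for (rep in 1:20) {
    nT <- sample(2:6, 1)
    targets <- data.frame(compound_id = paste0("T", 1:nT),
                          rt = round(runif(nT, 1, 8), 2),
                          class = sample(c("PFCA", "PFSA", "FTS"), nT, TRUE),
                          neutral_mass = round(runif(nT, 100, 600), 1))
    ssa <- list(rt = round(runif(1, 1, 8), 2),
                class = sample(c("PFCA", "PFSA"), 1),
                neutral_mass = round(runif(1, 100, 600), 1))
    key <- cbind(abs(targets$rt - ssa$rt),
                 as.integer(targets$class != ssa$class),
                 abs(targets$neutral_mass - ssa$neutral_mass))
    want <- targets$compound_id[order(key[, 1], key[, 2], key[, 3])][1]
    expect_equal(as.character(assignSurrogate(ssa, targets)), want)
  }
})

test_that("QC gate follows the stated boundary conventions", {
  expect_equal(qcGate(2.9)$flags, "low_snr")
  expect_false(qcGate(3)$pass)             # "greater than 3" is strict
  expect_true(qcGate(3.01)$pass)
  expect_true(qcGate(10, 0.25, 0.05, TRUE)$pass)
  expect_equal(qcGate(10, 0.30)$flags, "ion_ratio") # "below 30%" strict
  expect_equal(qcGate(10, 0, 0.15, TRUE)$flags, "rt_drift")
  expect_true(qcGate(10, 0, 0.1, TRUE)$pass)  # "within +-0.1 min" inclusive
  expect_true(qcGate(10, 0, 0.5, FALSE)$pass) # no RT gate without standard
  # full truth table over boundary combinations
  for (snr in c(2.9, 3, 3.1)) {
    for (ir in c(0.29, 0.30)) {
      for (rtv in c(0.1, 0.11)) {
        got <- qcGate(snr, ir, rtv, TRUE)
        expect_equal(got$pass, snr > 3 && ir < 0.30 && abs(rtv) <= 0.1)
      }
    }
  }
})

test_that("MQL extrapolates linearly to S/N 10", {
  expect_equal(estimateMql(data.frame(conc = 2, snr = 4)), 5)
  expect_equal(estimateMql(data.frame(conc = 3.7, snr = 10)), 3.7)
  expect_equal(estimateMql(data.frame(conc = c(2, 8), snr = c(4, 40))), 2)
  expect_true(is.na(estimateMql(data.frame(conc = numeric(0),
                                           snr = numeric(0)))))
})

test_that("blank correction floors at zero", {
  expect_equal(blankCorrect(10, 2), 8)
  expect_equal(blankCorrect(2, 5), 0)
  expect_equal(blankCorrect(10, 0), 10)
  expect_error(blankCorrect(-1, 0))
})

test_that("noiseless end-to-end semi-quantification is exact", {
  study <- simulateStudy(defaultStudyDesign(seed = 23))
  scr <- screenStudy(study$features, study$blanks, study$suspects,
                     study$spectra)
  rrf <- fitRrf(study$calibration)
  rec <- semiQuantify(scr$annotations, scr$groups$features, rrf,
                      study$suspects)
  gt <- study$ground_truth$concentration
  planted <- mapply(function(cmp, s) gt[cmp, s], rec$compound_id,
                    rec$sample_id)
  # unit RRFs: the surrogate always shares the generating response, so
  # recovery is exact up to floating point
  expect_equal(rec$conc, unname(planted), tolerance = 1e-9)
  expect_true(all(rec$status %in% c("quantified", "semi_quantified")))
  expect_true(all(rec$conc >= 0))
})
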