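test_that("attribute normalization min-max scales with direction alignment", {
  sch <- hazardAttributeSchema()
  h <- matrix(rep(c(2, 4, 6), 18), nrow = 3,
              dimnames = list(c("a", "b", "c"), sch$attribute))
  n <- normalizeAttributes(h)
  higher <- sch$attribute[sch$direction == "higher"]
  lower <- sch$attribute[sch$direction == "lower"]
  expect_true(all(n[, higher] == c(0, 0.5, 1)))
  expect_true(all(n[, lower] == c(1, 0.5, 0))) # reflected (biodegradation)
  h[, 1] <- 5 # constant attribute -> zeros
  expect_true(all(normalizeAttributes(h)[, 1] == 0))
  expect_error(normalizeAttributes(h[1, , drop = FALSE]), "single compound")
})

test_that("ToxPi weights conserve to exactly 1", {
  # rational check over the common denominator 180
  num <- 3L * 20L + 2L * 30L + 3L * 10L + 10L * 3L
  expect_identical(num, 180L)
  expect_equal(sum(toxpiWeights()), 1, tolerance = 1e-12)
})

test_that("ToxPi is the weighted attribute sum in [0, 1]", {
  sch <- hazardAttributeSchema()
  ones <- matrix(1, 2, 18, dimnames = list(c("a", "b"), sch$attribute))
  expect_equal(unname(toxpiScore(ones)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(toxpiScore(ones * 0)), c(0, 0))
  pOnly <- ones * 0
  pOnly[, sch$attribute[sch$group == "persistence"]] <- 1
  expect_equal(unname(toxpiScore(pOnly)), c(1, 1) / 3, tolerance = 1e-12)
  expect_error(toxpiScore(ones[, 1:5]), "weights")
})

test_that("a uniformly dominant compound attains the maximum ToxPi", {
  sch <- hazardAttributeSchema()
  set.seed(47)
  h <- simulateHazardTable(paste0("c", 1:5), seed = 47)
  h["c3", sch$direction == "higher"] <-
    apply(h[, sch$direction == "higher"], 2, max) + 1
  h["c3", sch$direction == "lower"] <-
    apply(h[, sch$direction == "lower", drop = FALSE], 2, min) - 0.01
  tp <- toxpiScore(normalizeAttributes(h))
  expect_equal(names(which.max(tp)), "c3")
  expect_equal(unname(tp["c3"]), 1, tolerance = 1e-12)
  # identical attribute rows give identical ToxPi
  hSame <- h[rep(1, 3), ]; rownames(hSame) <- c("x", "y", "z")
  expect_equal(diff(range(toxpiScore(normalizeAttributes(hSame)))), 0)
})

test_that("magnitude and exposure follow the min-max definitions", {
  expect_equal(concentrationMagnitude(c(1, 5.5, 10)), c(0, 0.5, 1))
  expect_warning(m <- concentrationMagnitude(c(2, 2, 2)), "degenerate")
  expect_equal(m, c(0, 0, 0))
  expect_equal(exposureScore(0.75, 0.5), 0.375)
  expect_equal(exposureScore(0, 0.9), 0)
  e <- normalizeExposure(c(0.1, 0.4, 0.9))
  expect_equal(e, c(0, 0.375, 1))
  expect_equal(sum(e == 1), 1L)
})

test_that("risk classification follows the published category bounds", {
  ri <- c(0.15, 0.1, 0.05, 0.01, 0.005, 0.001, 0.0005)
  want <- c("high", "medium", "medium", "low", "low", "negligible",
            "negligible")
  expect_equal(as.character(classifyRisk(ri)), want)
  expect_equal(as.character(classifyRisk(riskIndex(0.5, 0.2))), "medium")
  expect_equal(as.character(classifyRisk(riskIndex(0.9, 0))), "negligible")
  expect_error(riskIndex(1.2, 0.5), "\\[0, 1\\]")
  expect_error(classifyRisk(-0.1))
})

test_that("risk index is monotone and scale invariant", {
  set.seed(53)
  study <- simulateConcentrations(defaultStudyDesign(seed = 53))
  pe <- study$experiment
  h <- simulateHazardTable(compoundInfo(pe)$compound_id, seed = 53)
  r1 <- prioritizeRisk(pe, h)
  # scale invariance: multiplying all concentrations by k changes nothing
  pe2 <- PfasExperiment(concentrations(pe) * 7, quantStatus(pe),
                        compoundInfo(pe), sampleInfo(pe))
  r2 <- prioritizeRisk(pe2, h)
  expect_equal(r1$magnitude, r2$magnitude)
  expect_equal(r1$exposure_norm, r2$exposure_norm)
  expect_equal(r1$ri, r2$ri)
  # monotone in hazard attributes: raising one compound's hazardous
  # attributes never lowers its RI
  sch <- hazardAttributeSchema()
  h3 <- h
  cmp <- r1$compound_id[3]
  h3[cmp, sch$direction == "higher"] <- h3[cmp, sch$direction == "higher"] + 1
  r3 <- prioritizeRisk(pe, h3)
  expect_gte(r3$ri[r3$compound_id == cmp], r1$ri[r1$compound_id == cmp])
})

test_that("a dominant low-hazard compound can outrank high-ToxPi compounds", {
  # the concentration-driven exposure term lets an abundant, always-
  # detected compound (the TFA analogue) exceed the risk rank of more
  # toxic but scarce compounds
  study <- simulateConcentrations(defaultStudyDesign(seed = 59))
  pe <- study$experiment
  h <- simulateHazardTable(compoundInfo(pe)$compound_id, seed = 59)
  r <- prioritizeRisk(pe, h)
  expect_equal(r$compound_id[1], "TFA")
  expect_equal(r$exposure_norm[1], 1)
  higherTox <- r$toxpi > r$toxpi[1]
  expect_true(any(higherTox) && all(r$ri[higherTox] < r$ri[1]))
})
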