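noiselessConfig <- function(n = 3L, seed = 5L)
  syntheticConfig(nSpecimens = n, jitterSigmaMm = 0,
                  labelConfusion = identityConfusion(),
                  splitMergeProb = 0, seed = seed)

test_that("the same seed reproduces the cohort exactly", {
  c1 <- generateCohort(syntheticConfig(nSpecimens = 2, seed = 71))
  c2 <- generateCohort(syntheticConfig(nSpecimens = 2, seed = 71))
  expect_identical(names(c1$cases), names(c2$cases))
  r1 <- regions(c1$cases[[1]]); r2 <- regions(c2$cases[[1]])
  expect_length(r2, length(r1))
  for (i in seq_along(r1)) {
    expect_identical(regionLabel(r1[[i]]), regionLabel(r2[[i]]))
    expect_identical(regionRings(r1[[i]]), regionRings(r2[[i]]))
  }
  expect_identical(c1$truth$lesions, c2$truth$lesions)
  c3 <- generateCohort(syntheticConfig(nSpecimens = 2, seed = 72))
  expect_false(identical(c1$truth$lesions, c3$truth$lesions))
})

test_that("the noiseless limit reproduces truth through the whole pipeline", {
  cohort <- generateCohort(noiselessConfig())
  for (case in cohort$cases) {
    for (key in c("any_pca", "cspca", "cg_idc")) {
      cc <- caseConcordance(case, key)
      if (!is.na(cc$weightedDSC))
        expect_equal(cc$weightedDSC, 1, tolerance = 1e-9)
    }
    # observer areas equal the latent truth areas
    truth <- cohort$truth$slideAreas
    for (key in c("any_pca", "cspca")) {
      cc <- caseConcordance(case, key)
      want <- truth[truth$specimenId == specimenId(case) &
                    truth$category == key, ]
      expect_equal(cc$sumX, sum(want$areaCm2), tolerance = 1e-9)
      expect_equal(cc$sumY, sum(want$areaCm2), tolerance = 1e-9)
    }
  }
  # kappa 1 wherever defined, index lesions identical
  t3 <- slideAgreementTable(cohort$cases, nBoot = 200, seed = 1)
  expect_true(all(t3$kappa == 1))
  for (case in cohort$cases) {
    p <- indexConcordance(case)
    if (!is.null(p)) {
      expect_equal(p$dsc, 1, tolerance = 1e-9)
      expect_true(p$ggAgreement)
    }
  }
})

test_that("label confusion alone degrades grading but not tumour localization", {
  cfg <- syntheticConfig(nSpecimens = 4, jitterSigmaMm = 0, splitMergeProb = 0,
                         seed = 73)  # default (non-identity) confusion
  cohort <- generateCohort(cfg)
  kappas <- numeric(0)
  for (case in cohort$cases) {
    cc <- caseConcordance(case, "any_pca")
    expect_equal(cc$weightedDSC, 1, tolerance = 1e-9)
  }
  t3 <- slideAgreementTable(cohort$cases, nBoot = 200, seed = 1)
  expect_true(all(t3$kappa[t3$category == "any_pca"] == 1))
  # confusion moves labels across bins/patterns: some category kappas drop
  expect_true(any(t3$kappa < 1))
})

test_that("boundary jitter degrades the expected DSC monotonically", {
  shape <- circleShape(5)
  means <- vapply(c(0.1, 0.5, 1.0, 2.0), function(sig) {
    set.seed(74)
    mean(vapply(1:80, function(b) {
      a <- histoConcord:::.shapeRing(shape, histoConcord:::.jitterRadii(shape$radii, sig))
      b2 <- histoConcord:::.shapeRing(shape, histoConcord:::.jitterRadii(shape$radii, sig))
      pa <- list(list(a)); pb <- list(list(b2))
      2 * polysIntersectionAreaCm2(pa, pb) /
        (unionAreaCm2(pa) + unionAreaCm2(pb))
    }, 0))
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("pipeline DSC under jitter matches the Monte-Carlo raster oracle", {
  shape <- circleShape(5)
  oracle <- expectedDscOracle(shape, sigmaMm = 0.5, nMc = 120, seed = 75,
                              cellMm = 0.1)
  set.seed(76)
  pipe <- vapply(1:120, function(b) {
    a <- histoConcord:::.shapeRing(shape, histoConcord:::.jitterRadii(shape$radii, 0.5))
    b2 <- histoConcord:::.shapeRing(shape, histoConcord:::.jitterRadii(shape$radii, 0.5))
    pa <- list(list(a)); pb <- list(list(b2))
    2 * polysIntersectionAreaCm2(pa, pb) /
      (unionAreaCm2(pa) + unionAreaCm2(pb))
  }, 0)
  sePipe <- stats::sd(pipe) / sqrt(length(pipe))
  tol <- 3 * sqrt(oracle$se^2 + sePipe^2)
  expect_lt(abs(mean(pipe) - oracle$meanDSC), max(tol, 5e-3))
  expect_identical(expectedDscOracle(shape, 0, nMc = 100)$meanDSC, 1)
})

test_that("oracle variance shrinks roughly as 1/n", {
  shape <- circleShape(5)
  o1 <- expectedDscOracle(shape, 1.0, nMc = 100, seed = 77, cellMm = 0.25)
  o2 <- expectedDscOracle(shape, 1.0, nMc = 400, seed = 77, cellMm = 0.25)
  expect_lt(o2$se, o1$se)
  expect_equal(o2$se / o1$se, 0.5, tolerance = 0.4)
})

test_that("infeasible and malformed configs are rejected", {
  expect_error(syntheticConfig(lesionRadiusRangeMm = c(5, 30)), "infeasible")
  bad <- identityConfusion(); bad[1, 1] <- 0.5
  expect_error(syntheticConfig(labelConfusion = bad), "sum to 1")
})

test_that("truth record areas are internally consistent", {
  cohort <- generateCohort(noiselessConfig(n = 2, seed = 78))
  sa <- cohort$truth$slideAreas
  # category containment: cspca never exceeds any_pca on a slide
  wide <- reshape(sa, idvar = c("specimenId", "slideIndex"),
                  timevar = "category", direction = "wide")
  expect_true(all(wide$areaCm2.cspca <= wide$areaCm2.any_pca + 1e-12))
})
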