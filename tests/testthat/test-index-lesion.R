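lesionCase <- function(p1, p2, slides = 4L, specimen = "S1") {
  caseFrom(p1, p2, specimen = specimen, slides = slides)
}

test_that("lesion assembly merges within-slide components and across adjacent slides", {
  sq <- function(x0, slide) list(ring = squareRing(x0, 0, 10), label = "GP3",
                                 slide = slide)
  other <- list(list(ring = squareRing(0, 30, 4), label = "GP3", slide = 1L))
  # single polygon -> single lesion
  case1 <- lesionCase(list(sq(0, 1)), other)
  expect_length(assembleLesions(case1, "P1"), 1)
  # overlapping footprints on consecutive slides merge
  case2 <- lesionCase(list(sq(0, 1), sq(5, 2)), other)
  l2 <- assembleLesions(case2, "P1")
  expect_length(l2, 1)
  expect_equal(l2[[1]]$slides, c(1L, 2L))
  expect_equal(l2[[1]]$totalAreaCm2, 2)
  expect_equal(l2[[1]]$volumeCm3, 2 * 4 / 10)
  # identical footprints with a slide gap stay separate
  case3 <- lesionCase(list(sq(0, 1), sq(0, 3)), other)
  expect_length(assembleLesions(case3, "P1"), 2)
  # abutting same-slide polygons merge into one in-slide component
  case4 <- lesionCase(list(sq(0, 1), sq(10.2, 1)), other)
  l4 <- assembleLesions(case4, "P1")
  expect_length(l4, 1)
  expect_equal(l4[[1]]$totalAreaCm2, 2, tolerance = 1e-9)
})

test_that("index selection applies the area floor, GG ranking and volume tie-break", {
  mkLesion <- function(areaCm2, gg) list(totalAreaCm2 = areaCm2,
                                         volumeCm3 = areaCm2 * 0.4, gg = gg)
  # a small GG5 focus loses to a large GG3 lesion because of the 0.5 cm^2 floor
  pick <- selectIndex(list(mkLesion(0.3, 5L), mkLesion(2.0, 3L)))
  expect_identical(pick$gg, 3L)
  expect_false(pick$belowAreaThreshold)
  # equal GG: highest volume wins
  pick2 <- selectIndex(list(mkLesion(1.0, 3L), mkLesion(2.0, 3L)))
  expect_equal(pick2$totalAreaCm2, 2.0)
  # permutation invariance
  set.seed(61)
  lesions <- list(mkLesion(0.7, 2L), mkLesion(1.4, 3L), mkLesion(0.9, 3L),
                  mkLesion(3.0, 1L))
  base <- selectIndex(lesions)
  for (i in 1:5) {
    perm <- selectIndex(sample(lesions))
    expect_equal(perm$totalAreaCm2, base$totalAreaCm2)
    expect_identical(perm$gg, base$gg)
  }
  # nothing reaches the floor: fall back with a flag
  pick3 <- selectIndex(list(mkLesion(0.2, 2L), mkLesion(0.3, 1L)))
  expect_true(pick3$belowAreaThreshold)
  expect_identical(pick3$gg, 2L)
  expect_error(selectIndex(list()))
})

test_that("representation does not matter: re-cut polygons with the same union", {
  other <- list(list(ring = squareRing(0, 30, 4), label = "GP4", slide = 1L))
  whole <- lesionCase(list(list(ring = squareRing(0, 0, 10), label = "GP4",
                                slide = 1L)), other)
  halves <- lesionCase(list(
    list(ring = squareRing(0, 0, 5), label = "GP4", slide = 1L),
    list(ring = cbind(c(0, 10, 10, 0), c(5, 5, 10, 10)), label = "GP4", slide = 1L),
    list(ring = cbind(c(5, 10, 10, 5), c(0, 0, 5, 5)), label = "GP4", slide = 1L)),
    other)
  lw <- assembleLesions(whole, "P1")
  lh <- assembleLesions(halves, "P1")
  expect_length(lh, 1)
  expect_equal(lh[[1]]$totalAreaCm2, lw[[1]]$totalAreaCm2, tolerance = 1e-9)
  expect_identical(lh[[1]]$gg, lw[[1]]$gg)
})

test_that("index concordance pairs lesions and scores localization plus grading", {
  # identical index lesions: dsc 1, agreement true
  p <- list(list(ring = squareRing(0, 0, 10), label = "GP4", slide = 1L))
  case <- lesionCase(p, p)
  res <- indexConcordance(case)
  expect_equal(res$dsc, 1)
  expect_true(res$ggAgreement)
  # same footprint, different grading: agreement false
  p2 <- list(list(ring = squareRing(0, 0, 10), label = "GS4+3_50-80", slide = 1L))
  res2 <- indexConcordance(lesionCase(p, p2))
  expect_equal(res2$dsc, 1)
  expect_identical(c(res2$ggP1, res2$ggP2), c(4L, 3L))
  expect_false(res2$ggAgreement)
  # a rater with no tumour regions: unmatched
  benign <- list(list(ring = squareRing(0, 0, 5), label = "PROSTATITIS", slide = 1L))
  expect_null(indexConcordance(lesionCase(p, benign)))
})

test_that("cohort summary pools, averages and counts grade agreement", {
  tab <- data.frame(areaP1 = c(1, 1), areaP2 = c(1, 1),
                    dsc = c(1, 0.5), ggP1 = c(2L, 3L), ggP2 = c(2L, 4L))
  s <- cohortIndexSummary(tab)
  expect_equal(s$pooledWeightedDSC, 0.75)
  expect_equal(s$meanDSC, 0.75)
  expect_equal(s$ggAgreementFraction, 0.5)
  one <- cohortIndexSummary(data.frame(areaP1 = 2, areaP2 = 2.2, dsc = 0.9,
                                       ggP1 = 3L, ggP2 = 3L))
  expect_equal(one$pooledWeightedDSC, 0.9)
  expect_equal(one$meanDSC, 0.9)
  expect_equal(one$ggAgreementFraction, 1)
})

test_that("selection recovers planted ground-truth index lesions", {
  set.seed(62)
  other <- list(list(ring = squareRing(40, 40, 3), label = "GP3", slide = 1L))
  for (i in 1:10) {
    # planted: a big GG3 lesion and a smaller-but-eligible GG4 lesion
    bigSide <- runif(1, 12, 16); smallSide <- runif(1, 8, 10)
    p1 <- list(
      list(ring = squareRing(0, 0, bigSide), label = "GS4+3_50-80", slide = 1L),
      list(ring = squareRing(25, 0, smallSide), label = "GP4", slide = 1L))
    case <- lesionCase(p1, other, specimen = sprintf("T%d", i))
    idx <- selectIndex(assembleLesions(case, "P1"))
    # both exceed 0.5 cm^2; GG4 must win regardless of its smaller area
    expect_identical(idx$gg, 4L)
    expect_equal(idx$totalAreaCm2, (smallSide / 10)^2, tolerance = 1e-9)
  }
})
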