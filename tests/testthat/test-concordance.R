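makeOverlap <- function(x, y, inter, slide = 1L) {
  data.frame(slideIndex = slide, xAreaCm2 = x, yAreaCm2 = y,
             intersectionCm2 = inter,
             dsc = if (x + y > 0) 2 * inter / (x + y) else NA_real_)
}

test_that("per-slide DSC covers perfect, absent and partial overlap", {
  sq <- squareRing(0, 0, 10)
  mk <- function(ring, rater) makeRegionSet(
    list(regionFrom(ring, paste0("r", rater), rater = rater)), "any_pca")
  same <- slideDSC(mk(sq, "P1"), mk(sq, "P2"))
  expect_equal(same$dsc, 1)
  far <- slideDSC(mk(sq, "P1"), mk(squareRing(50, 0, 10), "P2"))
  expect_equal(far$dsc, 0)
  half <- slideDSC(mk(sq, "P1"), mk(squareRing(5, 0, 10), "P2"))
  expect_equal(half$dsc, 0.5)
  # neither rater annotated: undefined, never zero
  none <- slideDSC(makeRegionSet(list(), "any_pca", "S", 1L, "P1"),
                   makeRegionSet(list(), "any_pca", "S", 1L, "P2"))
  expect_true(is.na(none$dsc))
})

test_that("specimen weighting sums to one and reproduces the pooled form", {
  ov <- rbind(makeOverlap(1, 1, 1, 1L), makeOverlap(1, 1, 0, 2L))
  res <- rpsWeightedDSC(ov)
  expect_equal(sum(res$perSlide$weight), 1)
  expect_equal(res$weightedDSC, 0.5)
  one <- rpsWeightedDSC(makeOverlap(2, 2, 2))
  expect_equal(one$weightedDSC, 1)
})

test_that("weighted DSC equals 2*sum(inter)/(sum x + sum y) on random specimens", {
  set.seed(41)
  for (i in 1:120) {
    n <- sample(2:10, 1)
    x <- round(runif(n, 0, 5), 3)
    y <- round(runif(n, 0, 5), 3)
    # allow empty-by-both and one-sided slides
    x[runif(n) < 0.2] <- 0
    y[runif(n) < 0.2] <- 0
    inter <- runif(n) * pmin(x, y)
    ov <- do.call(rbind, lapply(seq_len(n), function(k)
      makeOverlap(x[k], y[k], inter[k], k)))
    res <- rpsWeightedDSC(ov)
    if (sum(x) + sum(y) > 0) {
      expect_equal(res$weightedDSC, 2 * sum(inter) / (sum(x) + sum(y)),
                   tolerance = 1e-12)
      expect_true(res$weightedDSC >= 0 && res$weightedDSC <= 1)
    } else expect_true(is.na(res$weightedDSC))
  }
})

test_that("weighted DSC is monotone in any slide's intersection and scale invariant", {
  set.seed(42)
  x <- runif(5, 1, 3); y <- runif(5, 1, 3)
  inter <- runif(5) * pmin(x, y)
  mk <- function(iv, scale = 1) do.call(rbind, lapply(1:5, function(k)
    makeOverlap(scale * x[k], scale * y[k], scale * iv[k], k)))
  base <- rpsWeightedDSC(mk(inter))$weightedDSC
  bumped <- inter; bumped[3] <- min(x[3], y[3])
  expect_gte(rpsWeightedDSC(mk(bumped))$weightedDSC, base)
  expect_equal(rpsWeightedDSC(mk(inter, scale = 7.3))$weightedDSC, base,
               tolerance = 1e-12)
})

test_that("empty-vs-empty slides carry no weight instead of counting as agreement", {
  ov <- rbind(makeOverlap(1, 1, 0.5, 1L), makeOverlap(0, 0, 0, 2L))
  res <- rpsWeightedDSC(ov)
  expect_equal(res$perSlide$weight[2], 0)
  expect_equal(res$weightedDSC, 0.5)
  # one-sided slide: DSC 0 with positive weight
  ov2 <- rbind(makeOverlap(1, 1, 1, 1L), makeOverlap(1, 0, 0, 2L))
  res2 <- rpsWeightedDSC(ov2)
  expect_gt(res2$perSlide$weight[2], 0)
  expect_equal(res2$weightedDSC, 2 / 3)
})

test_that("cross-specimen pooling weights by combined annotated area", {
  expect_equal(pooledWeightedDSC(0.8, 3), 0.8)
  expect_equal(pooledWeightedDSC(c(1, 0), c(1, 1)), 0.5)
  expect_true(is.na(pooledWeightedDSC(c(NA_real_, NA_real_), c(1, 1))))
  # identity: pooling per-specimen pooled values equals pooling all slides
  set.seed(43)
  sx <- list(); agg <- c(); tot <- c(); allI <- 0; allXY <- 0
  for (p in 1:6) {
    n <- sample(3:8, 1)
    x <- runif(n, 0, 4); y <- runif(n, 0, 4); i <- runif(n) * pmin(x, y)
    ov <- do.call(rbind, lapply(seq_len(n), function(k) makeOverlap(x[k], y[k], i[k], k)))
    r <- rpsWeightedDSC(ov)
    agg <- c(agg, r$weightedDSC); tot <- c(tot, r$sumX + r$sumY)
    allI <- allI + sum(i); allXY <- allXY + sum(x) + sum(y)
  }
  expect_equal(pooledWeightedDSC(agg, tot), 2 * allI / allXY, tolerance = 1e-12)
})

test_that("caseConcordance runs the full geometry path for one specimen", {
  # two slides; rater 2 shifts the square by 5 mm on slide 2
  p1 <- list(list(ring = squareRing(0, 0, 10), label = "GP3", slide = 1L),
             list(ring = squareRing(0, 0, 10), label = "GP3", slide = 2L))
  p2 <- list(list(ring = squareRing(0, 0, 10), label = "GP3", slide = 1L),
             list(ring = squareRing(5, 0, 10), label = "GP3", slide = 2L))
  case <- caseFrom(p1, p2, slides = 2L)
  res <- caseConcordance(case, "any_pca")
  # slide 1 dsc 1 (weight 1/2), slide 2 dsc 0.5 (weight 1/2)
  expect_equal(res$weightedDSC, 0.75)
  expect_equal(res$zCm2, 2)
  # no cribriform annotated anywhere: undefined
  expect_true(is.na(caseConcordance(case, "cg_idc")$weightedDSC))
})
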