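test_that("label parsing is total over the taxonomy and rejects bad input", {
  for (lab in knownLabels()) {
    p <- parseRegionLabel(lab)
    expect_identical(p$label, lab)
    if (p$category == "gleason" && p$kind == "mixed") {
      expect_true(p$primary != p$secondary)
      hiIsPrimary <- p$primary > p$secondary
      if (hiIsPrimary) expect_true(p$bin %in% c("50-80", ">80"))
      else expect_true(p$bin %in% c("<20", "20-50"))
    }
  }
  expect_error(parseRegionLabel("GP6"), "unknown")
  expect_error(parseRegionLabel("GS3+3<20"), "equal patterns")
  expect_error(parseRegionLabel("GS3+4_50-80"), "invalid")
  expect_error(parseRegionLabel("GS4+3<20"), "invalid")
})

test_that("pattern fractions sum to one for Gleason labels and split by bin", {
  for (lab in knownLabels()) {
    f <- patternFractions(lab)
    cat <- parseRegionLabel(lab)$category
    expect_equal(sum(f), if (cat == "gleason") 1 else 0)
  }
  expect_equal(patternFractions("GS3+4<20"), c("3" = 0.9, "4" = 0.1, "5" = 0))
  expect_equal(patternFractions("GS4+3_50-80"), c("3" = 0.35, "4" = 0.65, "5" = 0))
  expect_equal(patternFractions("GP5"), c("3" = 0, "4" = 0, "5" = 1))
})

test_that("Grade Group translation is total and monotone in the secondary pattern", {
  expect_identical(translateToGG(3, 3), 1L)
  expect_identical(translateToGG(3, 4), 2L)
  expect_identical(translateToGG(4, 3), 3L)
  expect_identical(translateToGG(4, 4), 4L)
  expect_identical(translateToGG(3, 5), 4L)
  expect_identical(translateToGG(5, 3), 4L)
  expect_identical(translateToGG(4, 5), 5L)
  expect_identical(translateToGG(5, 4), 5L)
  expect_identical(translateToGG(5, 5), 5L)
  for (p in 3:5) for (s in 3:4)
    expect_lte(translateToGG(p, s), translateToGG(p, s + 1L))
})

test_that("category selection implements the tumour-category definitions", {
  sq <- squareRing(0, 0, 10)
  gp3 <- regionFrom(sq, "a", label = "GP3")
  mixed <- regionFrom(sq, "b", label = "GS3+4<20")
  cg <- regionFrom(sq, "c", label = "CGIDC")
  regs <- list(gp3, mixed, cg)
  expect_length(regionsForCategory(regs, "any_pca"), 2)
  expect_length(regionsForCategory(regs, "cspca"), 1)   # mixed only
  expect_length(regionsForCategory(regs, "gp3"), 2)     # pure 3 + mixed 3+4
  expect_length(regionsForCategory(regs, "gp4"), 1)     # mixed 3+4
  expect_length(regionsForCategory(regs, "gp5"), 0)
  expect_length(regionsForCategory(regs, "cg_idc"), 1)
  # a pure GP3 slide has tumour but no clinically significant tumour
  expect_length(regionsForCategory(list(gp3), "cspca"), 0)
})

test_that("mixed-score area plus small pure area reproduces the worked slide", {
  # one observer: 0.26 cm^2 of GS 3+4 (<20% GP4) plus 0.04 cm^2 of GP3
  mixed <- regionFrom(cbind(c(0, 6.5, 6.5, 0), c(0, 0, 4, 4)), "m",
                      label = "GS3+4<20")      # 26 mm^2
  pure3 <- regionFrom(cbind(c(10, 12, 12, 10), c(0, 0, 2, 2)), "p",
                      label = "GP3")           # 4 mm^2
  regs <- list(mixed, pure3)
  anyA <- makeRegionSet(regionsForCategory(regs, "any_pca"), "any_pca")
  csA <- makeRegionSet(regionsForCategory(regs, "cspca"), "cspca")
  expect_equal(areaCm2(anyA), 0.30)
  expect_equal(areaCm2(csA), 0.26)
})

test_that("composition picks primary by area and applies the 5% highest-pattern override", {
  c1 <- compositionFromAreas(c("3" = 2, "4" = 1))
  expect_identical(c(c1$primary, c1$secondary), c(3L, 4L))
  c2 <- compositionFromAreas(c("3" = 2, "4" = 1, "5" = 0.05))  # 5-share 1.6%
  expect_identical(c(c2$primary, c2$secondary), c(3L, 4L))
  expect_true(c2$minorPattern5)
  c3 <- compositionFromAreas(c("3" = 2, "4" = 0.5, "5" = 0.2))  # 5-share 7.4%
  expect_identical(c(c3$primary, c3$secondary), c(3L, 5L))
  expect_false(c3$minorPattern5)
  # single pattern: secondary equals primary
  c4 <- compositionFromAreas(c("4" = 1))
  expect_identical(c(c4$primary, c4$secondary, c4$gg), c(4L, 4L, 4L))
  # ties broken toward the higher pattern
  c5 <- compositionFromAreas(c("3" = 1, "4" = 1))
  expect_identical(c5$primary, 4L)
  expect_error(compositionFromAreas(c("3" = 0)), "positive")
})

test_that("the 5% override rule matches a brute-force evaluation over share grids", {
  # independent oracle: direct restatement of the rule evaluated pointwise
  oracleSecondary <- function(a) {
    pats <- c(3L, 4L, 5L)
    shares <- a / sum(a)
    primary <- pats[max(which(a == max(a)))]
    hi <- max(pats[a > 0])
    if (hi > primary && shares[as.character(hi)] >= 0.05) return(hi)
    # second-largest among patterns that qualify: lower-grade always, a
    # higher-grade pattern only with a >= 5% share
    qual <- pats != primary & a > 0 & (pats < primary | shares >= 0.05)
    if (!any(qual)) return(primary)
    cand <- pats[qual]
    cand[order(-a[qual], -cand)][1]
  }
  for (s5 in seq(0, 0.30, by = 0.01)) for (s4 in seq(0, 0.5, by = 0.05)) {
    a <- c("3" = 1, "4" = s4, "5" = s5)
    comp <- compositionFromAreas(a)
    expect_identical(comp$secondary, oracleSecondary(a))
  }
})

test_that("composition is scale invariant", {
  set.seed(31)
  for (i in 1:25) {
    a <- c("3" = runif(1), "4" = runif(1), "5" = runif(1) * 0.2)
    c1 <- compositionFromAreas(a)
    c2 <- compositionFromAreas(a * runif(1, 0.01, 100))
    expect_identical(c1[c("primary", "secondary", "gg", "minorPattern5")],
                     c2[c("primary", "secondary", "gg", "minorPattern5")])
  }
})

test_that("lesion-style translation reproduces the worked discordance example", {
  # observer A: a GS 4+3 (50-80% GP4) area plus a GP4 cribriform area -> GG 3
  mixed <- regionFrom(squareRing(0, 0, 10), "m", label = "GS4+3_50-80")
  gp4 <- regionFrom(squareRing(10, 0, 5), "g", label = "GP4")
  cg <- regionFrom(squareRing(10, 0, 5), "c", label = "CGIDC")
  compA <- compositionFromRegions(list(mixed, gp4, cg))
  expect_identical(compA$gg, 3L)
  # observer B: the entire area annotated GP4 -> GG 4
  compB <- compositionFromRegions(list(regionFrom(squareRing(0, 0, 12), "b",
                                                  label = "GP4")))
  expect_identical(compB$gg, 4L)
})
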