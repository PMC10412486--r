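## Synthetic paired-observer annotation cohorts.
##
## Ground-truth lesions are star-shaped polygons (radial Fourier
## perturbations of ellipses) spanning contiguous slides. Each observer sees
## the truth through two independent noise channels:
##   geometry — radial Gaussian jitter of the boundary control points,
##              smoothed along the boundary (sigma in mm);
##   labels   — a stochastic confusion matrix over the label taxonomy.
## A "style-difference" mode additionally lets one observer redraw a mixed
## Gleason-score region as two pure-pattern halves covering the same
## footprint, reproducing the documented phenomenon of low DSC without
## substantive disagreement. All randomness flows from a single seed.

.N_BOUNDARY <- 48L

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' 2 observers, 10 specimens, 6--9 whole-mount slides each (74 slides per
#' ten specimens on average), 4 mm slices, 1--3 tumour foci per specimen,
#' boundary jitter of 0.5 mm (the annotation protocol's stated precision
#' floor) and mild label confusion concentrated where observers genuinely
#' disagree (mixed-score bins, cribriform growth).
#'
#' @param nSpecimens Number of specimens.
#' @param slidesRange Integer range (min, max) of slides per specimen.
#' @param lesionsRange Integer range of tumour foci per specimen.
#' @param sliceThicknessMm Sectioning thickness in mm.
#' @param slideSizeMm Slide frame (width, height) in mm.
#' @param lesionRadiusRangeMm Base lesion radius range in mm.
#' @param jitterSigmaMm Radial boundary jitter s.d. in mm (0 = perfect
#'   boundary agreement).
#' @param splitMergeProb Probability that an observer redraws a mixed-score
#'   region as two pure-pattern halves over the same footprint.
#' @param labelConfusion Row-stochastic matrix over [knownLabels()];
#'   `identityConfusion()` gives perfect label agreement.
#' @param gleasonLabelProbs Named sampling probabilities for truth lesion
#'   labels (Gleason labels only).
#' @param cgidcProb Probability that a lesion carries a cribriform/IDC
#'   sub-region.
#' @param prostatitisProb,hgpinProb Per-specimen probabilities of a benign
#'   mimic region.
#' @param seed Integer RNG seed.
#' @return A validated config list of class `"syntheticConfig"`.
#' @export
syntheticConfig <- function(nSpecimens = 10L,
                            slidesRange = c(6L, 9L),
                            lesionsRange = c(1L, 3L),
                            sliceThicknessMm = 4,
                            slideSizeMm = c(50, 40),
                            lesionRadiusRangeMm = c(2.5, 8),
                            jitterSigmaMm = 0.5,
                            splitMergeProb = 0.1,
                            labelConfusion = defaultConfusion(),
                            gleasonLabelProbs = c(
                              "GP3" = 0.30, "GP4" = 0.25, "GP5" = 0.05,
                              "GS3+4<20" = 0.12, "GS3+4_20-50" = 0.10,
                              "GS4+3_50-80" = 0.13, "GS4+3>80" = 0.05),
                            cgidcProb = 0.3,
                            prostatitisProb = 0.3,
                            hgpinProb = 0.2,
                            seed = 1L) {
  cfg <- list(nSpecimens = as.integer(nSpecimens),
              slidesRange = as.integer(slidesRange),
              lesionsRange = as.integer(lesionsRange),
              sliceThicknessMm = sliceThicknessMm,
              slideSizeMm = slideSizeMm,
              lesionRadiusRangeMm = lesionRadiusRangeMm,
              jitterSigmaMm = jitterSigmaMm,
              splitMergeProb = splitMergeProb,
              labelConfusion = labelConfusion,
              gleasonLabelProbs = gleasonLabelProbs,
              cgidcProb = cgidcProb, prostatitisProb = prostatitisProb,
              hgpinProb = hgpinProb, seed = as.integer(seed))
  stopifnot(cfg$nSpecimens >= 1L, cfg$jitterSigmaMm >= 0,
            cfg$splitMergeProb >= 0, cfg$splitMergeProb <= 1,
            all(cfg$gleasonLabelProbs >= 0))
  lc <- cfg$labelConfusion
  if (!is.matrix(lc) || !identical(rownames(lc), knownLabels()) ||
      !identical(colnames(lc), knownLabels()))
    stop("labelConfusion must be a matrix with knownLabels() rows and columns")
  if (any(lc < 0) || any(abs(rowSums(lc) - 1) > 1e-12))
    stop("labelConfusion rows must be non-negative and sum to 1")
  if (max(cfg$lesionRadiusRangeMm) * 2.2 > min(cfg$slideSizeMm))
    stop("infeasible config: lesions larger than the slide frame")
  class(cfg) <- "syntheticConfig"
  cfg
}

#' Identity label-confusion matrix (perfect label agreement)
#' @return Identity matrix over [knownLabels()].
#' @export
identityConfusion <- function() {
  labs <- knownLabels()
  m <- diag(length(labs))
  dimnames(m) <- list(labs, labs)
  m
}

#' Default label-confusion matrix
#'
#' Mild, asymmetric confusion concentrated where observers plausibly
#' disagree: neighbouring mixed-score bins, pure vs mixed labels sharing a
#' pattern, and cribriform/IDC against plain pattern 4.
#'
#' @return Row-stochastic matrix over [knownLabels()].
#' @export
defaultConfusion <- function() {
  m <- identityConfusion()
  bump <- function(from, to, p) {
    m[from, to] <<- m[from, to] + p
    m[from, from] <<- m[from, from] - p
  }
  bump("GP3", "GS3+4<20", 0.05)
  bump("GP4", "GS4+3_50-80", 0.06)
  bump("GP4", "GS4+3>80", 0.04)
  bump("GS3+4<20", "GS3+4_20-50", 0.08)
  bump("GS3+4_20-50", "GS3+4<20", 0.08)
  bump("GS4+3_50-80", "GS4+3>80", 0.06)
  bump("GS4+3>80", "GP4", 0.06)
  bump("CGIDC", "GP4", 0.10)
  m
}

## ---- truth geometry --------------------------------------------------------

.starRadii <- function(baseR, nPts = .N_BOUNDARY) {
  theta <- seq(0, 2 * pi, length.out = nPts + 1L)[-(nPts + 1L)]
  r <- rep(baseR, nPts)
  for (k in 2:5) {
    amp <- stats::rnorm(1, 0, 0.06 * baseR / (k - 1))
    phase <- stats::runif(1, 0, 2 * pi)
    r <- r + amp * cos(k * theta + phase)
  }
  pmax(r, 0.25 * baseR)
}

.shapeRing <- function(shape, radii = shape$radii) {
  theta <- seq(0, 2 * pi, length.out = length(radii) + 1L)[-(length(radii) + 1L)]
  x <- radii * cos(theta)
  y <- shape$aspect * radii * sin(theta)
  rot <- shape$rot
  cbind(shape$center[1] + x * cos(rot) - y * sin(rot),
        shape$center[2] + x * sin(rot) + y * cos(rot))
}

.circularSmooth <- function(v, window = 5L) {
  n <- length(v)
  k <- (window - 1L) %/% 2L
  idx <- outer(seq_len(n), -k:k, function(i, d) ((i + d - 1L) %% n) + 1L)
  rowMeans(matrix(v[idx], nrow = n))
}

.jitterRadii <- function(radii, sigmaMm) {
  if (sigmaMm == 0) return(radii)
  # pre-scale so the smoothed noise has marginal s.d. sigmaMm
  noise <- stats::rnorm(length(radii), 0, sigmaMm * sqrt(5))
  pmax(radii + .circularSmooth(noise, 5L), 0.2)
}

.clipHalfplane <- function(ring, x0, keepLeft) {
  inside <- if (keepLeft) ring[, 1] <= x0 else ring[, 1] >= x0
  n <- nrow(ring)
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p <- ring[i, ]; q <- ring[j, ]
    if (inside[i]) out <- rbind(out, p)
    if (inside[i] != inside[j]) {
      t <- (x0 - p[1]) / (q[1] - p[1])
      out <- rbind(out, p + t * (q - p))
    }
  }
  out
}

## ---- cohort generation -----------------------------------------------------

#' Generate a synthetic paired-observer annotation cohort
#'
#' Draws ground-truth lesions, benign mimics and secondary cribriform/IDC
#' layers, then derives each observer's annotations through boundary jitter,
#' label confusion and the optional style-difference redraw. Fully
#' deterministic given the config seed.
#'
#' @param config A [syntheticConfig()].
#' @return List with `cases` (named list of [RPSCase-class]) and `truth`, a
#'   list with `lesions` (data.frame: specimen, lesion id, label, slides
#'   spanned, total truth area, Grade Group) and `slideAreas` (data.frame of
#'   latent per-slide per-category truth areas before observer noise).
#' @examples
#' cohort <- generateCohort(syntheticConfig(nSpecimens = 2, seed = 7))
#' names(cohort$cases)
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(config$seed)
  labs <- knownLabels()
  gleasonProbs <- config$gleasonLabelProbs / sum(config$gleasonLabelProbs)
  W <- config$slideSizeMm[1]; H <- config$slideSizeMm[2]
  cases <- list()
  truthLesions <- list()
  truthAreas <- list()

  for (sp in seq_len(config$nSpecimens)) {
    specId <- sprintf("SYN%02d", sp)
    nSlides <- if (config$slidesRange[1] == config$slidesRange[2])
      config$slidesRange[1] else
      sample(config$slidesRange[1]:config$slidesRange[2], 1L)
    nLes <- if (config$lesionsRange[1] == config$lesionsRange[2])
      config$lesionsRange[1] else
      sample(config$lesionsRange[1]:config$lesionsRange[2], 1L)

    ## --- truth regions: list of (slide, label, layer, shape) -------------
    truthRegions <- list()
    centers <- matrix(numeric(0), ncol = 2)
    radiiUsed <- numeric(0)
    for (le in seq_len(nLes)) {
      baseR <- stats::runif(1, config$lesionRadiusRangeMm[1],
                            config$lesionRadiusRangeMm[2])
      # rejection placement: keep foci separated so truth lesions are distinct
      for (try in 1:25) {
        ctr <- c(stats::runif(1, baseR + 2, W - baseR - 2),
                 stats::runif(1, baseR + 2, H - baseR - 2))
        if (!nrow(centers)) break
        d <- sqrt(colSums((t(centers) - ctr)^2))
        if (all(d > radiiUsed + baseR + 3)) break
      }
      centers <- rbind(centers, ctr); radiiUsed <- c(radiiUsed, baseR)
      label <- sample(names(gleasonProbs), 1L, prob = gleasonProbs)
      nSpan <- sample(1:min(3L, nSlides), 1L)
      start <- sample(seq_len(nSlides - nSpan + 1L), 1L)
      scales <- switch(nSpan, `1` = 1, `2` = c(1, 0.7), `3` = c(0.7, 1, 0.7))
      radii <- .starRadii(baseR)
      aspect <- stats::runif(1, 0.6, 1)
      rot <- stats::runif(1, 0, pi)
      lesionSlides <- start:(start + nSpan - 1L)
      for (k in seq_along(lesionSlides)) {
        shape <- list(center = ctr, radii = radii * scales[k],
                      aspect = aspect, rot = rot)
        truthRegions[[length(truthRegions) + 1L]] <- list(
          slide = lesionSlides[k], label = label, lesion = le,
          layer = "gleason", shape = shape)
      }
      if (stats::runif(1) < config$cgidcProb &&
          label %in% c("GP4", "GP5", "GS4+3_50-80", "GS4+3>80")) {
        s <- lesionSlides[sample.int(length(lesionSlides), 1L)]
        k <- match(s, lesionSlides)
        shape <- list(center = ctr, radii = radii * scales[k] * 0.45,
                      aspect = aspect, rot = rot)
        truthRegions[[length(truthRegions) + 1L]] <- list(
          slide = s, label = "CGIDC", lesion = le, layer = "cg_idc",
          shape = shape)
      }
      truthLesions[[length(truthLesions) + 1L]] <- data.frame(
        specimenId = specId, lesion = le, label = label,
        firstSlide = start, lastSlide = start + nSpan - 1L,
        totalAreaCm2 = sum(vapply(lesionSlides, function(s) {
          k <- match(s, lesionSlides)
          ringsAreaCm2(list(.shapeRing(list(center = ctr,
                                            radii = radii * scales[k],
                                            aspect = aspect, rot = rot))))
        }, 0)),
        gg = compositionFromAreas(patternFractions(label))$gg,
        stringsAsFactors = FALSE)
    }
    for (benign in c("PROSTATITIS", "HGPIN")) {
      p <- if (benign == "PROSTATITIS") config$prostatitisProb else
        config$hgpinProb
      if (stats::runif(1) < p) {
        baseR <- stats::runif(1, 1.5, 4)
        ctr <- c(stats::runif(1, baseR + 1, W - baseR - 1),
                 stats::runif(1, baseR + 1, H - baseR - 1))
        shape <- list(center = ctr, radii = .starRadii(baseR),
                      aspect = stats::runif(1, 0.6, 1),
                      rot = stats::runif(1, 0, pi))
        truthRegions[[length(truthRegions) + 1L]] <- list(
          slide = sample(seq_len(nSlides), 1L), label = benign, lesion = NA,
          layer = tolower(benign), shape = shape)
      }
    }

    ## --- latent per-slide category areas ---------------------------------
    for (s in seq_len(nSlides)) {
      onSlide <- Filter(function(tr) tr$slide == s, truthRegions)
      for (key in categoryKeys()) {
        polys <- lapply(Filter(function(tr) .labelInCategory(tr$label, key),
                               onSlide),
                        function(tr) list(.shapeRing(tr$shape)))
        truthAreas[[length(truthAreas) + 1L]] <- data.frame(
          specimenId = specId, slideIndex = s, category = key,
          areaCm2 = unionAreaCm2(polys), stringsAsFactors = FALSE)
      }
    }

    ## --- observer annotations --------------------------------------------
    regionsOut <- list()
    for (rater in c("P1", "P2")) {
      for (ti in seq_along(truthRegions)) {
        tr <- truthRegions[[ti]]
        seen <- sample(labs, 1L, prob = config$labelConfusion[tr$label, ])
        radii <- .jitterRadii(tr$shape$radii, config$jitterSigmaMm)
        ring <- .shapeRing(tr$shape, radii)
        rid <- sprintf("%s_t%02d_%s", specId, ti, rater)
        seenParsed <- parseRegionLabel(seen)
        doSplit <- seenParsed$category == "gleason" &&
          seenParsed$kind == "mixed" &&
          stats::runif(1) < config$splitMergeProb
        if (doSplit) {
          x0 <- mean(range(ring[, 1]))
          halves <- list(.clipHalfplane(ring, x0, TRUE),
                         .clipHalfplane(ring, x0, FALSE))
          hlabs <- c(sprintf("GP%d", seenParsed$primary),
                     sprintf("GP%d", seenParsed$secondary))
          for (h in 1:2)
            if (nrow(halves[[h]]) >= 3L &&
                ringsAreaCm2(list(halves[[h]])) > 1e-4)
              regionsOut[[length(regionsOut) + 1L]] <- AnnotationRegion(
                paste0(rid, c("a", "b")[h]), specId, tr$slide, rater,
                hlabs[h], list(halves[[h]]))
        } else {
          regionsOut[[length(regionsOut) + 1L]] <- AnnotationRegion(
            rid, specId, tr$slide, rater, seen, list(ring))
        }
      }
    }
    cases[[specId]] <- RPSCase(specId, nSlides, regionsOut,
                               sliceThicknessMm = config$sliceThicknessMm)
  }
  list(cases = cases,
       truth = list(lesions = do.call(rbind, truthLesions),
                    slideAreas = do.call(rbind, truthAreas),
                    config = config))
}

.labelInCategory <- function(label, key) {
  p <- parseRegionLabel(label)
  switch(key,
    any_pca = p$category == "gleason",
    cspca = p$category == "gleason" && max(p$primary, p$secondary) >= 4L,
    gp3 = p$category == "gleason" && 3L %in% c(p$primary, p$secondary),
    gp4 = p$category == "gleason" && 4L %in% c(p$primary, p$secondary),
    gp5 = p$category == "gleason" && 5L %in% c(p$primary, p$secondary),
    p$category == key)
}

#' Monte-Carlo oracle for the expected DSC under boundary jitter
#'
#' Brute-force estimate of the expected Dice overlap of two independently
#' jittered copies of one truth shape, with each pair's overlap measured by
#' grid rasterization — a route fully independent of the exact sweep
#' engine.
#'
#' @param shape A shape list (`center`, `radii`, `aspect`, `rot`) as built
#'   internally by the generator; use [circleShape()] for a simple one.
#' @param sigmaMm Radial jitter s.d. in mm.
#' @param nMc Number of Monte-Carlo pairs (>= 100).
#' @param seed RNG seed.
#' @param cellMm Rasterization cell size in mm.
#' @return List: `meanDSC`, `se` (standard error), `nMc`.
#' @export
expectedDscOracle <- function(shape, sigmaMm, nMc = 200L, seed = 1L,
                              cellMm = 0.2) {
  stopifnot(nMc >= 100L)
  set.seed(seed)
  if (sigmaMm == 0) return(list(meanDSC = 1, se = 0, nMc = nMc))
  pad <- 6 * sigmaMm
  allR <- max(shape$radii) + pad
  xr <- shape$center[1] + c(-allR, allR)
  yr <- shape$center[2] + c(-allR, allR)
  gx <- seq(xr[1] + cellMm / 2, xr[2], by = cellMm)
  gy <- seq(yr[1] + cellMm / 2, yr[2], by = cellMm)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  dscs <- vapply(seq_len(nMc), function(b) {
    rA <- .shapeRing(shape, .jitterRadii(shape$radii, sigmaMm))
    rB <- .shapeRing(shape, .jitterRadii(shape$radii, sigmaMm))
    inA <- .pointsInPolys(px, py, list(list(rA)))
    inB <- .pointsInPolys(px, py, list(list(rB)))
    2 * sum(inA & inB) / (sum(inA) + sum(inB))
  }, 0)
  list(meanDSC = mean(dscs), se = stats::sd(dscs) / sqrt(nMc), nMc = nMc)
}

#' A circular truth shape for oracle experiments
#'
#' @param radiusMm Circle radius in mm.
#' @param center Centre coordinates in mm.
#' @param nPts Number of boundary control points.
#' @return A shape list usable with [expectedDscOracle()].
#' @export
circleShape <- function(radiusMm = 5, center = c(0, 0), nPts = .N_BOUNDARY) {
  list(center = center, radii = rep(radiusMm, nPts), aspect = 1, rot = 0)
}
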