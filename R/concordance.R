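## Surface-overlap concordance: per-slide Dice similarity coefficient (DSC),
## area-weighted DSC per specimen, and pooled weighted DSC across specimens.
##
## DSC = 2 |X ^ Y| / (|X| + |Y|) for the two observers' surfaces X, Y on one
## slide. The per-slide weight is (X + Y) / (2 Z), with Z the mean surface
## area annotated by the two observers over all slides of the specimen, so
## the per-specimen weighted DSC (the sum of weighted per-slide terms) is
## algebraically the pooled form 2 * sum(^) / (sum X + sum Y). Slides where
## neither observer annotated the category carry weight 0: they are not
## scored as agreement.

#' Per-slide Dice overlap of two observers' surfaces
#'
#' @param x,y [RegionSet-class] objects for the same slide and category from
#'   the two observers.
#' @return A one-row data.frame: `slideIndex`, `xAreaCm2`, `yAreaCm2`,
#'   `intersectionCm2`, `dsc`. The DSC is `NA` (undefined, never 0) when
#'   neither observer annotated the category.
#' @examples
#' sq <- list(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' r1 <- AnnotationRegion("a", "s", 1L, "P1", "GP3", sq)
#' r2 <- AnnotationRegion("b", "s", 1L, "P2", "GP3", sq)
#' slideDSC(makeRegionSet(list(r1), "any_pca"),
#'          makeRegionSet(list(r2), "any_pca"))
#' @export
slideDSC <- function(x, y) {
  inter <- intersectionAreaCm2(x, y)
  xs <- areaCm2(x); ys <- areaCm2(y)
  dsc <- if (xs + ys > 0) 2 * inter / (xs + ys) else NA_real_
  slide <- if (!is.na(x@slideIndex)) x@slideIndex else y@slideIndex
  data.frame(slideIndex = slide, xAreaCm2 = xs, yAreaCm2 = ys,
             intersectionCm2 = inter, dsc = dsc)
}

#' Area-weighted DSC for one specimen
#'
#' Pools per-slide overlaps into the specimen-level weighted DSC: each
#' slide's DSC enters with weight `(X + Y) / (2 Z)` where `Z` is the mean
#' total area annotated by the two observers over the specimen's slides.
#' Weights over the specimen sum to 1, and the weighted sum equals
#' `2 * sum(intersections) / (sum X + sum Y)` exactly.
#'
#' @param overlaps data.frame of per-slide rows as returned by [slideDSC()]
#'   (columns `xAreaCm2`, `yAreaCm2`, `intersectionCm2`, and `dsc`).
#' @return List with `zCm2`, `weightedDSC` (`NA` when no area was annotated
#'   by either observer on any slide), `perSlide` (the input with a `weight`
#'   column), `sumX`, `sumY`, `sumIntersection`.
#' @export
rpsWeightedDSC <- function(overlaps) {
  sx <- sum(overlaps$xAreaCm2); sy <- sum(overlaps$yAreaCm2)
  si <- sum(overlaps$intersectionCm2)
  z <- (sx + sy) / 2
  w <- if (z > 0) (overlaps$xAreaCm2 + overlaps$yAreaCm2) / (2 * z)
       else rep(0, nrow(overlaps))
  overlaps$weight <- w
  wdsc <- if (z > 0) {
    terms <- ifelse(w > 0, w * overlaps$dsc, 0)
    sum(terms)
  } else NA_real_
  list(zCm2 = z, weightedDSC = wdsc, perSlide = overlaps,
       sumX = sx, sumY = sy, sumIntersection = si)
}

#' Pool weighted DSCs across specimens
#'
#' Cross-specimen pooling uses the same weighting scheme as within-specimen
#' pooling: each specimen enters with weight proportional to its total
#' annotated area `sum(X) + sum(Y)`, so the result equals the all-slides
#' pooled form `2 * sum(intersections) / (sum X + sum Y)` over the cohort.
#'
#' @param weightedDSC Numeric vector of per-specimen weighted DSCs (`NA`
#'   entries excluded).
#' @param totalAreaCm2 Numeric vector of per-specimen `sum(X) + sum(Y)`
#'   totals (same length).
#' @return Pooled weighted DSC, or `NA` when every specimen is undefined.
#' @examples
#' pooledWeightedDSC(c(0.9, 0.5), c(3, 1))  # (0.9*3 + 0.5*1) / 4
#' @export
pooledWeightedDSC <- function(weightedDSC, totalAreaCm2) {
  stopifnot(length(weightedDSC) == length(totalAreaCm2))
  ok <- !is.na(weightedDSC) & totalAreaCm2 > 0
  if (!any(ok)) return(NA_real_)
  sum(weightedDSC[ok] * totalAreaCm2[ok]) / sum(totalAreaCm2[ok])
}

#' Full surface concordance of one specimen for one category
#'
#' Builds each observer's per-slide [RegionSet-class] for the category,
#' computes per-slide overlaps and the specimen's weighted DSC.
#'
#' @param case An [RPSCase-class].
#' @param categoryKey A category key (see [categoryKeys()]).
#' @return As [rpsWeightedDSC()], plus `specimenId` and `categoryKey`.
#' @export
caseConcordance <- function(case, categoryKey) {
  rs <- raters(case)
  regs <- regions(case)
  slides <- vapply(regs, slideIndex, 1L)
  ratersOf <- vapply(regs, raterId, "")
  rows <- lapply(seq_len(slideCount(case)), function(s) {
    sub <- regs[slides == s]
    xr <- regionsForCategory(sub[ratersOf[slides == s] == rs[1L]], categoryKey)
    yr <- regionsForCategory(sub[ratersOf[slides == s] == rs[2L]], categoryKey)
    x <- makeRegionSet(xr, categoryKey, specimenId(case), s, rs[1L])
    y <- makeRegionSet(yr, categoryKey, specimenId(case), s, rs[2L])
    slideDSC(x, y)
  })
  res <- rpsWeightedDSC(do.call(rbind, rows))
  res$specimenId <- specimenId(case)
  res$categoryKey <- categoryKey
  res
}
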