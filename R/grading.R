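## Analysis categories and Gleason composition.
##
## Category semantics:
##   any_pca      any Gleason region (pattern 3 or higher)
##   cspca        any Gleason region containing pattern 4 or higher (pure
##                GP4/GP5 and every mixed Gleason-score label, full area)
##   gp3/gp4/gp5  regions whose label CONTAINS the pattern (pure or mixed,
##                full region, not spatially split)
##   cg_idc, prostatitis, hgpin   their own separately annotated layers
##
## Composition (primary/secondary pattern, Grade Group) works on per-pattern
## AREAS: pure regions contribute everything to their pattern, mixed regions
## are split between their two patterns at the bin-midpoint fraction of the
## high-grade pattern (see patternFractions()).

#' Analysis category keys
#'
#' @return Character vector of the category names used throughout reports.
#' @export
categoryKeys <- function() {
  c("any_pca", "cspca", "gp3", "gp4", "gp5", "cg_idc", "prostatitis", "hgpin")
}

#' Select the regions contributing to an analysis category
#'
#' @param regionList List of [AnnotationRegion-class] objects from one
#'   observer and slide.
#' @param key A category key (see [categoryKeys()]).
#' @return The subset of `regionList` contributing to the category. Whole
#'   regions are returned: clinically significant cancer includes the full
#'   area of mixed Gleason-score regions containing pattern >= 4.
#' @examples
#' r <- AnnotationRegion("r", "s", 1L, "P1", "GS3+4<20",
#'                       list(cbind(c(0, 5, 5, 0), c(0, 0, 5, 5))))
#' length(regionsForCategory(list(r), "cspca"))  # 1
#' @export
regionsForCategory <- function(regionList, key) {
  key <- match.arg(key, categoryKeys())
  keep <- vapply(regionList, function(r) {
    p <- parseRegionLabel(r@label)
    switch(key,
      any_pca = p$category == "gleason",
      cspca = p$category == "gleason" && max(p$primary, p$secondary) >= 4L,
      gp3 = p$category == "gleason" && 3L %in% c(p$primary, p$secondary),
      gp4 = p$category == "gleason" && 4L %in% c(p$primary, p$secondary),
      gp5 = p$category == "gleason" && 5L %in% c(p$primary, p$secondary),
      cg_idc = p$category == "cg_idc",
      prostatitis = p$category == "prostatitis",
      hgpin = p$category == "hgpin")
  }, TRUE)
  regionList[keep]
}

#' Per-pattern Gleason areas of a set of regions
#'
#' Sums region areas into pattern-3/4/5 buckets, splitting mixed
#' Gleason-score regions at the bin-midpoint fraction.
#'
#' @param regionList List of [AnnotationRegion-class] objects (non-Gleason
#'   regions are ignored).
#' @return Named numeric vector `c("3", "4", "5")` of areas in cm^2.
#' @export
patternAreas <- function(regionList) {
  out <- c("3" = 0, "4" = 0, "5" = 0)
  for (r in regionList)
    out <- out + patternFractions(r@label) * r@areaCm2
  out
}

#' Derive the Gleason composition from per-pattern areas
#'
#' The primary pattern is the pattern with the largest surface area (ties
#' broken toward the higher pattern). The secondary pattern is the pattern
#' with the second-largest area, overridden by the highest pattern present
#' when that pattern's share of the total tumour area is at least 5%; a
#' pattern higher than the primary that falls below the 5% share never
#' becomes secondary (it is recorded via the minor-pattern flag). With a
#' single pattern, secondary equals primary (3+3 convention). A minor
#' pattern 5 is flagged when pattern 5 is present but occupies less than 5%
#' of the tumour area.
#'
#' @param areaByPattern Named numeric vector with names `"3"`, `"4"`, `"5"`
#'   (cm^2); at least one entry must be positive.
#' @return List with `primary`, `secondary` (integer patterns),
#'   `gg` (ISUP Grade Group 1--5), `totalAreaCm2`, `areaByPattern` and
#'   `minorPattern5` (logical).
#' @examples
#' compositionFromAreas(c("3" = 2, "4" = 0.5, "5" = 0.2))  # secondary 5
#' @export
compositionFromAreas <- function(areaByPattern) {
  a <- c("3" = 0, "4" = 0, "5" = 0)
  a[names(areaByPattern)] <- as.numeric(areaByPattern)
  if (any(a < 0) || all(a == 0))
    stop("areaByPattern must be non-negative with at least one positive entry")
  total <- sum(a)
  pats <- c(3L, 4L, 5L)
  present <- pats[a > 0]
  # primary: largest area, ties toward the higher pattern
  primary <- pats[max(which(a == max(a)))]
  # secondary: second-largest area, except that patterns HIGHER than the
  # primary only qualify when they hold at least 5% of the tumour area
  # (smaller high-grade foci are recorded via the minor-pattern flag)
  rest <- a; rest[as.character(primary)] <- 0
  tooSmall <- pats > primary & a / total < 0.05
  rest[tooSmall] <- 0
  secondary <- if (all(rest == 0)) primary
               else pats[max(which(rest == max(rest)))]
  highest <- max(present)
  if (highest > primary && a[as.character(highest)] / total >= 0.05)
    secondary <- highest
  minor5 <- a["5"] > 0 && a["5"] / total < 0.05
  list(primary = primary, secondary = secondary,
       gg = translateToGG(primary, secondary),
       totalAreaCm2 = total, areaByPattern = a,
       minorPattern5 = unname(minor5))
}

#' Gleason composition of a region list
#'
#' Convenience wrapper: [patternAreas()] followed by
#' [compositionFromAreas()]. Returns `NULL` when the list contains no
#' Gleason region.
#'
#' @param regionList List of [AnnotationRegion-class] objects.
#' @return A composition list (see [compositionFromAreas()]) or `NULL`.
#' @export
compositionFromRegions <- function(regionList) {
  a <- patternAreas(regionList)
  if (all(a == 0)) return(NULL)
  compositionFromAreas(a)
}
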