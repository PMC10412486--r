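#' @import methods
NULL

#' AnnotationRegion: one labelled polygon drawn by one pathologist
#'
#' A single polygon annotation on one whole-mount slide: an outer boundary
#' ring plus optional hole rings in millimetre coordinates, carrying the
#' specimen, slide, observer and a label from the annotation taxonomy
#' ([knownLabels()]). The surface area in cm^2 is computed on construction
#' and cached.
#'
#' @slot regionId Opaque region identifier.
#' @slot specimenId Specimen (prostatectomy) identifier.
#' @slot slideIndex 1-based slide index, apex to base.
#' @slot raterId Observer identifier.
#' @slot label Serialized label string (see [knownLabels()]).
#' @slot rings List of rings (`n x 2` mm matrices); outer ring first,
#'   positively oriented after normalization, holes after.
#' @slot areaCm2 Cached surface area in cm^2.
#'
#' @aliases AnnotationRegion-class
#' @export
setClass("AnnotationRegion",
  representation(regionId = "character", specimenId = "character",
                 slideIndex = "integer", raterId = "character",
                 label = "character", rings = "list", areaCm2 = "numeric"))

setValidity("AnnotationRegion", function(object) {
  msgs <- character(0)
  if (length(object@slideIndex) != 1L || is.na(object@slideIndex) ||
      object@slideIndex < 1L)
    msgs <- c(msgs, "slideIndex must be a single integer >= 1")
  lab <- tryCatch({ parseRegionLabel(object@label); NULL },
                  error = function(e) conditionMessage(e))
  if (!is.null(lab)) msgs <- c(msgs, lab)
  if (!length(object@rings) ||
      !all(vapply(object@rings, function(r) is.matrix(r) && ncol(r) == 2 &&
                    nrow(r) >= 3, TRUE)))
    msgs <- c(msgs, "rings must be a list of n x 2 matrices with n >= 3")
  else {
    if (!all(vapply(object@rings, .ringIsSimple, TRUE)))
      msgs <- c(msgs, "rings must be simple (non-self-intersecting)")
    if (.signedRingArea(object@rings[[1L]]) <= 0)
      msgs <- c(msgs, "outer ring must be positively oriented")
    a <- ringsAreaCm2(object@rings)
    if (a <= 0) msgs <- c(msgs, "region area must be positive")
    if (abs(a - object@areaCm2) > 1e-9)
      msgs <- c(msgs, "cached areaCm2 disagrees with ring signed area")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an AnnotationRegion
#'
#' @param regionId,specimenId,raterId Opaque identifier strings.
#' @param slideIndex 1-based slide index (apex to base).
#' @param label Label string from the annotation taxonomy.
#' @param rings List of rings (`n x 2` mm matrices), outer ring first; ring
#'   orientation is normalized automatically.
#' @return An [AnnotationRegion-class] object with cached area.
#' @examples
#' AnnotationRegion("r1", "RPS1", 1L, "P1", "GP3",
#'                  list(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))))
#' @export
AnnotationRegion <- function(regionId, specimenId, slideIndex, raterId,
                             label, rings) {
  rings <- .normalizeRings(rings)
  new("AnnotationRegion", regionId = as.character(regionId),
      specimenId = as.character(specimenId),
      slideIndex = as.integer(slideIndex), raterId = as.character(raterId),
      label = as.character(label), rings = rings,
      areaCm2 = ringsAreaCm2(rings))
}

#' RPSCase: one radical-prostatectomy specimen annotated by two observers
#'
#' Holds every [AnnotationRegion-class] drawn by exactly two observers over
#' the serial whole-mount slides of one specimen, plus the sectioning
#' geometry (slide count, slice thickness).
#'
#' @slot specimenId Specimen identifier.
#' @slot slideCount Number of annotated whole-mount slides.
#' @slot sliceThicknessMm Sectioning thickness in mm (default 4).
#' @slot regions List of [AnnotationRegion-class] objects from two raters.
#' @slot rpsSurfaceAreaCm2 Optional total sectioned surface area (NA if
#'   unknown).
#'
#' @aliases RPSCase-class
#' @export
setClass("RPSCase",
  representation(specimenId = "character", slideCount = "integer",
                 sliceThicknessMm = "numeric", regions = "list",
                 rpsSurfaceAreaCm2 = "numeric"))

setValidity("RPSCase", function(object) {
  msgs <- character(0)
  if (object@slideCount < 1L) msgs <- c(msgs, "slideCount must be >= 1")
  if (object@sliceThicknessMm <= 0)
    msgs <- c(msgs, "sliceThicknessMm must be positive")
  if (length(object@regions)) {
    ok <- vapply(object@regions, is, TRUE, class2 = "AnnotationRegion")
    if (!all(ok)) return("regions must all be AnnotationRegion objects")
    sids <- vapply(object@regions, function(r) r@specimenId, "")
    if (!all(sids == object@specimenId))
      msgs <- c(msgs, "all regions must carry the case's specimenId")
    slides <- vapply(object@regions, function(r) r@slideIndex, 1L)
    if (any(slides > object@slideCount))
      msgs <- c(msgs, "region slideIndex exceeds slideCount")
    rs <- unique(vapply(object@regions, function(r) r@raterId, ""))
    if (length(rs) != 2L)
      msgs <- c(msgs, sprintf("expected exactly 2 raters, found %d", length(rs)))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an RPSCase
#'
#' @param specimenId Specimen identifier.
#' @param slideCount Number of annotated slides.
#' @param regions List of [AnnotationRegion-class] objects (two raters).
#' @param sliceThicknessMm Slice thickness in mm (default 4, the standard
#'   whole-mount sectioning interval).
#' @param rpsSurfaceAreaCm2 Optional total sectioned surface area.
#' @return An [RPSCase-class] object.
#' @export
RPSCase <- function(specimenId, slideCount, regions,
                    sliceThicknessMm = 4, rpsSurfaceAreaCm2 = NA_real_) {
  new("RPSCase", specimenId = as.character(specimenId),
      slideCount = as.integer(slideCount),
      sliceThicknessMm = as.numeric(sliceThicknessMm),
      regions = regions, rpsSurfaceAreaCm2 = as.numeric(rpsSurfaceAreaCm2))
}

#' RegionSet: one observer's merged surface for one slide and category
#'
#' The union of an observer's regions contributing to one analysis category
#' on one slide — the `X` (or `Y`) whose area and pairwise overlap feed the
#' Dice similarity coefficient. Overlapping same-observer polygons are not
#' double counted: the cached area is the exact union area.
#'
#' @slot specimenId,raterId Identifiers.
#' @slot slideIndex Slide index.
#' @slot categoryKey Analysis category (see [categoryKeys()]).
#' @slot polys Polyset: list of polygons (each a list of rings).
#' @slot areaCm2 Exact union area in cm^2.
#'
#' @aliases RegionSet-class
#' @export
setClass("RegionSet",
  representation(specimenId = "character", slideIndex = "integer",
                 raterId = "character", categoryKey = "character",
                 polys = "list", areaCm2 = "numeric"))

setValidity("RegionSet", function(object) {
  msgs <- character(0)
  if (object@areaCm2 < 0) msgs <- c(msgs, "areaCm2 must be >= 0")
  if (length(object@polys)) {
    indiv <- vapply(object@polys, ringsAreaCm2, 0)
    if (object@areaCm2 > sum(indiv) + 1e-9)
      msgs <- c(msgs, "union area exceeds sum of member areas")
    if (object@areaCm2 < max(indiv) - 1e-9)
      msgs <- c(msgs, "union area below largest member area")
  } else if (object@areaCm2 != 0)
    msgs <- c(msgs, "empty geometry must have area 0")
  if (length(msgs)) msgs else TRUE
})

#' Build a RegionSet from regions of one observer, slide and category
#'
#' Merges the given regions into a single surface for DSC computation.
#' Degenerate regions (area below 1e-6 cm^2) are dropped with a warning, as
#' they fall below any meaningful precision of the annotation protocol.
#'
#' @param regions List of [AnnotationRegion-class] objects sharing slide and
#'   rater (may be empty).
#' @param categoryKey Analysis category name the set represents.
#' @param specimenId,slideIndex,raterId Identifiers; required when `regions`
#'   is empty, otherwise taken from the regions.
#' @return A [RegionSet-class] with exact union area.
#' @export
makeRegionSet <- function(regions, categoryKey,
                          specimenId = NA_character_, slideIndex = NA_integer_,
                          raterId = NA_character_) {
  if (length(regions)) {
    slides <- unique(vapply(regions, function(r) r@slideIndex, 1L))
    raters <- unique(vapply(regions, function(r) r@raterId, ""))
    specs <- unique(vapply(regions, function(r) r@specimenId, ""))
    if (length(slides) != 1L || length(raters) != 1L || length(specs) != 1L)
      stop("all regions in a RegionSet must share specimen, slide and rater")
    areas <- vapply(regions, function(r) r@areaCm2, 0)
    drop <- areas < .MIN_REGION_AREA_CM2
    if (any(drop)) {
      warning(sprintf("dropping %d degenerate region(s) below %g cm^2",
                      sum(drop), .MIN_REGION_AREA_CM2))
      regions <- regions[!drop]
    }
    polys <- lapply(regions, function(r) r@rings)
    specimenId <- specs; slideIndex <- slides; raterId <- raters
  } else polys <- list()
  new("RegionSet", specimenId = as.character(specimenId),
      slideIndex = as.integer(slideIndex), raterId = as.character(raterId),
      categoryKey = as.character(categoryKey), polys = polys,
      areaCm2 = unionAreaCm2(polys))
}

#' Overlap area between two observers' region sets
#'
#' Exact area of `X intersect Y` for two [RegionSet-class] objects from the
#' same slide and category but different observers.
#'
#' @param a,b [RegionSet-class] objects.
#' @return Intersection area in cm^2.
#' @export
intersectionAreaCm2 <- function(a, b) {
  stopifnot(is(a, "RegionSet"), is(b, "RegionSet"))
  if (length(a@polys) && length(b@polys)) {
    if (!identical(a@slideIndex, b@slideIndex) ||
        !identical(a@categoryKey, b@categoryKey))
      stop("RegionSets must share slide and category")
    if (identical(a@raterId, b@raterId))
      stop("RegionSets must come from different raters")
  }
  polysIntersectionAreaCm2(a@polys, b@polys)
}

## ---- accessors -------------------------------------------------------------

#' @describeIn AnnotationRegion-class Surface area in cm^2.
#' @param object An object.
#' @export
setGeneric("areaCm2", function(object) standardGeneric("areaCm2"))
#' @export
setMethod("areaCm2", "AnnotationRegion", function(object) object@areaCm2)
#' @export
setMethod("areaCm2", "RegionSet", function(object) object@areaCm2)

#' Accessor generics for annotation containers
#'
#' `specimenId()`, `raterId()`, `slideIndex()`, `regionLabel()`,
#' `regionRings()`, `regions()`, `slideCount()` and `sliceThicknessMm()`
#' read the corresponding fields of [AnnotationRegion-class],
#' [RPSCase-class] and [RegionSet-class] objects.
#'
#' @param object An object.
#' @return The field value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("specimenId", function(object) standardGeneric("specimenId"))
#' @export
setMethod("specimenId", "AnnotationRegion", function(object) object@specimenId)
#' @export
setMethod("specimenId", "RPSCase", function(object) object@specimenId)
#' @export
setMethod("specimenId", "RegionSet", function(object) object@specimenId)

#' @rdname accessors
#' @export
setGeneric("raterId", function(object) standardGeneric("raterId"))
#' @export
setMethod("raterId", "AnnotationRegion", function(object) object@raterId)
#' @export
setMethod("raterId", "RegionSet", function(object) object@raterId)

#' @rdname accessors
#' @export
setGeneric("slideIndex", function(object) standardGeneric("slideIndex"))
#' @export
setMethod("slideIndex", "AnnotationRegion", function(object) object@slideIndex)
#' @export
setMethod("slideIndex", "RegionSet", function(object) object@slideIndex)

#' @rdname accessors
#' @export
setGeneric("regionLabel", function(object) standardGeneric("regionLabel"))
#' @export
setMethod("regionLabel", "AnnotationRegion", function(object) object@label)

#' @rdname accessors
#' @export
setGeneric("regionRings", function(object) standardGeneric("regionRings"))
#' @export
setMethod("regionRings", "AnnotationRegion", function(object) object@rings)

#' @rdname accessors
#' @export
setGeneric("regions", function(object) standardGeneric("regions"))
#' @export
setMethod("regions", "RPSCase", function(object) object@regions)

#' @rdname accessors
#' @export
setGeneric("slideCount", function(object) standardGeneric("slideCount"))
#' @export
setMethod("slideCount", "RPSCase", function(object) object@slideCount)

#' @rdname accessors
#' @export
setGeneric("sliceThicknessMm",
           function(object) standardGeneric("sliceThicknessMm"))
#' @export
setMethod("sliceThicknessMm", "RPSCase",
          function(object) object@sliceThicknessMm)

#' @rdname accessors
#' @export
setGeneric("raters", function(object) standardGeneric("raters"))
#' @export
setMethod("raters", "RPSCase", function(object)
  sort(unique(vapply(object@regions, function(r) r@raterId, ""))))

setMethod("show", "AnnotationRegion", function(object) {
  cat(sprintf("AnnotationRegion %s | specimen %s slide %d rater %s | %s | %.4f cm^2\n",
              object@regionId, object@specimenId, object@slideIndex,
              object@raterId, object@label, object@areaCm2))
})

setMethod("show", "RPSCase", function(object) {
  cat(sprintf("RPSCase %s: %d slides (%.1f mm slices), %d regions, raters: %s\n",
              object@specimenId, object@slideCount, object@sliceThicknessMm,
              length(object@regions),
              paste(raters(object), collapse = ", ")))
})

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet %s | specimen %s slide %s rater %s | %d polygon(s) | %.4f cm^2\n",
              object@categoryKey, object@specimenId,
              as.character(object@slideIndex), object@raterId,
              length(object@polys), object@areaCm2))
})
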