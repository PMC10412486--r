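## GeoJSON import/export of paired-observer annotation sets.
##
## Dialect: RFC 7946 geometry syntax with PLANAR millimetre coordinates in a
## per-slide frame (origin at the slide's lower-left). Each feature is one
## Polygon with properties: region_id, specimen_id, slide_index, rater_id,
## label, and optionally slide_count / slice_thickness_mm /
## rps_surface_area_cm2 carried on every feature of the specimen.

.requireProp <- function(props, name, fid) {
  if (is.null(props[[name]]))
    stop(sprintf("feature '%s': missing property '%s'", fid, name))
  props[[name]]
}

#' Read a paired-observer annotation set from GeoJSON
#'
#' Parses a GeoJSON FeatureCollection of polygon annotations (millimetre
#' coordinates) into [RPSCase-class] objects grouped by specimen. Region
#' areas are computed and cached on construction.
#'
#' @param path Path to a GeoJSON file.
#' @return Named list of [RPSCase-class] objects, one per specimen, sorted
#'   by specimen id.
#' @seealso [writeAnnotationSet()] for the inverse; the two round-trip.
#' @export
readAnnotationSet <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  feats <- doc$features
  regions <- vector("list", length(feats))
  meta <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    props <- f$properties
    fid <- if (!is.null(props$region_id)) props$region_id else sprintf("#%d", i)
    geom <- f$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon"))
      stop(sprintf("feature '%s': geometry must be a Polygon (got %s)",
                   fid, if (is.null(geom)) "none" else geom$type))
    regionId <- .requireProp(props, "region_id", fid)
    spec <- as.character(.requireProp(props, "specimen_id", fid))
    slide <- as.integer(.requireProp(props, "slide_index", fid))
    rater <- as.character(.requireProp(props, "rater_id", fid))
    label <- as.character(.requireProp(props, "label", fid))
    if (!label %in% knownLabels())
      stop(sprintf("feature '%s': unknown label '%s'", fid, label))
    rings <- lapply(geom$coordinates, function(ring) {
      m <- do.call(rbind, lapply(ring, function(pt) as.numeric(pt[1:2])))
      # drop RFC 7946 closing vertex
      if (nrow(m) > 1L && all(abs(m[1L, ] - m[nrow(m), ]) < 1e-12))
        m <- m[-nrow(m), , drop = FALSE]
      m
    })
    regions[[i]] <- AnnotationRegion(regionId, spec, slide, rater, label, rings)
    if (is.null(meta[[spec]])) meta[[spec]] <- list()
    for (nm in c("slide_count", "slice_thickness_mm", "rps_surface_area_cm2"))
      if (!is.null(props[[nm]])) meta[[spec]][[nm]] <- as.numeric(props[[nm]])
  }
  specs <- sort(unique(vapply(regions, specimenId, "")))
  cases <- lapply(specs, function(s) {
    rs <- regions[vapply(regions, specimenId, "") == s]
    m <- meta[[s]]
    slideMax <- max(vapply(rs, slideIndex, 1L))
    RPSCase(s,
            slideCount = if (!is.null(m$slide_count)) as.integer(m$slide_count)
                         else slideMax,
            regions = rs,
            sliceThicknessMm = if (!is.null(m$slice_thickness_mm))
                                 m$slice_thickness_mm else 4,
            rpsSurfaceAreaCm2 = if (!is.null(m$rps_surface_area_cm2))
                                  m$rps_surface_area_cm2 else NA_real_)
  })
  names(cases) <- specs
  cases
}

#' Write a paired-observer annotation set to GeoJSON
#'
#' Serializes [RPSCase-class] objects to a GeoJSON FeatureCollection that
#' [readAnnotationSet()] reads back identically (ids, labels, vertices to
#' full double precision).
#'
#' @param cases A list of [RPSCase-class] objects (possibly empty).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeAnnotationSet <- function(cases, path) {
  features <- list()
  for (case in cases) {
    for (r in regions(case)) {
      coords <- lapply(regionRings(r), function(ring) {
        closed <- rbind(ring, ring[1L, ])
        lapply(seq_len(nrow(closed)), function(k) c(closed[k, 1], closed[k, 2]))
      })
      props <- list(region_id = r@regionId, specimen_id = r@specimenId,
                    slide_index = r@slideIndex, rater_id = r@raterId,
                    label = r@label, slide_count = slideCount(case),
                    slice_thickness_mm = sliceThicknessMm(case))
      if (!is.na(case@rpsSurfaceAreaCm2))
        props$rps_surface_area_cm2 <- case@rpsSurfaceAreaCm2
      features[[length(features) + 1L]] <- list(
        type = "Feature",
        geometry = list(type = "Polygon", coordinates = coords),
        properties = props)
    }
  }
  doc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       always_decimal = FALSE, pretty = FALSE)
  invisible(path)
}
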