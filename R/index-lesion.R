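## Index-lesion assembly, selection and between-observer concordance.
##
## A lesion is a connected tumour focus: per-slide connected components of
## one observer's Gleason regions (adjacency tolerance 0.5 mm), merged
## across consecutive slides whenever their footprints overlap in the shared
## specimen frame. The index lesion is the highest-Grade-Group lesion with
## total surface area >= 0.5 cm^2, ties broken by volume.

#' Assemble an observer's lesions across serial slides
#'
#' @param case An [RPSCase-class].
#' @param rater Rater id (must be one of the case's two observers).
#' @param adjacencyTolMm In-slide adjacency tolerance in mm (default 0.5).
#' @return List of lesions; each a list with `raterId`, `specimenId`,
#'   `regionIds`, `slides`, `footprints` (named list: slide index ->
#'   polyset), `totalAreaCm2` (sum of per-slide footprint union areas),
#'   `volumeCm3` (total area x slice thickness), `composition` (see
#'   [compositionFromAreas()]) and `gg`.
#' @export
assembleLesions <- function(case, rater, adjacencyTolMm = 0.5) {
  regs <- regions(case)
  keep <- vapply(regs, function(r) r@raterId == rater &&
                   parseRegionLabel(r@label)$category == "gleason", TRUE)
  regs <- regs[keep]
  if (!length(regs)) return(list())
  slides <- vapply(regs, slideIndex, 1L)

  # 2D components per slide; node = (slide, in-slide component)
  nodeOf <- integer(length(regs))
  nodes <- list()
  for (s in sort(unique(slides))) {
    idx <- which(slides == s)
    polys <- lapply(regs[idx], regionRings)
    comp <- connectedComponents(polys, adjacencyTolMm)
    for (cid in unique(comp)) {
      nodes[[length(nodes) + 1L]] <- list(slide = s, members = idx[comp == cid])
      nodeOf[idx[comp == cid]] <- length(nodes)
    }
  }

  # merge nodes on consecutive slides with overlapping footprints
  n <- length(nodes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nodeSlide <- vapply(nodes, `[[`, 1L, "slide")
  footOf <- lapply(nodes, function(nd) lapply(regs[nd$members], regionRings))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (abs(nodeSlide[i] - nodeSlide[j]) != 1L) next
    if (polysIntersectionAreaCm2(footOf[[i]], footOf[[j]]) > 0) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  lesions <- lapply(unique(roots), function(rt) {
    members <- unlist(lapply(which(roots == rt), function(i) nodes[[i]]$members))
    lr <- regs[members]
    ls <- sort(unique(vapply(lr, slideIndex, 1L)))
    foot <- lapply(ls, function(s)
      lapply(lr[vapply(lr, slideIndex, 1L) == s], regionRings))
    names(foot) <- as.character(ls)
    totalArea <- sum(vapply(foot, unionAreaCm2, 0))
    comp <- compositionFromRegions(lr)
    list(raterId = rater, specimenId = specimenId(case),
         regionIds = vapply(lr, function(r) r@regionId, ""),
         slides = ls, footprints = foot, totalAreaCm2 = totalArea,
         volumeCm3 = totalArea * sliceThicknessMm(case) / 10,
         composition = comp, gg = comp$gg)
  })
  lesions[order(-vapply(lesions, `[[`, 0, "totalAreaCm2"))]
}

#' Select the index lesion
#'
#' Among lesions with total surface area >= `minAreaCm2`, picks the highest
#' ISUP Grade Group, ties broken by volume. When no lesion reaches the
#' threshold the same rule is applied to all lesions and the result is
#' flagged (`belowAreaThreshold = TRUE`).
#'
#' @param lesions Non-empty list of lesions (see [assembleLesions()]).
#' @param minAreaCm2 Area threshold in cm^2 (default 0.5).
#' @return The selected lesion, with `belowAreaThreshold` attached.
#' @export
selectIndex <- function(lesions, minAreaCm2 = 0.5) {
  stopifnot(length(lesions) >= 1L)
  areas <- vapply(lesions, `[[`, 0, "totalAreaCm2")
  pool <- lesions[areas >= minAreaCm2]
  below <- length(pool) == 0L
  if (below) pool <- lesions
  ggs <- vapply(pool, `[[`, 0L, "gg")
  vols <- vapply(pool, `[[`, 0, "volumeCm3")
  pick <- which(ggs == max(ggs))
  pick <- pick[which.max(vols[pick])]
  out <- pool[[pick]]
  out$belowAreaThreshold <- below
  out
}

#' Index-lesion concordance for one specimen
#'
#' Pairs the two observers' index lesions and scores localization (weighted
#' DSC over the lesions' per-slide footprints) and grading (Grade Group
#' equality). The DSC is computed on the lesion-restricted footprints only,
#' over the union of slides either lesion touches.
#'
#' @param case An [RPSCase-class].
#' @param adjacencyTolMm In-slide adjacency tolerance in mm.
#' @return List: `specimenId`, `lesionP1`, `lesionP2`, `dsc` (weighted DSC),
#'   `ggP1`, `ggP2`, `ggAgreement`; or `NULL` when either observer
#'   annotated no tumour (reported as unmatched upstream).
#' @export
indexConcordance <- function(case, adjacencyTolMm = 0.5) {
  rs <- raters(case)
  l1 <- assembleLesions(case, rs[1L], adjacencyTolMm)
  l2 <- assembleLesions(case, rs[2L], adjacencyTolMm)
  if (!length(l1) || !length(l2)) return(NULL)
  i1 <- selectIndex(l1)
  i2 <- selectIndex(l2)
  slidesAll <- sort(unique(c(i1$slides, i2$slides)))
  rows <- lapply(slidesAll, function(s) {
    pa <- i1$footprints[[as.character(s)]]
    pb <- i2$footprints[[as.character(s)]]
    xa <- if (is.null(pa)) 0 else unionAreaCm2(pa)
    ya <- if (is.null(pb)) 0 else unionAreaCm2(pb)
    inter <- if (is.null(pa) || is.null(pb)) 0
             else polysIntersectionAreaCm2(pa, pb)
    data.frame(slideIndex = s, xAreaCm2 = xa, yAreaCm2 = ya,
               intersectionCm2 = inter,
               dsc = if (xa + ya > 0) 2 * inter / (xa + ya) else NA_real_)
  })
  w <- rpsWeightedDSC(do.call(rbind, rows))
  list(specimenId = specimenId(case), lesionP1 = i1, lesionP2 = i2,
       dsc = w$weightedDSC, sumX = w$sumX, sumY = w$sumY,
       ggP1 = i1$gg, ggP2 = i2$gg, ggAgreement = identical(i1$gg, i2$gg))
}

#' Cohort summary of index-lesion agreement
#'
#' @param pairs List of non-`NULL` results of [indexConcordance()], or a
#'   data.frame with columns `areaP1`, `areaP2`, `dsc`, `ggP1`, `ggP2` (the
#'   layout of a per-specimen index-lesion table).
#' @return List: `pooledWeightedDSC` (area-weighted across specimens),
#'   `meanDSC` (unweighted), `ggAgreementFraction` and `nPairs`.
#' @export
cohortIndexSummary <- function(pairs) {
  if (is.data.frame(pairs)) {
    tot <- pairs$areaP1 + pairs$areaP2
    dsc <- pairs$dsc
    agree <- pairs$ggP1 == pairs$ggP2
  } else {
    stopifnot(length(pairs) >= 1L)
    tot <- vapply(pairs, function(p) p$sumX + p$sumY, 0)
    dsc <- vapply(pairs, `[[`, 0, "dsc")
    agree <- vapply(pairs, `[[`, TRUE, "ggAgreement")
  }
  list(pooledWeightedDSC = pooledWeightedDSC(dsc, tot),
       meanDSC = mean(dsc, na.rm = TRUE),
       ggAgreementFraction = mean(agree),
       nPairs = length(dsc))
}
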