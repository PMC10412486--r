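## Planar polygon measure engine.
##
## Geometry lives in millimetre coordinates in a per-slide frame. A "ring" is
## an n x 2 matrix of vertices (not closed); a "polygon" is a list of rings
## (first ring outer, later rings holes, even-odd semantics); a "polyset" is
## a list of polygons whose union defines a region set.
##
## Union and intersection AREAS are computed exactly (up to double precision)
## by a slab sweep: the x axis is cut at every vertex and every pairwise
## edge-crossing abscissa; inside each slab the edges are non-crossing linear
## segments, so sorting them by height at the slab midline yields a stack of
## trapezoids with constant even-odd membership for each polygon. Summing
## trapezoid areas by membership gives |A|, |B| and |A .. B| in one pass.
## An independent grid rasterization oracle is provided for testing.

.EPS_MM <- 1e-9
.MIN_REGION_AREA_CM2 <- 1e-6

.signedRingArea <- function(ring) {
  # shoelace, mm^2; ring an n x 2 matrix, not closed
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Surface area of a single annotation boundary
#'
#' Shoelace area of the outer ring minus the areas of any hole rings,
#' converted to square centimetres. Hole rings are assumed nested inside the
#' outer ring and mutually disjoint.
#'
#' @param rings List of rings; each ring an `n x 2` matrix of millimetre
#'   coordinates. First ring is the outer boundary, the rest are holes.
#' @return Area in cm^2.
#' @examples
#' sq <- list(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' ringsAreaCm2(sq)  # 1 cm^2
#' @export
ringsAreaCm2 <- function(rings) {
  stopifnot(is.list(rings), length(rings) >= 1L)
  a <- abs(.signedRingArea(rings[[1L]]))
  if (length(rings) > 1L)
    a <- a - sum(vapply(rings[-1L], function(r) abs(.signedRingArea(r)), 0))
  a / 100
}

.normalizeRings <- function(rings) {
  # outer ring counter-clockwise (positive), holes clockwise
  lapply(seq_along(rings), function(i) {
    r <- rings[[i]]
    storage.mode(r) <- "double"
    dimnames(r) <- NULL
    s <- .signedRingArea(r)
    wantPos <- (i == 1L)
    if ((s > 0) != wantPos) r <- r[rev(seq_len(nrow(r))), , drop = FALSE]
    r
  })
}

.ringIsSimple <- function(ring, eps = .EPS_MM) {
  n <- nrow(ring)
  if (n < 3L) return(FALSE)
  x1 <- ring[, 1]; y1 <- ring[, 2]
  nxt <- c(seq_len(n)[-1L], 1L)
  x2 <- ring[nxt, 1]; y2 <- ring[nxt, 2]
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    # skip edges sharing an endpoint with edge i
    js <- js[js != i + 1L & !(i == 1L & js == n)]
    if (!length(js)) next
    hit <- .segmentsCross(x1[i], y1[i], x2[i], y2[i],
                          x1[js], y1[js], x2[js], y2[js], eps)
    if (any(hit)) return(FALSE)
  }
  TRUE
}

.segmentsCross <- function(ax, ay, bx, by, cx, cy, dx, dy, eps = .EPS_MM) {
  # TRUE where segment AB properly crosses segments CD (vectorized over CD)
  d1x <- bx - ax; d1y <- by - ay
  d2x <- dx - cx; d2y <- dy - cy
  den <- d1x * d2y - d1y * d2x
  ex <- cx - ax; ey <- cy - ay
  t <- (ex * d2y - ey * d2x) / den
  u <- (ex * d1y - ey * d1x) / den
  ok <- abs(den) > eps & t > eps & t < 1 - eps & u > eps & u < 1 - eps
  ok & !is.na(ok)
}

.polysEdges <- function(polys, setId, pidOffset = 0L) {
  # flatten a polyset into an edge table; every ring of a polygon shares the
  # polygon's id so even-odd parity is tracked per polygon
  out <- vector("list", length(polys))
  for (i in seq_along(polys)) {
    rings <- polys[[i]]
    e <- lapply(rings, function(r) {
      n <- nrow(r)
      nxt <- c(seq_len(n)[-1L], 1L)
      cbind(x1 = r[, 1], y1 = r[, 2], x2 = r[nxt, 1], y2 = r[nxt, 2])
    })
    e <- do.call(rbind, e)
    out[[i]] <- cbind(e, pid = pidOffset + i, set = setId)
  }
  e <- do.call(rbind, out)
  if (is.null(e)) return(NULL)
  keep <- abs(e[, "x1"] - e[, "x2"]) > .EPS_MM | abs(e[, "y1"] - e[, "y2"]) > .EPS_MM
  e[keep, , drop = FALSE]
}

.crossingXs <- function(E) {
  n <- nrow(E)
  if (n < 2L) return(numeric(0))
  ij <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  i <- ij[, 1L]; j <- ij[, 2L]
  ax <- E[i, "x1"]; ay <- E[i, "y1"]; bx <- E[i, "x2"]; by <- E[i, "y2"]
  cx <- E[j, "x1"]; cy <- E[j, "y1"]; dx <- E[j, "x2"]; dy <- E[j, "y2"]
  d1x <- bx - ax; d1y <- by - ay
  d2x <- dx - cx; d2y <- dy - cy
  den <- d1x * d2y - d1y * d2x
  ex <- cx - ax; ey <- cy - ay
  t <- (ex * d2y - ey * d2x) / den
  u <- (ex * d1y - ey * d1x) / den
  ok <- abs(den) > .EPS_MM & t >= 0 & t <= 1 & u >= 0 & u <= 1
  ok[is.na(ok)] <- FALSE
  (ax + t * d1x)[ok]
}

.sweepAreas <- function(polysA, polysB = NULL) {
  # returns c(a =, b =, ab =) areas in mm^2 of union(A), union(B), A-and-B
  nA <- length(polysA)
  eA <- .polysEdges(polysA, 1L, 0L)
  eB <- if (length(polysB)) .polysEdges(polysB, 2L, nA) else NULL
  E <- rbind(eA, eB)
  if (is.null(E) || nrow(E) == 0L) return(c(a = 0, b = 0, ab = 0))
  nPoly <- nA + length(polysB)
  inSetA <- c(rep(TRUE, nA), rep(FALSE, length(polysB)))

  xs <- sort(c(E[, "x1"], E[, "x2"], .crossingXs(E)))
  xs <- xs[c(TRUE, diff(xs) > .EPS_MM)]
  if (length(xs) < 2L) return(c(a = 0, b = 0, ab = 0))

  exmin <- pmin(E[, "x1"], E[, "x2"])
  exmax <- pmax(E[, "x1"], E[, "x2"])
  areaA <- 0; areaB <- 0; areaAB <- 0
  for (s in seq_len(length(xs) - 1L)) {
    x0 <- xs[s]; x1 <- xs[s + 1L]
    w <- x1 - x0
    if (w <= .EPS_MM) next
    # vertical edges never cross the slab interior and would yield 0/0 slopes
    span <- which(exmin <= x0 + .EPS_MM & exmax >= x1 - .EPS_MM &
                    exmax - exmin > 0)
    if (length(span) < 2L) next
    ex1 <- E[span, "x1"]; ey1 <- E[span, "y1"]
    ex2 <- E[span, "x2"]; ey2 <- E[span, "y2"]
    slope <- (ey2 - ey1) / (ex2 - ex1)
    ya <- ey1 + (x0 - ex1) * slope
    yb <- ey1 + (x1 - ex1) * slope
    ord <- order((ya + yb) / 2)
    pid <- E[span, "pid"][ord]
    yaO <- ya[ord]; ybO <- yb[ord]
    parity <- integer(nPoly)
    cntA <- 0L; cntB <- 0L
    for (k in seq_len(length(ord) - 1L)) {
      p <- pid[k]
      parity[p] <- 1L - parity[p]
      delta <- if (parity[p] == 1L) 1L else -1L
      if (inSetA[p]) cntA <- cntA + delta else cntB <- cntB + delta
      gap <- ((yaO[k + 1L] - yaO[k]) + (ybO[k + 1L] - ybO[k])) / 2 * w
      if (cntA > 0L) areaA <- areaA + gap
      if (cntB > 0L) areaB <- areaB + gap
      if (cntA > 0L && cntB > 0L) areaAB <- areaAB + gap
    }
  }
  c(a = as.numeric(areaA), b = as.numeric(areaB), ab = as.numeric(areaAB))
}

#' Area of the union of a polygon set
#'
#' Exact area of the union of (possibly overlapping) polygons, in cm^2.
#' Overlapping polygons from the same observer are counted once, so the
#' result is a well-defined annotated surface area.
#'
#' @param polys A polyset: list of polygons, each a list of rings.
#' @return Union area in cm^2 (0 for an empty list).
#' @examples
#' sq <- function(x0, y0, s) list(cbind(c(x0, x0 + s, x0 + s, x0),
#'                                      c(y0, y0, y0 + s, y0 + s)))
#' unionAreaCm2(list(sq(0, 0, 10), sq(5, 5, 10)))
#' @export
unionAreaCm2 <- function(polys) {
  if (!length(polys)) return(0)
  unname(.sweepAreas(polys)["a"]) / 100
}

#' Area of the intersection of two polygon sets
#'
#' Exact area of `union(A) intersect union(B)` in cm^2 — the overlap
#' `|X .. Y|` between two observers' annotated surfaces on one slide.
#'
#' @param polysA,polysB Polysets (lists of polygons, each a list of rings).
#' @return Intersection area in cm^2.
#' @export
polysIntersectionAreaCm2 <- function(polysA, polysB) {
  if (!length(polysA) || !length(polysB)) return(0)
  unname(.sweepAreas(polysA, polysB)["ab"]) / 100
}

.pointsInPolys <- function(px, py, polys) {
  inAny <- rep(FALSE, length(px))
  for (poly in polys) {
    cross <- integer(length(px))
    for (r in poly) {
      n <- nrow(r)
      nxt <- c(seq_len(n)[-1L], 1L)
      for (k in seq_len(n)) {
        ay <- r[k, 2]; by <- r[nxt[k], 2]
        if (ay == by) next
        ax <- r[k, 1]; bx <- r[nxt[k], 1]
        hit <- ((ay > py) != (by > py)) &
          (px < ax + (py - ay) * (bx - ax) / (by - ay))
        cross <- cross + hit
      }
    }
    inAny <- inAny | (cross %% 2L == 1L)
  }
  inAny
}

#' Rasterization oracle for polygon-set area
#'
#' Estimates the area of a polygon set by counting grid-cell centres that
#' fall inside it (even-odd rule per polygon, union across polygons). This
#' is a deliberately independent route from the exact sweep computation and
#' converges to the true area as `cellMm` shrinks; it exists to validate the
#' exact engine.
#'
#' @param polys A polyset (list of polygons, each a list of rings), or a
#'   [RegionSet-class] object.
#' @param cellMm Grid cell edge length in millimetres (> 0).
#' @return Estimated area in cm^2.
#' @examples
#' sq <- list(list(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))))
#' rasterizeOracle(sq, cellMm = 0.1)
#' @export
rasterizeOracle <- function(polys, cellMm) {
  stopifnot(is.numeric(cellMm), cellMm > 0)
  if (is(polys, "RegionSet")) polys <- polys@polys
  if (!length(polys)) return(0)
  allPts <- do.call(rbind, unlist(polys, recursive = FALSE))
  xr <- range(allPts[, 1]); yr <- range(allPts[, 2])
  gx <- seq(xr[1] + cellMm / 2, xr[2], by = cellMm)
  gy <- seq(yr[1] + cellMm / 2, yr[2], by = cellMm)
  if (!length(gx) || !length(gy)) return(0)
  if (length(gx) * length(gy) > 6e7)
    stop("rasterization grid too large; increase cellMm")
  # process by rows of the grid to bound memory
  total <- 0L
  chunk <- max(1L, floor(4e6 / length(gx)))
  for (start in seq(1L, length(gy), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(gy))
    px <- rep(gx, times = length(idx))
    py <- rep(gy[idx], each = length(gx))
    total <- total + sum(.pointsInPolys(px, py, polys))
  }
  total * cellMm^2 / 100
}

#' Rasterization oracle for two-set overlap
#'
#' Grid-counting estimate of the two observers' areas and their overlap on
#' a shared grid spanning both sets; the Dice coefficient follows from the
#' counts. Independent of the exact sweep engine; used to validate it.
#'
#' @param polysA,polysB Polysets (lists of polygons, each a list of rings).
#' @param cellMm Grid cell edge length in millimetres.
#' @return List: `areaA`, `areaB`, `areaAB` (cm^2) and `dsc`.
#' @export
rasterizeOverlap <- function(polysA, polysB, cellMm) {
  stopifnot(is.numeric(cellMm), cellMm > 0)
  allPts <- do.call(rbind, unlist(c(polysA, polysB), recursive = FALSE))
  xr <- range(allPts[, 1]); yr <- range(allPts[, 2])
  gx <- seq(xr[1] + cellMm / 2, xr[2], by = cellMm)
  gy <- seq(yr[1] + cellMm / 2, yr[2], by = cellMm)
  if (length(gx) * length(gy) > 6e7)
    stop("rasterization grid too large; increase cellMm")
  nA <- 0L; nB <- 0L; nAB <- 0L
  chunk <- max(1L, floor(4e6 / length(gx)))
  for (start in seq(1L, length(gy), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(gy))
    px <- rep(gx, times = length(idx))
    py <- rep(gy[idx], each = length(gx))
    inA <- .pointsInPolys(px, py, polysA)
    inB <- .pointsInPolys(px, py, polysB)
    nA <- nA + sum(inA); nB <- nB + sum(inB); nAB <- nAB + sum(inA & inB)
  }
  f <- cellMm^2 / 100
  list(areaA = nA * f, areaB = nB * f, areaAB = nAB * f,
       dsc = if (nA + nB > 0) 2 * nAB / (nA + nB) else NA_real_)
}

.pointSegDist <- function(px, py, ax, ay, bx, by) {
  # vectorized over segments AB for a single point P
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 > 0, ((px - ax) * dx + (py - ay) * dy) / len2, 0)
  t <- pmin(1, pmax(0, t))
  qx <- ax + t * dx; qy <- ay + t * dy
  sqrt((px - qx)^2 + (py - qy)^2)
}

.ringSegs <- function(poly) {
  segs <- lapply(poly, function(r) {
    n <- nrow(r)
    nxt <- c(seq_len(n)[-1L], 1L)
    cbind(ax = r[, 1], ay = r[, 2], bx = r[nxt, 1], by = r[nxt, 2])
  })
  do.call(rbind, segs)
}

#' Minimum distance between two polygons
#'
#' Euclidean distance in millimetres between two polygons (0 when they
#' overlap, touch, or one contains the other).
#'
#' @param polyA,polyB Polygons (lists of rings).
#' @return Distance in mm.
#' @export
polyDistanceMm <- function(polyA, polyB) {
  sa <- .ringSegs(polyA); sb <- .ringSegs(polyB)
  # containment / overlap
  if (any(.pointsInPolys(sa[, "ax"], sa[, "ay"], list(polyB)))) return(0)
  if (any(.pointsInPolys(sb[, "ax"], sb[, "ay"], list(polyA)))) return(0)
  best <- Inf
  for (i in seq_len(nrow(sa))) {
    if (any(.segmentsCross(sa[i, "ax"], sa[i, "ay"], sa[i, "bx"], sa[i, "by"],
                           sb[, "ax"], sb[, "ay"], sb[, "bx"], sb[, "by"],
                           eps = 0))) return(0)
    d1 <- .pointSegDist(sa[i, "ax"], sa[i, "ay"],
                        sb[, "ax"], sb[, "ay"], sb[, "bx"], sb[, "by"])
    d2 <- .pointSegDist(sa[i, "bx"], sa[i, "by"],
                        sb[, "ax"], sb[, "ay"], sb[, "bx"], sb[, "by"])
    best <- min(best, d1, d2)
  }
  for (i in seq_len(nrow(sb))) {
    d1 <- .pointSegDist(sb[i, "ax"], sb[i, "ay"],
                        sa[, "ax"], sa[, "ay"], sa[, "bx"], sa[, "by"])
    best <- min(best, d1)
  }
  best
}

#' Group polygons into connected components
#'
#' Partitions polygons such that two polygons belong to the same group iff
#' they come within `adjacencyTolMm` of each other, transitively. Used to
#' assemble tumour foci from separately drawn regions: regions drawn as
#' distinct polygons but within drawing precision of one another belong to
#' one focus.
#'
#' @param polys List of polygons (each a list of rings).
#' @param adjacencyTolMm Adjacency tolerance in mm; default 0.5, half the
#'   annotation protocol's stated precision floor.
#' @return Integer vector of group labels (1-based), one per polygon.
#' @examples
#' sq <- function(x0) list(cbind(c(x0, x0 + 5, x0 + 5, x0), c(0, 0, 5, 5)))
#' connectedComponents(list(sq(0), sq(5.2), sq(20)), adjacencyTolMm = 0.5)
#' @export
connectedComponents <- function(polys, adjacencyTolMm = 0.5) {
  n <- length(polys)
  if (!n) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ri <- find(i); rj <- find(j)
    if (ri == rj) next
    if (polyDistanceMm(polys[[i]], polys[[j]]) <= adjacencyTolMm)
      parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}
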