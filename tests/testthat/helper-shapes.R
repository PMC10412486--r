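# Shared fixture builders: all geometry is generated in code at test time.

squareRing <- function(x0, y0, side) {
  cbind(c(x0, x0 + side, x0 + side, x0),
        c(y0, y0, y0 + side, y0 + side))
}

# radial (star-shaped) polygon around a centre: simple by construction
starRing <- function(cx, cy, rMin = 2, rMax = 8, n = 24) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- stats::runif(n, rMin, rMax)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

regionFrom <- function(ring, id = "r1", specimen = "S1", slide = 1L,
                       rater = "P1", label = "GP3") {
  AnnotationRegion(id, specimen, slide, rater, label,
                   if (is.matrix(ring)) list(ring) else ring)
}

# one-slide two-rater case built from (label, ring) pairs per rater
caseFrom <- function(p1, p2, specimen = "S1", slides = 1L) {
  regs <- list()
  k <- 0
  for (r in p1) {
    k <- k + 1
    regs[[k]] <- AnnotationRegion(sprintf("p1_%d", k), specimen,
                                  r$slide %||% 1L, "P1", r$label, list(r$ring))
  }
  for (r in p2) {
    k <- k + 1
    regs[[k]] <- AnnotationRegion(sprintf("p2_%d", k), specimen,
                                  r$slide %||% 1L, "P2", r$label, list(r$ring))
  }
  RPSCase(specimen, slides, regs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
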