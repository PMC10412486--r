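## Per-slide categorical calls and chance-corrected agreement.
##
## Fleiss' multi-rater kappa, specialized here to two observers: category
## proportions for the expected agreement are pooled over both observers.
## Confidence intervals are percentile bootstrap over subjects (slides),
## because the agreement statistic has no convenient closed-form interval
## for small samples.

#' Derive per-slide categorical calls for each observer
#'
#' For every slide and observer: presence booleans for each analysis
#' category (area > 0), primary/secondary Gleason pattern and the minor
#' pattern 5 flag from the slide's Gleason composition.
#'
#' @param case An [RPSCase-class].
#' @return data.frame with one row per slide x rater: `specimenId`,
#'   `slideIndex`, `raterId`, logical columns `any_pca`, `cspca`, `gp3`,
#'   `gp4`, `gp5`, `cg_idc`, `prostatitis`, `hgpin`, `minor_pattern5`, and
#'   integer `primary_gp`, `secondary_gp` (`NA` on tumour-free slides).
#' @export
deriveCalls <- function(case) {
  rs <- raters(case)
  regs <- regions(case)
  slides <- vapply(regs, slideIndex, 1L)
  ratersOf <- vapply(regs, raterId, "")
  grid <- expand.grid(slideIndex = seq_len(slideCount(case)), raterId = rs,
                      stringsAsFactors = FALSE)
  presence <- c("any_pca", "cspca", "gp3", "gp4", "gp5",
                "cg_idc", "prostatitis", "hgpin")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$slideIndex[i]; rt <- grid$raterId[i]
    sub <- regs[slides == s & ratersOf == rt]
    out <- data.frame(specimenId = specimenId(case), slideIndex = s,
                      raterId = rt, stringsAsFactors = FALSE)
    for (k in presence)
      out[[k]] <- length(regionsForCategory(sub, k)) > 0L
    comp <- compositionFromRegions(sub)
    out$primary_gp <- if (is.null(comp)) NA_integer_ else comp$primary
    out$secondary_gp <- if (is.null(comp)) NA_integer_ else comp$secondary
    out$minor_pattern5 <- if (is.null(comp)) FALSE else comp$minorPattern5
    out
  })
  do.call(rbind, rows)
}

#' Fleiss' kappa for paired categorical calls
#'
#' Multi-rater Fleiss kappa with the observers' pooled category proportions
#' as the chance model. When every subject receives the same single category
#' from both observers the statistic is degenerate (0/0); agreement is then
#' perfect and kappa is reported as 1 with `degenerate = TRUE`.
#'
#' @param ratings A matrix or data.frame, subjects in rows and raters in
#'   columns; entries are category labels (any atomic type).
#' @return List: `kappa`, `pObserved`, `pExpected`, `nSubjects`, `nRaters`,
#'   `categories`, `degenerate`.
#' @examples
#' fleissKappa(cbind(rep(c("pos", "neg"), c(48, 26)),
#'                   rep(c("pos", "neg"), c(48, 26))))$kappa  # 1
#' @export
fleissKappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  stopifnot(ncol(ratings) >= 2L, nrow(ratings) >= 2L)
  if (any(is.na(ratings))) stop("ratings must not contain NA")
  cats <- sort(unique(as.vector(ratings)))
  N <- nrow(ratings); n <- ncol(ratings)
  counts <- vapply(cats, function(cc) rowSums(ratings == cc),
                   numeric(N))
  counts <- matrix(counts, nrow = N)
  Pi <- (rowSums(counts^2) - n) / (n * (n - 1))
  pObs <- mean(Pi)
  pj <- colSums(counts) / (N * n)
  pExp <- sum(pj^2)
  degenerate <- length(cats) == 1L
  kappa <- if (degenerate) 1 else (pObs - pExp) / (1 - pExp)
  list(kappa = kappa, pObserved = pObs, pExpected = pExp,
       nSubjects = N, nRaters = n, categories = cats,
       degenerate = degenerate)
}

#' Percentile-bootstrap confidence interval for Fleiss' kappa
#'
#' Resamples subjects (slides) with replacement; degenerate resamples are
#' scored as kappa 1, consistent with [fleissKappa()].
#'
#' @param ratings Subjects x raters matrix of category labels.
#' @param nBoot Number of bootstrap resamples (>= 200; default 2000).
#' @param seed Integer RNG seed; recorded in the result for reproducibility.
#' @param conf Confidence level (default 0.95).
#' @return List: `ciLow`, `ciHigh`, `nBoot`, `seed`, `ciMethod`.
#' @export
kappaCI <- function(ratings, nBoot = 2000L, seed = 1L, conf = 0.95) {
  stopifnot(nBoot >= 200L)
  ratings <- as.matrix(ratings)
  N <- nrow(ratings)
  stats <- local({
    set.seed(seed)
    vapply(seq_len(nBoot), function(b) {
      idx <- sample.int(N, N, replace = TRUE)
      fleissKappa(ratings[idx, , drop = FALSE])$kappa
    }, 0)
  })
  alpha <- (1 - conf) / 2
  qs <- unname(stats::quantile(stats, c(alpha, 1 - alpha), type = 7))
  list(ciLow = qs[1L], ciHigh = qs[2L], nBoot = nBoot, seed = seed,
       ciMethod = "percentile bootstrap over subjects")
}

#' Verbal agreement band for a kappa value
#'
#' Standard interpretation bands: below 0 poor, 0--0.20 slight, 0.21--0.40
#' fair, 0.41--0.60 moderate, 0.61--0.80 substantial, 0.81--1.00 almost
#' perfect.
#'
#' @param kappa Numeric kappa value.
#' @return Character band label.
#' @export
kappaBand <- function(kappa) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L)
  if (kappa < 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' Slide-level agreement table across a cohort
#'
#' Derives per-slide calls for every specimen and computes Fleiss kappa
#' (with bootstrap CI) per category: presence categories over all slides;
#' primary and secondary Gleason pattern as nominal multi-category variables
#' over the slides where BOTH observers call tumour present.
#'
#' @param cases List of [RPSCase-class] objects.
#' @param nBoot Bootstrap resamples for the CIs.
#' @param seed RNG seed for the bootstrap.
#' @return data.frame with one row per category: `category`, `nSlides`,
#'   `posP1`, `posP2` (positive-call counts; `NA` for the pattern rows),
#'   `kappa`, `ciLow`, `ciHigh`, `band`, `degenerate`.
#' @export
slideAgreementTable <- function(cases, nBoot = 2000L, seed = 1L) {
  calls <- do.call(rbind, lapply(cases, deriveCalls))
  # rater ids may differ between cases; align by per-case rater order
  byCase <- split(calls, calls$specimenId)
  p1 <- do.call(rbind, lapply(byCase, function(d) {
    r <- sort(unique(d$raterId)); d[d$raterId == r[1L], ]
  }))
  p2 <- do.call(rbind, lapply(byCase, function(d) {
    r <- sort(unique(d$raterId)); d[d$raterId == r[2L], ]
  }))
  o1 <- order(p1$specimenId, p1$slideIndex)
  o2 <- order(p2$specimenId, p2$slideIndex)
  p1 <- p1[o1, ]; p2 <- p2[o2, ]
  presence <- c("any_pca", "cspca", "gp3", "gp4", "gp5",
                "minor_pattern5", "cg_idc", "prostatitis", "hgpin")
  rows <- list()
  for (k in presence) {
    m <- cbind(p1[[k]], p2[[k]])
    fk <- fleissKappa(m)
    ci <- kappaCI(m, nBoot = nBoot, seed = seed)
    rows[[k]] <- data.frame(category = k, nSlides = nrow(m),
                            posP1 = sum(p1[[k]]), posP2 = sum(p2[[k]]),
                            kappa = fk$kappa, ciLow = ci$ciLow,
                            ciHigh = ci$ciHigh, band = kappaBand(fk$kappa),
                            degenerate = fk$degenerate,
                            stringsAsFactors = FALSE)
  }
  both <- p1$any_pca & p2$any_pca
  for (k in c("primary_gp", "secondary_gp")) {
    m <- cbind(p1[[k]][both], p2[[k]][both])
    if (nrow(m) >= 2L) {
      fk <- fleissKappa(m)
      ci <- kappaCI(m, nBoot = nBoot, seed = seed)
      rows[[k]] <- data.frame(category = k, nSlides = nrow(m),
                              posP1 = NA_integer_, posP2 = NA_integer_,
                              kappa = fk$kappa, ciLow = ci$ciLow,
                              ciHigh = ci$ciHigh, band = kappaBand(fk$kappa),
                              degenerate = fk$degenerate,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
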