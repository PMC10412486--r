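## Label taxonomy for whole-mount prostatectomy annotation regions.
##
## Serialized label strings are the canonical on-disk form (GeoJSON property
## "label") and are bijective with the parsed representation:
##   "GP3" "GP4" "GP5"                     pure Gleason patterns
##   "GS3+4<20" "GS3+4_20-50"              mixed Gleason scores, bin = share of
##   "GS4+3_50-80" "GS4+3>80"              the high-grade (secondary resp.
##                                         primary) pattern
##   "CGIDC"                               cribriform growth / intraductal ca.
##   "PROSTATITIS" "HGPIN"                 benign mimics

#' Known annotation label strings
#'
#' The closed set of label strings accepted by [parseRegionLabel()]. Mixed
#' Gleason-score labels carry a percentage bin for the high-grade pattern;
#' bins below 50% are only valid when the high-grade pattern is the
#' secondary pattern (e.g. 3+4), bins of 50% and above only when it is the
#' primary (e.g. 4+3).
#'
#' @return Character vector of valid label strings.
#' @examples
#' knownLabels()
#' @export
knownLabels <- function() {
  c("GP3", "GP4", "GP5",
    "GS3+4<20", "GS3+4_20-50", "GS4+3_50-80", "GS4+3>80",
    "CGIDC", "PROSTATITIS", "HGPIN")
}

## bin string -> assumed fraction of the HIGH-grade pattern (bin midpoint;
## ">80" and "<20" use 0.90 / 0.10)
.binFraction <- c("<20" = 0.10, "20-50" = 0.35, "50-80" = 0.65, ">80" = 0.90)

#' Parse an annotation label string
#'
#' Decodes a serialized label into its structured form: the annotation
#' category (`gleason`, `cg_idc`, `prostatitis`, `hgpin`) and, for Gleason
#' regions, whether the region is a pure pattern or a mixed Gleason score,
#' the primary/secondary patterns and the high-grade percentage bin.
#'
#' @param label A single label string (see [knownLabels()]).
#' @return A list with elements `label`, `category`, and for Gleason regions
#'   `kind` (`"pure"` or `"mixed"`), `primary`, `secondary`, `bin` (`NA` for
#'   pure labels) and `highFraction`, the assumed area fraction of the
#'   high-grade pattern (bin midpoint; 1 for pure labels, attributed to the
#'   single pattern).
#' @examples
#' parseRegionLabel("GS4+3_50-80")
#' @export
parseRegionLabel <- function(label) {
  stopifnot(is.character(label), length(label) == 1L, !is.na(label))
  if (label == "CGIDC")
    return(list(label = label, category = "cg_idc"))
  if (label == "PROSTATITIS")
    return(list(label = label, category = "prostatitis"))
  if (label == "HGPIN")
    return(list(label = label, category = "hgpin"))
  if (grepl("^GP[345]$", label)) {
    gp <- as.integer(sub("^GP", "", label))
    return(list(label = label, category = "gleason", kind = "pure",
                primary = gp, secondary = gp, bin = NA_character_,
                highFraction = 1))
  }
  m <- regmatches(label,
                  regexec("^GS([345])\\+([345])(<20|_20-50|_50-80|>80)$", label))[[1]]
  if (length(m) == 4L) {
    p <- as.integer(m[2]); s <- as.integer(m[3])
    bin <- sub("^_", "", m[4])
    if (p == s)
      stop("invalid mixed label (equal patterns): ", label)
    highIsPrimary <- p > s
    if (highIsPrimary && !(bin %in% c("50-80", ">80")))
      stop("bin '", bin, "' invalid when the high-grade pattern is primary: ", label)
    if (!highIsPrimary && !(bin %in% c("<20", "20-50")))
      stop("bin '", bin, "' invalid when the high-grade pattern is secondary: ", label)
    return(list(label = label, category = "gleason", kind = "mixed",
                primary = p, secondary = s, bin = bin,
                highFraction = unname(.binFraction[bin])))
  }
  stop("unknown annotation label: '", label, "'")
}

#' Area attribution of a label across Gleason patterns
#'
#' Returns the fraction of a region's surface area attributed to each
#' Gleason pattern 3, 4, 5. Pure labels attribute everything to their single
#' pattern; mixed Gleason-score labels split between the two patterns at the
#' bin-midpoint fraction of the high-grade pattern. Non-Gleason labels
#' attribute nothing.
#'
#' @param label A label string.
#' @return Named numeric vector `c("3", "4", "5")` summing to 1 for Gleason
#'   labels, to 0 otherwise.
#' @examples
#' patternFractions("GS3+4<20")  # 90% GP3, 10% GP4
#' @export
patternFractions <- function(label) {
  p <- parseRegionLabel(label)
  out <- c("3" = 0, "4" = 0, "5" = 0)
  if (p$category != "gleason") return(out)
  hi <- max(p$primary, p$secondary)
  lo <- min(p$primary, p$secondary)
  if (p$kind == "pure") {
    out[as.character(p$primary)] <- 1
  } else {
    out[as.character(hi)] <- p$highFraction
    out[as.character(lo)] <- out[as.character(lo)] + (1 - p$highFraction)
  }
  out
}

#' Patterns contained in a label
#'
#' @param label A label string.
#' @return Integer vector of the Gleason patterns present in the label
#'   (empty for non-Gleason labels).
#' @export
labelPatterns <- function(label) {
  p <- parseRegionLabel(label)
  if (p$category != "gleason") return(integer(0))
  sort(unique(c(p$primary, p$secondary)))
}

#' Translate a Gleason pattern pair to an ISUP Grade Group
#'
#' Standard ISUP mapping of the (primary, secondary) Gleason pattern pair:
#' 3+3 -> GG1, 3+4 -> GG2, 4+3 -> GG3, 4+4 / 3+5 / 5+3 -> GG4,
#' 4+5 / 5+4 / 5+5 -> GG5.
#'
#' @param primary,secondary Integer Gleason patterns in `{3, 4, 5}`.
#' @return Integer Grade Group 1--5.
#' @examples
#' translateToGG(4, 3)  # GG 3
#' @export
translateToGG <- function(primary, secondary) {
  stopifnot(primary %in% 3:5, secondary %in% 3:5)
  score <- primary + secondary
  if (score == 6L) return(1L)
  if (score == 7L) return(if (primary == 3L) 2L else 3L)
  if (score == 8L) return(4L)
  5L
}
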