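## End-to-end orchestration and table rendering.
##
## runPipeline() turns a set of paired-observer cases into the four standard
## reports: per-specimen annotated areas + weighted DSC for tumour
## categories (table 1), the same for cribriform/IDC (table 2), slide-level
## Fleiss kappas (table 3) and index-lesion concordance (table 4), plus a
## JSON run manifest. aggregateFromRows() is the aggregation-only entry
## point: it reproduces the Total rows of such tables from their printed
## per-specimen rows.

.roundHalfEven <- function(x, digits) round(x, digits)  # R rounds half-even

#' Aggregate per-specimen rows into table totals
#'
#' Column sums for area columns; area-weighted pooling for weighted-DSC
#' columns (each specimen weighted by its two observers' combined annotated
#' area); optionally the unweighted mean of a DSC column.
#'
#' @param rows data.frame of per-specimen rows.
#' @param areaCols Character vector of area column names to sum.
#' @param dscCols Named list: DSC column name -> character vector of the two
#'   area columns giving that column's pooling weight.
#' @param meanCols Character vector of DSC columns to also average
#'   unweighted.
#' @return Named list of totals: `sum_<col>` for areas, `pooled_<col>` for
#'   weighted-DSC columns, `mean_<col>` for mean columns.
#' @examples
#' rows <- data.frame(a1 = c(1, 3), a2 = c(1, 3), d = c(0.5, 0.9))
#' aggregateFromRows(rows, "a1", list(d = c("a1", "a2")), "d")
#' @export
aggregateFromRows <- function(rows, areaCols = character(0),
                              dscCols = list(), meanCols = character(0)) {
  stopifnot(nrow(rows) >= 1L)
  out <- list()
  for (ac in areaCols) out[[paste0("sum_", ac)]] <- sum(rows[[ac]])
  for (dc in names(dscCols)) {
    w <- rowSums(rows[dscCols[[dc]]])
    out[[paste0("pooled_", dc)]] <- pooledWeightedDSC(rows[[dc]], w)
  }
  for (mc in meanCols) out[[paste0("mean_", mc)]] <- mean(rows[[mc]], na.rm = TRUE)
  out
}

#' Per-specimen surface-concordance table for a category pair
#'
#' @param cases Named list of [RPSCase-class] objects.
#' @param categories Category keys to tabulate side by side.
#' @return data.frame: one row per specimen with, per category, the two
#'   observers' total annotated areas and the weighted DSC; plus a list
#'   attribute `"totals"` with column sums and pooled weighted DSCs.
#' @export
cohortConcordanceTable <- function(cases, categories = c("any_pca", "cspca")) {
  rows <- lapply(cases, function(case) {
    row <- data.frame(specimenId = specimenId(case), stringsAsFactors = FALSE)
    for (key in categories) {
      cc <- caseConcordance(case, key)
      row[[paste0(key, "_p1_cm2")]] <- cc$sumX
      row[[paste0(key, "_p2_cm2")]] <- cc$sumY
      row[[paste0(key, "_wdsc")]] <- cc$weightedDSC
    }
    row
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  totals <- list()
  for (key in categories) {
    p1 <- paste0(key, "_p1_cm2"); p2 <- paste0(key, "_p2_cm2")
    dc <- paste0(key, "_wdsc")
    totals[[paste0("sum_", p1)]] <- sum(tab[[p1]])
    totals[[paste0("sum_", p2)]] <- sum(tab[[p2]])
    totals[[paste0("pooled_", dc)]] <-
      pooledWeightedDSC(tab[[dc]], tab[[p1]] + tab[[p2]])
  }
  attr(tab, "totals") <- totals
  tab
}

#' Per-specimen index-lesion table
#'
#' @param cases Named list of [RPSCase-class] objects.
#' @param adjacencyTolMm In-slide adjacency tolerance in mm.
#' @return data.frame with columns `specimenId`, `areaP1`, `areaP2`, `ggP1`,
#'   `ggP2`, `dsc`, `ggAgreement`; specimens where an observer annotated no
#'   tumour are reported with `NA` (unmatched). Summary via
#'   [cohortIndexSummary()] on the complete rows.
#' @export
cohortIndexTable <- function(cases, adjacencyTolMm = 0.5) {
  rows <- lapply(cases, function(case) {
    p <- indexConcordance(case, adjacencyTolMm)
    if (is.null(p))
      return(data.frame(specimenId = specimenId(case), areaP1 = NA_real_,
                        areaP2 = NA_real_, ggP1 = NA_integer_,
                        ggP2 = NA_integer_, dsc = NA_real_,
                        ggAgreement = NA, stringsAsFactors = FALSE))
    data.frame(specimenId = p$specimenId,
               areaP1 = p$lesionP1$totalAreaCm2,
               areaP2 = p$lesionP2$totalAreaCm2,
               ggP1 = p$ggP1, ggP2 = p$ggP2, dsc = p$dsc,
               ggAgreement = p$ggAgreement, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

#' Run the full concordance pipeline and write reports
#'
#' Computes surface concordance, slide-level agreement and index-lesion
#' concordance for a cohort of paired-observer cases and writes
#' `table1.csv` (tumour categories), `table2.csv` (cribriform/IDC),
#' `table3.csv` (slide-level kappas), `table4.csv` (index lesions), raw
#' unrounded companions (`*_raw.csv`) and `manifest.json`. Byte-identical
#' outputs for identical inputs and seed.
#'
#' @param cases Named list of [RPSCase-class] objects, or the path of a
#'   GeoJSON annotation file to read.
#' @param outDir Output directory (created if missing).
#' @param adjacencyTolMm In-slide adjacency tolerance in mm.
#' @param nBoot Bootstrap resamples for kappa CIs.
#' @param seed RNG seed for the bootstrap (recorded in the manifest).
#' @param digits Display rounding for the rounded CSVs (default 2).
#' @return Invisibly, a list with all computed tables and totals.
#' @export
runPipeline <- function(cases, outDir, adjacencyTolMm = 0.5, nBoot = 2000L,
                        seed = 1L, digits = 2L) {
  if (is.character(cases)) cases <- readAnnotationSet(cases)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  # a broken specimen is logged and skipped; the run continues
  ok <- vapply(cases, function(case) tryCatch({
    methods::validObject(case)
    TRUE
  }, error = function(e) {
    message(sprintf("skipping specimen %s: %s",
                    specimenId(case), conditionMessage(e)))
    FALSE
  }), TRUE)
  cases <- cases[ok]
  if (!length(cases)) stop("no valid specimens to process")

  t1 <- cohortConcordanceTable(cases, c("any_pca", "cspca"))
  t2 <- cohortConcordanceTable(cases, "cg_idc")
  # keep only specimens where either observer annotated cribriform/IDC
  t2 <- t2[t2$cg_idc_p1_cm2 + t2$cg_idc_p2_cm2 > 0, , drop = FALSE]
  t3 <- slideAgreementTable(cases, nBoot = nBoot, seed = seed)
  t4 <- cohortIndexTable(cases, adjacencyTolMm)

  writePair <- function(tab, name, totalRow = NULL) {
    raw <- tab
    if (!is.null(totalRow)) raw <- rbind(raw, totalRow)
    utils::write.csv(raw, file.path(outDir, paste0(name, "_raw.csv")),
                     row.names = FALSE)
    num <- vapply(raw, is.numeric, TRUE)
    raw[num] <- lapply(raw[num], .roundHalfEven, digits = digits)
    utils::write.csv(raw, file.path(outDir, paste0(name, ".csv")),
                     row.names = FALSE)
  }

  totalRow1 <- data.frame(
    specimenId = "Total",
    any_pca_p1_cm2 = sum(t1$any_pca_p1_cm2),
    any_pca_p2_cm2 = sum(t1$any_pca_p2_cm2),
    any_pca_wdsc = pooledWeightedDSC(t1$any_pca_wdsc,
                                     t1$any_pca_p1_cm2 + t1$any_pca_p2_cm2),
    cspca_p1_cm2 = sum(t1$cspca_p1_cm2),
    cspca_p2_cm2 = sum(t1$cspca_p2_cm2),
    cspca_wdsc = pooledWeightedDSC(t1$cspca_wdsc,
                                   t1$cspca_p1_cm2 + t1$cspca_p2_cm2),
    stringsAsFactors = FALSE)
  writePair(t1, "table1", totalRow1)

  if (nrow(t2)) {
    totalRow2 <- data.frame(
      specimenId = "Total",
      cg_idc_p1_cm2 = sum(t2$cg_idc_p1_cm2),
      cg_idc_p2_cm2 = sum(t2$cg_idc_p2_cm2),
      cg_idc_wdsc = pooledWeightedDSC(t2$cg_idc_wdsc,
                                      t2$cg_idc_p1_cm2 + t2$cg_idc_p2_cm2),
      stringsAsFactors = FALSE)
    writePair(t2, "table2", totalRow2)
  } else writePair(t2, "table2")

  writePair(t3, "table3")

  ok <- stats::complete.cases(t4[c("dsc", "ggP1", "ggP2")])
  idxSummary <- if (any(ok)) cohortIndexSummary(
    data.frame(areaP1 = t4$areaP1[ok], areaP2 = t4$areaP2[ok],
               dsc = t4$dsc[ok], ggP1 = t4$ggP1[ok], ggP2 = t4$ggP2[ok]))
    else NULL
  totalRow4 <- if (!is.null(idxSummary)) data.frame(
    specimenId = "Total", areaP1 = sum(t4$areaP1[ok]),
    areaP2 = sum(t4$areaP2[ok]), ggP1 = NA_integer_, ggP2 = NA_integer_,
    dsc = idxSummary$pooledWeightedDSC, ggAgreement = NA,
    stringsAsFactors = FALSE) else NULL
  writePair(t4, "table4", totalRow4)

  manifest <- list(
    package = "histoConcord",
    version = as.character(utils::packageVersion("histoConcord")),
    seed = seed, nBoot = nBoot, adjacencyTolMm = adjacencyTolMm,
    digits = digits, nSpecimens = length(cases),
    nSlides = sum(vapply(cases, slideCount, 1L)),
    indexSummary = idxSummary)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(table1 = t1, table2 = t2, table3 = t3, table4 = t4,
                 table1Totals = totalRow1, indexSummary = idxSummary,
                 manifest = manifest))
}

#' Bundled per-specimen summary tables from the motivating study
#'
#' Plain-CSV copies of the printed per-specimen summary rows of the
#' two-observer whole-mount annotation study this pipeline operationalizes:
#' annotated areas and weighted DSC for tumour categories
#' (`"areas_pca"`), for cribriform/IDC (`"areas_cgidc"`), slide-level
#' positive-call counts (`"slide_calls"`) and index-lesion characteristics
#' (`"index_lesions"`). These serve as inputs to the aggregation layer
#' ([aggregateFromRows()], [cohortIndexSummary()]).
#'
#' @param which One of `"areas_pca"`, `"areas_cgidc"`, `"slide_calls"`,
#'   `"index_lesions"`.
#' @return data.frame of the printed rows.
#' @examples
#' head(studyTable("areas_pca"))
#' @export
studyTable <- function(which = c("areas_pca", "areas_cgidc", "slide_calls",
                                 "index_lesions")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("study_", which, ".csv"),
                      package = "histoConcord", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
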