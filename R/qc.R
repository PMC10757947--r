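#' Analyte quality control
#'
#' Analytes are screened with two rules before analysis: (1) a
#' limit-of-detection rule on the amount per mg dry weight, and (2) a
#' coefficient-of-variation rule computed from recurrent quality-control-pool
#' measurements. Both thresholds are strict inequalities: boundary values are
#' retained.
#'
#' @name qc
NULL

#' Coefficient of variation of an analyte over QC-pool samples
#'
#' Sample standard deviation (n - 1 denominator by default) of the analyte's
#' amounts in the QC-pool samples divided by their mean. A zero mean yields
#' `Inf` (the analyte will be removed by the CV filter).
#'
#' @param table A [lipidome_table()] with at least two QC-pool samples.
#' @param analyte Analyte name.
#' @param denominator `"n-1"` (default, conventional for QC CV) or `"n"`.
#' @return The CV as a single number (possibly `Inf`).
#' @export
compute_analyte_cv <- function(table, analyte, denominator = c("n-1", "n")) {
  stopifnot(inherits(table, "lipidome_table"))
  denominator <- match.arg(denominator)
  if (!analyte %in% colnames(table$amounts)) {
    stop("unknown analyte '", analyte, "'")
  }
  qc <- table$amounts[.qc_idx(table), analyte]
  if (length(qc) < 2) stop("need at least 2 QC-pool samples to compute a CV")
  s <- stats::sd(qc)
  if (denominator == "n") s <- s * sqrt((length(qc) - 1) / length(qc))
  m <- mean(qc)
  if (m == 0) return(Inf)
  s / m
}

#' Apply analyte quality filters
#'
#' Removes an analyte when its mean amount over experimental (non-QC)
#' samples is strictly below the limit of detection, or its QC-pool CV is
#' strictly above `cv_max`. Exact boundary values (`lod`, `cv_max`) are
#' retained.
#'
#' @param table A [lipidome_table()] with QC-pool samples.
#' @param lod Limit of detection on the amount scale (default 0.00005,
#'   i.e. 0.00005 nmol-equivalents of internal standard per mg).
#' @param cv_max Maximum allowed QC coefficient of variation (default 0.3).
#' @param lod_rule How the LOD rule aggregates over experimental samples:
#'   `"mean"` (default) removes when the mean is below `lod`; `"all"` when
#'   every sample is below; `"any"` when any sample is below.
#' @return A list with `table` (the filtered [lipidome_table()]) and
#'   `report`, a tibble with one row per removed analyte: `analyte`,
#'   `reason` ("CV" or "LOD"), `value`, `threshold`. Analytes failing both
#'   rules are reported once with reason "LOD".
#' @export
apply_qc_filters <- function(table, lod = 0.00005, cv_max = 0.3,
                             lod_rule = c("mean", "all", "any")) {
  stopifnot(inherits(table, "lipidome_table"))
  lod_rule <- match.arg(lod_rule)
  analytes <- colnames(table$amounts)
  exp_amounts <- table$amounts[.exp_idx(table), , drop = FALSE]
  lod_stat <- switch(
    lod_rule,
    mean = colMeans(exp_amounts),
    all = apply(exp_amounts, 2, max),
    any = apply(exp_amounts, 2, min)
  )
  fails_lod <- lod_stat < lod
  cvs <- vapply(analytes, function(a) compute_analyte_cv(table, a), numeric(1))
  fails_cv <- cvs > cv_max

  removed <- fails_lod | fails_cv
  report <- tibble::tibble(
    analyte = analytes[removed],
    reason = unname(ifelse(fails_lod[removed], "LOD", "CV")),
    value = unname(ifelse(fails_lod[removed], lod_stat[removed], cvs[removed])),
    threshold = unname(ifelse(fails_lod[removed], lod, cv_max))
  )
  keep <- analytes[!removed]
  if (length(keep) == 0) stop("all analytes were removed by the QC filters")
  filtered <- lipidome_table(table$samples,
                             table$amounts[, keep, drop = FALSE])
  list(table = filtered, report = report)
}

#' Write a QC removal report to TSV
#'
#' @param report The `report` tibble from [apply_qc_filters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
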