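#' Lipidome table container
#'
#' A `lipidome_table` holds a sample-by-analyte matrix of normalized mass
#' spectral signal per mg leaf dry weight (a value of 1 corresponds to the
#' intensity of 1 nmol of internal standard), sample metadata (genotype,
#' treatment, experimental run, block, QC-pool flag), and the parsed
#' [parse_species()] objects of the analytes.
#'
#' @name lipidome-table
NULL

#' Construct a lipidome table
#'
#' @param samples A data frame with columns `sample_id`, `genotype`,
#'   `treatment` ("OT"/"HT"), `run`, `block`, `is_qc_pool`. QC-pool rows may
#'   carry `NA` genotype/treatment/run/block.
#' @param amounts A numeric sample x analyte matrix (non-negative); row names
#'   must match `samples$sample_id`, column names are species shorthand.
#' @return An object of class `lipidome_table`.
#' @export
lipidome_table <- function(samples, amounts) {
  samples <- tibble::as_tibble(samples)
  required <- c("sample_id", "genotype", "treatment", "run", "block",
                "is_qc_pool")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0) {
    stop("sample metadata lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id values")
  amounts <- as.matrix(amounts)
  storage.mode(amounts) <- "double"
  if (is.null(rownames(amounts)) || is.null(colnames(amounts))) {
    stop("amounts matrix must have sample row names and analyte column names")
  }
  if (anyDuplicated(colnames(amounts))) stop("duplicate analyte names")
  if (!identical(sort(rownames(amounts)), sort(as.character(samples$sample_id)))) {
    stop("amounts row names must match samples$sample_id")
  }
  amounts <- amounts[as.character(samples$sample_id), , drop = FALSE]
  if (anyNA(amounts)) stop("missing amount cells are not allowed; use explicit 0")
  if (any(amounts < 0)) stop("negative amounts are not allowed")
  exp_trt <- samples$treatment[!samples$is_qc_pool]
  if (!all(exp_trt %in% c("OT", "HT"))) {
    stop("treatment must be 'OT' or 'HT' for experimental samples")
  }
  species <- lapply(colnames(amounts), parse_species)
  names(species) <- colnames(amounts)
  structure(
    list(samples = samples, amounts = amounts, species = species),
    class = "lipidome_table"
  )
}

#' @export
print.lipidome_table <- function(x, ...) {
  n_qc <- sum(x$samples$is_qc_pool)
  cat("<lipidome_table> ", nrow(x$amounts), " samples (", n_qc, " QC pool) x ",
      ncol(x$amounts), " analytes\n", sep = "")
  trt <- table(x$samples$treatment[!x$samples$is_qc_pool])
  cat("  treatments:", paste(names(trt), trt, sep = "=", collapse = ", "), "\n")
  cat("  genotypes:", length(unique(stats::na.omit(
    x$samples$genotype[!x$samples$is_qc_pool]))), "\n")
  invisible(x)
}

#' Analyte names of a lipidome table
#' @param table A `lipidome_table`.
#' @return Character vector of analyte shorthand names.
#' @export
analyte_names <- function(table) {
  stopifnot(inherits(table, "lipidome_table"))
  colnames(table$amounts)
}

#' Headgroup class of each analyte
#' @param table A `lipidome_table`.
#' @return Named character vector, analyte -> headgroup class code.
#' @export
analyte_classes <- function(table) {
  stopifnot(inherits(table, "lipidome_table"))
  vapply(table$species, function(s) s$headgroup$name, character(1))
}

# experimental (non-QC) subset helpers
.exp_idx <- function(table) which(!table$samples$is_qc_pool)
.qc_idx <- function(table) which(table$samples$is_qc_pool)

#' Read a lipidome table from CSV/TSV
#'
#' Long format has columns `sample_id`, `genotype`, `treatment`, `run`,
#' `block`, `is_qc_pool`, `species`, `amount` (one row per cell). Wide format
#' has the same metadata columns followed by one column per species. Species
#' names are validated with [parse_species()]; unparseable names are reported
#' with their row (long) or column (wide).
#'
#' @param path Path to a CSV or TSV file (UTF-8, "." decimal separator).
#' @param format `"long"` or `"wide"`.
#' @param sep Field separator; default guessed from the file extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @return A [lipidome_table()].
#' @export
read_lipidome <- function(path, format = c("long", "wide"), sep = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  meta_cols <- c("sample_id", "genotype", "treatment", "run", "block",
                 "is_qc_pool")
  if (format == "long") {
    required <- c(meta_cols, "species", "amount")
    missing <- setdiff(required, names(df))
    if (length(missing) > 0) {
      stop("missing required column(s): ", paste(missing, collapse = ", "))
    }
    for (i in seq_along(df$species)) {
      tryCatch(parse_species(df$species[i]),
               error = function(e) {
                 stop("row ", i, ": ", conditionMessage(e), call. = FALSE)
               })
    }
    if (any(is.na(df$amount))) stop("missing amount values")
    if (any(df$amount < 0)) stop("negative amount values")
    samples <- unique(df[meta_cols])
    sp <- unique(df$species)
    amounts <- matrix(NA_real_, nrow = nrow(samples), ncol = length(sp),
                      dimnames = list(samples$sample_id, sp))
    amounts[cbind(match(df$sample_id, samples$sample_id),
                  match(df$species, sp))] <- df$amount
    if (anyNA(amounts)) stop("long table is not complete: missing cells")
  } else {
    missing <- setdiff(meta_cols, names(df))
    if (length(missing) > 0) {
      stop("missing required column(s): ", paste(missing, collapse = ", "))
    }
    sp <- setdiff(names(df), meta_cols)
    if (length(sp) == 0) stop("wide table has no species columns")
    for (s in sp) {
      tryCatch(parse_species(s),
               error = function(e) {
                 stop("column '", s, "': ", conditionMessage(e), call. = FALSE)
               })
    }
    samples <- df[meta_cols]
    amounts <- as.matrix(df[sp])
    rownames(amounts) <- samples$sample_id
  }
  samples$is_qc_pool <- as.logical(samples$is_qc_pool)
  lipidome_table(samples, amounts)
}

#' Write a lipidome table to CSV/TSV
#'
#' @param table A `lipidome_table`.
#' @param path Output path.
#' @param format `"long"` or `"wide"`.
#' @param sep Field separator; default guessed from the extension as in
#'   [read_lipidome()].
#' @return `path`, invisibly.
#' @export
write_lipidome <- function(table, path, format = c("long", "wide"), sep = NULL) {
  stopifnot(inherits(table, "lipidome_table"))
  format <- match.arg(format)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  meta <- as.data.frame(table$samples)
  if (format == "wide") {
    out <- cbind(meta, as.data.frame(table$amounts, check.names = FALSE))
  } else {
    sp <- colnames(table$amounts)
    out <- data.frame(
      meta[rep(seq_len(nrow(meta)), times = length(sp)), , drop = FALSE],
      species = rep(sp, each = nrow(meta)),
      amount = as.vector(table$amounts),
      check.names = FALSE, row.names = NULL
    )
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
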