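#' Remodeling statistics
#'
#' Class totals and composition shares, unsaturation indices, the
#' occurrence-weighted acyl-chain fold-change matrix, and treatment
#' comparisons with least-squares means and Fisher's LSD.
#'
#' @name remodeling-stats
NULL

#' Unsaturation index of a lipid molecular species
#'
#' The average number of C-C double bonds per acyl chain: total double-bond
#' equivalents divided by the number of acyl positions of the headgroup
#' class. Extra oxygens are ignored.
#'
#' @param species A `lipid_species` from [parse_species()].
#' @return The unsaturation index (>= 0).
#' @export
#' @examples
#' species_unsaturation_index(parse_species("DGDG 36:6"))        # 3
#' species_unsaturation_index(parse_species("TG 18:3_18:3_18:2")) # 8/3
species_unsaturation_index <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  n_pos <- species$headgroup$n_acyl_positions
  if (is.na(n_pos) || n_pos < 1L) {
    stop("class '", species$headgroup$name,
         "' has no defined acyl-chain count; unsaturation index unsupported")
  }
  species$total_double_bonds / n_pos
}

#' Unsaturation index of a headgroup class
#'
#' Amount-weighted mean of the member species' unsaturation indices:
#' sum(species index x species amount) / sum(species amount), with amounts
#' aggregated over the selected samples.
#'
#' @param table A [lipidome_table()].
#' @param class Headgroup class code (e.g. "DGDG").
#' @param samples Optional character vector of sample ids to aggregate over;
#'   default all experimental (non-QC) samples.
#' @return The class unsaturation index.
#' @export
class_unsaturation_index <- function(table, class, samples = NULL) {
  stopifnot(inherits(table, "lipidome_table"))
  cls <- analyte_classes(table)
  members <- names(cls)[cls == class]
  if (length(members) == 0) stop("no analytes of class '", class, "' in table")
  if (is.null(samples)) {
    rows <- .exp_idx(table)
  } else {
    rows <- match(samples, table$samples$sample_id)
    if (anyNA(rows)) stop("unknown sample id(s)")
  }
  amt <- table$amounts[rows, members, drop = FALSE]
  weights <- colMeans(amt)
  total <- sum(weights)
  if (total <= 0) {
    stop("class '", class, "' has zero total amount in the selected samples")
  }
  ui <- vapply(table$species[members], species_unsaturation_index, numeric(1))
  sum(ui * weights) / total
}

#' Per-sample class unsaturation indices
#'
#' Computes the amount-weighted class unsaturation index separately within
#' each experimental sample, giving a sample x class matrix suitable as
#' trait input to [treatment_comparison()].
#'
#' @param table A [lipidome_table()].
#' @param classes Classes to include; default all classes with a defined
#'   acyl-chain count present in the table.
#' @return Numeric matrix, experimental samples x classes. Cells where a
#'   sample has zero total class amount are `NA`.
#' @export
unsaturation_indices <- function(table, classes = NULL) {
  stopifnot(inherits(table, "lipidome_table"))
  cls <- analyte_classes(table)
  supported <- vapply(table$species, function(s) {
    np <- s$headgroup$n_acyl_positions
    !is.na(np) && np >= 1L
  }, logical(1))
  if (is.null(classes)) classes <- sort(unique(cls[supported]))
  rows <- .exp_idx(table)
  out <- matrix(NA_real_, length(rows), length(classes),
                dimnames = list(table$samples$sample_id[rows], classes))
  for (cl in classes) {
    members <- names(cls)[cls == cl & supported]
    if (length(members) == 0) next
    amt <- table$amounts[rows, members, drop = FALSE]
    ui <- vapply(table$species[members], species_unsaturation_index, numeric(1))
    tot <- rowSums(amt)
    val <- as.vector(amt %*% ui) / tot
    val[tot <= 0] <- NA_real_
    out[, cl] <- val
  }
  out
}

#' Class totals and composition shares by treatment
#'
#' Per treatment and headgroup class: the sum of per-species treatment
#' LS-means, and the share of the lipidome-wide total signal.
#'
#' @param table A [lipidome_table()].
#' @param separate_ox If `TRUE`, species with extra oxygens are bucketed
#'   into a pseudo-class "ox-lipid" instead of their headgroup class.
#' @param use_ls_means If `TRUE` (default) species amounts per treatment are
#'   LS-means from the factorial block model; if `FALSE`, arithmetic
#'   treatment means (identical on balanced designs).
#' @return A tibble with columns `class`, `treatment`, `total`, `share`;
#'   shares sum to 1 within each treatment.
#' @export
class_totals_and_shares <- function(table, separate_ox = FALSE,
                                    use_ls_means = TRUE) {
  stopifnot(inherits(table, "lipidome_table"))
  cls <- analyte_classes(table)
  if (separate_ox) {
    ox <- vapply(table$species, function(s) s$total_extra_oxygens > 0L,
                 logical(1))
    cls[ox] <- "ox-lipid"
  }
  Y <- .exp_amounts(table)
  meta <- table$samples[.exp_idx(table), ]
  if (use_ls_means) {
    ctx <- .design_context(meta)
    fit <- .fit_lsmeans(ctx, Y)
    per_trt <- rbind(OT = fit$ot, HT = fit$ht)
  } else {
    per_trt <- rbind(
      OT = colMeans(Y[meta$treatment == "OT", , drop = FALSE]),
      HT = colMeans(Y[meta$treatment == "HT", , drop = FALSE])
    )
  }
  out <- list()
  for (trt in rownames(per_trt)) {
    totals <- tapply(per_trt[trt, ], cls, sum)
    grand <- sum(totals)
    if (grand <= 0) stop("zero total signal under treatment ", trt)
    out[[trt]] <- tibble::tibble(
      class = names(totals), treatment = trt,
      total = as.numeric(totals), share = as.numeric(totals) / grand
    )
  }
  do.call(rbind, out)
}

#' Percent change from OT to HT
#'
#' @param ot Amount under optimal temperature (> 0).
#' @param ht Amount under high temperature.
#' @return `100 * (ht - ot) / ot`.
#' @export
#' @examples
#' percent_change(1.0, 2.52)  # +152
percent_change <- function(ot, ht) {
  if (any(ot <= 0)) stop("percent change undefined for ot <= 0")
  100 * (ht - ot) / ot
}

#' Treatment comparison with LS-means and Fisher's LSD
#'
#' Fits the two-factor factorial block model (genotype, treatment, their
#' interaction, and run-by-replication block effects) to each response and
#' compares treatment LS-means with Fisher's least significant difference at
#' level `alpha`.
#'
#' @param table A [lipidome_table()].
#' @param responses Analyte names (`level = "analyte"`) or class codes
#'   (`level = "class"`, responses are per-sample class totals). Default:
#'   all analytes / all classes.
#' @param level `"analyte"` or `"class"`.
#' @param traits Optional numeric matrix or data frame of additional
#'   response columns (e.g. physiological traits or the output of
#'   [unsaturation_indices()]), rows matching the experimental samples.
#' @param alpha Significance level for the LSD test (default 0.05).
#' @return A tibble with one row per response: `response`, `ot_lsmean`,
#'   `ht_lsmean`, `se_ot`, `se_ht`, `percent_change`, `lsd`, `significant`.
#'   `significant` is `TRUE` iff |HT - OT| exceeds the LSD threshold.
#'   Percent change is `NA` when the OT LS-mean is not positive.
#' @export
treatment_comparison <- function(table, responses = NULL,
                                 level = c("analyte", "class"),
                                 traits = NULL, alpha = 0.05) {
  stopifnot(inherits(table, "lipidome_table"))
  level <- match.arg(level)
  Yexp <- .exp_amounts(table)
  if (level == "analyte") {
    if (is.null(responses)) responses <- colnames(Yexp)
    unknown <- setdiff(responses, colnames(Yexp))
    if (length(unknown) > 0) {
      stop("unknown analyte(s): ", paste(unknown, collapse = ", "))
    }
    Y <- Yexp[, responses, drop = FALSE]
  } else {
    cls <- analyte_classes(table)
    if (is.null(responses)) responses <- sort(unique(cls))
    unknown <- setdiff(responses, cls)
    if (length(unknown) > 0) {
      stop("unknown class(es): ", paste(unknown, collapse = ", "))
    }
    Y <- vapply(responses, function(cl) {
      rowSums(Yexp[, cls == cl, drop = FALSE])
    }, numeric(nrow(Yexp)))
    colnames(Y) <- responses
  }
  if (!is.null(traits)) {
    traits <- as.matrix(traits)
    if (nrow(traits) != nrow(Y)) {
      stop("traits must have one row per experimental sample")
    }
    if (is.null(colnames(traits))) {
      colnames(traits) <- paste0("trait", seq_len(ncol(traits)))
    }
    Y <- cbind(Y, traits)
  }
  ctx <- .table_context(table)
  fit <- .fit_lsmeans(ctx, Y, alpha = alpha)
  pc <- ifelse(fit$ot > 0, 100 * (fit$ht - fit$ot) / fit$ot, NA_real_)
  tibble::tibble(
    response = colnames(Y),
    ot_lsmean = unname(fit$ot), ht_lsmean = unname(fit$ht),
    se_ot = unname(fit$se_ot), se_ht = unname(fit$se_ht),
    percent_change = unname(pc),
    lsd = unname(fit$lsd),
    significant = unname(abs(fit$ht - fit$ot) > fit$lsd)
  )
}

#' Occurrence-weighted acyl-chain fold-change matrix
#'
#' For each headgroup class and acyl chain, computes the ratio of the
#' occurrence-weighted summed amounts under HT to those under OT: the sum
#' over the class's acyl-resolved species of (species amount x number of
#' occurrences of the chain in that species), with per-treatment amounts
#' taken as LS-means from the factorial block model. Only species whose
#' fatty acyl composition is unambiguous contribute. Significance per cell
#' comes from the LSD test applied to the per-sample occurrence-weighted
#' sums. Oxidized chains (";O") are distinct columns from their unoxidized
#' forms.
#'
#' @param table A [lipidome_table()].
#' @param alpha Significance level for the per-cell LSD test.
#' @return An object of class `fold_change_matrix`: list with `fold_change`
#'   (class x chain matrix, `NA` where the chain is absent from the class's
#'   resolved species), `significant` (same shape), and `details`, a tibble
#'   with one row per defined cell (`class`, `chain`, `ot_sum`, `ht_sum`,
#'   `fold_change`, `lsd`, `significant`).
#' @export
acyl_fold_change <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "lipidome_table"))
  resolved <- names(table$species)[vapply(table$species,
                                          function(s) s$acyl_resolved,
                                          logical(1))]
  if (length(resolved) == 0) stop("no acyl-resolved species in table")
  cls <- analyte_classes(table)[resolved]
  occ <- lapply(table$species[resolved], count_acyl_occurrences)

  chain_keys <- sort(unique(unlist(lapply(occ, names))))
  chain_ord <- order(vapply(chain_keys, function(k) {
    ch <- .parse_chain(k)
    ch$carbons * 1e4 + ch$double_bonds * 1e2 + ch$extra_oxygens
  }, numeric(1)))
  chain_keys <- chain_keys[chain_ord]
  class_keys <- unique(cls)

  # per (class, chain): analyte weight vector of occurrence counts
  cells <- list()
  for (cl in class_keys) {
    members <- resolved[cls == cl]
    for (k in chain_keys) {
      w <- vapply(members, function(a) {
        cnt <- occ[[a]]
        if (k %in% names(cnt)) as.numeric(cnt[[k]]) else 0
      }, numeric(1))
      if (sum(w) > 0) {
        cells[[length(cells) + 1]] <- list(class = cl, chain = k,
                                           members = members, w = w)
      }
    }
  }
  Yexp <- .exp_amounts(table)
  W <- vapply(cells, function(cell) {
    as.vector(Yexp[, cell$members, drop = FALSE] %*% cell$w)
  }, numeric(nrow(Yexp)))
  ctx <- .table_context(table)
  fit <- .fit_lsmeans(ctx, W, alpha = alpha)

  fc_mat <- matrix(NA_real_, length(class_keys), length(chain_keys),
                   dimnames = list(class_keys, chain_keys))
  sig_mat <- matrix(NA, length(class_keys), length(chain_keys),
                    dimnames = list(class_keys, chain_keys))
  details <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cl <- cells[[i]]$class; k <- cells[[i]]$chain
    ot <- fit$ot[i]; ht <- fit$ht[i]
    fc <- if (ot > 0) ht / ot else NA_real_
    sig <- abs(ht - ot) > fit$lsd[i]
    fc_mat[cl, k] <- fc
    sig_mat[cl, k] <- sig
    details[[i]] <- tibble::tibble(
      class = cl, chain = k, ot_sum = ot, ht_sum = ht, fold_change = fc,
      lsd = fit$lsd[i], significant = sig
    )
  }
  structure(
    list(fold_change = fc_mat, significant = sig_mat,
         details = do.call(rbind, details)),
    class = "fold_change_matrix"
  )
}

#' @export
print.fold_change_matrix <- function(x, ...) {
  cat("<fold_change_matrix> ", nrow(x$fold_change), " classes x ",
      ncol(x$fold_change), " acyl chains (",
      sum(!is.na(x$fold_change)), " defined cells)\n", sep = "")
  print(round(x$fold_change, 2))
  invisible(x)
}
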