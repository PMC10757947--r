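# Least-squares-mean engine for the two-factor RCBD design.
#
# The experiment crosses genotype and temperature treatment in a randomized
# complete block design replicated over experimental runs. The model fitted
# is
#
#   y ~ genotype * treatment + block
#
# where `block` is the run-by-replication factor (blocks nested in runs; the
# factor absorbs run mean differences, so runs are pooled as in the source
# design). Treatment LS-means average the fitted cell means over genotypes
# and blocks; on balanced data they equal arithmetic treatment means. The
# LSD threshold uses the exact variance of the HT - OT contrast,
# t(1 - alpha/2, df) * sqrt(L' (X'X)^-1 L * MSE), which reduces to the
# textbook t * sqrt(2 * MSE / n) on balanced designs.
#
# All analytes share one design matrix, so a single QR factorization serves
# the whole amounts matrix.

# Build the design context from experimental-sample metadata.
.design_context <- function(meta) {
  stopifnot(all(!meta$is_qc_pool))
  if (anyNA(meta$genotype) || anyNA(meta$treatment)) {
    stop("experimental samples must have genotype and treatment")
  }
  geno <- factor(meta$genotype)
  trt <- factor(meta$treatment, levels = c("OT", "HT"))
  if (any(table(trt) == 0)) {
    stop("both OT and HT must have at least one observation")
  }
  block <- factor(paste(meta$run, meta$block, sep = "."))
  dat <- data.frame(genotype = geno, treatment = trt, block = block)
  # drop single-level factors (tiny toy designs) so model.matrix stays valid
  terms <- c(if (nlevels(geno) > 1) "genotype", "treatment",
             if (nlevels(geno) > 1) "genotype:treatment",
             if (nlevels(block) > 1) "block")
  form <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(form, dat)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    stop("design matrix is rank deficient; check genotype/treatment/block coding")
  }
  # prediction grid: every genotype x treatment x block combination
  grid <- expand.grid(genotype = levels(geno), treatment = levels(trt),
                      block = levels(block), KEEP.OUT.ATTRS = FALSE)
  Xg <- stats::model.matrix(form, grid)
  # averaging operators: rows of Xg -> one contrast row per treatment and
  # one per genotype x treatment cell
  trt_rows <- split(seq_len(nrow(grid)), grid$treatment)
  L_trt <- t(vapply(trt_rows, function(ii) colMeans(Xg[ii, , drop = FALSE]),
                    numeric(ncol(Xg))))
  cell_key <- interaction(grid$genotype, grid$treatment, sep = "\r")
  cell_rows <- split(seq_len(nrow(grid)), cell_key)
  L_cell <- t(vapply(cell_rows, function(ii) colMeans(Xg[ii, , drop = FALSE]),
                     numeric(ncol(Xg))))
  cell_meta <- do.call(rbind, strsplit(names(cell_rows), "\r", fixed = TRUE))
  xtx_inv <- chol2inv(qr.R(qr_x))
  list(
    qr = qr_x, n = nrow(X), rank = qr_x$rank,
    df_error = nrow(X) - qr_x$rank,
    L_trt = L_trt, L_cell = L_cell,
    cell_genotype = cell_meta[, 1], cell_treatment = cell_meta[, 2],
    xtx_inv = xtx_inv,
    n_genotypes = nlevels(geno), n_blocks = nlevels(block)
  )
}

# Fit all columns of Y at once; returns per-column LS-means, SEs, LSD.
.fit_lsmeans <- function(ctx, Y, alpha = 0.05) {
  Y <- as.matrix(Y)
  B <- qr.coef(ctx$qr, Y)
  B[is.na(B)] <- 0
  fitted <- qr.fitted(ctx$qr, Y)
  rss <- colSums((Y - fitted)^2)
  mse <- rss / ctx$df_error
  lsm <- ctx$L_trt %*% B  # 2 x p: rows OT, HT
  se_var <- vapply(rownames(ctx$L_trt), function(r) {
    l <- ctx$L_trt[r, ]
    drop(l %*% ctx$xtx_inv %*% l)
  }, numeric(1))
  l_diff <- ctx$L_trt["HT", ] - ctx$L_trt["OT", ]
  c_diff <- drop(l_diff %*% ctx$xtx_inv %*% l_diff)
  tcrit <- stats::qt(1 - alpha / 2, ctx$df_error)
  lsd <- tcrit * sqrt(c_diff * mse)
  list(
    ot = lsm["OT", ], ht = lsm["HT", ],
    se_ot = sqrt(se_var["OT"] * mse), se_ht = sqrt(se_var["HT"] * mse),
    mse = mse, df_error = ctx$df_error, lsd = lsd,
    n_per_mean = ctx$n / 2, coef = B
  )
}

# Genotype x treatment cell LS-means for all columns of Y.
.fit_cell_lsmeans <- function(ctx, Y) {
  B <- qr.coef(ctx$qr, as.matrix(Y))
  B[is.na(B)] <- 0
  cells <- ctx$L_cell %*% B
  list(values = cells, genotype = ctx$cell_genotype,
       treatment = ctx$cell_treatment)
}

# Convenience: context from a lipidome_table's experimental samples.
.table_context <- function(table) {
  meta <- table$samples[.exp_idx(table), ]
  .design_context(meta)
}

.exp_amounts <- function(table) {
  table$amounts[.exp_idx(table), , drop = FALSE]
}
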