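# Fixture builders used across the suite. All synthetic, built in code.

# Balanced experimental metadata: genotypes x {OT, HT} x runs x blocks,
# optionally followed by QC-pool samples.
balanced_meta <- function(n_geno = 2, n_run = 1, n_block = 3, n_qc = 0) {
  design <- expand.grid(genotype = sprintf("g%02d", seq_len(n_geno)),
                        treatment = c("OT", "HT"),
                        run = seq_len(n_run), block = seq_len(n_block),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(nrow(design))),
    genotype = design$genotype, treatment = design$treatment,
    run = design$run, block = design$block, is_qc_pool = FALSE
  )
  if (n_qc > 0) {
    meta <- rbind(meta, tibble::tibble(
      sample_id = sprintf("qc%02d", seq_len(n_qc)),
      genotype = NA_character_, treatment = NA_character_,
      run = NA_integer_, block = NA_integer_, is_qc_pool = TRUE
    ))
  }
  meta
}

# Table whose experimental amounts depend only on treatment: each species
# gets `ot` under OT and `ht` under HT (noise-free). QC samples get the
# values in `qc` (a species x n_qc matrix or a single vector recycled).
treatment_table <- function(species, ot, ht, n_geno = 2, n_run = 1,
                            n_block = 3, qc = NULL) {
  n_qc <- if (is.null(qc)) 0 else ncol(as.matrix(qc))
  meta <- balanced_meta(n_geno, n_run, n_block, n_qc)
  expm <- meta[!meta$is_qc_pool, ]
  amounts <- matrix(NA_real_, nrow(meta), length(species),
                    dimnames = list(meta$sample_id, species))
  for (j in seq_along(species)) {
    amounts[seq_len(nrow(expm)), j] <- ifelse(expm$treatment == "HT",
                                              ht[j], ot[j])
  }
  if (n_qc > 0) {
    amounts[meta$is_qc_pool, ] <- t(as.matrix(qc))
  }
  lipidome_table(meta, amounts)
}

# Random resolved-species table for oracle comparisons: <= 20 species drawn
# from several classes, balanced design, lognormal amounts.
random_resolved_table <- function(seed, n_species = 12, n_geno = 3,
                                  n_block = 2) {
  set.seed(seed)
  pool <- c(
    paste("DGDG", c("18:3_18:3", "18:3_16:0", "18:2_16:0", "16:0_16:0",
                    "16:0_18:3;O")),
    paste("PC", c("16:0_18:3", "16:0_18:2", "18:2_18:2", "18:3_18:3")),
    paste("TG", c("18:3_18:3_18:3", "18:3_18:3_18:2", "16:0_18:2_18:2")),
    paste("PG", c("18:3_16:1", "18:2_16:0")),
    c("sitosterol 18:2", "sitosterol 18:3", "LPC 16:0", "MGMG 18:3",
      "Sitosterol-Glc 16:0", "DG 16:0_18:2")
  )
  species <- sample(pool, min(n_species, length(pool)))
  meta <- balanced_meta(n_geno, 1, n_block, n_qc = 0)
  amounts <- matrix(stats::rlnorm(nrow(meta) * length(species), 0, 0.4),
                    nrow(meta), length(species),
                    dimnames = list(meta$sample_id, species))
  lipidome_table(meta, amounts)
}

# Brute-force occurrence-weighted fold change: enumerates (species, chain)
# pairs one at a time on arithmetic treatment means (equal to LS-means on
# these balanced designs). Independent of the package's vectorized path.
brute_force_fold_change <- function(table) {
  meta <- table$samples[!table$samples$is_qc_pool, ]
  amt <- table$amounts[meta$sample_id, , drop = FALSE]
  ot_mean <- colMeans(amt[meta$treatment == "OT", , drop = FALSE])
  ht_mean <- colMeans(amt[meta$treatment == "HT", , drop = FALSE])
  out <- list()
  for (a in colnames(amt)) {
    sp <- table$species[[a]]
    if (!sp$acyl_resolved) next
    for (ch in sp$chains) {
      key <- format(ch)
      cell <- paste(sp$headgroup$name, key, sep = "|")
      if (is.null(out[[cell]])) out[[cell]] <- c(ot = 0, ht = 0)
      out[[cell]] <- out[[cell]] + c(ot = ot_mean[[a]], ht = ht_mean[[a]])
    }
  }
  fc <- vapply(out, function(v) unname(v["ht"] / v["ot"]), numeric(1))
  names(fc) <- names(out)
  fc
}

# Tiny default-structure generation shared by slower tests (computed once).
default_gen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_lipidome(remodel_config(seed = 42))
    cache
  }
})
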