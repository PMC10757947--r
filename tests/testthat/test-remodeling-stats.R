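test_that("species unsaturation index is double bonds per acyl position", {
  expect_equal(species_unsaturation_index(parse_species("DGDG 36:6")), 3)
  expect_equal(species_unsaturation_index(parse_species("TG 18:3_18:3_18:2")),
               8 / 3)
  expect_equal(species_unsaturation_index(parse_species("PC 34:2")), 1)
  expect_error(species_unsaturation_index(parse_species("GSL 34:1;O2")),
               "unsupported")
})

test_that("class unsaturation index is the amount-weighted species mean", {
  tab <- treatment_table(c("DGDG 36:6", "DGDG 34:3"), ot = c(2, 1),
                         ht = c(2, 1))
  # (3.0 * 2 + 1.5 * 1) / 3 = 2.5
  expect_equal(class_unsaturation_index(tab, "DGDG"), 2.5)
  # single species: its own index
  tab1 <- treatment_table("DGDG 36:6", ot = 2, ht = 2)
  expect_equal(class_unsaturation_index(tab1, "DGDG"), 3)
  # equal amounts, indices 1 and 3 -> 2
  tab2 <- treatment_table(c("PC 34:2", "PC 36:6"), ot = c(5, 5), ht = c(5, 5))
  expect_equal(class_unsaturation_index(tab2, "PC"), 2)
  # splitting an amount over two species with the same index changes nothing
  tab3 <- treatment_table(c("DGDG 36:6", "DGDG 18:3_18:3", "DGDG 34:3"),
                          ot = c(1, 1, 1), ht = c(1, 1, 1))
  expect_equal(class_unsaturation_index(tab3, "DGDG"),
               class_unsaturation_index(
                 treatment_table(c("DGDG 36:6", "DGDG 34:3"),
                                 ot = c(2, 1), ht = c(2, 1)), "DGDG"))
  expect_error(class_unsaturation_index(
    treatment_table("DGDG 36:6", ot = 0, ht = 0), "DGDG"), "zero total")
})

test_that("class totals and shares sum to one and ignore zero classes", {
  tab <- treatment_table(c("MGDG 36:6", "DGDG 36:6"), ot = c(49, 51),
                         ht = c(49, 51))
  cs <- class_totals_and_shares(tab)
  ot <- cs[cs$treatment == "OT", ]
  expect_equal(ot$share[ot$class == "MGDG"], 0.49)
  expect_equal(ot$share[ot$class == "DGDG"], 0.51)
  expect_equal(sum(ot$share), 1)
  # adding a zero-amount class leaves shares unchanged
  tab0 <- treatment_table(c("MGDG 36:6", "DGDG 36:6", "PC 34:2"),
                          ot = c(49, 51, 0), ht = c(49, 51, 0))
  cs0 <- class_totals_and_shares(tab0)
  ot0 <- cs0[cs0$treatment == "OT", ]
  expect_equal(ot0$share[ot0$class == "MGDG"], 0.49)
  # ox bucketing moves extra-oxygen species out of their headgroup class
  tabox <- treatment_table(c("DGDG 36:6", "DGDG 16:0_18:3;O"),
                           ot = c(3, 1), ht = c(3, 1))
  csx <- class_totals_and_shares(tabox, separate_ox = TRUE)
  otx <- csx[csx$treatment == "OT", ]
  expect_equal(otx$share[otx$class == "ox-lipid"], 0.25)
})

test_that("percent change follows 100 * (ht - ot) / ot", {
  expect_equal(percent_change(1.0, 2.52), 152)
  expect_equal(percent_change(2.0, 1.0), -50)
  expect_equal(percent_change(1.0, 1.0), 0)
  expect_error(percent_change(0, 1), "ot <= 0")
})

test_that("LS-means equal cell means and MSE is zero on noise-free designs", {
  tab <- treatment_table(c("PC 34:2", "PE 34:2"), ot = c(1, 2),
                         ht = c(1.91, 1), n_geno = 2, n_block = 3)
  tc <- treatment_comparison(tab)
  expect_equal(tc$ot_lsmean, c(1, 2))
  expect_equal(tc$ht_lsmean, c(1.91, 1))
  expect_equal(tc$percent_change, c(91, -50))
  expect_equal(tc$lsd, c(0, 0))
})

test_that("LSD threshold matches the textbook formula and an lm oracle", {
  set.seed(11)
  meta <- balanced_meta(n_geno = 2, n_run = 1, n_block = 3)
  eff <- ifelse(meta$treatment == "HT", 1, 0)
  y <- 5 + eff + rnorm(nrow(meta), 0, 0.01)
  amounts <- matrix(y, ncol = 1, dimnames = list(meta$sample_id, "PC 34:2"))
  tab <- lipidome_table(meta, amounts)
  tc <- treatment_comparison(tab)

  fit <- lm(y ~ genotype * treatment + factor(block), data = meta)
  mse <- sum(residuals(fit)^2) / df.residual(fit)
  n_per <- nrow(meta) / 2
  lsd_textbook <- qt(0.975, df.residual(fit)) * sqrt(2 * mse / n_per)
  expect_equal(tc$lsd, lsd_textbook, tolerance = 1e-10)
  expect_true(tc$significant)
  # LS-means on this balanced design equal arithmetic treatment means
  expect_equal(tc$ot_lsmean, mean(y[meta$treatment == "OT"]), tolerance = 1e-12)
  expect_equal(tc$ht_lsmean, mean(y[meta$treatment == "HT"]), tolerance = 1e-12)
})

test_that("class-level and trait responses run through the same comparison", {
  tab <- treatment_table(c("PC 34:2", "PC 36:4", "PE 34:2"),
                         ot = c(1, 1, 2), ht = c(2, 1, 1))
  tc <- treatment_comparison(tab, level = "class")
  expect_setequal(tc$response, c("PC", "PE"))
  expect_equal(tc$ot_lsmean[tc$response == "PC"], 2)
  expect_equal(tc$ht_lsmean[tc$response == "PC"], 3)

  ui <- unsaturation_indices(tab)
  tcu <- treatment_comparison(tab, responses = character(0),
                              level = "analyte", traits = ui)
  expect_true(all(c("PC", "PE") %in% tcu$response))
})

test_that("acyl fold change reproduces hand-computed occurrence weighting", {
  # single species: ratio of treatment means
  tab <- treatment_table("TG 18:3_18:3_18:3", ot = 1, ht = 2)
  fc <- acyl_fold_change(tab)
  expect_equal(fc$fold_change["TG", "18:3"], 2)

  # two species with multiplicities 1 and 2:
  # (1*1 + 0.5*2) / (2*1 + 1*2) = 0.5
  tab <- treatment_table(c("PC 16:0_18:3", "PC 18:3_18:3", "PE 16:0_18:2"),
                         ot = c(2, 1, 1), ht = c(1, 0.5, 1))
  fc <- acyl_fold_change(tab)
  expect_equal(fc$fold_change["PC", "18:3"], 0.5)
  # 16:0 appears once in one PC species
  expect_equal(fc$fold_change["PC", "16:0"], 0.5)
  # chains absent from a class's resolved species are undefined, not zero
  expect_true(is.na(fc$fold_change["PE", "18:3"]))
  expect_true(is.na(fc$fold_change["PC", "18:2"]))
})

test_that("acyl fold change equals the brute-force enumeration oracle", {
  for (seed in c(101, 202, 303)) {
    tab <- random_resolved_table(seed, n_species = sample(8:20, 1))
    fc <- acyl_fold_change(tab)
    oracle <- brute_force_fold_change(tab)
    for (cell in names(oracle)) {
      parts <- strsplit(cell, "|", fixed = TRUE)[[1]]
      expect_equal(fc$fold_change[parts[1], parts[2]], oracle[[cell]],
                   tolerance = 1e-10, label = cell)
    }
    # no defined cells beyond the oracle's
    expect_equal(sum(!is.na(fc$fold_change)), length(oracle))
  }
})

test_that("shares, indices, fold changes and percent changes are scale invariant", {
  tab <- random_resolved_table(77, n_species = 10)
  scaled <- lipidome_table(tab$samples, tab$amounts * 37.5)
  expect_equal(class_totals_and_shares(scaled)$share,
               class_totals_and_shares(tab)$share, tolerance = 1e-12)
  for (cl in unique(analyte_classes(tab))) {
    np <- tab$species[[which(analyte_classes(tab) == cl)[1]]]$headgroup$n_acyl_positions
    if (is.na(np) || np < 1) next
    expect_equal(class_unsaturation_index(scaled, cl),
                 class_unsaturation_index(tab, cl), tolerance = 1e-12)
  }
  expect_equal(acyl_fold_change(scaled)$fold_change,
               acyl_fold_change(tab)$fold_change, tolerance = 1e-12)
  tc <- treatment_comparison(tab)
  tcs <- treatment_comparison(scaled)
  expect_equal(tcs$percent_change, tc$percent_change, tolerance = 1e-10)
})
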