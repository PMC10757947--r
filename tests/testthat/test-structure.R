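test_that("ordination handles rank-1 data, orthogonality and reconstruction", {
  # collinear 2-D points: PC1 carries all variance
  x <- cbind(a = 1:10, b = 2 * (1:10))
  ord <- ordinate(x)
  expect_equal(ord$variance_share[1], 1, tolerance = 1e-12)

  set.seed(5)
  x <- matrix(rnorm(60), 10, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  ord <- ordinate(x)
  # scores' covariance is diagonal
  cv <- cov(ord$scores)
  expect_equal(cv[upper.tri(cv)], rep(0, sum(upper.tri(cv))),
               tolerance = 1e-10)
  # scores %*% t(loadings) reconstructs the centered matrix
  recon <- ord$scores %*% t(ord$loadings)
  centered <- scale(x, center = TRUE, scale = FALSE)
  expect_equal(unname(recon), unname(centered[, ]), tolerance = 1e-8)
  # sign convention: largest-magnitude loading positive per component
  for (j in seq_len(ncol(ord$loadings))) {
    expect_gte(ord$loadings[which.max(abs(ord$loadings[, j])), j], 0)
  }
  # constant column with scaling on names the offender
  xc <- cbind(x, flat = rep(1, 10))
  expect_error(ordinate(xc, scale. = TRUE), "flat")
})

test_that("Spearman co-occurrence handles monotone pairs and ties", {
  tab <- random_resolved_table(9, n_species = 6)
  # monotone increasing/reversed pairs via raw replicates
  n <- sum(!tab$samples$is_qc_pool)
  amounts <- cbind(
    "PC 34:2" = as.numeric(1:n),
    "PE 34:2" = as.numeric(1:n)^2,     # monotone transform -> rho 1
    "PI 34:2" = as.numeric(n:1),       # reversed -> rho -1
    "PG 34:2" = c(2, 2, rep(3, n - 2)) # ties
  )
  rownames(amounts) <- tab$samples$sample_id[!tab$samples$is_qc_pool]
  meta <- tab$samples[!tab$samples$is_qc_pool, ]
  tt <- lipidome_table(meta, amounts)
  rho <- cooccurrence_matrix(tt, method = "raw")
  expect_equal(rho["PC 34:2", "PE 34:2"], 1)
  expect_equal(rho["PC 34:2", "PI 34:2"], -1)
  # ties: equals rank-then-Pearson with average ranks
  expect_equal(rho["PC 34:2", "PG 34:2"],
               cor(rank(amounts[, "PC 34:2"]), rank(amounts[, "PG 34:2"])),
               tolerance = 1e-12)
  # symmetric with unit diagonal
  expect_equal(unclass(rho), t(unclass(rho)))
  expect_equal(unname(diag(rho)), rep(1, ncol(rho)))
})

test_that("constant analytes are excluded from co-occurrence with a warning", {
  set.seed(13)
  meta <- balanced_meta(n_geno = 2, n_block = 2)
  amounts <- cbind("PC 34:2" = rnorm(nrow(meta), 10),
                   "PE 34:2" = rep(1, nrow(meta)))
  rownames(amounts) <- meta$sample_id
  tt <- lipidome_table(meta, abs(amounts))
  expect_warning(rho <- cooccurrence_matrix(tt, method = "raw"), "constant")
  expect_true(all(is.na(rho["PE 34:2", colnames(rho) != "PE 34:2"])))
  expect_equal(attr(rho, "excluded"), "PE 34:2")
  # excluded rows are dropped before clustering
  cl <- cluster_lipids(rho, k = 1)
  expect_false("PE 34:2" %in% cl$assignments$item)
})

test_that("complete-linkage clustering recovers separable blocks", {
  items <- c(paste0("A", 1:3), paste0("B", 1:2))
  rho <- matrix(-1, 5, 5, dimnames = list(items, items))
  rho[1:3, 1:3] <- 1
  rho[4:5, 4:5] <- 1
  class(rho) <- c("cooccurrence_matrix", "matrix")
  cl <- cluster_lipids(rho, k = 2)
  a <- cl$assignments
  expect_equal(length(unique(a$cluster[grepl("^A", a$item)])), 1L)
  expect_equal(length(unique(a$cluster[grepl("^B", a$item)])), 1L)
  # labels ordered by size: the A block (3 items) is cluster 1
  expect_equal(unique(a$cluster[grepl("^A", a$item)]), 1L)
  # k = n gives singletons
  cln <- cluster_lipids(rho, k = 5)
  expect_equal(sort(cln$assignments$cluster), 1:5)
  expect_error(cluster_lipids(rho, k = 6), "exceeds")
  # newick export produces a parseable tree
  nwk <- cluster_tree_newick(cl)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, items)
})

test_that("cluster assignments are invariant to input row order", {
  tab <- random_resolved_table(31, n_species = 12)
  rho <- cooccurrence_matrix(tab)
  cl1 <- cluster_lipids(rho, k = 3)
  set.seed(8)
  perm <- sample(nrow(rho))
  rho2 <- rho[perm, perm]
  class(rho2) <- class(rho)
  cl2 <- cluster_lipids(rho2, k = 3)
  m1 <- cl1$assignments[order(cl1$assignments$item), ]
  m2 <- cl2$assignments[order(cl2$assignments$item), ]
  expect_equal(m1, m2)
})

test_that("genotype classification labels anchors and degenerates at k = 1", {
  gen <- default_gen()
  tab <- apply_qc_filters(gen$table)$table
  res <- classify_genotypes(tab, k = 6)
  expect_equal(nrow(res$assignments), 54L)
  # anchors force the labels regardless of score
  g_mid <- res$scores$genotype[which.min(abs(res$scores$score))]
  anchored <- classify_genotypes(tab, k = 6, anchors = list(tolerant = g_mid))
  expect_equal(anchored$labels$tolerant,
               anchored$assignments$cluster[anchored$assignments$item == g_mid])
  expect_error(classify_genotypes(tab, anchors = list(tolerant = "nope")),
               "not in table")
  # k = 1: single cluster, no tolerance labels
  deg <- classify_genotypes(tab, k = 1)
  expect_equal(unique(deg$assignments$cluster), 1L)
  expect_null(deg$labels$tolerant)
  expect_null(deg$labels$susceptible)
})

test_that("classification score tracks the programmed tolerance ranking", {
  gen <- default_gen()
  tab <- apply_qc_filters(gen$table)$table
  res <- classify_genotypes(tab, k = 6)
  sc <- merge(res$scores, gen$truth$genotypes, by = "genotype")
  expect_gte(cor(sc$score, sc$g, method = "spearman"), 0.8)
  # tolerant-labeled cluster has the highest mean programmed g; the
  # susceptible-labeled cluster sits at (or indistinguishably near) the
  # bottom of the programmed ranking
  mean_g <- tapply(sc$g, sc$cluster, mean)
  expect_equal(as.integer(names(which.max(mean_g))), res$labels$tolerant)
  expect_lte(mean_g[[as.character(res$labels$susceptible)]],
             min(mean_g) + 0.05)
})
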