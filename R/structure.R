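#' Multivariate structure discovery
#'
#' Principal component ordination of samples, Spearman co-occurrence of
#' lipid analytes, complete-linkage clustering of the co-occurrence matrix,
#' and Ward clustering of genotypes with heat-tolerance classification.
#'
#' @name structure-discovery
NULL

#' Principal component ordination
#'
#' Thin wrapper around [stats::prcomp()] with a deterministic sign
#' convention: within each component, the loading of largest magnitude is
#' made positive.
#'
#' @param x Numeric samples x analytes matrix (>= 2 rows and columns).
#' @param scale. Scale columns to unit variance (default `FALSE`,
#'   centering always applied). Constant columns with scaling on raise an
#'   error naming the analyte.
#' @return An object of class `ordination`: list with `scores`, `loadings`,
#'   `variance_share`, `sdev`, `center`, `scale`.
#' @export
ordinate <- function(x, scale. = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need at least 2 samples and 2 analytes")
  if (scale.) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      stop("constant analyte(s) cannot be scaled: ",
           paste(colnames(x)[sds == 0], collapse = ", "))
    }
  }
  p <- stats::prcomp(x, center = TRUE, scale. = scale.)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(p$rotation))) {
    i_max <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i_max, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  structure(
    list(scores = p$x, loadings = p$rotation,
         variance_share = p$sdev^2 / sum(p$sdev^2),
         sdev = p$sdev, center = p$center, scale = p$scale),
    class = "ordination"
  )
}

#' @export
print.ordination <- function(x, ...) {
  cat("<ordination> ", nrow(x$scores), " samples, ", ncol(x$scores),
      " components\n", sep = "")
  vs <- round(100 * x$variance_share[seq_len(min(5, length(x$variance_share)))], 1)
  cat("  variance explained (%):", paste(vs, collapse = ", "), "...\n")
  invisible(x)
}

#' Spearman co-occurrence matrix of lipid analytes
#'
#' Pairwise Spearman rank correlations among analytes, computed over
#' genotype-by-treatment cell LS-means (both treatments inform
#' co-occurrence) or over raw experimental replicates. Ties are handled with
#' average ranks. Analytes with constant observation vectors have undefined
#' correlations; their rows/columns are `NA` and recorded in the
#' `"excluded"` attribute with a warning.
#'
#' @param table A [lipidome_table()].
#' @param method `"lsmeans"` (default; one observation per genotype x
#'   treatment cell) or `"raw"` (per-sample replicates).
#' @return A symmetric analyte x analyte correlation matrix with unit
#'   diagonal (class `cooccurrence_matrix`).
#' @export
cooccurrence_matrix <- function(table, method = c("lsmeans", "raw")) {
  stopifnot(inherits(table, "lipidome_table"))
  method <- match.arg(method)
  if (method == "lsmeans") {
    ctx <- .table_context(table)
    cellfit <- .fit_cell_lsmeans(ctx, .exp_amounts(table))
    obs <- cellfit$values
  } else {
    obs <- .exp_amounts(table)
  }
  constant <- apply(obs, 2, function(v) stats::sd(v) == 0)
  rho <- suppressWarnings(stats::cor(obs, method = "spearman"))
  if (any(constant)) {
    warning("constant analyte vector(s) excluded from co-occurrence: ",
            paste(colnames(obs)[constant], collapse = ", "))
    rho[constant, ] <- NA_real_
    rho[, constant] <- NA_real_
  }
  diag(rho) <- 1
  structure(rho, class = c("cooccurrence_matrix", "matrix"),
            excluded = colnames(obs)[constant])
}

# relabel cutree clusters: 1..k by decreasing size, ties by first item
.relabel_clusters <- function(labels) {
  sizes <- table(labels)
  first <- vapply(names(sizes), function(l) min(which(labels == l)), numeric(1))
  ord <- order(-as.numeric(sizes), first)
  new <- match(as.character(labels), names(sizes)[ord])
  names(new) <- names(labels)
  new
}

.cluster_assignment <- function(items, labels, hc, method, metric, k) {
  structure(
    list(
      assignments = tibble::tibble(item = items, cluster = labels),
      tree = hc, linkage = method, metric = metric, k = k
    ),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", nrow(x$assignments), " items in ", x$k,
      " clusters (", x$linkage, " linkage, ", x$metric, " distance)\n",
      sep = "")
  print(table(cluster = x$assignments$cluster))
  invisible(x)
}

#' Cluster lipid analytes by co-occurrence
#'
#' Complete-linkage agglomerative clustering on Euclidean distances between
#' rows of the Spearman correlation matrix (the standard
#' correlation-heatmap construction), cut into `k` clusters. Cluster labels
#' are 1..k ordered by decreasing size, ties broken by first item. Items
#' are sorted lexicographically before clustering, so the result is
#' invariant to input row order.
#'
#' @param corr A [cooccurrence_matrix()] (rows with `NA`, e.g. excluded
#'   constant analytes, are dropped first).
#' @param k Number of clusters (default 6).
#' @return A `cluster_assignment` (see [classify_genotypes()] for fields).
#' @export
cluster_lipids <- function(corr, k = 6) {
  stopifnot(inherits(corr, "cooccurrence_matrix") || is.matrix(corr))
  m <- unclass(corr)
  excluded <- attr(m, "excluded")
  attr(m, "excluded") <- NULL
  if (length(excluded) > 0) {
    keep <- setdiff(rownames(m), excluded)
    m <- m[keep, keep, drop = FALSE]
  }
  # drop any remaining items with undefined correlations until complete
  while (nrow(m) > 0 && anyNA(m)) {
    worst <- which.max(rowSums(is.na(m)))
    m <- m[-worst, -worst, drop = FALSE]
  }
  if (k > nrow(m)) stop("k (", k, ") exceeds number of analytes (", nrow(m), ")")
  if (nrow(m) == 1) {
    return(.cluster_assignment(rownames(m), 1L, NULL, "complete",
                               "euclidean", k))
  }
  ord <- order(rownames(m))
  m <- m[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "complete")
  labels <- .relabel_clusters(stats::cutree(hc, k = k))
  .cluster_assignment(rownames(m), unname(labels[rownames(m)]), hc,
                      "complete", "euclidean", k)
}

#' Cluster genotypes by heat-response lipid levels and label tolerance
#'
#' Genotypes are clustered (Ward linkage on Euclidean distance) on their
#' HT-treatment LS-means of the tolerance-panel analytes (species of DGDG,
#' MGDG, PG, TG and SE by default), standardized per analyte (z-scores).
#' The cut at `k` clusters is labeled: the "tolerant" cluster either
#' contains the tolerant anchor genotype (when anchors are supplied) or
#' maximizes mean(z of 18:3-containing TG and SE analytes) - mean(z of
#' 18:3-containing DGDG/MGDG/PG analytes); the "susceptible" cluster is
#' labeled symmetrically. With `k = 1` no tolerance labels are assigned.
#'
#' @param table A [lipidome_table()].
#' @param panel_classes Headgroup classes forming the tolerance panel.
#' @param k Number of clusters (default 6).
#' @param anchors Optional named list or vector with entries `tolerant`
#'   and/or `susceptible` giving genotype ids of known contrasting lines.
#' @param infer Optional chain-inference lookup passed to
#'   [contains_chain()] for unresolved panel species.
#' @return A `cluster_assignment` with additional fields `scores` (tibble:
#'   `genotype`, `cluster`, `score`) and `labels` (list with `tolerant` and
#'   `susceptible` cluster numbers, possibly `NULL`).
#' @export
classify_genotypes <- function(table,
                               panel_classes = c("DGDG", "MGDG", "PG", "TG", "SE"),
                               k = 6, anchors = NULL, infer = NULL) {
  stopifnot(inherits(table, "lipidome_table"))
  cls <- analyte_classes(table)
  panel <- names(cls)[cls %in% panel_classes]
  if (length(panel) == 0) {
    stop("no analytes of the panel classes present: ",
         paste(panel_classes, collapse = ", "))
  }
  ctx <- .table_context(table)
  cellfit <- .fit_cell_lsmeans(ctx, .exp_amounts(table)[, panel, drop = FALSE])
  ht <- cellfit$treatment == "HT"
  mat <- cellfit$values[ht, , drop = FALSE]
  rownames(mat) <- cellfit$genotype[ht]
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  if (k > nrow(mat)) stop("k exceeds the number of genotypes")
  if (!is.null(anchors)) {
    anchors <- as.list(anchors)
    bad <- setdiff(unlist(anchors), rownames(mat))
    if (length(bad) > 0) {
      stop("anchor genotype(s) not in table: ", paste(bad, collapse = ", "))
    }
  }
  # z-score per analyte; drop analytes constant across genotypes
  sds <- apply(mat, 2, stats::sd)
  usable <- sds > 0
  z <- scale(mat[, usable, drop = FALSE])

  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = "ward.D2")
  labels <- .relabel_clusters(stats::cutree(hc, k = k))
  genotypes <- rownames(z)

  # remodeling score: up-set (18:3 TG/SE) minus down-set (18:3 DGDG/MGDG/PG)
  has_183 <- vapply(colnames(z), function(a) {
    tryCatch(contains_chain(table$species[[a]], "18:3", infer = infer),
             error = function(e) FALSE)
  }, logical(1))
  acls <- cls[colnames(z)]
  up <- has_183 & acls %in% c("TG", "SE")
  down <- has_183 & acls %in% c("DGDG", "MGDG", "PG")
  score <- rep(NA_real_, length(genotypes))
  if (any(up) && any(down)) {
    score <- rowMeans(z[, up, drop = FALSE]) - rowMeans(z[, down, drop = FALSE])
  } else if (any(up)) {
    score <- rowMeans(z[, up, drop = FALSE])
  } else if (any(down)) {
    score <- -rowMeans(z[, down, drop = FALSE])
  }

  lab_tol <- lab_sus <- NULL
  if (k >= 2) {
    cl_of <- function(g) unname(labels[match(g, genotypes)])
    cluster_score <- tapply(score, labels[genotypes], mean)
    tol_anchored <- !is.null(anchors$tolerant)
    sus_anchored <- !is.null(anchors$susceptible)
    if (tol_anchored) {
      lab_tol <- cl_of(anchors$tolerant[1])
    } else if (!all(is.na(cluster_score))) {
      lab_tol <- as.integer(names(which.max(cluster_score)))
    }
    if (sus_anchored) {
      lab_sus <- cl_of(anchors$susceptible[1])
    } else if (!all(is.na(cluster_score))) {
      lab_sus <- as.integer(names(which.min(cluster_score)))
    }
    # on conflict an anchored label wins over a score-derived one; two
    # conflicting score-derived (or anchored) labels cancel
    if (!is.null(lab_tol) && !is.null(lab_sus) && lab_tol == lab_sus) {
      if (tol_anchored && !sus_anchored) lab_sus <- NULL
      else if (sus_anchored && !tol_anchored) lab_tol <- NULL
      else lab_tol <- lab_sus <- NULL
    }
  }
  out <- .cluster_assignment(genotypes, unname(labels[genotypes]), hc,
                             "ward.D2", "euclidean", k)
  out$scores <- tibble::tibble(genotype = genotypes,
                               cluster = out$assignments$cluster,
                               score = unname(score))
  out$labels <- list(tolerant = lab_tol, susceptible = lab_sus)
  out
}

#' Export a cluster merge tree in newick format
#'
#' @param assignment A `cluster_assignment` from [cluster_lipids()] or
#'   [classify_genotypes()].
#' @param path Optional output path; when `NULL` the newick string is
#'   returned.
#' @return The newick string (invisibly when written to a file).
#' @export
cluster_tree_newick <- function(assignment, path = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  phy <- ape::as.phylo(assignment$tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
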