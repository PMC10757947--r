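#' SNP marker distribution summaries
#'
#' Expected versus observed marker counts per chromosome (expectations
#' proportional to chromosome size within each subgenome) and per 10-Mb bin
#' along each chromosome, with exact binomial deviation tests.
#'
#' @name marker-distribution
NULL

#' Construct a genome layout
#'
#' @param chrom Chromosome names.
#' @param subgenome Subgenome label per chromosome (e.g. "A"/"B").
#' @param size_mb Chromosome size in Mb (> 0).
#' @return A tibble of class `genome_layout`.
#' @export
genome_layout <- function(chrom, subgenome, size_mb) {
  if (any(size_mb <= 0)) stop("chromosome sizes must be > 0")
  if (anyDuplicated(chrom)) stop("duplicate chromosome names")
  out <- tibble::tibble(chrom = as.character(chrom),
                        subgenome = as.character(subgenome),
                        size_mb = as.numeric(size_mb))
  class(out) <- c("genome_layout", class(out))
  out
}

#' Read a genome layout TSV (columns chrom, subgenome, size_mb)
#' @param path Path to the layout file.
#' @return A [genome_layout()].
#' @export
read_genome_layout <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("chrom", "subgenome", "size_mb"), names(df))
  if (length(missing) > 0) {
    stop("layout file lacks column(s): ", paste(missing, collapse = ", "))
  }
  genome_layout(df$chrom, df$subgenome, df$size_mb)
}

#' Construct a marker set
#'
#' @param chrom Chromosome name per marker.
#' @param pos 1-based position in bp per marker.
#' @param layout Optional [genome_layout()] to validate against (positions
#'   within chromosome sizes, chromosome names known).
#' @return A tibble of class `marker_set` with columns `chrom`, `pos`.
#' @export
marker_set <- function(chrom, pos, layout = NULL) {
  pos <- as.numeric(pos)
  if (any(pos < 1)) stop("marker positions must be >= 1")
  out <- tibble::tibble(chrom = as.character(chrom), pos = pos)
  if (!is.null(layout)) {
    unknown <- setdiff(unique(out$chrom), layout$chrom)
    if (length(unknown) > 0) {
      stop("marker chromosome(s) not in layout: ",
           paste(unknown, collapse = ", "))
    }
    sizes_bp <- layout$size_mb[match(out$chrom, layout$chrom)] * 1e6
    if (any(out$pos > sizes_bp)) {
      stop("marker position(s) beyond chromosome size")
    }
  }
  class(out) <- c("marker_set", class(out))
  out
}

#' Read markers from a VCF or a chrom/pos TSV
#'
#' For VCF input only CHROM and POS are used; each record line counts once
#' (multi-allelic records are single lines). TSV input needs columns
#' `chrom` and `pos` (a third id column is ignored).
#'
#' @param path Path to a `.vcf`/`.vcf.gz` file or a TSV.
#' @param layout Optional [genome_layout()] for validation.
#' @return A [marker_set()].
#' @export
read_markers <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF requires the vcfR package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    return(marker_set(vcfR::getCHROM(v), as.numeric(vcfR::getPOS(v)),
                      layout = layout))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("chrom", "pos"), names(df))
  if (length(missing) > 0) {
    stop("marker file lacks column(s): ", paste(missing, collapse = ", "))
  }
  marker_set(df$chrom, df$pos, layout = layout)
}

#' Observed and expected marker counts per chromosome
#'
#' The expected count for a chromosome is the subgenome's marker total
#' divided by the subgenome size in Mb, multiplied by the chromosome size in
#' Mb (i.e. proportional allocation by size within each subgenome).
#'
#' @param layout A [genome_layout()].
#' @param markers A [marker_set()]; all chromosomes must be in the layout.
#' @return A tibble: `chrom`, `subgenome`, `size_mb`, `observed`,
#'   `expected`.
#' @export
expected_per_chromosome <- function(layout, markers) {
  unknown <- setdiff(unique(markers$chrom), layout$chrom)
  if (length(unknown) > 0) {
    stop("marker chromosome(s) not in layout: ", paste(unknown, collapse = ", "))
  }
  obs <- table(factor(markers$chrom, levels = layout$chrom))
  sub_total <- tapply(as.numeric(obs), layout$subgenome, sum)
  sub_size <- tapply(layout$size_mb, layout$subgenome, sum)
  density <- sub_total[layout$subgenome] / sub_size[layout$subgenome]
  tibble::tibble(
    chrom = layout$chrom,
    subgenome = layout$subgenome,
    size_mb = layout$size_mb,
    observed = as.integer(obs),
    expected = as.numeric(density * layout$size_mb)
  )
}

#' Observed and expected marker counts per bin along chromosomes
#'
#' Bins are half-open intervals `[start, start + bin_mb)` in Mb from
#' position 0 (1-based bp positions are binned on `(pos - 1) / 1e6`). The
#' expected count of a full bin is the chromosome's marker total divided by
#' its size in Mb times `bin_mb`; a truncated final bin's expectation is
#' scaled by its actual width.
#'
#' @param layout A [genome_layout()].
#' @param markers A [marker_set()].
#' @param bin_mb Bin width in Mb (default 10).
#' @return A tibble: `chrom`, `bin_start_mb`, `bin_end_mb`, `width_mb`,
#'   `observed`, `expected`.
#' @export
expected_per_bin <- function(layout, markers, bin_mb = 10) {
  if (bin_mb <= 0) stop("bin_mb must be > 0")
  unknown <- setdiff(unique(markers$chrom), layout$chrom)
  if (length(unknown) > 0) {
    stop("marker chromosome(s) not in layout: ", paste(unknown, collapse = ", "))
  }
  out <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    ch <- layout$chrom[i]
    size <- layout$size_mb[i]
    starts <- bin_mb * (seq_len(ceiling(size / bin_mb)) - 1)
    ends <- pmin(starts + bin_mb, size)
    pos_mb <- (markers$pos[markers$chrom == ch] - 1) / 1e6
    idx <- pmin(floor(pos_mb / bin_mb) + 1, length(starts))
    obs <- tabulate(idx, nbins = length(starts))
    total <- length(pos_mb)
    out[[i]] <- tibble::tibble(
      chrom = ch,
      bin_start_mb = starts, bin_end_mb = ends, width_mb = ends - starts,
      observed = obs,
      expected = total / size * (ends - starts)
    )
  }
  do.call(rbind, out)
}

#' Exact binomial deviation test for observed vs expected marker counts
#'
#' Two-sided exact binomial test of `observed` successes in `total` trials
#' against probability `expected / total`, flagging deviations at level
#' `alpha`. The significance procedure is an interpretation chosen here;
#' the counting arithmetic it accompanies follows the size-proportional
#' expectations of [expected_per_chromosome()] / [expected_per_bin()].
#'
#' @param observed Observed count(s).
#' @param expected Expected count(s) (> 0).
#' @param total Total marker count(s) the expectation was derived from.
#' @param alpha Significance level (default 0.05).
#' @return A tibble: `observed`, `expected`, `p_value`, `flag` ("high",
#'   "low" or "none").
#' @export
deviation_test <- function(observed, expected, total, alpha = 0.05) {
  n <- max(length(observed), length(expected), length(total))
  observed <- rep_len(observed, n)
  expected <- rep_len(expected, n)
  total <- rep_len(total, n)
  if (any(expected <= 0)) stop("expected counts must be > 0")
  if (any(observed > total)) stop("observed exceeds total")
  if (any(total < 1)) stop("degenerate total")
  p <- expected / total
  if (any(p > 1)) stop("expected exceeds total")
  pv <- vapply(seq_len(n), function(i) {
    stats::binom.test(observed[i], total[i], p = p[i],
                      alternative = "two.sided")$p.value
  }, numeric(1))
  flag <- ifelse(pv >= alpha, "none",
                 ifelse(observed > expected, "high", "low"))
  tibble::tibble(observed = observed, expected = expected,
                 p_value = pv, flag = flag)
}

#' Marker distribution summary with deviation flags
#'
#' Convenience wrapper combining [expected_per_chromosome()],
#' [expected_per_bin()] and [deviation_test()].
#'
#' @param layout A [genome_layout()].
#' @param markers A [marker_set()].
#' @param bin_mb Bin width in Mb (default 10).
#' @param alpha Significance level (default 0.05).
#' @return A list with `per_chromosome` and `per_bin` tibbles, each
#'   including `p_value` and `flag` columns. Per-chromosome tests use the
#'   subgenome marker total; per-bin tests use the chromosome total (bins on
#'   chromosomes without markers are untested, `flag = NA`).
#' @export
marker_distribution <- function(layout, markers, bin_mb = 10, alpha = 0.05) {
  per_chr <- expected_per_chromosome(layout, markers)
  sub_total <- tapply(per_chr$observed, per_chr$subgenome, sum)
  tot_chr <- as.integer(sub_total[per_chr$subgenome])
  per_chr$p_value <- NA_real_
  per_chr$flag <- NA_character_
  ok <- per_chr$expected > 0
  if (any(ok)) {
    dt <- deviation_test(per_chr$observed[ok], per_chr$expected[ok],
                         tot_chr[ok], alpha = alpha)
    per_chr$p_value[ok] <- dt$p_value
    per_chr$flag[ok] <- dt$flag
  }

  per_bin <- expected_per_bin(layout, markers, bin_mb = bin_mb)
  chr_total <- tapply(per_bin$observed, per_bin$chrom, sum)
  tot <- as.integer(chr_total[per_bin$chrom])
  per_bin$p_value <- NA_real_
  per_bin$flag <- NA_character_
  testable <- tot > 0
  if (any(testable)) {
    dtb <- deviation_test(per_bin$observed[testable],
                          per_bin$expected[testable], tot[testable],
                          alpha = alpha)
    per_bin$p_value[testable] <- dtb$p_value
    per_bin$flag[testable] <- dtb$flag
  }
  list(per_chromosome = per_chr, per_bin = per_bin)
}
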