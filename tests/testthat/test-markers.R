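make_layout <- function() {
  genome_layout(c("chr1", "chr2", "chr3"), c("A", "A", "B"), c(20, 80, 50))
}

test_that("per-chromosome expectations are size-proportional within subgenomes", {
  lay <- make_layout()
  # subgenome A: 100 Mb, 1000 markers; chr1 (20 Mb) expects 200
  mk <- marker_set(
    chrom = c(rep("chr1", 300), rep("chr2", 700), rep("chr3", 40)),
    pos = rep(1, 1040)
  )
  pc <- expected_per_chromosome(lay, mk)
  expect_equal(pc$expected[pc$chrom == "chr1"], 200)
  expect_equal(pc$expected[pc$chrom == "chr2"], 800)
  expect_equal(pc$observed[pc$chrom == "chr1"], 300L)
  # expectations within a subgenome sum to the subgenome's marker total
  expect_equal(sum(pc$expected[pc$subgenome == "A"]), 1000, tolerance = 1e-9)
  expect_equal(sum(pc$expected[pc$subgenome == "B"]), 40, tolerance = 1e-9)
  expect_error(
    expected_per_chromosome(lay, tibble::tibble(chrom = "chrX", pos = 5)),
    "chrX")
})

test_that("per-bin expectations use half-open bins and truncate the last bin", {
  lay <- genome_layout("c1", "A", 50)
  set.seed(2)
  mk <- marker_set("c1", sample.int(50e6, 500, replace = TRUE))
  pb <- expected_per_bin(lay, mk, bin_mb = 10)
  expect_equal(nrow(pb), 5L)
  expect_equal(pb$expected, rep(100, 5))
  expect_equal(sum(pb$observed), 500L)
  # bin expectations sum to the chromosome's marker total
  expect_equal(sum(pb$expected), 500, tolerance = 1e-9)

  # 25 Mb chromosome: last bin is 5 Mb wide with half a full expectation
  lay2 <- genome_layout("c1", "A", 25)
  mk2 <- marker_set("c1", c(1, 10e6, 10e6 + 1, 24e6))
  pb2 <- expected_per_bin(lay2, mk2, bin_mb = 10)
  expect_equal(pb2$width_mb, c(10, 10, 5))
  expect_equal(pb2$expected[3], pb2$expected[1] / 2)
  # half-open binning: position 10e6 is in bin 1 ((pos-1)/1e6 < 10),
  # 10e6 + 1 in bin 2
  expect_equal(pb2$observed, c(2L, 1L, 1L))
  expect_error(expected_per_bin(lay2, mk2, bin_mb = 0), "bin_mb")
})

test_that("deviation test equals the exhaustive binomial sum", {
  # tiny case checked by enumeration: total 10, expected 5, observed 9
  dt <- deviation_test(9, 5, 10)
  d_obs <- dbinom(9, 10, 0.5)
  p_enum <- sum(dbinom(0:10, 10, 0.5)[dbinom(0:10, 10, 0.5) <= d_obs + 1e-12])
  expect_equal(dt$p_value, p_enum, tolerance = 1e-10)
  expect_equal(dt$flag, "high")

  # random small cases against the same enumeration oracle
  set.seed(3)
  for (i in 1:20) {
    total <- sample(5:50, 1)
    expected <- runif(1, 0.5, total - 0.5)
    observed <- sample(0:total, 1)
    dt <- deviation_test(observed, expected, total)
    p <- expected / total
    dens <- dbinom(0:total, total, p)
    p_enum <- sum(dens[dens <= dbinom(observed, total, p) * (1 + 1e-7)])
    expect_equal(dt$p_value, p_enum, tolerance = 1e-7)
  }

  # extreme depletion is flagged low
  dt <- deviation_test(0, 100, 1000)
  expect_equal(dt$flag, "low")
  expect_lt(dt$p_value, 1e-10)
  # observed equal to expected is never flagged
  dt <- deviation_test(200, 200, 1000)
  expect_equal(dt$flag, "none")
  expect_error(deviation_test(5, 0, 10), "> 0")
  expect_error(deviation_test(11, 5, 10), "exceeds")
})

test_that("marker generation respects enrichment and degenerate n", {
  lay <- make_layout()
  expect_equal(nrow(generate_markers(lay, 0, seed = 1)), 0L)

  mk <- generate_markers(lay, 20000, seed = 4)
  md <- marker_distribution(lay, mk)
  # uniform markers: observed close to expected everywhere
  expect_true(all(abs(md$per_chromosome$observed -
                        md$per_chromosome$expected) /
                    md$per_chromosome$expected < 0.1))

  mk3 <- generate_markers(lay, 20000, enrichment = c(chr1 = 3), seed = 4)
  md3 <- marker_distribution(lay, mk3)
  expect_equal(md3$per_chromosome$flag[md3$per_chromosome$chrom == "chr1"],
               "high")
  # positions stay within chromosome bounds
  sizes <- lay$size_mb[match(mk3$chrom, lay$chrom)] * 1e6
  expect_true(all(mk3$pos >= 1 & mk3$pos <= sizes))
})

test_that("marker and layout files round-trip, including VCF", {
  lay <- make_layout()
  lay_path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(as.data.frame(lay), lay_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  expect_equal(read_genome_layout(lay_path)$size_mb, lay$size_mb)

  tsv_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos", "chr1\t100", "chr1\t2000", "chr2\t5"), tsv_path)
  mk <- read_markers(tsv_path, layout = lay)
  expect_equal(nrow(mk), 3L)

  skip_if_not_installed("vcfR")
  vcf_path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=20000000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tT\t.\tPASS\t.",
    "chr1\t2000\t.\tG\tC,A\t.\tPASS\t.",
    "chr2\t5\t.\tT\tG\t.\tPASS\t."
  ), vcf_path)
  mkv <- read_markers(vcf_path, layout = lay)
  expect_equal(nrow(mkv), 3L)  # multi-allelic record counts once
  expect_equal(mkv$pos, c(100, 2000, 5))
})
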