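panel_fixture <- function() {
  variants <- rbind(
    make_variant("SV0001", "chr1", 200000, kind = "SV", end_info = 205000,
                 sv_length = -5000, ref = "N", alt = "<DEL>"),
    make_variant("SV0002", "chr2", 150000, kind = "SV", end_info = 150000,
                 sv_length = 384, ref = "N", alt = "<INS>"))
  geno_panel(c("HG001", "HG002", "HG003"), variants,
             matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 3))
}

test_that("genotype VCFs round-trip through write and read", {
  p <- panel_fixture()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotype_vcf(p, path)
  p2 <- read_genotype_vcf(path, kind = "SV")
  expect_equal(p2$samples, p$samples)
  expect_equal(p2$variants, p$variants)
  expect_equal(unname(p2$calls), unname(p$calls))
  # SVLEN signs preserved
  expect_equal(p2$variants$sv_length, c(-5000, 384))
  # determinism: writing again is byte-identical
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_genotype_vcf(p2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("empty panels produce a header-only VCF that reads back empty", {
  p <- panel_fixture()
  empty <- geno_panel(p$samples, p$variants[0, ],
                      p$calls[, 0, drop = FALSE])
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotype_vcf(empty, path)
  expect_true(all(grepl("^#", readLines(path))))
})

test_that("multi-allelic and non-diploid records are dropped and counted", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tHG001\tHG002",
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t200\trs2\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t1/2",
    "chr1\t300\trs3\tA\tG\t.\tPASS\t.\tGT\t0\t0/1",
    "chr1\t400\trs4\tA\tG\t.\tq10\t.\tGT\t1/1\t0/0"), path)
  expect_warning(p <- read_genotype_vcf(path, kind = "SNP"), "dropped")
  counts <- attr(p, "counts")
  expect_equal(unname(counts["scanned"]), 4)
  expect_equal(unname(counts["multiallelic"]), 1)
  expect_equal(unname(counts["nondiploid"]), 1)
  expect_equal(unname(counts["retained"]), 2)
  expect_equal(p$variants$variant_id, c("rs1", "rs4"))
  expect_equal(sum(counts[c("retained", "multiallelic", "nondiploid", "filtered")]),
               unname(counts["scanned"]))
  # non-PASS rows can be excluded on request
  expect_warning(p2 <- read_genotype_vcf(path, kind = "SNP",
                                         keep_filtered = FALSE))
  expect_equal(p2$variants$variant_id, "rs1")
  expect_equal(unname(attr(p2, "counts")["filtered"]), 1)
})

test_that("symbolic SV alleles carry their END annotation", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tHG001",
    "chr1\t300000\tSV9\tN\t<DEL>\t.\tPASS\tEND=305000\tGT\t0/1"), path)
  p <- read_genotype_vcf(path, kind = "SV")
  expect_equal(p$variants$end_info, 305000)
  expect_equal(sv_span(p)$span_end, 305000)
})

test_that("a region filter restricts the panel", {
  p <- panel_fixture()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotype_vcf(p, path)
  sub <- read_genotype_vcf(path, kind = "SV", region = "chr1:1-500000")
  expect_equal(sub$variants$variant_id, "SV0001")
  expect_error(read_genotype_vcf(path, kind = "SV", region = "chr1"),
               class = "svld_format_error")
})

test_that("a VCF without GT is rejected", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tHG001",
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tDP\t10"), path)
  expect_error(read_genotype_vcf(path, kind = "SNP"),
               class = "svld_format_error")
})
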