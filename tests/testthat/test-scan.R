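scan_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "svldscan-test-fixture")
      fx <- build_fixture(seed = 1, dir = dir)
      scan <- sv_snp_scan(fx$sv_vcf, fx$snp_vcf, fx$gwas_tsv, verbose = FALSE)
      cache <<- list(fx = fx, scan = scan)
    }
    cache
  }
})

test_that("the scan reproduces the planted truth table", {
  x <- scan_fixture()
  want <- x$fx$truth[x$fx$truth$expected_in_catalog, ]
  got <- x$scan$catalog
  expect_setequal(paste(got$sv_id, got$snp_rsid),
                  paste(want$sv_id, want$snp_id))
  # catalog g2 values equal the truth's realized values
  m <- match(got$sv_id, want$sv_id)
  expect_equal(got$g_squared, want$realized_g2[m], tolerance = 1e-12)
  expect_equal(got$n_samples, want$n_samples[m])
})

test_that("every catalog entry satisfies its invariants", {
  x <- scan_fixture()
  cat <- x$scan$catalog
  cfg <- x$scan$config
  expect_true(all(cat$g_squared >= cfg$min_g2))
  expect_true(all(cat$gwas_p_value < cfg$gwas_p_threshold))
  expect_true(all(cat$distance_bp <= cfg$flank))
  expect_true(all(cat$ld_p_value > 0 & cat$ld_p_value <= 1))
  s <- x$scan$summary
  expect_lte(s$pairs_passing, s$candidate_pairs)
  expect_lte(s$candidate_pairs, s$svs_read * s$snps_matched)
  expect_equal(s$catalog_rows, nrow(cat))
})

test_that("threshold and flank degenerations behave as documented", {
  x <- scan_fixture()
  fx <- x$fx
  # min_g2 = 0: every non-degenerate candidate pair is emitted
  all_scan <- sv_snp_scan(fx$sv_vcf, fx$snp_vcf, fx$gwas_tsv, min_g2 = 0,
                          verbose = FALSE)
  expect_equal(nrow(all_scan$catalog),
               all_scan$summary$candidate_pairs - all_scan$summary$degenerate_pairs)
  # flank = 0: only SNPs inside SV bodies can pair
  suppressWarnings(
    inside_only <- sv_snp_scan(fx$sv_vcf, fx$snp_vcf, fx$gwas_tsv, flank = 0,
                               verbose = FALSE))
  expect_true(all(inside_only$pairs$inside_sv))
})

test_that("catalog files are byte-stable and round-trip", {
  x <- scan_fixture()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(x$scan, p1)
  rescan <- sv_snp_scan(x$fx$sv_vcf, x$fx$snp_vcf, x$fx$gwas_tsv,
                        verbose = FALSE)
  write_catalog(rescan, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(length(readLines(p1)), nrow(x$scan$catalog) + 1)
  back <- read_catalog(p1)
  expect_equal(back$sv_id, x$scan$catalog$sv_id)
  expect_equal(back$g_squared, signif(x$scan$catalog$g_squared, 6),
               tolerance = 1e-10)
  # empty catalog still writes a header-only file
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(x$scan$catalog[0, ], p3)
  expect_equal(length(readLines(p3)), 1)
})

test_that("collapse mode folds trait rows into unique pairs", {
  x <- scan_fixture()
  fx <- x$fx
  # duplicate an association under a second trait to exercise the fold
  gw <- readr::read_tsv(fx$gwas_tsv, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  extra <- gw[1, ]
  extra$`DISEASE/TRAIT` <- "second trait"
  gw2_path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(rbind(gw, extra), gw2_path, progress = FALSE)
  per_trait <- sv_snp_scan(fx$sv_vcf, fx$snp_vcf, gw2_path, verbose = FALSE)
  folded <- sv_snp_scan(fx$sv_vcf, fx$snp_vcf, gw2_path, collapse = TRUE,
                        verbose = FALSE)
  expect_gt(nrow(per_trait$catalog), nrow(folded$catalog))
  expect_false(any(duplicated(paste(folded$catalog$sv_id,
                                    folded$catalog$snp_rsid))))
  expect_true(any(grepl("; ", folded$catalog$trait, fixed = TRUE)))
})

test_that("tidy, glance and the plot methods work on scan objects", {
  x <- scan_fixture()
  expect_identical(tidy(x$scan), x$scan$catalog)
  g <- glance(x$scan)
  expect_equal(nrow(g), 1)
  expect_true(all(c("candidate_pairs", "unique_svs", "unique_traits")
                  %in% names(g)))
  expect_s3_class(autoplot(x$scan), "ggplot")
  expect_s3_class(plot_scan_funnel(x$scan), "ggplot")
  expect_output(print(x$scan), "SV-SNP LD scan")
})
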