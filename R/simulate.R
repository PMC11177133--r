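#' Simulate an unphased two-locus diploid panel
#'
#' Draws `2 * n_diploid` haplotypes from the multinomial distribution over
#' the four two-locus haplotypes and pairs consecutive draws into diploids
#' (random union of gametes, hence Hardy-Weinberg equilibrium at both
#' sites), returning the induced unphased genotype codes. The default panel
#' size of 32 diploids mirrors the long-read human reference panel that
#' motivates this package's defaults.
#'
#' @param freqs A [hap_freqs()] object or length-4 numeric vector.
#' @param n_diploid Number of diploid individuals (default 32).
#' @param seed Optional integer; when given, sampling happens under
#'   [withr::with_seed()] so the draw is reproducible without touching the
#'   caller's RNG state.
#' @return A tibble with columns `sample_id`, `sv_gt`, `snp_gt` (genotype
#'   codes 0/1/2).
#' @examples
#' simulate_panel(freqs_from_target(0.5, 0.5, 0.85), n_diploid = 32, seed = 1)
#' @export
simulate_panel <- function(freqs, n_diploid = 32, seed = NULL) {
  h <- as_hap(freqs)
  if (n_diploid < 2) {
    stop_svld("n_diploid must be at least 2", "svld_no_data_error")
  }
  draw <- function() sample.int(4L, size = 2L * n_diploid, replace = TRUE,
                                prob = h)
  haps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  a2 <- c(0L, 0L, 1L, 1L)[haps] # A2 allele carried by each haplotype
  b2 <- c(0L, 1L, 0L, 1L)[haps]
  odd <- seq(1L, 2L * n_diploid, by = 2L)
  tibble(
    sample_id = sprintf("HG%03d", seq_len(n_diploid)),
    sv_gt = a2[odd] + a2[odd + 1L],
    snp_gt = b2[odd] + b2[odd + 1L]
  )
}

#' Default planted-pair specification
#'
#' A ready-made [build_fixture()] specification exercising every filter of
#' the scan: strong-LD positives (one deletion, one insertion, one SNP
#' inside the SV body), a window-distance negative, two GWAS-significance
#' negatives (one sub-threshold, one exactly at 5e-8 to pin the strict
#' inequality), a low-LD negative and a monomorphic (degenerate) pair. Each
#' pair sits in its own isolated region so windows cannot capture a foreign
#' SNP.
#'
#' @return A tibble understood by [build_fixture()].
#' @export
plant_pairs_default <- function() {
  tibble(
    chrom     = c("chr1",  "chr1",  "chr1",  "chr2",  "chr2",  "chr2",  "chr3",  "chr3"),
    sv_pos    = c(2e6,     4e6,     6e6,     2e6,     4e6,     6e6,     2e6,     4e6),
    sv_len    = c(5000,    384,     207,     5000,    1000,    5000,    2500,    80),
    sv_type   = c("DEL",   "INS",   "INS",   "DEL",   "DEL",   "DEL",   "DEL",   "INS"),
    offset_bp = c(50000,   -30000,  150000,  50000,   20000,   10000,   NA,      95000),
    snp_pos   = c(NA,      NA,      NA,      NA,      NA,      NA,      2001000, NA),
    target_r2 = c(1,       0.95,    1,       1,       0.10,    1,       1,       1),
    p_freq    = c(0.5,     0.5,     0.5,     0.5,     0.4,     0.5,     0.5,     0.5),
    q_freq    = c(0.5,     0.5,     0.5,     0.5,     0.6,     0.5,     0.5,     0.5),
    gwas_p    = c(1e-12,   4e-14,   1e-12,   9.13e-7, 1e-12,   1e-12,   2e-246,  5e-8),
    trait     = c("age-related macular degeneration", "refractive error",
                  "recombination hotspot activity", "cognitive function",
                  "coronary artery disease", "multiple sclerosis",
                  "lipoprotein (a) levels", "rheumatoid arthritis"),
    mode      = c("sampled", "sampled", "sampled", "sampled", "sampled",
                  "monomorphic", "sampled", "sampled")
  )
}

# integer table with dosage correlation exactly 4/5; scales to any multiple
# of six samples (see expand_exact_table)
.boundary_table_unit <- c(0, 0, 0, 1, 2, 0, 0, 0, 3)

# deterministic per-sample expansion of an integer count table
expand_exact_table <- function(cells, n_diploid) {
  cells <- as.integer(cells)
  if (sum(cells) == 0 || n_diploid %% sum(cells) != 0) {
    stop_svld(sprintf(
      "exact tables need n_diploid to be a multiple of %d", sum(cells)),
      "svld_fixture_error")
  }
  k <- n_diploid %/% sum(cells)
  sv <- rep(rep(0:2, each = 3), times = cells * k)
  snp <- rep(rep(0:2, times = 3), times = cells * k)
  tibble(sample_id = sprintf("HG%03d", seq_len(n_diploid)),
         sv_gt = as.integer(sv), snp_gt = as.integer(snp))
}

#' Build a fully synthetic scan fixture
#'
#' Writes the three scan inputs — an SV VCF, a SNP VCF and a GWAS-style
#' association TSV — for a set of planted SV-SNP pairs, plus a truth table
#' stating which pairs the scan must emit and which filter excludes the
#' rest. Truth labels are computed from the *realized* genotypes (the
#' written files), not from the intended parameters, so sampling noise can
#' never put the truth on the wrong side of a threshold.
#'
#' The specification is one row per planted pair with columns:
#' `chrom`; `sv_pos`; `sv_len` (positive magnitude); `sv_type` (`"DEL"` or
#' `"INS"`); `offset_bp` (SNP distance from the SV span: `>= 0` places the
#' SNP right of the end, negative left of the start; ignored when `snp_pos`
#' is given, which may place the SNP inside the SV body); `target_r2`;
#' `p_freq`, `q_freq` (allele frequencies); `gwas_p`; `trait`; `mode`
#' (`"sampled"` — multinomial draw; `"exact_boundary"` — a deterministic
#' table whose g2 is exactly 0.80, requires `n_diploid` divisible by 6;
#' `"monomorphic"` — the SV is fixed hom-ref, yielding a degenerate pair).
#'
#' @param pairs Planted-pair tibble (default [plant_pairs_default()]).
#' @param n_diploid Panel size (default 32).
#' @param seed Integer seed; fixtures are byte-identical across runs with
#'   the same seed.
#' @param dir Output directory (created if needed).
#' @param flank,min_g2,gwas_p_threshold Filter settings used to derive the
#'   truth labels; match them to the scan under test.
#' @param isolation_bp Minimum padding between planted regions on the same
#'   chromosome; collisions are an error.
#' @return A list: paths `sv_vcf`, `snp_vcf`, `gwas_tsv`, `truth_tsv`; the
#'   `truth` tibble; and the two in-memory panels.
#' @export
build_fixture <- function(pairs = plant_pairs_default(), n_diploid = 32,
                          seed = 1, dir = tempdir(), flank = 1e5,
                          min_g2 = 0.80, gwas_p_threshold = 5e-8,
                          isolation_bp = 150000) {
  pairs <- as_tibble(pairs)
  if (!"snp_pos" %in% names(pairs)) pairs$snp_pos <- NA_real_
  n_pairs <- nrow(pairs)
  if (n_pairs == 0) stop_svld("no pairs to plant", "svld_fixture_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  sv_start <- pairs$sv_pos
  sv_end <- ifelse(pairs$sv_type == "INS", pairs$sv_pos,
                   pairs$sv_pos + pairs$sv_len)
  snp_pos <- ifelse(!is.na(pairs$snp_pos), pairs$snp_pos,
                    ifelse(pairs$offset_bp >= 0, sv_end + pairs$offset_bp,
                           sv_start + pairs$offset_bp))

  # pairwise region isolation so no SV window can reach a foreign SNP
  lo <- pmin(sv_start, snp_pos) - isolation_bp
  hi <- pmax(sv_end, snp_pos) + isolation_bp
  for (chr in unique(pairs$chrom)) {
    i <- which(pairs$chrom == chr)
    if (length(i) > 1) {
      o <- i[order(lo[i])]
      if (any(lo[o][-1] <= hi[o][-length(o)])) {
        stop_svld(sprintf("planted regions collide on %s", chr),
                  "svld_fixture_error")
      }
    }
  }

  samples <- sprintf("HG%03d", seq_len(n_diploid))
  sv_calls <- matrix(NA_integer_, n_diploid, n_pairs)
  snp_calls <- matrix(NA_integer_, n_diploid, n_pairs)
  for (i in seq_len(n_pairs)) {
    g <- switch(pairs$mode[i],
      sampled = simulate_panel(
        freqs_from_target(pairs$p_freq[i], pairs$q_freq[i], pairs$target_r2[i]),
        n_diploid = n_diploid, seed = seed + 7919L * i),
      exact_boundary = expand_exact_table(.boundary_table_unit, n_diploid),
      monomorphic = {
        g0 <- simulate_panel(
          freqs_from_target(0.5, pairs$q_freq[i], 0),
          n_diploid = n_diploid, seed = seed + 7919L * i)
        g0$sv_gt <- 0L
        g0
      },
      stop_svld(paste0("unknown mode: ", pairs$mode[i]), "svld_fixture_error"))
    sv_calls[, i] <- g$sv_gt
    snp_calls[, i] <- g$snp_gt
  }

  sv_ids <- sprintf("SV%04d", seq_len(n_pairs))
  rsids <- sprintf("rs%06d", 100000L + seq_len(n_pairs))
  sv_variants <- tibble(
    variant_id = sv_ids, chrom = pairs$chrom, pos = sv_start,
    ref = "N", alt = paste0("<", pairs$sv_type, ">"), kind = "SV",
    end_info = sv_end,
    sv_length = ifelse(pairs$sv_type == "INS", pairs$sv_len, -pairs$sv_len))
  snp_variants <- tibble(
    variant_id = rsids, chrom = pairs$chrom, pos = snp_pos,
    ref = "A", alt = "G", kind = "SNP",
    end_info = NA_real_, sv_length = NA_real_)

  sv_panel <- geno_panel(samples, sv_variants, sv_calls)
  snp_panel <- geno_panel(samples, snp_variants, snp_calls)

  sv_vcf <- file.path(dir, "planted_sv.vcf")
  snp_vcf <- file.path(dir, "planted_snp.vcf")
  write_genotype_vcf(sv_panel, sv_vcf)
  write_genotype_vcf(snp_panel, snp_vcf)

  gwas <- tibble(
    SNPS = rsids,
    CHR_ID = norm_chrom(pairs$chrom),
    CHR_POS = format(snp_pos, scientific = FALSE, trim = TRUE),
    `DISEASE/TRAIT` = pairs$trait,
    `P-VALUE` = format(pairs$gwas_p, scientific = TRUE, trim = TRUE),
    PUBMEDID = sprintf("%d", 30000000L + seq_len(n_pairs)))
  gwas_tsv <- file.path(dir, "planted_gwas.tsv")
  readr::write_tsv(gwas, gwas_tsv, progress = FALSE)

  # truth from realized genotypes, in pipeline filter order
  truth <- purrr::map_dfr(seq_len(n_pairs), function(i) {
    res <- g_squared(tabulate_double_genotypes(sv_calls[, i], snp_calls[, i]))
    win_lo <- max(1, sv_start[i] - flank)
    win_hi <- sv_end[i] + flank
    in_window <- snp_pos[i] >= win_lo & snp_pos[i] <= win_hi
    gwas_sig <- pairs$gwas_p[i] < gwas_p_threshold
    excluded_by <- if (!gwas_sig) "gwas_p"
      else if (!in_window) "window"
      else if (res$degenerate) "degenerate"
      else if (res$g_squared < min_g2) "g2"
      else "none"
    tibble(sv_id = sv_ids[i], snp_id = rsids[i], chrom = pairs$chrom[i],
           sv_start = sv_start[i], sv_end = sv_end[i], snp_pos = snp_pos[i],
           gwas_p = pairs$gwas_p[i], trait = pairs$trait[i],
           realized_g2 = res$g_squared, n_samples = res$n_samples,
           in_window = in_window, gwas_significant = gwas_sig,
           degenerate = res$degenerate,
           expected_in_catalog = excluded_by == "none",
           excluded_by = excluded_by)
  })
  truth_tsv <- file.path(dir, "planted_truth.tsv")
  readr::write_tsv(truth, truth_tsv, progress = FALSE)

  list(sv_vcf = sv_vcf, snp_vcf = snp_vcf, gwas_tsv = gwas_tsv,
       truth_tsv = truth_tsv, truth = truth,
       sv_panel = sv_panel, snp_panel = snp_panel)
}
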