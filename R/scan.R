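#' Scan for SVs in high LD with GWAS-significant SNPs
#'
#' Runs the full catalog workflow: read the SV and SNP genotype panels,
#' restrict them to their shared samples, read the association table and
#' keep genome-wide-significant rows (`p < gwas_p_threshold`, strict), match
#' them to genotyped SNPs by chromosome and position, enumerate candidate
#' pairs within `flank` bp of each SV's endpoints, tabulate the nine double
#' genotypes per pair, compute the genotypic squared correlation g2 with its
#' chi-square LD p-value, and keep pairs with `g2 >= min_g2`. The g2
#' threshold is inclusive (a pair at exactly 0.80 is retained); 0.80 is the
#' consensus tag-SNP proxy level.
#'
#' The scan is deterministic: identical inputs produce an identical catalog.
#' Pairs where either site is monomorphic among the shared samples are
#' counted and skipped, never an error.
#'
#' @param sv_vcf,snp_vcf Paths to the SV and SNP genotype VCFs.
#' @param gwas_tsv Path to the association table (see [read_associations()]).
#' @param flank Window size in bp around the SV endpoints (default `1e5`).
#' @param min_g2 Minimum g2 for a pair to enter the catalog (default `0.80`,
#'   inclusive).
#' @param gwas_p_threshold GWAS significance threshold (default `5e-8`,
#'   strict `<`).
#' @param include_snps_inside_sv Keep SNPs located inside the SV body
#'   (default `TRUE`).
#' @param collapse Emit one row per (SV, SNP) pair with traits concatenated
#'   (`"; "`-separated, minimum GWAS p-value) instead of one row per trait
#'   association (default `FALSE`).
#' @param keep_filtered Passed to [read_genotype_vcf()].
#' @param verbose Emit stage-boundary messages with the attrition counts
#'   (default `TRUE`).
#' @return An object of class `svld_scan`: a list with `catalog` (the
#'   filtered entries; see [write_catalog()] for the column layout), `pairs`
#'   (every scored candidate pair with its g2, before thresholding),
#'   `summary` (one-row tibble of stage counts) and `config`. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' \donttest{
#' fx <- build_fixture(plant_pairs_default(), n_diploid = 32, seed = 1,
#'                     dir = tempdir())
#' scan <- sv_snp_scan(fx$sv_vcf, fx$snp_vcf, fx$gwas_tsv, verbose = FALSE)
#' glance(scan)
#' }
#' @export
sv_snp_scan <- function(sv_vcf, snp_vcf, gwas_tsv,
                        flank = 1e5, min_g2 = 0.80, gwas_p_threshold = 5e-8,
                        include_snps_inside_sv = TRUE, collapse = FALSE,
                        keep_filtered = TRUE, verbose = TRUE) {
  if (min_g2 < 0 || min_g2 > 1) {
    stop_svld("min_g2 must lie in [0, 1]", "svld_format_error")
  }
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, svld_error = function(e) {
      abort(paste0("stage '", name, "': ", conditionMessage(e)),
            class = class(e), parent = e)
    })
  }

  sv_panel <- stage("read SV VCF",
                    read_genotype_vcf(sv_vcf, kind = "SV",
                                      keep_filtered = keep_filtered))
  snp_panel <- stage("read SNP VCF",
                     read_genotype_vcf(snp_vcf, kind = "SNP",
                                       keep_filtered = keep_filtered))
  say("read %d SVs, %d SNPs", nrow(sv_panel$variants), nrow(snp_panel$variants))

  shared <- stage("intersect samples", intersect_samples(sv_panel, snp_panel))
  sv_panel <- shared$a
  snp_panel <- shared$b
  say("shared samples: %d", length(sv_panel$samples))

  assoc <- stage("read associations", read_associations(gwas_tsv))
  sig <- filter_significant(assoc, threshold = gwas_p_threshold)
  say("associations: %d read, %d genome-wide significant", nrow(assoc), nrow(sig))

  matched <- stage("match SNPs", attach_genotyped_snp(sig, snp_panel))
  say("matched to genotyped SNPs: %d association rows (%d unmatched)",
      nrow(matched), attr(matched, "n_unmatched"))

  pairs <- stage("enumerate pairs", candidate_pairs(
    sv_panel$variants,
    dplyr::distinct(tibble(snp_id = matched$snp_id,
                           chrom = matched$chrom, pos = matched$pos)),
    flank = flank, include_inside_sv = include_snps_inside_sv))
  say("candidate pairs within %g bp: %d", flank, nrow(pairs))

  score_one <- function(sv_id, snp_id) {
    tab <- tryCatch(
      tabulate_double_genotypes(sv_panel$calls[, sv_id],
                                snp_panel$calls[, snp_id]),
      svld_no_data_error = function(e) NULL)
    if (is.null(tab)) {
      return(tibble(g_squared = NA_real_, n_samples = 0L,
                    p_value = NA_real_, degenerate = TRUE))
    }
    g_squared(tab)
  }
  empty_scores <- tibble(g_squared = numeric(), n_samples = integer(),
                         p_value = numeric(), degenerate = logical())
  scored <- dplyr::bind_cols(
    pairs,
    if (nrow(pairs) == 0) empty_scores
    else purrr::map2_dfr(pairs$sv_id, pairs$snp_id, score_one)
  )
  n_degenerate <- sum(scored$degenerate)
  passing <- scored[!scored$degenerate & scored$g_squared >= min_g2, ,
                    drop = FALSE]
  say("scored pairs: %d degenerate skipped, %d with g2 >= %g",
      n_degenerate, nrow(passing), min_g2)

  sv_meta <- sv_span(sv_panel$variants)
  catalog <- passing |>
    dplyr::left_join(
      tibble(snp_id = matched$snp_id, snp_rsid = matched$rsid,
             snp_ref = matched$snp_ref, snp_alt = matched$snp_alt,
             trait = matched$trait, gwas_p_value = matched$p_value,
             pubmed_id = matched$pubmed_id),
      by = "snp_id", relationship = "many-to-many") |>
    dplyr::left_join(
      tibble(sv_id = sv_meta$variant_id, sv_length = sv_meta$sv_length),
      by = "sv_id") |>
    dplyr::transmute(
      sv_id = .data$sv_id, sv_chrom = .data$chrom,
      sv_start = .data$sv_start, sv_end = .data$sv_end,
      sv_length = .data$sv_length,
      snp_rsid = .data$snp_rsid, snp_pos = .data$snp_pos,
      snp_ref = .data$snp_ref, snp_alt = .data$snp_alt,
      g_squared = .data$g_squared, ld_p_value = .data$p_value,
      n_samples = .data$n_samples, distance_bp = .data$distance_bp,
      trait = .data$trait, gwas_p_value = .data$gwas_p_value,
      pubmed_id = .data$pubmed_id) |>
    dplyr::arrange(.data$sv_chrom, .data$sv_start, .data$snp_pos, .data$trait)

  if (collapse) {
    catalog <- catalog |>
      dplyr::group_by(dplyr::across(c("sv_id", "sv_chrom", "sv_start",
                                      "sv_end", "sv_length", "snp_rsid",
                                      "snp_pos", "snp_ref", "snp_alt",
                                      "g_squared", "ld_p_value", "n_samples",
                                      "distance_bp"))) |>
      dplyr::summarise(
        trait = paste(sort(unique(.data$trait)), collapse = "; "),
        gwas_p_value = min(.data$gwas_p_value),
        pubmed_id = paste(sort(unique(.data$pubmed_id)), collapse = ";"),
        .groups = "drop") |>
      dplyr::arrange(.data$sv_chrom, .data$sv_start, .data$snp_pos, .data$trait)
  }

  if (nrow(catalog) == 0) warn("scan produced an empty catalog")

  summary <- tibble(
    n_samples_shared = length(sv_panel$samples),
    svs_read = nrow(sv_panel$variants),
    snps_read = nrow(snp_panel$variants),
    associations_total = nrow(assoc),
    associations_significant = nrow(sig),
    snps_matched = dplyr::n_distinct(matched$snp_id),
    candidate_pairs = nrow(pairs),
    degenerate_pairs = n_degenerate,
    pairs_passing = nrow(passing),
    catalog_rows = nrow(catalog),
    unique_svs = dplyr::n_distinct(catalog$sv_id),
    unique_snps = dplyr::n_distinct(catalog$snp_rsid),
    unique_traits = dplyr::n_distinct(catalog$trait)
  )
  structure(list(catalog = catalog, pairs = scored, summary = summary,
                 config = list(sv_vcf = sv_vcf, snp_vcf = snp_vcf,
                               gwas_tsv = gwas_tsv, flank = flank,
                               min_g2 = min_g2,
                               gwas_p_threshold = gwas_p_threshold,
                               include_snps_inside_sv = include_snps_inside_sv,
                               collapse = collapse)),
            class = "svld_scan")
}

#' @export
print.svld_scan <- function(x, ...) {
  s <- x$summary
  cat("SV-SNP LD scan\n")
  cat(sprintf("  samples shared: %d\n", s$n_samples_shared))
  cat(sprintf("  SVs %d | SNPs %d | significant associations %d\n",
              s$svs_read, s$snps_read, s$associations_significant))
  cat(sprintf("  candidate pairs %d -> passing g2 >= %g: %d (%d degenerate skipped)\n",
              s$candidate_pairs, x$config$min_g2, s$pairs_passing,
              s$degenerate_pairs))
  cat(sprintf("  catalog: %d rows, %d SVs, %d SNPs, %d traits\n",
              s$catalog_rows, s$unique_svs, s$unique_snps, s$unique_traits))
  invisible(x)
}

#' @describeIn sv_snp_scan Return the catalog as a tibble.
#' @param x An `svld_scan` object.
#' @param ... Unused.
#' @export
tidy.svld_scan <- function(x, ...) x$catalog

#' @describeIn sv_snp_scan Return the one-row stage-count summary.
#' @export
glance.svld_scan <- function(x, ...) x$summary

#' Write a scan catalog to TSV
#'
#' Writes the catalog with a fixed header, rows sorted by (chromosome, SV
#' start, SNP position, trait) and floating-point columns formatted at six
#' significant digits, so re-running an identical scan yields a byte-identical
#' file. The file round-trips through [read_catalog()].
#'
#' @param x An `svld_scan` object or a catalog tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(x, path) {
  catalog <- if (inherits(x, "svld_scan")) x$catalog else as_tibble(x)
  fmt <- function(v) ifelse(is.na(v), "NA",
                            trimws(formatC(v, digits = 6, format = "g")))
  out <- catalog |>
    dplyr::mutate(dplyr::across(c("g_squared", "ld_p_value", "gwas_p_value"), fmt),
                  dplyr::across(c("sv_start", "sv_end", "sv_length", "snp_pos",
                                  "n_samples", "distance_bp"),
                                ~ ifelse(is.na(.x), "NA",
                                         format(.x, scientific = FALSE,
                                                trim = TRUE))))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a scan catalog written by [write_catalog()]
#'
#' @param path Path to a catalog TSV.
#' @return The catalog tibble with numeric columns restored.
#' @export
read_catalog <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sv_id = "c", sv_chrom = "c", sv_start = "d", sv_end = "d",
    sv_length = "d", snp_rsid = "c", snp_pos = "d", snp_ref = "c",
    snp_alt = "c", g_squared = "d", ld_p_value = "d", n_samples = "d",
    distance_bp = "d", trait = "c", gwas_p_value = "d", pubmed_id = "c"),
    progress = FALSE)
}
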