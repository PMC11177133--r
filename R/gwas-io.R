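#' Read a GWAS-catalog style association table
#'
#' Parses a tab-separated association table into a tibble of one row per
#' SNP-trait association. Two header dialects are recognized
#' (case-insensitively):
#'
#' * the GWAS Catalog export: `SNPS`, `CHR_ID`, `CHR_POS`, `P-VALUE`,
#'   `DISEASE/TRAIT`, `PUBMEDID` (and optionally
#'   `STRONGEST SNP-RISK ALLELE`);
#' * a minimal generic dialect: `rsid`, `chrom`, `pos`, `p_value`, `trait`,
#'   `pubmed_id` (and optionally `risk_allele`).
#'
#' Rows listing several rsIDs in one field (haplotype entries, `"rs1 x rs2"`
#' or semicolon/comma separated) are dropped and counted, as are rows whose
#' position or p-value does not parse or lies outside (0, 1]. Scientific
#' notation p-values (`"5E-08"`, `"2E-246"`) parse as ordinary doubles; a
#' reported p-value so small that it underflows to zero is clamped to the
#' smallest positive normal double and flagged in the `underflow` column.
#'
#' @param path Path to a tab-separated association file with a header.
#' @return A tibble with columns `rsid`, `chrom` (normalized, no `"chr"`
#'   prefix), `pos`, `p_value`, `trait`, `pubmed_id`, `risk_allele`,
#'   `underflow`, plus a `counts` attribute recording dropped rows.
#' @seealso [filter_significant()], [attach_genotyped_snp()]
#' @export
read_associations <- function(path) {
  if (!file.exists(path)) {
    stop_svld(paste0("association table not found: ", path), "svld_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  lookup <- function(candidates) {
    hit <- match(tolower(candidates), tolower(names(raw)))
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0) NULL else names(raw)[hit[1]]
  }
  cols <- list(
    rsid      = lookup(c("SNPS", "rsid", "snp", "snp_id")),
    chrom     = lookup(c("CHR_ID", "chrom", "chr", "chromosome")),
    pos       = lookup(c("CHR_POS", "pos", "position", "bp")),
    p_value   = lookup(c("P-VALUE", "p_value", "pvalue", "p")),
    trait     = lookup(c("DISEASE/TRAIT", "trait", "disease_trait", "phenotype")),
    pubmed_id = lookup(c("PUBMEDID", "pubmed_id", "pmid"))
  )
  absent <- names(cols)[vapply(cols, is.null, logical(1))]
  if (length(absent) > 0) {
    stop_svld(paste0("association table lacks required column(s): ",
                     paste(absent, collapse = ", ")), "svld_format_error")
  }
  risk_col <- lookup(c("STRONGEST SNP-RISK ALLELE", "risk_allele"))

  out <- tibble(
    rsid = raw[[cols$rsid]],
    chrom = norm_chrom(raw[[cols$chrom]]),
    pos = suppressWarnings(as.numeric(raw[[cols$pos]])),
    p_value = suppressWarnings(as.numeric(raw[[cols$p_value]])),
    trait = raw[[cols$trait]],
    pubmed_id = raw[[cols$pubmed_id]],
    risk_allele = if (is.null(risk_col)) NA_character_ else raw[[risk_col]]
  )
  n_total <- nrow(out)

  multi <- grepl("[;,]|\\bx\\b", out$rsid)
  out <- out[!multi, , drop = FALSE]
  n_multi <- sum(multi)

  # p-values printed below double range underflow to 0 on parse; keep them as
  # the smallest positive normal rather than discarding a real association
  zero_p <- !is.na(out$p_value) & out$p_value == 0
  out$underflow <- zero_p
  out$p_value[zero_p] <- .Machine$double.xmin

  ok <- !is.na(out$pos) & out$pos >= 1 &
    !is.na(out$p_value) & out$p_value > 0 & out$p_value <= 1 &
    !is.na(out$rsid) & out$rsid != ""
  n_unparseable <- sum(!ok)
  out <- out[ok, , drop = FALSE]

  if (n_multi + n_unparseable > 0) {
    warn(sprintf("%s: dropped %d of %d rows (%d multi-SNP, %d unparseable)",
                 basename(path), n_multi + n_unparseable, n_total,
                 n_multi, n_unparseable))
  }
  attr(out, "counts") <- c(total = n_total, retained = nrow(out),
                           multi_snp = n_multi, unparseable = n_unparseable)
  out
}

#' Keep genome-wide-significant associations
#'
#' Retains associations with `p_value` strictly below the threshold. The
#' conventional genome-wide significance level 5e-8 is the default, and the
#' comparison is strict: a p-value of exactly 5e-8 is excluded.
#'
#' @param associations Tibble from [read_associations()].
#' @param threshold Significance threshold (default `5e-8`).
#' @return The filtered tibble, original ordering preserved.
#' @examples
#' a <- tibble::tibble(rsid = c("rs1", "rs2"), chrom = "1", pos = c(1e6, 2e6),
#'                     p_value = c(4e-14, 9.13e-7), trait = "t",
#'                     pubmed_id = "1", risk_allele = NA, underflow = FALSE)
#' filter_significant(a)
#' @export
filter_significant <- function(associations, threshold = 5e-8) {
  if (length(threshold) != 1 || is.na(threshold) || threshold <= 0 || threshold > 1) {
    stop_svld("threshold must be a single value in (0, 1]", "svld_format_error")
  }
  dplyr::filter(associations, .data$p_value < threshold)
}

#' Match associations to genotyped SNPs
#'
#' Joins an association table to the SNP genotype panel by chromosome and
#' 1-based position (chromosome names are normalized on both sides). Allele
#' or rsID disagreements between the catalog and the panel do not break a
#' positional match but are flagged (`id_conflict`), since the LD statistic
#' is computed from the genotype panel alone and identity affects labeling
#' only. Associations with no genotyped SNP at their locus are counted in
#' the `n_unmatched` attribute, not raised.
#'
#' @param associations Tibble from [read_associations()] (typically after
#'   [filter_significant()]).
#' @param panel A SNP [geno_panel()].
#' @return A tibble of matches: the association columns plus `snp_id`,
#'   `snp_ref`, `snp_alt` and `id_conflict`, with attribute `n_unmatched`.
#' @export
attach_genotyped_snp <- function(associations, panel) {
  snps <- panel$variants
  snp_tbl <- tibble(
    snp_id = snps$variant_id,
    chrom = norm_chrom(snps$chrom),
    pos = snps$pos,
    snp_ref = snps$ref,
    snp_alt = snps$alt
  )
  matched <- dplyr::inner_join(associations, snp_tbl,
                               by = c("chrom", "pos"),
                               relationship = "many-to-many")
  matched$id_conflict <- !is.na(matched$rsid) & !is.na(matched$snp_id) &
    grepl("^rs", matched$snp_id) & matched$rsid != matched$snp_id
  n_unmatched <- nrow(dplyr::anti_join(associations, snp_tbl,
                                       by = c("chrom", "pos")))
  attr(matched, "n_unmatched") <- n_unmatched
  matched
}
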