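#' Encode diploid VCF genotype strings
#'
#' Maps raw diploid GT strings to integer genotype codes: `0` = hom-ref,
#' `1` = het, `2` = hom-alt, `NA` = missing. Phase separators (`/` and `|`)
#' are treated identically because the analysis is unphased. A lone `"."` is
#' treated as a missing call. Haploid or higher-ploidy calls, and allele
#' indices above 1 (non-biallelic), are rejected: the VCF reader skips such
#' sites with a warning rather than guessing.
#'
#' @param gt_field Character vector of GT strings (`"0/0"`, `"0|1"`, `"./."`,
#'   ...). Trailing FORMAT subfields (`"0/1:35"`) are tolerated and stripped.
#' @return Integer vector of genotype codes.
#' @examples
#' encode_genotype(c("0|1", "./.", "1/1", "0/0"))
#' @export
encode_genotype <- function(gt_field) {
  gt <- sub(":.*$", "", as.character(gt_field))
  gt[is.na(gt) | gt == "."] <- "./."
  gt <- gsub("|", "/", gt, fixed = TRUE)
  ok <- grepl("^(\\.|[0-9]+)/(\\.|[0-9]+)$", gt)
  if (!all(ok)) {
    stop_svld(sprintf("non-diploid genotype call(s): %s",
                      paste(unique(gt[!ok])[1:min(3, sum(!ok))], collapse = ", ")),
              "svld_nondiploid_error")
  }
  a1 <- sub("/.*$", "", gt)
  a2 <- sub("^.*/", "", gt)
  miss <- a1 == "." | a2 == "."
  a1[miss] <- "0"; a2[miss] <- "0"
  a1 <- as.integer(a1); a2 <- as.integer(a2)
  if (any(a1 > 1L | a2 > 1L)) {
    stop_svld("allele index above 1: site is not biallelic",
              "svld_nonbiallelic_error")
  }
  code <- a1 + a2
  code[miss] <- NA_integer_
  code
}

#' Decode genotype codes back to GT strings
#'
#' Inverse of [encode_genotype()] for the four codes; used by the VCF writer.
#'
#' @param code Integer vector of genotype codes (0, 1, 2 or `NA`).
#' @return Character vector of unphased GT strings.
#' @examples
#' decode_genotype(c(0L, 1L, 2L, NA))
#' @export
decode_genotype <- function(code) {
  out <- c("0/0", "0/1", "1/1")[as.integer(code) + 1L]
  out[is.na(code)] <- "./."
  out
}

#' Genotype panels
#'
#' A genotype panel couples an ordered sample list, a variant table and a
#' samples-by-variants matrix of genotype codes. The variant table is a
#' tibble with columns `variant_id`, `chrom`, `pos` (1-based), `ref`, `alt`,
#' `kind` (`"SV"` or `"SNP"`), `end_info` (1-based inclusive END for SVs,
#' `NA` otherwise) and `sv_length` (signed bp, insertions positive,
#' deletions negative, `NA` for SNPs).
#'
#' @param samples Character vector of sample IDs.
#' @param variants Tibble of variant records as described above.
#' @param calls Integer matrix of genotype codes, `length(samples)` rows by
#'   `nrow(variants)` columns.
#' @return An object of class `geno_panel`.
#' @seealso [read_genotype_vcf()], [intersect_samples()]
#' @export
geno_panel <- function(samples, variants, calls) {
  samples <- as.character(samples)
  variants <- as_tibble(variants)
  required <- c("variant_id", "chrom", "pos", "ref", "alt", "kind",
                "end_info", "sv_length")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0) {
    stop_svld(paste0("variant table lacks column(s): ",
                     paste(missing_cols, collapse = ", ")),
              "svld_panel_error")
  }
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(samples) || ncol(calls) != nrow(variants)) {
    stop_svld("calls matrix must be samples x variants", "svld_panel_error")
  }
  if (any(!is.na(calls) & (calls < 0L | calls > 2L))) {
    stop_svld("genotype codes must be 0, 1, 2 or NA", "svld_panel_error")
  }
  if (anyDuplicated(samples)) {
    stop_svld("duplicate sample IDs in panel", "svld_panel_error")
  }
  dimnames(calls) <- list(samples, variants$variant_id)
  structure(list(samples = samples, variants = variants, calls = calls),
            class = "geno_panel")
}

#' @export
print.geno_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d samples x %d variants (%s)\n",
              length(x$samples), nrow(x$variants),
              paste(unique(x$variants$kind), collapse = "/")))
  print(head(x$variants, 5), ...)
  invisible(x)
}

#' Reference span of structural variants
#'
#' Resolves the reference-coordinate interval each SV occupies. Deletions
#' span `[pos, END]`, using the END annotation when present and falling back
#' to `pos + |sv_length|`; insertions have a zero-length reference footprint,
#' so their span collapses to the anchor position. SNP rows pass through
#' with `span_start = span_end = pos`.
#'
#' @param variants A variant tibble (see [geno_panel()]) or a `geno_panel`.
#' @return The variant tibble with `span_start` and `span_end` columns added.
#' @examples
#' v <- tibble::tibble(variant_id = "SV1", chrom = "chr1", pos = 200000,
#'                     ref = "N", alt = "<DEL>", kind = "SV",
#'                     end_info = NA_real_, sv_length = -5000)
#' sv_span(v)
#' @export
sv_span <- function(variants) {
  if (inherits(variants, "geno_panel")) variants <- variants$variants
  variants <- as_tibble(variants)
  is_sv <- variants$kind == "SV"
  is_ins <- is_sv & !is.na(variants$sv_length) & variants$sv_length > 0
  no_info <- is_sv & !is_ins & is.na(variants$end_info) & is.na(variants$sv_length)
  if (any(no_info)) {
    stop_svld(sprintf("SV record(s) without END or length information: %s",
                      paste(head(variants$variant_id[no_info], 3), collapse = ", ")),
              "svld_malformed_record_error")
  }
  end <- variants$pos
  del <- is_sv & !is_ins
  end[del] <- ifelse(!is.na(variants$end_info[del]),
                     variants$end_info[del],
                     variants$pos[del] + abs(variants$sv_length[del]))
  if (any(end < variants$pos)) {
    stop_svld("SV span end precedes its start", "svld_malformed_record_error")
  }
  variants$span_start <- variants$pos
  variants$span_end <- end
  variants
}

#' Restrict two panels to their shared samples
#'
#' Subsets both panels to the sample IDs present in each, in a canonical
#' (lexicographic) order so downstream output is independent of input sample
#' ordering. A warning is raised when fewer than 20 samples are shared, since
#' LD estimates from very small panels are noisy (the reference human panel
#' motivating the defaults has 32 genomes).
#'
#' @param panel_a,panel_b [geno_panel()] objects.
#' @return A list with elements `a` and `b`: the two panels restricted to the
#'   shared samples in identical order.
#' @export
intersect_samples <- function(panel_a, panel_b) {
  shared <- sort(intersect(panel_a$samples, panel_b$samples))
  if (length(shared) == 0) {
    stop_svld("the two panels share no samples", "svld_no_common_samples_error")
  }
  if (length(shared) < 20) {
    warn(sprintf("only %d samples shared between panels; LD estimates will be noisy",
                 length(shared)))
  }
  take <- function(panel) {
    geno_panel(shared, panel$variants,
               panel$calls[match(shared, panel$samples), , drop = FALSE])
  }
  list(a = take(panel_a), b = take(panel_b))
}
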