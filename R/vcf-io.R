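#' Read a genotype panel from VCF
#'
#' Loads a VCF (plain or gzipped) into a [geno_panel()], keeping only
#' biallelic records with parseable diploid GT calls. Multi-allelic rows and
#' rows whose GT column contains haploid/polyploid or out-of-range allele
#' calls are dropped with a counted warning; the per-category counts are
#' attached to the result as `attr(panel, "counts")` so the attrition is
#' auditable (`retained + multiallelic + nondiploid + filtered = scanned`).
#'
#' For `kind = "SV"` the `END` and `SVLEN` INFO annotations are carried into
#' the variant table (`end_info`, `sv_length`); either explicit REF/ALT
#' sequences or symbolic alleles (`<DEL>`, `<INS>`) are accepted.
#'
#' @param path Path to a VCF file with a GT FORMAT field.
#' @param kind `"SNP"` or `"SV"`; controls span-metadata extraction.
#' @param region Optional `"chrom:start-end"` string; records outside the
#'   interval are discarded after reading.
#' @param keep_filtered Keep records with a non-PASS FILTER status (default
#'   `TRUE`, since filter semantics vary across SV call sets); set `FALSE`
#'   to retain only PASS/`.` rows.
#' @return A [geno_panel()] with a `counts` attribute.
#' @seealso [write_genotype_vcf()]
#' @export
read_genotype_vcf <- function(path, kind = c("SNP", "SV"), region = NULL,
                              keep_filtered = TRUE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop_svld(paste0("VCF not found: ", path), "svld_io_error")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n_total <- nrow(fix)
  counts <- c(scanned = n_total, retained = 0L, multiallelic = 0L,
              nondiploid = 0L, filtered = 0L)

  samples <- colnames(vcf@gt)[-1]
  if (is.null(samples)) samples <- character(0)

  empty_panel <- function() {
    variants <- tibble(variant_id = character(), chrom = character(),
                       pos = numeric(), ref = character(), alt = character(),
                       kind = character(), end_info = numeric(),
                       sv_length = numeric())
    p <- geno_panel(samples, variants,
                    matrix(integer(0), nrow = length(samples), ncol = 0))
    attr(p, "counts") <- counts
    p
  }
  if (n_total == 0) return(empty_panel())

  if (!grepl("GT", vcf@gt[1, "FORMAT"])) {
    stop_svld("VCF has no GT FORMAT field", "svld_format_error")
  }

  keep <- rep(TRUE, n_total)
  alt <- fix[, "ALT"]
  multi <- is.na(alt) | alt == "." | grepl(",", alt, fixed = TRUE)
  counts["multiallelic"] <- sum(multi & keep)
  keep <- keep & !multi
  if (!keep_filtered) {
    filt <- fix[, "FILTER"]
    bad_filter <- !(is.na(filt) | filt %in% c("PASS", "."))
    counts["filtered"] <- sum(bad_filter & keep)
    keep <- keep & !bad_filter
  }

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  calls <- matrix(NA_integer_, nrow = n_total, ncol = length(samples))
  for (i in which(keep)) {
    coded <- tryCatch(encode_genotype(gt_raw[i, ]), svld_error = function(e) e)
    if (inherits(coded, "svld_error")) {
      keep[i] <- FALSE
      counts["nondiploid"] <- counts["nondiploid"] + 1L
    } else {
      calls[i, ] <- coded
    }
  }
  counts["retained"] <- sum(keep)
  n_dropped <- n_total - counts["retained"]
  if (n_dropped > 0) {
    warn(sprintf("%s: dropped %d of %d records (%d multi-allelic, %d non-diploid/malformed GT, %d non-PASS)",
                 basename(path), n_dropped, n_total,
                 counts[["multiallelic"]], counts[["nondiploid"]],
                 counts[["filtered"]]))
  }
  if (!any(keep)) return(empty_panel())

  id <- unname(fix[keep, "ID"])
  chrom <- unname(fix[keep, "CHROM"])
  pos <- as.numeric(fix[keep, "POS"])
  no_id <- is.na(id) | id == "."
  id[no_id] <- paste0(chrom[no_id], "_", pos[no_id])

  if (kind == "SV") {
    end_info <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "END")))[keep]
    sv_length <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "SVLEN")))[keep]
  } else {
    end_info <- rep(NA_real_, sum(keep))
    sv_length <- rep(NA_real_, sum(keep))
  }

  variants <- tibble(
    variant_id = id, chrom = chrom, pos = pos,
    ref = unname(fix[keep, "REF"]), alt = unname(alt[keep]),
    kind = kind, end_info = end_info, sv_length = sv_length
  )
  calls <- t(calls[keep, , drop = FALSE])

  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) {
      stop_svld("region must be of the form 'chrom:start-end'", "svld_format_error")
    }
    in_region <- norm_chrom(variants$chrom) == norm_chrom(m[2]) &
      variants$pos >= as.numeric(m[3]) & variants$pos <= as.numeric(m[4])
    variants <- variants[in_region, , drop = FALSE]
    calls <- calls[, in_region, drop = FALSE]
  }

  panel <- geno_panel(samples, variants, calls)
  attr(panel, "counts") <- counts
  panel
}

#' Write a genotype panel to VCF
#'
#' Emits a minimal standard-compliant VCF 4.2 file (GT FORMAT; END, SVLEN
#' and SVTYPE INFO definitions; contig lines) that round-trips through
#' [read_genotype_vcf()] to an identical panel. SV records are written with
#' symbolic `<DEL>`/`<INS>` alleles and their END/SVLEN annotations; SVLEN
#' signs are preserved.
#'
#' @param panel A [geno_panel()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(panel, path) {
  if (!inherits(panel, "geno_panel")) {
    stop_svld("panel must be a geno_panel", "svld_panel_error")
  }
  v <- sv_span(panel$variants)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=svldscan",
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant described in this record">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Signed length difference between the REF and ALT alleles">',
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (nrow(v) > 0) {
    contig_len <- tapply(pmax(v$pos, v$span_end) + 10000L, v$chrom, max)
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(contig_len), as.integer(contig_len)))
  }
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", panel$samples),
                            collapse = "\t"))
  body <- character(0)
  if (nrow(v) > 0) {
    info <- rep(".", nrow(v))
    is_sv <- v$kind == "SV"
    if (any(is_sv)) {
      svtype <- ifelse(!is.na(v$sv_length[is_sv]) & v$sv_length[is_sv] > 0,
                       "INS", "DEL")
      info[is_sv] <- paste0(
        "END=", as.integer(v$span_end[is_sv]),
        ifelse(is.na(v$sv_length[is_sv]), "",
               paste0(";SVLEN=", as.integer(v$sv_length[is_sv]))),
        ";SVTYPE=", svtype)
    }
    gt_strings <- matrix("./.", nrow = length(panel$samples), ncol = nrow(v))
    if (length(panel$samples) > 0) {
      gt_strings <- matrix(decode_genotype(panel$calls),
                           nrow = length(panel$samples), ncol = nrow(v))
    }
    body <- vapply(seq_len(nrow(v)), function(i) {
      paste(c(v$chrom[i], format(v$pos[i], scientific = FALSE),
              v$variant_id[i], v$ref[i], v$alt[i], ".", "PASS", info[i], "GT",
              if (length(panel$samples)) gt_strings[, i]), collapse = "\t")
    }, character(1))
  }
  writeLines(c(header, body), path)
  invisible(path)
}
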