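#' Double-genotype count tables
#'
#' For two biallelic sites typed in the same diploid individuals there are
#' nine possible joint ("double") genotypes. A `geno_table` holds their
#' counts as a 3x3 matrix: rows are the SV genotype (`A1A1`, `A1A2`, `A2A2`),
#' columns the SNP genotype (`B1B1`, `B1B2`, `B2B2`). The cells correspond to
#' the counts x1..x9 read row by row, so `x[1]` is `num(A1A1, B1B1)` and
#' `x[9]` is `num(A2A2, B2B2)`.
#'
#' Counts may be real-valued: expected tables under a population model (see
#' [hwe_expected_table()]) are continuous, and every moment used downstream
#' is linear in the cells, so the estimator extends unchanged.
#'
#' @param x Numeric vector of length 9 (x1..x9, row-major) or a 3x3 matrix
#'   of non-negative counts.
#' @return An object of class `geno_table`: a 3x3 numeric matrix with
#'   genotype dimnames.
#' @examples
#' geno_table(c(10, 5, 1, 4, 20, 4, 1, 5, 10))
#' @seealso [tabulate_double_genotypes()], [g_squared()]
#' @export
geno_table <- function(x) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(3L, 3L))) {
      stop_svld("a genotype count table must be 3x3", "svld_table_error")
    }
    x <- as.vector(t(x)) # row-major x1..x9
  }
  x <- as.numeric(x)
  if (length(x) != 9L) {
    stop_svld("a genotype count table needs 9 cells (x1..x9)", "svld_table_error")
  }
  if (anyNA(x) || any(x < 0)) {
    stop_svld("genotype counts must be non-negative and non-missing", "svld_table_error")
  }
  m <- matrix(x, nrow = 3L, byrow = TRUE,
              dimnames = list(sv = c("A1A1", "A1A2", "A2A2"),
                              snp = c("B1B1", "B1B2", "B2B2")))
  structure(m, class = c("geno_table", "matrix", "array"))
}

#' @export
print.geno_table <- function(x, ...) {
  cat("Double-genotype count table (N = ", format(sum(x)), ")\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

# accept a geno_table or anything geno_table() accepts; return x1..x9 vector
as_cell_counts <- function(table) {
  if (!inherits(table, "geno_table")) table <- geno_table(table)
  as.vector(t(unclass(table)))
}

#' Tabulate the nine double genotypes of an SV-SNP pair
#'
#' Cross-tabulates per-sample unphased genotype codes at two biallelic sites
#' into the 3x3 [geno_table()] of double-genotype counts. Genotype codes are
#' integers counting alternate alleles: `0` = homozygous reference, `1` =
#' heterozygous, `2` = homozygous alternate, `NA` = missing. Samples missing
#' at either site are excluded (pairwise-complete), so the table total N is
#' specific to the pair.
#'
#' @param sv_gt,snp_gt Integer genotype code vectors of equal length, aligned
#'   by sample.
#' @return A [geno_table()] whose total equals the number of samples
#'   non-missing at both sites.
#' @examples
#' tabulate_double_genotypes(c(0L, 1L, 2L), c(0L, 1L, 2L))
#' @export
tabulate_double_genotypes <- function(sv_gt, snp_gt) {
  if (length(sv_gt) != length(snp_gt)) {
    stop_svld("sv_gt and snp_gt must be aligned vectors of equal length",
              "svld_alignment_error")
  }
  sv_gt <- as.integer(sv_gt)
  snp_gt <- as.integer(snp_gt)
  bad <- function(g) any(!is.na(g) & (g < 0L | g > 2L))
  if (bad(sv_gt) || bad(snp_gt)) {
    stop_svld("genotype codes must be 0 (hom-ref), 1 (het), 2 (hom-alt) or NA",
              "svld_table_error")
  }
  keep <- !is.na(sv_gt) & !is.na(snp_gt)
  if (!any(keep)) {
    stop_svld("no samples are non-missing at both sites", "svld_no_data_error")
  }
  cell <- 3L * sv_gt[keep] + snp_gt[keep] + 1L
  geno_table(tabulate(cell, nbins = 9L))
}
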