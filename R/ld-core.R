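#' Dosage moments of a double-genotype table
#'
#' Codes the genotypes at each site numerically as 1 (hom-ref), 2 (het),
#' 3 (hom-alt) and returns the five sample moments of the coded pair (X, Y)
#' implied by the cell counts: the cross moment E\[XY\], the means E\[X\] and
#' E\[Y\], and the raw second moments E\[X^2\] and E\[Y^2\]. Each is a linear
#' combination of the cells x1..x9 divided by N, so real-valued (expected)
#' tables are handled identically to integer ones.
#'
#' @param table A [geno_table()] (or anything `geno_table()` accepts).
#' @return A one-row tibble with columns `mu_xy`, `mu_x`, `mu_y`, `mu_x2`,
#'   `mu_y2` and `n`.
#' @examples
#' dosage_moments(geno_table(c(10, 5, 1, 4, 20, 4, 1, 5, 10)))
#' @export
dosage_moments <- function(table) {
  x <- as_cell_counts(table)
  n <- sum(x)
  if (n <= 0) stop_svld("table has no observations", "svld_no_data_error")
  tibble(
    mu_xy = sum(x * .dosage_x * .dosage_y) / n,
    mu_x  = sum(x * .dosage_x) / n,
    mu_y  = sum(x * .dosage_y) / n,
    mu_x2 = sum(x * .dosage_x^2) / n,
    mu_y2 = sum(x * .dosage_y^2) / n,
    n     = n
  )
}

#' Genotypic squared correlation g2 between two sites
#'
#' The linkage-disequilibrium statistic used throughout this package: the
#' squared Pearson correlation of the numerically coded (1/2/3) unphased
#' genotypes at two biallelic sites,
#' \deqn{g^2 = \frac{[\mu_{XY} - \mu_X \mu_Y]^2}
#'                  {[\mu_{X^2} - \mu_X^2][\mu_{Y^2} - \mu_Y^2]},}
#' computed from the nine double-genotype counts without any phasing step.
#' Under Hardy-Weinberg equilibrium g2 equals the standard haplotype-level
#' r2 (see [haplotype_r_squared()]); the package tests assert that identity.
#'
#' Internally the moments are assembled from weighted cell sums and divided
#' once, i.e. \eqn{(N S_{XY} - S_X S_Y)^2 / [(N S_{X^2} - S_X^2)(N S_{Y^2} -
#' S_Y^2)]}: for integer tables every sum is exact in double precision, so
#' tables whose g2 is a small rational (e.g. exactly 0.80) evaluate to the
#' correctly rounded double. Values exceeding 1 by at most `1e-12` (floating
#' error) are clamped to 1; larger excursions raise an internal-consistency
#' error.
#'
#' When either site is monomorphic among the counted samples the variance in
#' the denominator vanishes and g2 is undefined; the result is flagged
#' `degenerate` (never an error), so a scan can skip the pair.
#'
#' @param table A [geno_table()] (or anything `geno_table()` accepts).
#' @return A one-row tibble: `g_squared` (in \[0, 1\], `NA` if degenerate),
#'   `n_samples`, `p_value` (chi-square LD test, see [ld_pvalue()]; `NA` if
#'   degenerate), `degenerate` (logical).
#' @examples
#' g_squared(geno_table(c(2, 0, 0, 0, 0, 0, 0, 0, 2))) # perfect coupling
#' g_squared(geno_table(c(1, 2, 1, 2, 4, 2, 1, 2, 1))) # independence
#' @export
g_squared <- function(table) {
  x <- as_cell_counts(table)
  n <- sum(x)
  if (n <= 0) stop_svld("table has no observations", "svld_no_data_error")
  sx  <- sum(x * .dosage_x)
  sy  <- sum(x * .dosage_y)
  sxy <- sum(x * .dosage_x * .dosage_y)
  sx2 <- sum(x * .dosage_x^2)
  sy2 <- sum(x * .dosage_y^2)
  var_x <- n * sx2 - sx^2
  var_y <- n * sy2 - sy^2
  if (var_x <= 0 || var_y <= 0) {
    return(tibble(g_squared = NA_real_, n_samples = n,
                  p_value = NA_real_, degenerate = TRUE))
  }
  g2 <- (n * sxy - sx * sy)^2 / (var_x * var_y)
  if (g2 > 1) {
    if (g2 <= 1 + 1e-12) {
      g2 <- 1
    } else {
      stop_svld(sprintf("g2 = %.17g exceeds 1 beyond floating tolerance", g2),
                "svld_internal_error")
    }
  }
  tibble(g_squared = g2, n_samples = n,
         p_value = ld_pvalue(g2, n), degenerate = FALSE)
}

#' Chi-square p-value for the LD null hypothesis g2 = 0
#'
#' Refers the statistic `N * g2` to a chi-square distribution with one degree
#' of freedom, the dosage analogue of the standard allelic-trend LD test.
#' The p-value is strictly decreasing in g2 at fixed N and decreasing in N at
#' fixed g2 > 0; g2 = 0 gives p = 1.
#'
#' @param g_squared Numeric vector of g2 values in \[0, 1\] (`NA` allowed for
#'   degenerate pairs).
#' @param n_samples Number of samples behind each g2 (recycled).
#' @return Numeric vector of p-values in (0, 1\]; `NA` where `g_squared` is
#'   `NA`.
#' @examples
#' ld_pvalue(1, 32)
#' ld_pvalue(0, 32)
#' @export
ld_pvalue <- function(g_squared, n_samples) {
  if (any(!is.na(g_squared) & (g_squared < 0 | g_squared > 1))) {
    stop_svld("g_squared must lie in [0, 1]", "svld_internal_error")
  }
  if (any(!is.na(n_samples) & n_samples < 1)) {
    stop_svld("n_samples must be at least 1", "svld_no_data_error")
  }
  pchisq(n_samples * g_squared, df = 1, lower.tail = FALSE)
}

#' Brute-force dosage-expansion reference for g2
#'
#' Expands an integer count table into its N explicit per-individual dosage
#' pairs, computes the Pearson correlation with [stats::cor()], and returns
#' its square. This is a deliberately independent reference implementation
#' used to cross-check [g_squared()]; it is exported so the equivalence can
#' be audited, not as the production path.
#'
#' @param table A [geno_table()] with integer counts, N >= 2, neither site
#'   monomorphic.
#' @return The squared Pearson correlation of the expanded dosages.
#' @examples
#' dosage_pearson_oracle(geno_table(c(10, 5, 1, 4, 20, 4, 1, 5, 10)))
#' @export
dosage_pearson_oracle <- function(table) {
  x <- as_cell_counts(table)
  if (any(abs(x - round(x)) > 1e-9)) {
    stop_svld("dosage expansion requires integer counts", "svld_table_error")
  }
  x <- round(x)
  n <- sum(x)
  if (n < 2) stop_svld("need at least 2 observations", "svld_no_data_error")
  X <- rep(.dosage_x, times = x)
  Y <- rep(.dosage_y, times = x)
  if (length(unique(X)) < 2L || length(unique(Y)) < 2L) {
    stop_svld("a monomorphic site has no defined correlation",
              "svld_degenerate_error")
  }
  cor(X, Y)^2
}
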