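#' Two-locus haplotype frequencies
#'
#' Frequencies of the four haplotypes over two biallelic loci: `h11` (A1B1),
#' `h12` (A1B2), `h21` (A2B1), `h22` (A2B2). The A1 allele frequency is
#' `p = h11 + h12`, the B1 frequency `q = h11 + h21`, and the gametic
#' disequilibrium coefficient `D = h11*h22 - h12*h21`.
#'
#' @param h11,h12,h21,h22 Haplotype frequencies in \[0, 1\] summing to 1.
#'   `h11` may also be a length-4 numeric vector carrying all four.
#' @return A named numeric vector of class `hap_freqs`.
#' @examples
#' hap_freqs(0.4, 0.1, 0.1, 0.4)
#' @export
hap_freqs <- function(h11, h12 = NULL, h21 = NULL, h22 = NULL) {
  h <- if (length(h11) == 4L && is.null(h12)) as.numeric(h11)
       else as.numeric(c(h11, h12, h21, h22))
  if (length(h) != 4L || anyNA(h)) {
    stop_svld("haplotype frequencies need exactly four non-missing values",
              "svld_hap_error")
  }
  if (any(h < -1e-12) || any(h > 1 + 1e-12)) {
    stop_svld("haplotype frequencies must lie in [0, 1]", "svld_hap_error")
  }
  h <- pmin(pmax(h, 0), 1)
  if (abs(sum(h) - 1) > 1e-8) {
    stop_svld("haplotype frequencies must sum to 1", "svld_hap_error")
  }
  structure(setNames(h, c("h11", "h12", "h21", "h22")), class = "hap_freqs")
}

as_hap <- function(freqs) {
  if (inherits(freqs, "hap_freqs")) unclass(freqs) else unclass(hap_freqs(freqs))
}

#' @export
print.hap_freqs <- function(x, ...) {
  h <- unclass(x)
  p <- h[1] + h[2]; q <- h[1] + h[3]
  D <- h[1] * h[4] - h[2] * h[3]
  cat("Two-locus haplotype frequencies\n")
  print(h, ...)
  cat(sprintf("p(A1) = %.4g, q(B1) = %.4g, D = %.4g\n", p, q, D))
  invisible(x)
}

#' Haplotype-level r2
#'
#' The standard linkage-disequilibrium measure
#' \eqn{r^2 = D^2 / [p(1-p) q(1-q)]} computed from two-locus haplotype
#' frequencies. Under Hardy-Weinberg equilibrium this equals the genotypic
#' g2 of [g_squared()] exactly, which the package's tests verify.
#'
#' @param freqs A [hap_freqs()] object or length-4 numeric vector
#'   (h11, h12, h21, h22).
#' @return r2 in \[0, 1\].
#' @examples
#' haplotype_r_squared(hap_freqs(0.4, 0.1, 0.1, 0.4))
#' @export
haplotype_r_squared <- function(freqs) {
  h <- as_hap(freqs)
  p <- h[["h11"]] + h[["h12"]]
  q <- h[["h11"]] + h[["h21"]]
  if (p <= 0 || p >= 1 || q <= 0 || q >= 1) {
    stop_svld("r2 is undefined at a monomorphic locus (p or q in {0, 1})",
              "svld_degenerate_error")
  }
  D <- h[["h11"]] * h[["h22"]] - h[["h12"]] * h[["h21"]]
  D^2 / (p * (1 - p) * q * (1 - q))
}

#' Expected double-genotype table under Hardy-Weinberg equilibrium
#'
#' Builds the expected (real-valued) 3x3 double-genotype table for a sample
#' of `n` diploids formed by random union of gametes drawn from the given
#' haplotype frequencies. Cell probabilities are the closed-form products,
#' e.g. `P(A1A2, B1B2) = 2 (h11 h22 + h12 h21)`, and sum to 1.
#'
#' @param freqs A [hap_freqs()] object or length-4 numeric vector.
#' @param n Number of diploid individuals (>= 1).
#' @return A [geno_table()] of expected counts summing to `n`.
#' @examples
#' hwe_expected_table(hap_freqs(0.5, 0, 0, 0.5), 32)
#' @export
hwe_expected_table <- function(freqs, n) {
  h <- as_hap(freqs)
  if (length(n) != 1L || is.na(n) || n < 1) {
    stop_svld("n must be a single value >= 1", "svld_no_data_error")
  }
  h11 <- h[["h11"]]; h12 <- h[["h12"]]; h21 <- h[["h21"]]; h22 <- h[["h22"]]
  p_cells <- c(
    h11^2,                      # x1: A1A1, B1B1
    2 * h11 * h12,              # x2: A1A1, B1B2
    h12^2,                      # x3: A1A1, B2B2
    2 * h11 * h21,              # x4: A1A2, B1B1
    2 * (h11 * h22 + h12 * h21),# x5: A1A2, B1B2
    2 * h12 * h22,              # x6: A1A2, B2B2
    h21^2,                      # x7: A2A2, B1B1
    2 * h21 * h22,              # x8: A2A2, B1B2
    h22^2                       # x9: A2A2, B2B2
  )
  geno_table(n * p_cells)
}

#' Haplotype frequencies realizing a target r2
#'
#' Inverse construction used by the synthetic-data generator: given allele
#' frequencies `p` (A1) and `q` (B1) and a target r2, returns the haplotype
#' frequencies with \eqn{D = \pm\sqrt{r^2\, p(1-p) q(1-q)}} (positive
#' coupling by default) so that [haplotype_r_squared()] recovers the target
#' exactly. Not every (p, q, r2) combination is feasible: the haplotype
#' frequencies must all be non-negative, which bounds |D|. Infeasible
#' requests fail with the admissible r2 range in the message.
#'
#' @param p,q Allele frequencies in (0, 1).
#' @param r2 Target r-squared in \[0, 1\].
#' @param sign Direction of coupling: `"positive"` links A1 with B1,
#'   `"negative"` links A1 with B2 (exercises allele-relabel invariance).
#' @return A [hap_freqs()] object.
#' @examples
#' freqs_from_target(0.5, 0.5, 1)
#' haplotype_r_squared(freqs_from_target(0.3, 0.6, 0.36))
#' @export
freqs_from_target <- function(p, q, r2, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  if (p <= 0 || p >= 1 || q <= 0 || q >= 1) {
    stop_svld("allele frequencies must lie strictly inside (0, 1)",
              "svld_feasibility_error")
  }
  if (r2 < 0 || r2 > 1) {
    stop_svld("target r2 must lie in [0, 1]", "svld_feasibility_error")
  }
  denom <- p * (1 - p) * q * (1 - q)
  D <- sqrt(r2 * denom)
  d_max <- if (sign == "positive") min(p * (1 - q), (1 - p) * q)
           else min(p * q, (1 - p) * (1 - q))
  if (D > d_max + 1e-12) {
    stop_svld(sprintf(
      "r2 = %g is infeasible for p = %g, q = %g with %s coupling; admissible r2 range is [0, %.6g]",
      r2, p, q, sign, d_max^2 / denom), "svld_feasibility_error")
  }
  D <- min(D, d_max)
  if (sign == "negative") D <- -D
  hap_freqs(p * q + D, p * (1 - q) - D, (1 - p) * q - D, (1 - p) * (1 - q) + D)
}
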