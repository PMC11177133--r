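# internal helpers shared across modules

# dosage weights for the nine double-genotype cells, in x1..x9 order:
# rows = SV genotype (A1A1, A1A2, A2A2), columns = SNP genotype (B1B1, B1B2, B2B2)
.dosage_x <- rep(1:3, each = 3)
.dosage_y <- rep(1:3, times = 3)

#' Normalize chromosome names
#'
#' Strips a leading `"chr"` prefix so that `"chr10"` and `"10"` compare equal.
#' All coordinate matching in the package happens on normalized names; output
#' tables keep the names as they appeared in the genotype input.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector without the `"chr"` prefix.
#' @examples
#' norm_chrom(c("chr10", "10", "chrX"))
#' @export
norm_chrom <- function(x) {
  sub("^chr", "", as.character(x))
}

# consistent condition classes so callers (and tests) can branch on failure kind
stop_svld <- function(message, class) {
  abort(message, class = c(class, "svld_error"))
}
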