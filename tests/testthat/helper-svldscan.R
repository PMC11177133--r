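# shared fixtures and independent oracles, built in code

# random 3x3 count table with cells uniform in 0..max_count, redrawn until
# both marginals are polymorphic (non-degenerate)
rand_table <- function(max_count = 50) {
  repeat {
    x <- sample(0:max_count, 9, replace = TRUE)
    m <- matrix(x, 3, byrow = TRUE)
    rs <- rowSums(m); cs <- colSums(m)
    if (sum(rs > 0) >= 2 && sum(cs > 0) >= 2 && sum(x) >= 2) return(x)
  }
}

# random valid haplotype-frequency vector with p, q in (0.05, 0.95);
# D drawn uniformly inside its feasibility interval
rand_hap <- function() {
  p <- runif(1, 0.05, 0.95)
  q <- runif(1, 0.05, 0.95)
  d_lo <- -min(p * q, (1 - p) * (1 - q))
  d_hi <- min(p * (1 - q), (1 - p) * q)
  D <- runif(1, d_lo, d_hi)
  c(p * q + D, p * (1 - q) - D, (1 - p) * q - D, (1 - p) * (1 - q) + D)
}

# enumeration oracle: aggregate the 16 ordered haplotype pairs into the nine
# double-genotype cells (independent of the closed-form implementation)
hwe_enum_cells <- function(h) {
  a2 <- c(0, 0, 1, 1) # A2 alleles carried by haplotypes 11, 12, 21, 22
  b2 <- c(0, 1, 0, 1)
  cells <- matrix(0, 3, 3)
  for (i in 1:4) for (j in 1:4) {
    sv <- a2[i] + a2[j]
    snp <- b2[i] + b2[j]
    cells[sv + 1, snp + 1] <- cells[sv + 1, snp + 1] + h[i] * h[j]
  }
  as.vector(t(cells)) # x1..x9 row-major
}

# brute-force all-pairs windowing scan (O(n*m) reference for candidate_pairs)
brute_pairs <- function(svs, snps, flank) {
  out <- list()
  v <- svldscan::sv_span(svs)
  for (i in seq_len(nrow(v))) {
    lo <- max(1, v$span_start[i] - flank)
    hi <- v$span_end[i] + flank
    hit <- which(svldscan::norm_chrom(snps$chrom) == svldscan::norm_chrom(v$chrom[i]) &
                   snps$pos >= lo & snps$pos <= hi)
    if (length(hit) > 0) {
      out[[length(out) + 1]] <- data.frame(sv_id = v$variant_id[i],
                                           snp_id = snps$snp_id[hit])
    }
  }
  if (length(out) == 0) {
    return(data.frame(sv_id = character(), snp_id = character()))
  }
  res <- unique(do.call(rbind, out))
  res[order(res$sv_id, res$snp_id), , drop = FALSE]
}

# minimal variant tibble row
make_variant <- function(id, chrom, pos, kind = "SNP", end_info = NA_real_,
                         sv_length = NA_real_, ref = "A", alt = "G") {
  tibble::tibble(variant_id = id, chrom = chrom, pos = pos, ref = ref,
                 alt = alt, kind = kind, end_info = end_info,
                 sv_length = sv_length)
}

# random SV/SNP instance for windowing tests; some SNPs placed exactly at
# window boundaries to pin the closed-interval semantics
rand_window_instance <- function(n_sv, n_snp, flank) {
  chroms <- c("chr1", "chr2", "3")
  sv_chrom <- sample(chroms, n_sv, replace = TRUE)
  sv_pos <- sample(2e5:5e6, n_sv)
  sv_len <- sample(50:20000, n_sv)
  is_ins <- runif(n_sv) < 0.3
  svs <- tibble::tibble(
    variant_id = sprintf("SV%03d", seq_len(n_sv)),
    chrom = sv_chrom, pos = sv_pos, ref = "N",
    alt = ifelse(is_ins, "<INS>", "<DEL>"), kind = "SV",
    end_info = ifelse(is_ins, sv_pos, sv_pos + sv_len),
    sv_length = ifelse(is_ins, sv_len, -sv_len))
  snp_pos <- sample(1:5.5e6, n_snp)
  # pin a few SNPs exactly flank bp from a random SV's endpoints
  k <- min(10, n_snp, n_sv)
  pick <- sample(n_sv, k)
  snp_pos[seq_len(k)] <- ifelse(runif(k) < 0.5,
                                pmax(1, svs$pos[pick] - flank),
                                svs$end_info[pick] + flank)
  snp_chrom <- sample(chroms, n_snp, replace = TRUE)
  snp_chrom[seq_len(k)] <- svs$chrom[pick]
  snps <- tibble::tibble(snp_id = sprintf("rs%04d", seq_len(n_snp)),
                         chrom = snp_chrom, pos = snp_pos)
  list(svs = svs, snps = snps)
}
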