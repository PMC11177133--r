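# svldscan

Structural variants (SVs) — large insertions and deletions discovered mainly
by long-read sequencing — are absent from most GWAS genotyping arrays, yet
many genome-wide-significant GWAS SNPs may owe their association signal to a
nearby causal SV they tag through linkage disequilibrium (LD). `svldscan`
builds the catalog that makes such hypotheses concrete: for every biallelic
SV it finds the GWAS-significant SNPs within a physical window around the
SV's endpoints, measures their correlation directly from unphased genotypes,
and reports the SV–SNP–trait triples in high LD. The intended users are
statistical geneticists fine-mapping disease loci against an SV call set
(e.g. an HGSVC-style long-read panel) and a GWAS-catalog download.

## The statistic

For two biallelic sites typed in the same `N` diploids, code each
individual's genotype at the SV as `X ∈ {1, 2, 3}` (A1A1, A1A2, A2A2) and at
the SNP as `Y ∈ {1, 2, 3}`, and let `x1..x9` be the counts of the nine
double genotypes. The **genotypic squared correlation** is the squared
Pearson correlation of the coded genotypes,

```
g² = [μXY − μX μY]² / ([μX² − (μX)²][μY² − (μY)²])
```

with each moment a linear combination of `x1..x9` divided by `N`. No phasing
or haplotype-frequency estimation is involved; under Hardy–Weinberg
equilibrium g² equals the standard haplotype-level `r² = D²/(p(1−p)q(1−q))`,
an identity the test suite asserts to 1e-10. Significance of each pair is
assessed by referring `N·g²` to a chi-square distribution with 1 df.

A pair enters the catalog when all three filters pass:

* the SNP's trait association is genome-wide significant (`p < 5e-8`, strict);
* the SNP lies within 100 kbp of the SV's endpoints (closed interval,
  SNPs inside the SV body included);
* `g² ≥ 0.80`, the consensus tag-SNP threshold (inclusive).

All three are parameters of `sv_snp_scan()`.

## Worked example

The package ships a synthetic-data generator that plants SV–SNP pairs with
known haplotype structure, so the full pipeline runs without downloads:

```r
library(svldscan)

fx   <- build_fixture(seed = 1, dir = tempdir())   # 8 planted pairs, 32 diploids
scan <- sv_snp_scan(fx$sv_vcf, fx$snp_vcf, fx$gwas_tsv)
#> read 8 SVs, 8 SNPs
#> shared samples: 32
#> associations: 8 read, 6 genome-wide significant
#> matched to genotyped SNPs: 6 association rows (0 unmatched)
#> candidate pairs within 100000 bp: 5
#> scored pairs: 1 degenerate skipped, 3 with g2 >= 0.8

tidy(scan)[, c("sv_id", "snp_rsid", "g_squared", "ld_p_value", "distance_bp", "trait")]
#>    sv_id snp_rsid g_squared   ld_p_value distance_bp                            trait
#> 1 SV0001 rs100001 1.0000000 1.541726e-08       50000 age-related macular degeneration
#> 2 SV0002 rs100002 0.8895936 9.530948e-08       30000                 refractive error
#> 3 SV0007 rs100007 1.0000000 1.541726e-08           0           lipoprotein (a) levels
```

The eight planted pairs cover every filter: three true positives survive
(one of them a SNP inside the SV body, at distance 0), and the generator's
truth table (`fx$truth`) records why each of the other five was excluded —
outside the window, association not significant (including one planted at
exactly `p = 5e-8` to pin the strict inequality), g² below threshold, or a
monomorphic (degenerate) site. A `g_squared` of 1 with 32 samples gives the
chi-square p-value `1.54e-08`; `write_catalog(scan, "catalog.tsv")` writes
the byte-stable TSV, and `autoplot(scan)` / `plot_scan_funnel(scan)` show
the g²-vs-distance scatter and the stage-attrition funnel.

Low-level pieces are exported individually: `tabulate_double_genotypes()`,
`g_squared()`, `ld_pvalue()`, `haplotype_r_squared()`,
`hwe_expected_table()`, `read_genotype_vcf()`, `read_associations()`,
`candidate_pairs()`, `simulate_panel()`. A thin command-line wrapper lives
in `inst/cli/svld.R`:

```sh
Rscript inst/cli/svld.R scan --sv-vcf sv.vcf --snp-vcf snp.vcf \
  --gwas gwas.tsv --out catalog.tsv
```

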