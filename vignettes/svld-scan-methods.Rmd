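---
title: "Methods: unphased LD between structural variants and GWAS SNPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unphased LD between structural variants and GWAS SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svldscan)
```

## The problem and the model

A large share of genome-wide-significant GWAS SNPs has no resolved function.
One candidate explanation is that the SNP tags a nearby causal structural
variant (SV) through linkage disequilibrium: the SV, typically invisible to
array genotyping and short-read calling, drives the phenotype, and the SNP
merely travels with it on population haplotypes. `svldscan` screens an SV
genotype panel against GWAS-significant SNPs and catalogs the pairs whose
correlation is high enough for the SV to be a credible causal candidate.

The LD measure is the **genotypic squared correlation** g². For two
biallelic sites (SV alleles A1/A2, SNP alleles B1/B2) typed in the same
diploids, each individual falls into one of nine double-genotype classes
with counts $x_1, \dots, x_9$ ($N = \sum_i x_i$). Coding the genotypes
numerically as $X \in \{1,2,3\}$ for A1A1/A1A2/A2A2 and likewise
$Y$ for the SNP,

$$g^2 \;=\; \frac{\left[\mu_{XY} - \mu_X \mu_Y\right]^2}
{\left[\mu_{X^2} - \mu_X^2\right]\left[\mu_{Y^2} - \mu_Y^2\right]},$$

where every moment is a linear combination of $x_1..x_9$ divided by $N$
(e.g. $\mu_{XY} = \tfrac1N (x_1 + 2x_2 + 3x_3 + 2x_4 + 4x_5 + 6x_6 + 3x_7 +
6x_8 + 9x_9)$). This is the squared Pearson correlation of genotype
dosages, computable from **unphased** data: no haplotype phasing or
EM-based frequency estimation is needed, which avoids propagating phasing
error into the LD estimate. The correlation itself — not the underlying
haplotype frequencies — is the quantity of interest, since the question is
whether the SV could be driving the SNP's association signal.

Under Hardy–Weinberg equilibrium (genotypes formed by random union of
gametes) g² coincides exactly with the haplotype-level
$r^2 = D^2 / [p(1-p)q(1-q)]$, where $p$, $q$ are the A1 and B1 frequencies
and $D = h_{11}h_{22} - h_{12}h_{21}$. The package implements both sides of
this identity (`g_squared()` on `hwe_expected_table()` vs
`haplotype_r_squared()`) and the test suite asserts their agreement to
1e-10 across random frequency vectors — so the unphased estimator can be
interpreted on the familiar r² scale whenever HWE approximately holds. The
coding $\{1,2,3\}$ versus the alternative dosage convention $\{0,1,2\}$
differs by an affine shift, which Pearson correlation ignores; a test
asserts that too.

## The scan pipeline

`sv_snp_scan()` chains six stages, each exposed as its own function:

1. **Panels** (`read_genotype_vcf()`): SV and SNP genotypes are read from
   VCF. Only biallelic records with parseable diploid GT fields are kept;
   multi-allelic and malformed rows are dropped with counted warnings, so
   `retained + dropped = scanned` is auditable. SV reference spans come
   from the `END` INFO key when present, else `pos + |SVLEN|`; insertions
   have a zero-length reference footprint anchored at `pos`.
2. **Samples** (`intersect_samples()`): both panels are restricted to their
   shared samples in lexicographic order, making output independent of
   input sample ordering.
3. **Associations** (`read_associations()`, `filter_significant()`): the
   association table (GWAS-catalog export or a minimal generic dialect) is
   parsed and restricted to genome-wide-significant rows, `p < 5e-8`
   strict. Rows with several rsIDs (haplotype entries) or unparseable
   fields are dropped and counted.
4. **Matching** (`attach_genotyped_snp()`): associations are joined to
   genotyped SNPs by normalized chromosome and 1-based position. rsID or
   allele disagreements flag the match rather than discard it — LD is
   computed from the genotype panel alone, so identity affects labels, not
   g²; strand flipping is never attempted silently.
5. **Pairing** (`candidate_pairs()`): for every SV, SNPs within the closed
   window `[span_start − flank, span_end + flank]` (clamped at the
   chromosome start) on the same chromosome become candidates, via an
   interval index rather than an all-pairs scan; a brute-force double loop
   is the test oracle.
6. **Scoring and filtering**: each pair's nine double genotypes are
   tabulated pairwise-complete (a sample missing at either site is dropped
   for that pair only, so `n_samples` is pair-specific), g² and its
   p-value computed, and pairs with `g² ≥ min_g2` joined back to their
   trait rows — one catalog row per (SV, SNP, trait association), or one
   per pair with `collapse = TRUE`.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `flank` | 100,000 bp | window beyond each SV endpoint. In large human populations, haplotype r² around a site decays below ~0.2 within somewhat less than 100 kbp on average, so this captures the bulk of strongly correlated markers while bounding compute. Recombination-map-based (genetic-distance) windows are out of scope. |
| `gwas_p_threshold` | 5e-8 | conventional genome-wide significance; **strict** `<`, so `p = 5e-8` is excluded. |
| `min_g2` | 0.80 | consensus tag-SNP proxy level; **inclusive** `≥`, so a pair at exactly 0.80 is kept. Wording elsewhere sometimes suggests a strict comparison; the inclusive reading is implemented and configurable. |
| `include_snps_inside_sv` | `TRUE` | SNPs inside the SV body are inside the window by construction; LD with a SNP deleted by the SV may be an artifact of calling, so a switch can exclude them. |

The LD p-value refers $N g^2$ to $\chi^2_1$ — the dosage analogue of the
standard allelic LD test. This is an implementation choice: the upstream
analysis this mirrors reports p-values without specifying the test, and a
chi-square on $N r^2$ is the field's default; Fisher-exact or permutation
alternatives were considered and rejected as they would not change the
ranking (the statistic is monotone in g² at fixed N). Degenerate pairs —
either site monomorphic among the shared samples — have undefined g²; they
are flagged and skipped, never reported as 0/0 or raised as errors. No
small-sample bias correction is applied to g²; none is standard for this
estimator and the identity with r² under HWE holds for the uncorrected
moment form at any N.

## Numerical choices

The moments are assembled as integer-weighted cell sums with a single final
division: $g^2 = (N S_{XY} - S_X S_Y)^2 / [(N S_{X^2} - S_X^2)(N S_{Y^2} -
S_Y^2)]$. For integer tables every intermediate is exact in double
precision (well below $2^{53}$), so a table whose g² is a small rational —
the threshold-boundary fixtures at exactly $4/5$ — evaluates to the
correctly rounded double and the inclusive `≥ 0.80` comparison is exact,
with no tolerance band. Floating error can still push g² infinitesimally
above 1 for real-valued expected tables; excursions up to 1e-12 are clamped
to 1 and anything larger raises an internal-consistency error rather than
being hidden. Interval endpoints are closed on both sides in 1-based
coordinates — a SNP exactly `flank` bp from an endpoint is a candidate —
because "within ±100 kbp" reads inclusively and a documented closed
convention avoids off-by-one ambiguity; the BED export converts to 0-based
half-open at the boundary.

## The synthetic-data generator

Real inputs at scale (a long-read SV freeze and a GWAS-catalog download)
are external; the generator makes every stage testable without them.
`freqs_from_target(p, q, r2)` inverts the r² formula to haplotype
frequencies (positive-D coupling by default, with a feasibility check that
reports the admissible r² range — not every r² is reachable at every
allele-frequency pair; a sign switch exercises allele-relabel invariance).
`simulate_panel()` draws $2n$ haplotypes multinomially and pairs them into
diploids — random union of gametes, hence HWE by construction. The default
panel is 32 diploids, matching the scale of the long-read human panel that
motivates the defaults. `build_fixture()` writes the three scan inputs for
a set of planted pairs plus a truth table; the default plan
(`plant_pairs_default()`) plants positives and one negative per filter,
including an association at exactly `p = 5e-8` and a monomorphic SV.
Two design points matter for test reliability:

* **Truth is labelled post hoc from the realized genotypes**, not from the
  intended parameters, so a sampled pair landing on the "wrong" side of the
  g² threshold relabels its own truth — tests are never flaky from
  sampling noise.
* **Exact-boundary pairs use deterministic expected-count tables.** The
  smallest integer tables with g² exactly 0.80 have $N = 6$ (e.g.
  $x_4{=}1, x_5{=}2, x_9{=}3$) and scale to any multiple of six, so the
  boundary fixture uses a 30-sample panel; no 32-sample integer table
  attains exactly 4/5 in the searched families.

What the generator does **not** emulate: recombination along a chromosome
(each planted pair is an isolated two-locus system), population structure
and inbreeding (so HWE holds by construction, which real panels only
approximate), genotyping error, and missingness patterns correlated with
SV size. Passing tests therefore demonstrate correctness of the estimator
and pipeline mechanics, not robustness to HWE violations — on real data g²
remains a valid squared correlation of dosages, but its equality with
haplotype r² degrades as HWE fails.

## Problem sizes and verification

The shipped verification uses desk-scale problems chosen to exercise every
code path: 1,000 random count tables against a brute-force
dosage-expansion reference (agreement < 1e-10), 200 random haplotype
vectors for the g²/r² identity at $n \in \{10, 32, 1000\}$, 500 tables for
transposition/relabel invariance, 100 random windowing instances (up to
200 SVs × 500 SNPs) against the all-pairs scan, and 2,000 seeded 32-diploid
panels at planted r² = 0.85, whose mean sampled g² recovers the target
within 0.05 with ≥ 90% of draws above 0.5. The headline catalog of the
motivating analysis (16,377 pairs across 2,355 traits from 4,715 SVs and
7,892 SNPs) depends on specific external data freezes and is deliberately
not reproduced here; the scan's `glance()` counters expose the same
quantities (pairs, unique SVs, unique SNPs, unique traits) so a user with
those downloads can attempt the comparison.

## Known limitations

* Biallelic sites only; multi-allelic records are dropped, not decomposed.
* Diploid autosomal genotypes only: no haploid-LD mode for male sex
  chromosomes (such sites are skipped with a warning).
* Breakend (BND) SV notation, CRAM/BAM input and live GWAS-catalog queries
  are out of scope; inputs are VCF and TSV files.
* D and D′ are not estimated — the package is deliberately
  phasing-free, and g² is the only LD statistic reported.
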