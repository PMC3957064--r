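# vtet — variable threshold exact test for CNV association

`vtet` tests whether copy number variants (CNVs) in a short genomic region
are enriched in cases, directly from SNP-array intensity data — the Log R
Ratio (LRR) and B Allele Frequency (BAF) — **without a CNV-calling step**.
It is aimed at statistical geneticists analyzing case-control GWAS
intensity data, in the regime where conventional pipelines fail: CNVs
covering only 3–10 probes whose boundaries differ between carriers.
Recurrent CNVs (shared boundaries) are handled by the same test.

## The method

For a region of *T* probes with per-sample standardized intensities
*x*<sub>*it*</sub> (i.i.d. *N*(0,1) at copy-neutral probes), the evidence
that subject *i* carries a CNV anywhere in the region is the maximum
interval scan statistic over all sub-intervals of at least *L* ≥ 3 probes,

> *z*<sub>*ab*</sub> = Σ<sub>*t*=*a*..*b*</sub> *x*<sub>*t*</sub> / √(*b*−*a*+1),  *U* = max −*z* (deletions), max +*z* (duplications), or max |*z*| (either),

calibrated into a p-value *p*<sub>*i*</sub> against a Monte-Carlo null
table of the same maximum (10⁶ draws by default). For duplications, an
informative BAF *b* ∈ [0.2, 0.8] is first converted to a standard-normal
quantile *Y* of the folded distance |*b* − 0.5| and fused with the LRR as
*Z* = (*X* + *Y*)/√(2 + 2ρ) with ρ = −0.05 (denominator 1.38).

The **variable threshold exact test** then declares subjects with
*p*<sub>*i*</sub> ≤ *q*<sub>*k*</sub> tentative carriers at a grid of
thresholds *q*<sub>*k*</sub> = (expected false carriers)<sub>*k*</sub> /
(*m*+*n*) — default grid expecting (5, 2, 1, 0.5, 0.1) false carriers —
applies a one-sided Fisher exact test at each, and takes

> *Q* = min<sub>1≤*k*≤*K*</sub> *P*(*q*<sub>*k*</sub>),

with significance from case/control label permutation (the per-subject
evidence never involves the labels, so each permutation costs O(*K*)
hypergeometric updates). `scan_genome()` tiles a genome into 50-probe
segments, runs the test per segment and mode, applies Bonferroni control,
and emits QQ diagnostics. A full copy-state conditional simulator of
LRR/BAF data (`simulate_study()`, `estimate_power()`) supports type-I
error and power studies against the known-truth "ideal" Fisher test.

## Worked example

Simulate a 500-case / 500-control study over a 20-probe region where a
5-probe hemizygous deletion with population frequency 1% carries an odds
ratio of 5, then test the region:

```r
library(vtet)

cfg <- simulation_config(m = 500, n = 500, T = 20, cnv_len = 5,
                         f = 0.01, OR = 5, cnv_type = "CN1", seed = 7)
sim <- simulate_study(cfg)
x <- standardize_lrr(sim$matrix)
tables <- list(
  both        = build_null_table(20, 3, "both",        n_sim = 1e5, seed = 1),
  deletion    = build_null_table(20, 3, "deletion",    n_sim = 1e5, seed = 2),
  duplication = build_null_table(20, 3, "duplication", n_sim = 1e5, seed = 3))
ev  <- subject_region_pvalues(x, tables = tables, L = 3)
res <- vtet_region_test(ev, sim$phenotype, mode = "deletion",
                        params = vtet_params(seed = 11))
res
#> Variable threshold exact test (one-sided)
#>   500 cases, 500 controls; K = 5 thresholds
#>      q  a b fisher_p
#>  5e-03 20 9  0.02886
#>  2e-03 19 9  0.04138
#>  1e-03 18 8  0.03588
#>  5e-04 18 7  0.02036
#>  1e-04 16 7  0.04470
#>   Q = 0.02036; permutation p = 0.02794 (500 permutations, 13 successes)

ideal_test(sim$truth, sim$phenotype)   # known-truth Fisher ceiling
#> [1] 0.02036195
```

Reading the output: at the most liberal threshold (*q* = 5×10⁻³, ~5
expected false carriers) 20 cases and 9 controls look like carriers; as
*q* tightens the counts shrink toward the 18 true carrier cases and 7
carrier controls this replicate planted. The best Fisher p-value over the
grid is *Q* = 0.020 — here identical to the known-truth test, i.e. the
variable threshold recovered exactly the true carrier set — and label
permutation calibrates it to p ≈ 0.028.

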