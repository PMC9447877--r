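# dropscreen

Analysis of pooled shRNA dropout screens for drug-sensitizer discovery.

In a pooled dropout screen, a library of short hairpin RNAs — here a kinome
library of 535 targeting genes (518 kinases, 17 kinase-related) at 5 hairpins
per gene, spiked with 243 essential-gene and 272 non-essential-gene control
hairpins — is infected into cells at low multiplicity. A reference sample is
collected at t = 0, the population is then grown with or without drug at
1000× library coverage, and hairpin abundance is read out by sequencing.
Hairpins whose target gene sensitizes cells to the drug drop out of the
treated arm; a *sensitizer* gene is one whose hairpins are depleted in
treated relative to untreated cells. Screening several resistant cell lines
and intersecting their hit sets yields the candidates worth validating — the
genes hit in every line.

`dropscreen` implements the count-level analysis end to end, plus a seeded
synthetic screen generator so every step is testable against known truth:

- **Normalization** — median-of-ratios size factors
  `sf_j = median_i( k_ij / (∏_j k_ij)^(1/n) )` over hairpins with all-positive
  counts, rescaled to geometric mean 1.
- **Per-hairpin testing** — negative-binomial model `Var = μ + αμ²`;
  per-hairpin method-of-moments dispersions shared conservatively against a
  fitted `α(μ) = a₀ + a₁/μ` trend (each hairpin gets
  `max(α_MoM, trend)`); a two-sided Wald test on
  `log2FC = log2((mean_treated + ½)/(mean_ref + ½))` with the NB variance
  propagated by the delta method; Benjamini–Hochberg FDR across all hairpins
  per contrast.
- **Two-step hit calling** — primary: a gene needs ≥ 2 hairpins with
  log2FC < −1, FDR < 0.1 and baseMeanA > 100 in treated-vs-untreated, and no
  hairpin significantly changed in the opposite direction; secondary: its
  supporting hairpins must also show log2FC < −1 in treated-vs-t0, removing
  shRNAs that merely rose in the untreated arm.
- **Intersection** — per-line hit sets are combined into a full Venn
  partition; the all-lines region is the screen's headline readout.

## Worked example

The numbered drivers under `analysis/` run the whole study and write their
tables under `results/` (regenerated on each run, not shipped):

```sh
Rscript analysis/01_simulate_screens.R
Rscript analysis/02_differential_abundance.R
Rscript analysis/03_hit_calling.R
Rscript analysis/04_intersection_and_qc.R
```

Step 1 plants one common sensitizer and two line-private sensitizers per
cell line and prints them:

```
Planted common sensitizer: KIN0129
Planted private hits in CAL51: KIN0509, KIN0471
...
Simulated 3190 hairpins x 9 samples in each of 3 cell lines (seed 1).
```

Steps 2–4 normalize, test, call hits and intersect. With defaults
(coverage 1000, dispersion 0.05, n = 3 per arm) the output is:

```
CAL51: 3 primary hits, 3 after the t0 filter (too_few_hairpins: 532)
  hits: KIN0129, KIN0471, KIN0509
...
                region n_genes           genes
7 CAL120&CAL51&HCC1806       1         KIN0129
Common hits across all 3 lines: KIN0129
CAL51: planted KIN0129,KIN0471,KIN0509 | recovered 3/3 | spurious: none
CAL51 control separation (essential - nonessential median log2fc vs t0): -1.85
```

Every line recovers exactly its planted sensitizers, the three-way
intersection contains only the planted common gene, and essential-gene
control hairpins drop ~1.85 log2 units below non-essential controls between
t = 0 and the end of the screen — the expected quality signature of a healthy
dropout screen. The same pipeline runs on real count tables via
`run_screen_analysis(run_config(mode = "files", ...))`.

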