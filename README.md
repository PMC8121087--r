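# protacclim

Distribution-aware differential proteomics with bootstrapped cluster
support, for two-factor isobaric-label (TMT) experiments — built around
the statistics of cold acclimation in barley root meristems.

Quantitative bottom-up proteomics of root apex segments produces a
protein × sample matrix of log2 reporter-ion ratios relative to a pooled
channel, under a 2 × 4 factorial: root zone (tip, tip-adjacent) crossed
with treatment (control, cold, chitin, chitosan). Such ratios are often
non-Gaussian, so a single test family fits poorly across thousands of
proteins. `protacclim` implements the full analysis chain for this kind
of experiment, for proteomics analysts who want each step scriptable and
testable:

* **Pre-processing** — log2 transform and per-plex pooled-channel
  normalization; evidence filtering (≥ 2 razor + unique peptides, reverse
  hits removed); volcano quantities.
* **Distribution fingerprinting** — Shapiro–Wilk and bootstrapped
  Brown–Forsythe tests; squared-skewness/kurtosis (Cullen–Frey)
  fingerprint classified against exemplary distribution loci, calibrated
  to the sample size, to pick each protein's GLM family and link.
* **Differential abundance** — the eight-regressor two-factor GLM

      mu = b0 + b1*tip + b2*chitin + b3*chitosan + b4*cold
              + b1:b2 + b1:b3 + b1:b4

  with treatment contrasts against (tip-adjacent, control), Wald tests,
  Benjamini–Hochberg q-values per coefficient across proteins, response
  classes (tip-increased; cold-increased; cold-modulated tip-accumulated
  via the tip:cold interaction), Fisher-exact term enrichment.
* **Cluster inference** — Pearson-correlation distance, average-linkage
  clustering, multiscale bootstrap (scales 0.5–1.4) with approximately
  unbiased support from the `z(r) = v√r + c/√r` fit
  (`au = 1 − Φ(v − c)`), high-confidence sub-cluster extraction
  (au ≥ 0.99, 2–12 members), seeded K-means (k = 5), Newick export.
* **Class prediction** — random-forest Gini mean-decrease importance and
  a NIPALS PLS-DA with VIP scores (mean VIP² = 1 by construction).
* **Homology mapping** — Needleman–Wunsch global alignment with affine
  gaps (three-state DP, BLOSUM62 default, score > 10 acceptance) for
  cross-species ribosomal-protein family/paralog assignment with
  certain/potential peptide-evidence classes.
* **Content assay** — BSA standard curves, µg/mg fresh-weight conversion,
  distribution-aware group comparison with compact-letter display,
  ribosomal-fraction percentages.
* **Synthetic data** — seeded generators for every input (factorial
  intensity matrices with known coefficients, clusters and residual
  families; paralog-structured FASTA pairs; BCA plates), so the whole
  pipeline is testable with recorded ground truth.

## Worked example

Simulate a 100-protein experiment in which 10 proteins carry a 2 log2-unit
tip:cold interaction, then run fingerprinting, GLM fitting and response
classification:

```r
library(protacclim)

eff <- matrix(0, 100, 7, dimnames = list(NULL, regressor_names()[-1]))
eff[1:10, "tip:cold"] <- 2
spec <- simulation_spec(100, effects = eff, noise_sd = 0.5, seed = 42)
sim <- generate_intensity_matrix(spec)
sim$matrix
#> intensity_matrix: 100 proteins x 40 samples
#>   zones:      tip, tip_adjacent
#>   treatments: chitin, chitosan, cold, control

fp <- fingerprint_matrix(sim$matrix, B_levene = 200, seed = 1)
table(fp$glm_family)
#>    gamma gaussian
#>        5       95

da  <- fit_da(sim$matrix, fingerprints = fp)
cls <- classify_response(da)
sum(cls$class3[1:10])    # planted interaction proteins recovered
#> [1] 10
sum(cls$class3[-(1:10)]) # false interaction calls among 90 nulls
#> [1] 3
```

The three strongest interaction calls, with estimates near the planted
2 log2 units:

```r
top <- order(da$p[, "tip:cold"])[1:3]
round(cbind(estimate = da$coef[top, "tip:cold"],
            p = da$p[top, "tip:cold"],
            q = da$q[top, "tip:cold"]), 4)
#>               estimate p      q
#> HORVU_SIM0004   2.5778 0 0.0000
#> HORVU_SIM0001   2.1670 0 0.0012
#> HORVU_SIM0009   2.3187 0 0.0015
```

Content arithmetic works on reported assay means; for example a
ribosome-enriched fraction of 0.75 µg/mg FW against a cold-tip total of
4.15 µg/mg FW:

```r
rp_fraction(0.75, 4.15)
#> [1] 18
```

`run_pipeline(pipeline_config(seed = 1, outdir = "run1"))` executes the
whole chain on synthetic inputs and writes TSV/Newick/FASTA outputs plus a
JSON manifest with per-file checksums; a rerun with the same configuration
is bit-identical.

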