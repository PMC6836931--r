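# retrodyn

Dynamic transcriptomic retro-analysis of the acute surgical ("sham")
response.

Opening a mouse's chest — the sham arm of every myocardial-infarction
experiment — is itself a major transcriptional stimulus. Given a
three-time-point bulk RNA-seq design (0 min, 45 min, 24 h post-surgery,
eight animals per group), `retrodyn` answers two questions:

1. **Forward:** which transcripts respond, in which temporal modules, and
   which biological processes do those modules predict?
2. **Backward (retro-analysis):** which transcription factors most likely
   drove the response, and which upstream signalling network — typically a
   cytokine hub such as IL-6 — most plausibly activated those TFs?

## Methods at a glance

* **Differential expression** — per-transcript NB GLM with median-of-ratios
  size-factor offsets; likelihood-ratio test of per-group means vs one
  shared mean; Cox–Reid adjusted-profile-likelihood dispersion;
  quasi-likelihood F calibration; BH-FDR < 0.05 flags DETs.
* **Co-expression modules** — signed adjacency `((1+cor)/2)^beta` with the
  scale-free topology criterion for beta, topological overlap
  `TOM_ij = (sum_u a_iu a_uj + a_ij)/(min(k_i,k_j)+1-a_ij)`, average-linkage
  clustering, static cut + minimum-size merge, module eigengenes.
* **GO enrichment** — upper-tail hypergeometric tests with BH correction, a
  strict FDR < 1e-4 filter, and the continuity-corrected module-vs-DET
  z-score `z = (x - 0.5 - Bn/N) / sqrt(n (B/N)(1 - B/N))`, enriched when
  FDR < 1e-4 and z > 2; module-combination enumeration and best-predictor
  assignment.
* **TF over-representation** — one-tailed Fisher exact test per TF target
  set; F-score = −ln p (kept when F > 20, i.e. p < 2.06e-9); binomial
  z-score; five nested groups at |z| > 35/25/15/10/2.
* **Network retro-analysis** — greedy confidence-weighted growth of
  TF-seeded PPI subnetworks over five layers (+5/+10/+20/+30/+40 nodes),
  GO sensitivity/specificity of each layer against the DET-derived terms,
  selection at sensitivity ≥ 40% and growth ≥ 150% with maximal
  specificity, and k-means partition of the winner into core / secondary /
  peripheral tiers.
* **Synthetic study generator** — NB counts with three planted temporal
  modules (transient 45-min, 24-h up, 24-h down), planted GO/TF
  annotations, and a PPI graph with a planted cytokine-like hub, so every
  stage is testable against a known truth.

## Worked example

```r
library(retrodyn)
res <- runPipeline(defaultPipelineConfig(seed = 1))

res$partition
#> ModulePartition: 218 transcripts, 3 modules
#>   module sizes: 81, 71, 60
#>   unassigned: 6 (2.8%)

round(res$eigengenes$groupMeans, 3)
#>      0min  45min    24h
#> M1 -0.150 -0.103  0.252
#> M2  0.146  0.119 -0.265
#> M3 -0.121  0.261 -0.140

sel <- res$selection
sprintf("TF group %d, layer %d: sensitivity %.1f%%, specificity %.1f%%, growth %.0f%%",
        sel$tfGroup, sel$layer, sel$row$sensitivity, sel$row$specificity,
        sel$row$growth)
#> "TF group 2, layer 4: sensitivity 83.3%, specificity 83.3%, growth 375%"

res$tiers[["HUB1"]]
#> "core"
```

At seed 1 the pipeline calls 218 of 2000 transcripts differential (210 were
planted), recovers the three planted temporal modules (the eigengene group
means above show the 24-h up, 24-h down and transient 45-min shapes), and
the selected TF-seeded network — grown from the 8 strongest TFs — retrieves
83% of the DET-derived GO terms while the planted upstream hub lands in the
network's core tier.

A shell entry point wrapping the same functions is installed at
`inst/scripts/retrodyn.R`:

```sh
Rscript inst/scripts/retrodyn.R simulate --out simdir --seed 1
Rscript inst/scripts/retrodyn.R run --out rundir --seed 1
```

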