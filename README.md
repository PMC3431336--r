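# modnet

Inference and analysis of three-layer **modulator → TF → target** regulatory
networks from gene expression data.

Tumor suppressors (TSGs) and oncogenes (OCGs) frequently regulate
transcription indirectly, by modulating transcription factors (TFs) at the
post-translational level. Such modulators need not correlate with either the
TF or its targets, so coexpression methods miss them. What they do leave
behind is a conditional signature: the statistical dependence between a TF
and its target **changes with the modulator's expression**. `modnet` is
aimed at computational biologists who want to detect that signature at
cohort scale, confirm the implied TF→target regulations with binding-site
evidence, and analyze the resulting layered network.

## The method

For a candidate triplet (M, T, G), samples are ranked by the modulator M and
split into top and bottom tails of fraction *f* (default 0.35). The core
statistic is the conditional mutual-information contrast

    ΔI = I(T; G | M high) − I(T; G | M low)        [nats]

with MI estimated by the Gaussian copula, I = −½ ln(1 − ρ′²),
ρ′ = 2 sin(π ρ_s / 6) from the Spearman correlation ρ_s. Significance is
assessed on the variance-stabilized Fisher-z scale against a normal null
whose scale is calibrated, per (TF, target) pair, from that pair's own
permutation draws; Benjamini-Hochberg controls the FDR across all tested
triplets. Each surviving triplet must then pass binding-site confirmation:
MATCH-style PWM scanning of the target promoter (information-vector
weighted, min–max normalized core and matrix scores; thresholds 1.00 / 0.95),
and only triplets whose (T, G) pair has a predicted site enter the network.
Downstream operations cover PPI topology with empirical resampling
p-values (p = N/R over random same-size gene sets), feedback-loop and
dual-role detection, binary regulatory-profile clustering, hypergeometric
gene-set enrichment with BH adjustment, and bottom-up process-subnetwork
extraction.

A synthetic-data module generates every input with planted ground truth —
scale-free PPI, standardized expression with piecewise-linear planted
modulation (G = β(M)·T + ε, β switching in M's top-f quantile), PWMs and
promoters with planted sites — so the whole pipeline is testable against a
known answer.

## Worked example

```r
library(modnet)

b <- generate_benchmark(synthetic_config(), seed = 7)   # 85 genes x 489 samples
hits <- infer_modulations(b$expr, b$candidates, inference_config(seed = 8))
head(hits[, c("modulator", "tf", "target", "delta_I", "p", "q")], 3)
#>   modulator   tf target   delta_I            p            q
#> 1     OCG01 TF01  CG018 0.3513020 8.234103e-14 5.614161e-11
#> 2     TSG07 TF01  CG032 0.2223664 3.436643e-12 1.718322e-09
#> 3     TSG18 TF01  CG007 0.2727358 9.433634e-10 2.721240e-07
```

`delta_I` is the MI gain in modulator-high samples (OCG01 raises the
TF01→CG018 coupling by 0.35 nats); `q` is the BH-adjusted permutation-
calibrated p-value. Intersecting the 42 CMI triplets with the 40
PWM-predicted edges and assembling the network:

```r
edges <- predict_tf_targets(b$promoters, b$pwms, b$tf_map)   # 40 TF->target edges
net <- build_network(intersect_edges(hits, edges), b$truth$role_map)
print(net)
#> Three-layer regulatory network: 65 genes (12 TSG, 9 OCG, 4 TF, 40 target-class), 72 links
#>   layers: 21 modulators -> 4 TFs -> 40 targets
```

Against the planted truth this run recovers all 40 planted triplets with one
false positive (sensitivity 1.00, precision 0.976). The structural
operations are demonstrated on a synthetic replica of a published network's
printed facts:

```r
detect_feedback_loops(replica_network())
#>      tf  gene
#> 1  E2F3 CHEK2
#> 2  ETS1  EGFR
#> 3  ETS1 ERBB2
#> 4  ETS1 SPARC
#> 5 HMGA2   MYC
#> 6 HNF1B   MYC
```

The `analysis/` directory holds the numbered drivers of the full study
(`01_simulate.R` … `07_process_subnetworks.R`); each is a thin Rscript over
the package functions that prints what it found and writes its tables under
`results/`. The methods vignette
(`vignettes/modnet-methods.Rmd`) explains the model, the calibration of the
significance procedure, the synthetic world's assumptions and the package's
design choices.

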