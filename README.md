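# mascot

**M**icroarray **a**nalysis of **s**pinal-**c**ord-like mixed tissue with
cell-type-**o**riented **t**ranscriptomics.

`mascot` is an R/Bioconductor-style package for cell-type-aware
differential expression analysis of mixed CNS tissue profiled on
Affymetrix-style probe-pair microarrays, built around the analysis design
used for mutant-SOD1 ALS mouse spinal cord. Bulk tissue fold changes
confound within-cell regulation with disease-driven shifts in cell
composition (motor-neuron loss, astro-/microgliosis); the package
implements the full chain that untangles them:

1. **MAS5-style normalization** — per probeset and array, the signal is
   `2^TBW(log2(max(PM − IM, δ)))`, where TBW is the one-step Tukey
   biweight (`u = (x − med)/(5·MAD + ε)`, weights `(1 − u²)²`) and IM is
   the ideal mismatch (observed MM when MM < PM, else derived from the
   specific background `SB = TBW(log2(PM/MM))`). Detection calls come
   from an **exact** one-sided Wilcoxon signed-rank test of
   `R = (PM − MM)/(PM + MM)` against τ = 0.015 (all 2ⁿ sign assignments
   for ≤ 12 pairs; P if p < 0.04, M if p < 0.06, else A). Each array is
   independently scaled so its 2%-trimmed mean equals 500 — so existing
   samples never change when new ones are analyzed.
2. **Multi-comparison DEG extraction** — per comparison (3 mutant vs 3
   control): P/M calls in ≥ 3 of 6 arrays, fold change > 2 (either
   direction), Welch t + Benjamini–Hochberg q reported; probesets changed
   in the *same direction in all comparisons* are intersected and
   collapsed to unique genes.
3. **Integrated cell-type reference** — five commonly-scaled cell-type
   datasets (motor neurons, neurons, astrocytes, microglia,
   oligodendrocytes); a gene is *cell-type enriched* when one type's
   signal is ≥ 4× every other type's (inclusive).
4. **Ectopic-expression detection** — in a diseased isolated cell-type
   dataset, a foreign-class gene is flagged ectopic when its fold change
   exceeds 3× the *contamination envelope* (the max fold change of its
   home-type markers in that dataset) and an absolute floor of 10.
5. **Over-representation analysis** — per category: reference count m,
   observed k, expected `e = m·n/N`, fold enrichment `f = k/e`,
   upper-tail hypergeometric p, BH q.

A synthetic probe-level data generator with planted ground truth (cell
type profiles, composition shifts, disease effects, ectopic inductions,
probe affinities, log-normal noise + flat background) makes every claim
testable end to end.

## Worked example

```r
library(mascot)

# a self-contained three-comparison study with 40 planted DEGs
run <- runPipeline(pipelineConfig(nGenes = 2000, nDeg = 40, seed = 3),
                   outDir = "demo_run")

run$report$deg_sensitivity
#> [1] 1
run$report$deg_fdp
#> [1] 0
unlist(run$report$class_counts)
#>    motor_neuron          neuron       astrocyte       microglia
#>               1               3               1              22
#> oligodendrocyte    Unclassified
#>               0              13
run$ectopic[run$ectopic$flag, c("gene_id", "gene_fc", "envelope_max")]
#>    gene_id  gene_fc envelope_max
#> 43  g01112 36.44185     1.590965
```

All 40 planted DEGs are recovered with no false positives; the classified
list is microglia-dominant (22/40, as planted); and the one planted
50-fold ectopic astrocytic induction of a microglia-class gene is flagged
— its apparent 36.4-fold change far exceeds 3× the 1.59-fold contamination
envelope set by microglial markers in the same dataset. Scalar building
blocks are exported too:

```r
probesetSignal(pm = 1000, mm = 200)   # 800
detectionPvalue(rep(1000, 4), rep(10, 4))  # 0.0625 = 1/16, exact
classifyEnrichment(c(motor_neuron = 100, neuron = 90, astrocyte = 80,
                     microglia = 500, oligodendrocyte = 70))  # "microglia"
```

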