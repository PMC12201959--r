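# idscn

Individualized differential structural covariance network (IDSCN) analysis
for patient subtyping from regional grey-matter volumes.

Group-level structural covariance networks — region × region correlations of
grey-matter volume (GMV) across subjects — cannot be attributed to any one
patient. The IDSCN approach recovers a per-patient network by *leave-one-in
perturbation*: build the reference network (rSCN) from the controls, add one
patient and rebuild it (pSCN), and Z-score the difference at every edge,

    Z_ab = (pSCN_ab − rSCN_ab) / ((1 − rSCN_ab²) / (n − 1)),

where `n` is the number of controls and correlations are computed on
residuals after adjusting GMV for age, sex, education and site. Per patient,
edges with Bonferroni-corrected p < 0.001 over the C(R, 2) edge family are
"significantly altered"; edges altered in at least 5% of patients become
features; k-means over k = 2…10 with 100 restarts per k, scored by mean
silhouette width, partitions the patients into subtypes, which are then
characterized on edges, regional volumes, clinical scores (HAMD-17 /
HAMA-14) and demographics with covariate-adjusted tests.

The package is aimed at researchers who want this pipeline as tested,
reusable building blocks — and at anyone who wants to study its statistical
behaviour, since it ships a seeded synthetic-cohort generator
(`generateCohort()`) with planted edge perturbations, a two-subtype ground
truth, regional volume deficits and anxiety coupling, so every stage can be
validated against known truth. See the methods vignette
(`vignettes/idscn-methods.Rmd`) for the model, the generator's design and
its limitations.

## Worked example

```r
library(idscn)

res <- generateCohort(defaultConfig("paper_like", rngSeed = 7))
out <- runPipeline(res$cohort, pipelineConfig(rngSeed = 7), outDir = "run7")

out$report$edge_family_size                  # 13695  (C(166, 2) edges)
out$report$prevalence_threshold              # 8      (5% of 164 patients)
head(out$report$selected_edges, 3)
#>     i   j count
#> 1  40  90   164
#> 2 121 122   117
#> 3 123 124   117
out$report$chosen_k                          # 2
unlist(out$report$subtype_sizes)             # 117 47
out$report$n_significant_edge_differences    # 9
out$report$significant_gmv_regions           # 3 60 150
```

The report says: the 166-region atlas yields 13,695 unique edges; 10 edges
were significantly altered in at least 8 patients (their prevalences shown
in `selected_edges`); k-means chose 2 subtypes of 117 and 47 patients; 9 of
the 10 feature edges differ between the subtypes after Bonferroni
correction (all stronger in subtype 1), and three regions show lower GMV in
subtype 1. Clinical characterization lands the same way — higher anxiety in
subtype 1 and positive edge–anxiety correlations for the subtype-specific
edges, e.g.:

```r
subset(out$demographics, variable == "hama14")
#>   variable         test statistic        p
#>     hama14 two-sample t      7.43 5.96e-12
head(subset(out$clinicalCorrelations, score == "hama14"), 3)
#>      edge  score      r        p   n
#>     40-90 hama14 0.0164 8.35e-01 164
#>   121-122 hama14 0.4799 7.90e-11 164
#>   123-124 hama14 0.5133 2.10e-12 164
```

All of this is recovered structure: the `paper_like` generator plants
exactly those 10 edges (9 exclusive to the larger ground-truth subtype, 1
carried by everyone), the 3 deficit regions and the anxiety coupling.

`runPipeline(outDir =)` writes `subjects/labels/features` TSVs, per-patient
significant-edge tables, the comparison tables, `report.json` and a
reproducibility manifest. A thin command-line wrapper over the same
functions lives at `inst/scripts/idscn-cli.R`
(`simulate | build | subtype | characterize | run`).

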