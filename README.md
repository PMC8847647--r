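# lipidtraffic

Network-based **switch analysis** for multi-tissue lipidomics: where in an
organism is each lipid found, and how does that spatial distribution differ
between two phenotype groups?

Lipidomics studies of metabolic disease increasingly profile several
compartments at once — liver, serum, heart, skeletal muscle, adipose, CNS —
because lipid metabolism is controlled at the level of *traffic* between
tissues, not within any single one. Comparing raw abundances across tissues
is fragile (each matrix ionises differently), but *presence* is robust.
`lipidtraffic` turns per-sample abundance tables into presence/absence maps
on a user-declared tissue network and asks where the two phenotypes keep
different lipids. It is aimed at lipidomics and metabolomics analysts with
sample × variable intensity tables from any direct-infusion MS or NMR
pipeline.

## The method in brief

1. **Presence rule.** For each group, compartment and lipid variable, the
   presence fraction *B* is the share of samples with signal > 0; the
   variable is present when *B* ≥ 0.66 (closed bound, tunable).
2. **Switch categories** per group on the network:
   **A**-type — present in every compartment; **B**-type (per edge) —
   present in both endpoints of an adjacent tissue pair; **U**-type (per
   compartment) — present in exactly one compartment. A ⊆ every B-list by
   construction.
3. **List comparison.** For any scope (say, U-type TGs in adipose) the two
   groups' lists are aligned over their union and summarised by the
   Jaccard–Tanimoto coefficient *J* = |L₁ ∩ L₂| / |L₁ ∪ L₂| with a
   significance value *p* = P(J_null ≤ J_obs) under a fixed-margin
   exchangeable null (exact hypergeometric by default, seeded permutation
   or bootstrap as alternatives). Small *p*: the lists differ more than
   chance placement of same-sized lists would produce.
4. **Quantitative companions.** Error-normalised fold change
   ENFC = log2(mean_case/mean_control) / SE(log2 FC) (delta-method SE),
   Mann–Whitney group tests with Bonferroni thresholds, diagnostic
   fatty-acid ratios such as FA(15:0)/FA(17:0), and relative-abundance
   profiles.
5. **Outputs.** Per-category CSV lists, an overlap-statistics table,
   deterministic SVG figures (network pie map; per-lipid wiring diagrams)
   with JSON sidecars, and a run manifest.

A synthetic study generator with planted U/A/B structure, lognormal
abundances and stochastic dropout (`generate_study()`,
`truth_recovery_report()`) lets you validate the entire pipeline against a
known ground truth. The methods vignette
(`vignettes/lipid-traffic-analysis.Rmd`) documents the model, the null,
every tunable parameter and the design decisions.

## Worked example

```r
library(lipidtraffic)

# a synthetic two-group study: 6 compartments, n = 8, ~300 lipids,
# 10% per-sample dropout, planted distributional switches
study <- generate_study(synthetic_config(dropout = 0.1), seed = 2026)

res <- run_switch(study$dataset, output_dir = "lta_out",
                  control_group = "lean", seed = 7)
res$classification
#> Switch classification on 6 compartments, 300 variables
#>   lean: A = 65, U = 15/8/9/10/12/6, not detected = 55
#>   obese: A = 75, U = 12/5/12/10/8/5, not detected = 58

res$overlaps[res$overlaps$category != "U", 1:8]
#>    category       location n_group1 n_group2 n_intersection n_union     J        p
#> 7         A           <NA>       65       75             45      95 0.474 0.000166
#> 8         B adipose--serum      102      105             80     127 0.630 0.004822
#> 9         B     CNS--serum       94      104             75     123 0.610 0.003716
#> 10        B   heart--serum      102      109             82     129 0.636 0.005870
#> 11        B   liver--serum       90      104             75     119 0.630 0.011064
#> 12        B  serum--vastus       94      102             75     121 0.620 0.005206
```

Reading this: each group keeps 65–75 ubiquitous (A-type) lipids but only 45
are the *same* variables — J = 0.47 with p ≈ 0.0002 under the fixed-margin
null, strong evidence the two phenotypes run different lipid complements
through the whole network (the generator planted exactly such discordance).
The per-edge B-lists overlap at J ≈ 0.61–0.64: about two thirds of the
variables on each tissue axis are shared, the rest are phenotype-specific.

Drill into one scope and one variable set:

```r
al <- align_binary_lists(res$classification, "U", "adipose",
                         lipid_class = "TG")
jaccard_pvalue(al$x, al$y)
#> J 0.40, p 0.60  (intersection 2 / union 5, exact)

head(subset(res$enfc, abs(enfc) > 3))   # largest error-normalised changes
#>     variable mean_case mean_control fold_change  enfc
#> 279 PC(36:2)      2211         5647       0.392 -7.67
#> 197 PE(44:8)      2252          391       5.753  6.88
```

`lta_out/` now contains the per-category CSVs (`U_<group>_<tissue>.csv`,
`A_<group>.csv`, `B_<group>_<edge>.csv`, `classification_long.csv`),
`overlap_stats.csv`, `enfc.csv`, the network pie map `switch_map.svg`, a
wiring diagram of the A-type union, and `manifest.json` recording the
configuration and seed. Re-running with the same seed reproduces every file
byte for byte.

### Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli/lta.R", package="lipidtraffic"))') \
    switch --input mystudy.csv --control lean --only U,A,B --out lta_out
Rscript .../lta.R simulate --seed 1 --dropout 0.2 --out sim_out
```

Exit codes: 0 success, 2 validation failure, 3 statistical preconditions
unmet.

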