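---
title: "Lipid traffic analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lipid traffic analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidtraffic)
```

## The question the method answers

Lipid metabolism is a property of a whole organism, not of one tissue.
Lipids are synthesised mainly in the liver, circulate through serum, are
stored in adipose tissue, oxidised in heart and skeletal muscle, and used
structurally in the CNS. When two phenotype groups (say lean and obese
animals) are profiled by direct-infusion mass spectrometry in several of
these compartments, the interesting signal is often not "is lipid X more
abundant" but "is lipid X *present in different places*" — evidence that
the control of lipid distribution, not just biosynthesis, differs between
the groups.

`lipidtraffic` implements this *switch analysis*. It deliberately works on
presence/absence rather than abundance, because presence calls are robust
to the between-tissue normalisation problems that make cross-compartment
abundance comparisons treacherous.

## The model

### Presence rule

For each group $g$, compartment $c$ and lipid variable $v$, the presence
fraction is

$$B_{g,c,v} = \frac{\#\{\text{samples in } (g,c) \text{ with signal} > 0\}}
                   {\#\{\text{samples in } (g,c)\}}$$

and $v$ is *present* in $(g,c)$ when $B \ge 0.66$ — signal in at least
two thirds of the samples. The bound is closed: $B$ exactly at the
threshold counts as present. The threshold is a tunable parameter of
`binarize()` (and `--threshold` on the CLI); 0.66 is the default because
it tolerates a minority of failed injections per cell while still
requiring a clear majority of detections. With the comparison implemented
on exact counts (a fraction within $10^{-9}$ of the threshold counts as
reaching it), a cell with 33 of 50 samples positive is present at
threshold 0.66 even though neither number is exactly representable in
binary floating point.

### Switch categories on the tissue network

The compartments form a small undirected graph — by default serum as a hub
adjacent to liver, heart, vastus (skeletal muscle), adipose and CNS, which
mirrors how lipids physically move: nearly all inter-organ traffic transits
the circulation. Per group, each variable is classified:

* **A-type** — present in *every* compartment (ubiquitous);
* **B-type**, per edge — present in *both* endpoint compartments of that
  edge;
* **U-type**, per compartment — present in exactly *one* compartment.

B-type is deliberately non-exclusive: a variable present everywhere is a
member of every edge's B-list, so the A-list is a subset of every B-list.
That is how edge pies on the network map are read (they count everything
shared across the edge), and it keeps each edge's list interpretable on
its own. Variables present in a non-adjacent pair, or in three to five
scattered compartments, belong to the B-lists of any edge whose two
endpoints they cover and are labelled `multi` in the per-variable
traceability record; variables present nowhere go to a `not_detected`
list rather than being dropped.

The two groups are processed fully independently; only their finished
lists are compared. Pooling presence across phenotypes would erase
precisely the distributional switches the method looks for.

### Comparing the two groups' lists

For any scope (e.g. "U-type TGs in adipose", "B-type PCs on serum–heart")
the two groups' variable lists are aligned over their union, in a
canonical order (lipid class, then total carbons, then double bonds, then
name — a stable order so that reported statistics are reproducible), and
summarised by the Jaccard–Tanimoto coefficient

$$J = \frac{|L_1 \cap L_2|}{|L_1 \cup L_2|}.$$

The attached significance value asks: *if both groups drew their lists at
random from the same pool of variables, each keeping its observed list
size, how often would the lists overlap as little as observed?* Under
this fixed-margin, exchangeable-position null the intersection size $k$
is hypergeometric, and since $J$ is monotone in $k$,

$$p = P(J_{\mathrm{null}} \le J_{\mathrm{obs}})
    = P_{\mathrm{hyper}}(K \le k_{\mathrm{obs}}).$$

Small $p$ is evidence that the two phenotypes genuinely keep different
variables in that scope — note this is one-sided toward *dissimilarity*,
and identical lists give $p = 1$, not 0.5; a two-sided option (summing
all intersection sizes whose null probability does not exceed the
observed one's) is exposed for users who want the conventional reading.
The exact enumeration is the default up to vectors of length 170
(`phyper` in log space stays stable there); beyond that a seeded
permutation of one vector's positions is used, reported as
$(1 + \#\{J^* \le J_{\mathrm{obs}}\})/(R + 1)$ with $R = 10{,}000$
resamples by default. A third, "bootstrap" variant redraws both vectors
with independent Bernoulli entries at each list's observed marginal rate,
for users who prefer list sizes to vary under the null; the exact and
permutation routes are the primary ones, and the test suite checks they
agree within Monte-Carlo error.

No multiple-testing correction is applied across scopes: each $J$/$p$
pair annotates one location of the network map and is read as a local
similarity summary, not as a hypothesis-test family.

### Quantitative companions

* `enfc()` — the *error-normalised fold change*. The fold change of group
  means on the log2 scale, standardised by its delta-method standard
  error:
  $$\mathrm{ENFC} = \frac{\log_2 \bar{x}_{\mathrm{case}} -
                          \log_2 \bar{x}_{\mathrm{control}}}
    {\frac{1}{\ln 2}\sqrt{\frac{s^2_{\mathrm{case}}}{n_{\mathrm{case}}
       \bar{x}^2_{\mathrm{case}}}
      + \frac{s^2_{\mathrm{control}}}{n_{\mathrm{control}}
       \bar{x}^2_{\mathrm{control}}}}}$$
  This particular standardisation is one defensible reading of the name
  "error-normalised fold change" — dimensionless, exactly antisymmetric
  under swapping the groups (the implementation computes
  $\log_2\bar{x}_1 - \log_2\bar{x}_0$ rather than the log of the ratio so
  the antisymmetry is exact in floating point, something the test suite
  asserts with `expect_identical`), and zero exactly at fold change 1.
  Other normalisations exist in the field; the formula is documented
  here so results are interpretable, and the summary statistics needed
  to recompute any alternative are all returned.
* `compare_groups()` — lipidomic intensities are treated as unequally
  distributed and heteroscedastic, so groups are compared with the
  two-sided Mann–Whitney rank-sum test (exact null up to $n \le 8$ per
  group without ties, normal approximation with tie correction
  otherwise), with Bonferroni family-wise thresholds
  (`bonferroni_threshold()`, reported to 3 significant figures) rather
  than FDR: the variable families here are small (tens of fatty acids)
  and the cost of a false positive is high.
* `fa_ratio()` — diagnostic ratios such as FA(15:0)/FA(17:0) (a dairy-fat
  intake marker) are computed per sample and then averaged, not as a
  ratio of group means, so that the group comparison can run on the
  per-sample ratios; the ratio-of-means variant is available as an
  option. Samples with a zero denominator are excluded with a warning.

### Nomenclature

Variables are sum compositions, `CLASS(C:D)`. The parser accepts the
common glyceride/phospholipid/sphingolipid/fatty-acid class tokens
case-insensitively, stores any adduct annotation verbatim, and maps
unknown classes to `"other"` while still extracting the carbon and
double-bond counts. Two choices deserve a note:

* *Odd-chain status* is defined at the sum-composition level (total
  carbon count odd). Direct-infusion MS cannot resolve per-chain parity,
  and an odd total is the operational marker used when discussing
  odd-chain fatty acid metabolism.
* *TG-derived glycerides*: a DG is linked to a TG inventory when some TG
  differs from it by one acyl chain of 10–26 carbons and 0–6 double
  bonds (doubled for MG, which lacks two chains). The window spans
  medium-chain through long-chain polyunsaturated fatty acids with
  margin; there is no community-standard rule here, so the bounds are
  explicit arguments of `flag_tg_derived()`.

## The synthetic-data generator

`generate_study()` exists so that every stage of the pipeline can be
validated against a known answer. Its defaults mirror a realistic study
of this design: 6 compartments on the serum-centred network, 2 groups,
8 samples per group and compartment, ~300 variables across TG/PC/PE/SM
including odd-chain species. Each (group, variable) is planted as A,
U@compartment, B@edge or absent (weights 0.25/0.20/0.35/0.20 — most real
lipids are shared across part of the network, unique variables are a
minority); 30% of variables draw the two groups' categories
independently, planting the between-group switches; 20% carry a true
2-fold abundance change in the case group. Abundances are lognormal
(skewed, heteroscedastic, per-variable location spread over three orders
of magnitude), exactly 0 where absent, and each present sample is zeroed
independently with the dropout probability. Dropout at or above 0.34 is
refused: the expected detection rate would fall to 66% or below and the
presence rule would fail by construction rather than by noise.

What the generator does *not* emulate: ionisation-mode effects, adducts
and isobars, correlated dropout (real failed injections kill a whole
sample, not independent cells), compartment-specific intensity scales,
and biological correlation between lipids. Passing the recovery tests
therefore demonstrates the *logic* of the pipeline, not its robustness
to every artefact of real spectra.

### Two recovery metrics, deliberately

`truth_recovery_report()` reports both

* `recovery_rate` — the fraction of (group, variable) pairs whose
  recovered category label (with location) matches the planted one
  exactly; and
* `presence_call_accuracy` — the fraction of individual
  (group, compartment, variable) presence calls matching the planted
  pattern.

At dropout 0 both are exactly 1, and the test suite asserts that as a
hard invariant. Under dropout the two diverge sharply, and the reason is
worth understanding before reading any recovery number: with dropout
$d = 0.3$ and $n = 8$ samples, a truly present cell is *called* present
only with probability $P(\mathrm{Binom}(8, 0.7) \ge 6) \approx 0.55$, so
an A-type variable (six cells, all of which must survive) is exactly
recovered with probability $0.55^6 \approx 0.03$. Category-exact recovery
is thus dominated by binomial thinning at small $n$ (about 0.42 under the
default mix), while presence-call accuracy (about 0.82) measures how much
of the planted pattern survives per cell. The category metric is the
honest headline for "did the pipeline reconstruct the structure"; the
call-level metric is the right one for "how noisy is each presence
decision". Both are computed and written by `run_simulate()`.

## Reporting

`build_switch_figure()` lays the network out deterministically (hub at
the centre when one compartment is adjacent to all others, remaining
compartments on a circle in declared order), attaches the two groups' U
counts to nodes and B counts to edges, and copies $J$/$p$ annotations —
formatted to two decimals, as they are conventionally printed — from the
overlap table. Counts are *copied* from the classification, never
recomputed, and the test suite asserts figure count == classification
list size. `build_wiring_diagram()` draws one track per variable and
group with a stop at each compartment where presence holds, the standard
way to read which isoforms run through which tissues. Both render to
plain SVG text — byte-identical across reruns, diffable in tests — with
a JSON sidecar of every plotted number; colours default to blue for the
first (control) group and orange for the second.

## Numerical and interface choices

* Missing cells and explicit `NA` in input tables are coerced to 0 with
  a counted warning: the presence rule is defined on "signal > 0", so
  an unrecorded measurement and a non-detection are operationally the
  same thing here.
* Dataset CSVs are written with 17 significant digits, so a write/load
  round trip reproduces the abundance matrix bit for bit (asserted in
  the tests).
* Group labels are arbitrary text; `run_switch()` asks which label is
  the control to fix the ENFC sign convention and the figure colour
  order, defaulting to the alphabetically first label.
* Technical replicates are not collapsed: every input row is treated as
  an independent sample. If replicates exist, average them upstream.
* All resampling is seeded and the seed is recorded in the run manifest
  and the overlap table; reruns of `run_switch()` with the same seed are
  byte-identical (asserted in the tests).

## Validation scale

The packaged checks run at desk scale: brute-force classification
oracles on random instances of up to 5 compartments and 50 variables;
permutation-vs-exact agreement on 100 vector pairs of length ≤ 12 at
10,000 resamples; null calibration on 1,000 simulated list pairs;
recovery on the full default study (6 compartments × 2 groups × 8
samples × ~300 variables) across 20 seeds for the dropout condition.
These sizes exercise every code path while keeping the whole suite in
well under a minute of compute; nothing in the implementation is
specific to them.

## Known limitations

* Presence/absence discards abundance information by design; a variable
  that collapses 100-fold but stays detectable does not register in the
  switch analysis (that is what ENFC is for).
* Exactly two groups per run; multi-group designs need pairwise runs.
* The network is user-declared biology, not inferred from data, and the
  analysis is blind to traffic *direction* — establishing directional
  flux needs labelling studies, which are out of scope.
* The hypergeometric null conditions on the observed list sizes; if the
  binarisation threshold is mis-set, both lists shrink or grow together
  and $J$/$p$ cannot detect that.
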