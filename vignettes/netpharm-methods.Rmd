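---
title: "Methods: network pharmacology and downstream omics statistics in netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network pharmacology and downstream omics statistics in netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

`netpharm` chains five statistical stages that are usually scattered
across web tools and ad-hoc scripts: ADME compound screening, interaction-
network construction and hub extraction, over-representation analysis,
xenograft efficacy statistics, and the 16S/metabolome downstream tests.
This vignette documents the models behind each stage, the defaults and
why they were chosen, the numerical conventions, and what the synthetic
data can and cannot establish.

## ADME screening

A compound passes when its oral bioavailability strictly exceeds 30%
and its drug-likeness strictly exceeds 0.18. Both values are consumed as
database annotations, never computed from structure. Whether boundary
values (OB exactly 30) should pass is a genuinely open convention; we
read the published "> 30%" literally and use strict inequalities, with
`strict = FALSE` available for sensitivity checks. Tables are long
format — one row per compound-herb pair — because multi-herb formulas
share chemicals between herbs: per-herb candidate counts therefore sum
to more than the distinct candidate total, which is exactly the
arithmetic seen in published herb contributions (e.g. 4 + 36 + 14 + 90 =
144 contributions from 138 distinct candidates).

## Networks and hub extraction

All graphs are simple and undirected; duplicate edges and self-loops are
dropped at construction and every edge endpoint must be a declared,
typed node (compound / target / protein). Degree and betweenness come
from igraph; betweenness is normalised by `(n-1)(n-2)/2`. Closeness is
computed per connected component as `(n_comp - 1) / sum(d)` and then
scaled by `(n_comp - 1)/(n - 1)` (the Wasserman–Faust adjustment), so
values remain comparable when a network is disconnected — which
intersections routinely are. "Network centrality" (NC) is not a
standard term; we interpret it as mean neighbour degree (neighbourhood
connectivity, as reported by Cytoscape). Because published hub screens
of this kind list only three median cutoffs, NC is computed and
reported but not part of the default hub filter; `use_nc = TRUE` adds
it as a fourth condition.

Two further conventions are deliberately fixed:

* **Intersection vs merge.** Workflows of this kind sometimes say
  "merged" and sometimes "intersected" for combining the compound-target
  and disease-target PPI networks. Since the published combined-network
  sizes are far below either input, intersection (node-id and edge-set
  intersection) is the default; `mode = "merge"` gives the union.
* **Medians on the filtered network.** Hub cutoffs default to the
  medians of the network actually being filtered (the intersection),
  computed over all its nodes, with strict `>` — the conventional
  median-threshold screen. All hub sets and reports are sorted
  lexicographically so runs are deterministic.

First-neighbour expansion defaults ON when building a PPI around seed
targets: a few hundred seeds yielding a network of several thousand
nodes is only possible with interactor expansion, and that is the scale
published pipelines report. Seeds missing from the edge list are kept
as isolated nodes (with a warning) rather than silently dropped.

## Over-representation analysis

The ORA p-value is the hypergeometric upper tail `P(X >= k)`; DAVID's
EASE variant (tail at `k - 1`) is available via `ease = TRUE` but is
not the default, since EASE is a proprietary convention and neither
choice reproduces results tied to an external annotation snapshot. The
universe defaults to the union of all collection members — the least
presumptuous background when none is stated. Terms with zero overlap
are not tested and do not count toward the number of tests (DAVID
behaviour). Adjustment is Benjamini–Hochberg; `enriched` means
q < 0.05. The GMT reader is in-package because the term-description
column must survive the round trip.

## Xenograft efficacy

Volumes use the ellipsoid approximation `V = L * W^2 / 2` (mm³
internally; `units = "cm3"` for display). TGI is computed from arm
mean volumes (ratio of means): on published day-32 volumes this
reproduces the reported high-dose value of 26.836% to three decimals.
One published arm (PD-1: reported 48.216%) is inconsistent with its own
reported volumes (4.847 vs 8.496 cm³ implies 42.95%); `netpharm`
reports the recomputed value and the discrepancy rather than guessing
the intent. A `mean_of_ratios` convention (averaging `1 - Vt_i/Vc_j`
over treated-control pairs) is provided because some published arms
match neither convention exactly. Between-arm tests default to the
equal-variance Student t-test, per the usual "unpaired t-test" wording
of such studies; Welch is a flag; `anova_bh` runs one-way ANOVA plus
BH-adjusted pairwise tests. "Relative tumour volume" in such papers is
treated as absolute mean volume: no baseline normalisation is stated,
and the TGI arithmetic only reproduces under that reading.

## Microbiome statistics

Shannon uses the natural log (the mothur convention; `base = 2`
available). "Chao" is read as Chao1, bias-corrected by default
(`S_obs + F1(F1-1)/(2(F2+1))`, the mothur default), classic form by
flag. ACE uses rare cutoff 10; when every rare taxon is a singleton the
coverage estimate is zero and ACE falls back to Chao1 with a warning.
These estimators are implemented from their closed forms (the flags
above are not all exposed by existing packages) and are cross-checked
against vegan in the test suite.

Differential abundance aggregates counts to a lineage rank, converts to
per-sample relative abundances (no rarefaction depth is assumed,
because none is typically stated), and applies the two-sided Wilcoxon
rank-sum test per taxon: exact when both groups have at most 10 samples
and the data are tie-free, otherwise the normal approximation with tie
and continuity correction. The exact/approximate boundary matters: the
worst-case disagreement between the approximate and exact p-value is
about 0.09 for 2-vs-2 samples and only drops below 0.02 once both
groups have at least 5 samples, so small-group p-values should always
come from the exact path (as they do by default). Kruskal–Wallis is
available for multi-group tables; LDA-effect-size biomarker ranking
(LEfSe) is deliberately not reimplemented — users wanting LEfSe output
should use the original tool. Ordination of microbiome data is
delegated to `pca()` on relative abundances; published figures labelled
"PCoA (PCA)" are ambiguous between the two, and no UniFrac tree input
is in scope.

## Metabolome statistics

PCA is the SVD of the centred (and by default unit-variance) matrix;
zero-variance features are dropped with a warning, and each component's
sign is fixed so its largest-magnitude loading is positive —
a determinism convention, not a statistical choice. PLS-DA is NIPALS
PLS1 on autoscaled data with a centred two-group indicator response
(the one-hot coding of a two-class contrast collapses to one column).
VIP is `sqrt(p * sum_a(SSY_a w_ja^2) / sum_a(SSY_a))`, which satisfies
`sum(VIP^2) = p` exactly; this identity is enforced in the tests at
machine precision. The literature often says only "VIP > 1.0 and
p < 0.05": we assume PLS-DA (the universal source of VIP in
metabolomics; OPLS-DA cannot be ruled out but is not guessed), default
to 2 components (score-plot convention), use Student's unpaired t-test
on natural-log intensities after half-minimum imputation of nonpositive
values, and leave p-values unadjusted (again following the usual
wording), with BH available via `adjust = "BH"`. The VIP > 1 boundary
is strict. Venn logic between contrast-specific feature lists supports
exclusive sets, the common core, and arbitrary `&`/`|`/`!` expressions
over set names — the "present in A and B but absent in C" construction
used when isolating combination-therapy-specific metabolites.

## The synthetic-data module

Generators draw from substreams derived deterministically from one root
seed (`seed * 7919 + offset mod 2^31 - 1`), so identical specs give
byte-identical outputs. Defaults are fixed once, to emulate the study
design this pipeline targets:

| knob | default | rationale |
|---|---|---|
| `n_compounds`, `frac_pass_adme` | 476, 0.29 | published formula scale: 476 chemicals, 138 candidates |
| `ppi_nodes`, `ppi_attach_edges` | 300, 5 | scale-free graph by preferential attachment; edge count is exactly `m(n-m)`; the m earliest nodes are planted hubs |
| `n_samples_per_group` | 12 | the study's group sizes (12/12/9/11) |
| `taxon_fold_change`, `n_diff_taxa` | 4, 6 of 60 | a 4-fold compositional shift, planted among the more abundant half so it is detectable at 20k reads |
| `metabolite_log2_shift` | 3 (log2 units) | strong LC-MS effect vs within-group SD 0.6 |
| `arms` | 8 multipliers | derived from published day-32 volumes via `V0 e^{r·mult·t}` with V0 = 50 mm³ and control reaching 8.496 cm³ at day 32 |
| `n_mice_per_arm`, `noise_cv` | 12, 0.3 | 8 × 12 = 96 animals; 30% caliper CV |

OTU counts are Dirichlet-multinomial (precision 200, 20 000 reads per
sample) — the standard overdispersion model for 16S counts. Metabolite
log-intensities are Gaussian with pooled-QC samples at the global mean
profile plus small noise, reproducing the tight QC clustering expected
in PCA score plots. Tumour growth is exponential per arm with
multiplicative log-normal noise of the stated CV (mean corrected to 1).

What the generators do **not** emulate: raw reads, spectra or
chromatograms; taxonomic structure beyond a fabricated lineage;
compositional correlation between taxa; batch effects, drift, or
censored/missing measurements; immunology readouts. Passing the
recovery suites therefore shows the statistics are implemented
correctly and calibrated — not that real studies of this design would
achieve those recovery rates.

Two additional constructors, `synthetic_gqd_compound_table()` and
`synthetic_crc_target_lists()`, are labelled synthetic stand-ins: they
reproduce only the published *marginal counts* (476 chemicals / 138
candidates with herb contributions 4/36/14/90; disease-target lists of
47/111/7 merging to 150) with fabricated identities, so the screening
and deduplication arithmetic can be exercised at the published scale.

## Problem sizes and calibration checks

The test suite exercises: exact-oracle equality of all four
centralities on 200 random graphs of up to 8 nodes (Floyd–Warshall
distances and adjacency-power path counting as independent oracles);
full enumeration of the hypergeometric tail up to N = 12; 200-replicate
BH null calibration of ORA (mean enriched fraction ≤ 5%); the VIP
identity across model shapes; planted-signal recovery (≥ 80% of hubs,
enriched terms, differential taxa and shifted metabolites at their
stated thresholds) at the default spec; and 100-replicate null runs per
downstream stage requiring zero FDR-corrected discoveries in ≥ 90% of
replicates. These sizes keep the default run to well under a minute
while leaving the Monte-Carlo margins comfortable.

## Known limitations

* Published hub lists, pathway tables and metabolite counts tied to
  external database snapshots (interactomes, annotation services,
  taxonomy references) and undeposited raw data are out of scope and
  not reproduced; the package reproduces the *methods*, and the few
  printed quantities that are self-contained (the TGI arithmetic).
* The normal-approximation Wilcoxon path is a large-sample tool; below
  5 samples per group its p-values can deviate from exact ones by more
  than 0.02 (worst case ≈ 0.09 at 2 vs 2). The exact path covers that
  regime by default.
* PLS-DA VIP depends on the component count; with the default 2
  components VIP ranks are stable in simulation, but no
  cross-validation of component count is performed.
* The classic Chao1 form is undefined when F2 = 0; the implementation
  returns Chao's limiting form `S_obs + F1(F1-1)/2` there.
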