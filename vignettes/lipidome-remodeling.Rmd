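---
title: "Methods: quantifying leaf lipidome remodeling under heat stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying leaf lipidome remodeling under heat stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidremodel)
```

## The scientific problem

When plants experience sustained high temperatures, membrane fluidity rises
and membrane function degrades. A well-documented counter-response —
homeoviscous adaptation — is to remodel the membrane lipidome toward lower
unsaturation: polyunsaturated acyl chains (chiefly 18:3, linolenic acid) are
removed from the plastidic galactolipids (MGDG, DGDG), sulfolipid (SQDG) and
phosphatidylglycerol (PG), and from the extra-plastidic phospholipids (PC,
PE, PI, PS, PA), while triacylglycerols (TG) and sterol esters (SE) absorb
the displaced chains as neutral-lipid buffers. Oxidized-lipid (";O") species
decline alongside, as their 18:3 substrate leaves the membrane.

`lipidremodel` implements the quantitative machinery for detecting and
scoring this remodeling from a direct-infusion ESI–MS/MS quantification
table: shorthand-name parsing, analyte quality control, unsaturation
indices, occurrence-weighted acyl-chain fold changes, factorial
treatment comparisons, co-occurrence and genotype clustering, and SNP
marker-distribution arithmetic for the genetic follow-up. A synthetic-data
generator with full ground truth makes every stage testable end to end.

## Nomenclature model

A lipid species name is a headgroup-class code plus either a *sum
composition* (`"DGDG 36:6"`, total acyl carbons:total double-bond
equivalents) or a resolved, underscore-separated chain list
(`"TG 18:3_18:3_18:2"`). A `;O`*n* suffix on a chain counts oxygens beyond
the carbonyl oxygen (`"DGDG 16:0_18:3;O"`). Sterol lipids are named by their
moiety: `"sitosterol 18:2"` (SE), `"Sitosterol-Glc"` (SG),
`"Sitosterol-Glc 16:0"` (ASG).

Chain-level statistics only use species whose acyl composition is
unambiguous. For classes with a single acyl position (LPC, LPE, MGMG, DGMG,
SE, ASG) the sum composition determines the chain uniquely, so those species
are treated as resolved even without an underscore. Sum compositions on
multi-position classes stay ambiguous: asking whether `"DGDG 36:6"` contains
an 18:3 chain is an error unless the caller supplies an explicit
composition-to-chains lookup (`infer = list("36:6" = c("18:3", "18:3"))`).
We never guess chain splits.

Two modeling conventions worth noting:

* N-acyl PE (`PE-N`) chemically carries a third (amide-linked) chain; we
  model it at the glycerol-diacyl level (2 positions) and its species in the
  default roster are sum compositions only, so it never enters chain-level
  statistics.
* Glycosphingolipids (GSL) have an undefined acyl-position count in this
  taxonomy (`NA`); they are excluded from unsaturation and fold-change
  statistics but participate in totals, shares and clustering.

The class taxonomy (positions, compartment, membrane-diacyl flag) ships as
a plain TSV (`inst/extdata/headgroup_classes.tsv`) and can be overridden via
`headgroup_classes(path = ...)`.

## Quality control

Two screens, both strict inequalities (boundary values are retained):

* **Limit of detection.** An analyte is removed when its mean amount over
  experimental samples falls below `lod = 0.00005` (normalized signal per mg
  dry weight, where 1.0 is the intensity of 1 nmol of internal standard).
  Whether such a rule should aggregate by mean, by any-sample or by
  all-sample is genuinely open; mean is the default, with `lod_rule =
  "any"/"all"` available.
* **QC-pool CV.** The coefficient of variation over the recurrent QC-pool
  injections — sample standard deviation (n−1 denominator, the QC
  convention; configurable) over the mean — must not exceed `cv_max = 0.3`.
  A zero QC mean yields an infinite CV and removal.

Filtering is idempotent, and the removal report (analyte, reason, value,
threshold) accounts exactly for the difference between input and output.

## The statistical model

The design is a two-factor factorial (genotype × temperature, OT vs HT) in
randomized complete blocks, replicated over experimental runs. We fit, per
response,

$$y = \mu + G_i + T_j + (GT)_{ij} + B_k + \varepsilon$$

with genotype, treatment and their interaction as fixed effects and the
run-by-replication block as a fixed factor. The source analysis treated
replication as a random effect (a GLIMMIX mixed model); with a balanced
design the treatment LS-means coincide under either choice, and only the
LSD inference can differ slightly. Blocks are nested in runs, so the
six-level block factor absorbs run mean differences — the runs-pooled
analysis — and an additional run main effect would be aliased with it.

All responses share one design matrix, so a single QR factorization serves
the full analyte matrix. Treatment LS-means average fitted cell means over
genotypes and blocks; on balanced data they equal arithmetic treatment
means (asserted in the tests). Fisher's LSD uses the exact contrast
variance, $t_{1-\alpha/2,\,df_e}\sqrt{L^\top(X^\top X)^{-1}L\,\mathrm{MSE}}$,
which reduces to the textbook $t\sqrt{2\,\mathrm{MSE}/n}$ in the balanced
case. Per the source convention, comparisons are per-response at
$\alpha = 0.05$ with no multiplicity adjustment; percent changes are
reported on the LS-mean scale, $100\,(HT - OT)/OT$.

## Unsaturation indices

The species-level unsaturation index is total double-bond equivalents
divided by the class's acyl-position count (extra oxygens ignored); the
class-level index is the amount-weighted mean of its species' indices.
`class_unsaturation_index()` aggregates amounts over a chosen sample subset
(e.g. all OT samples); `unsaturation_indices()` computes the index per
sample so the class index can be run through the same LS-mean/LSD
comparison as any trait.

## Occurrence-weighted acyl fold changes

For a class $c$ and chain $a$, with $n_{s,a}$ the number of occurrences of
$a$ in resolved species $s$,

$$\mathrm{FC}(c, a) = \frac{\sum_{s \in c} n_{s,a}\,\bar{y}^{HT}_s}
                           {\sum_{s \in c} n_{s,a}\,\bar{y}^{OT}_s},$$

with $\bar y$ treatment LS-means. Oxidized chains are separate columns,
never merged with their parent chain. A cell is *undefined* (`NA`), not
zero, when no resolved species of the class carries the chain or the OT sum
is zero. Significance is tested on the per-sample occurrence-weighted sums
(whether the source tested the sums or the ratios is not stated; the sums
are the quantity with a per-sample distribution, so they are what we test).
The implementation is verified against a brute-force enumeration oracle
that walks (species, chain-occurrence) pairs one at a time.

## Multivariate structure

* **Ordination** wraps `prcomp` with a deterministic sign convention (the
  largest-magnitude loading of each component is made positive).
* **Co-occurrence** is pairwise Spearman correlation among analytes over
  genotype × treatment cell LS-means (108 observations per analyte at the
  default design), so both treatments inform co-occurrence; a raw-replicate
  option exists. On the balanced design the cell LS-means equal cell means
  and are computed by aggregation. Constant vectors have undefined rank
  correlations; they are excluded with a warning rather than imputed.
* **Lipid clustering** is the standard correlation-heatmap construction:
  complete-linkage agglomeration on Euclidean distances between rows of the
  correlation matrix, cut at `k = 6`. The source describes both a
  most-highly-correlated matching and complete-linkage/Euclidean clustering;
  the latter is the reproducible construction, and the ρ matrix itself is
  returned for heatmap display. Items are sorted lexicographically before
  clustering and labels are ordered by cluster size, so assignments are
  invariant to input row order.
* **Genotype classification** standardizes (z-score per analyte) the HT
  LS-means of the tolerance-panel species (DGDG, MGDG, PG, TG, SE) —
  without standardization the high-abundance galactolipids would dominate
  the distances — then clusters genotypes with Ward linkage (the
  incremental sum-of-squares criterion on Euclidean distances, `ward.D2`)
  and cuts at `k = 6`. The *tolerant* cluster is the one containing the
  tolerant anchor genotype when anchors are known, otherwise the cluster
  maximizing mean z of 18:3-containing TG/SE species minus mean z of
  18:3-containing DGDG/MGDG/PG species; *susceptible* is symmetric. An
  anchored label wins over a conflicting score-derived one; two conflicting
  labels of the same provenance cancel.

## Marker-distribution arithmetic

Expected marker counts are size-proportional: per chromosome, the subgenome
marker total divided by subgenome Mb times chromosome Mb; per 10-Mb bin,
the chromosome total divided by chromosome Mb times the bin width, the
final truncated bin scaled by its actual width. Bins are half-open in Mb
from position 0, computed on `(pos − 1)/1e6` (1-based VCF positions).
Expected counts within a subgenome (or chromosome) sum exactly to the
observed total — a conservation property the tests assert. The source never
names its significance procedure; we use an exact two-sided binomial test
of the observed count against `expected/total` and document it as an
interpretation, not a reproduction.

## The synthetic-data generator

The generator emulates the study conditions: 54 genotypes × 2 treatments ×
2 runs × 3 blocks (648 experimental samples) plus 8 recurrent QC-pool
samples, over a 192-species roster spanning all 22 classes. The roster
mirrors what is enumerable from the study — 12/5/1/4/3 oxidized species in
DGDG/MGDG/SQDG/PC/PE, 2 SE + 3 SG + 9 ASG sterol species — and synthesizes
the remainder from the chains the study names; it is representative, not
identical, since the full analyte list is not published. Class shares
default to MGDG 0.49, DGDG 0.29, PC 0.075, PE 0.04, PG 0.035, PI 0.02, with
the remaining 0.05 spread over the minor classes.

Amounts follow a multiplicative lognormal model — MS signal noise is
multiplicative and every effect of interest is a fold or percent:

$$y_{s,a} = \underbrace{T \cdot \pi_{c(a)} \cdot w_a}_{\text{baseline}}
\cdot e^{\gamma_i} \cdot e^{\rho_r + \beta_{rb}}
\cdot M_a^{\,g_i \cdot \mathbb{1}[HT]} \cdot e^{\varepsilon},
\qquad \varepsilon \sim N(0, 0.15^2)$$

* Per-analyte HT multipliers $M_a$ are drawn once per dataset from uniform
  ranges by category, matching the magnitudes the study reports:
  18:3-containing membrane diacyl species U(0.53, 0.75); 18:3-containing TG
  U(1.9, 2.2); SE U(2.5, 5.4); SG U(1.05, 1.4); oxidized species
  U(0.4, 0.8); ASG U(0.4, 0.9); all others U(0.9, 1.1).
* The genotype tolerance parameter $g_i \in [0,1]$ scales each multiplier
  toward 1 (`M^g`), so $g$ ranks genotypes by remodeling strength — the
  quantity `classify_genotypes()` must recover. The default $g_i \sim
  U(0.5, 1)$ says every line remodels but to different degrees; an explicit
  `g_override` vector programs known strong or weak remodelers. Ground
  truth records both $M_a$ and the population-level expected fold
  $\overline{M_a^{g_i}}$, which is what the pipeline's fold estimates
  target.
* Genotype, run and block effects have lognormal sd 0.05; residual sd is
  0.15 on the log scale; QC-pool samples are drawn around the grand mean
  composition with CV 0.1.
* Planted QC violations (3 CV violators at an exact sample CV of 0.45,
  2 LOD violators rescaled to mean 2 × 10⁻⁵) are confined to unremarkable
  minor-class analytes so shares and programmed fold changes stay clean.
  The CV violators use a fixed zero-mean pattern rather than random draws,
  so their sample CV is exactly 0.45 under any seed.
* The grand total signal is 2.0 per mg (arbitrary units on the
  internal-standard scale), which keeps the smallest roster analytes two
  orders of magnitude above the detection limit unless deliberately
  planted below it.

What the generator does *not* emulate: run × treatment interactions,
missing injections, heteroscedastic class-specific noise, correlated
residuals within a sample beyond the shared genotype/block factors, or
isotope/adduct artifacts. Passing the recovery tests therefore shows the
pipeline is correct under its stated model, not that real instrument data
meet that model.

## Numerical choices and degenerate inputs

* Zero-variance responses give MSE 0 and LSD 0; any non-zero difference is
  then flagged, which is the right answer for noise-free fixtures.
* Percent change and fold-change cells are errors/`NA` when the OT
  reference is not positive — never silently 0.
* Rank-deficient designs (e.g. a treatment missing) are an error, not a
  silent pseudo-inverse fit.
* Agglomeration ties are resolved by the lexicographic pre-sort of items;
  `cutree` labels are re-ordered by cluster size (ties by first item).
* Problem sizes: the test suite and the acceptance script run the full
  default design (648 × 192) through every stage — generation, QC, LS-mean
  fits, fold-change matrix, both clusterings — in a few seconds on one CPU,
  plus a 14,000-marker distribution summary; these sizes were chosen to
  match the emulated study exactly rather than a scaled-down version.

## Known limitations

* Fixed-effect blocks instead of the source's random-effect replication:
  identical LS-means here, but LSD thresholds are not guaranteed to equal
  the mixed-model ones on unbalanced data.
* No sn-position or double-bond-position semantics; underscore order is
  preserved as given.
* The di-chain inference for unresolved diacyl compositions is opt-in and
  lookup-driven; no inference is attempted for 3-position classes.
* The marker deviation test treats markers as independent draws, which
  linkage disequilibrium violates; flags are descriptive, not genome-wide
  inference.
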