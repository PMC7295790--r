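---
title: "Optimizing culturomics condition panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing culturomics condition panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(culturopt)
```

## The problem

Culturomics surveys a microbial community by plating the same specimens
under tens of culture conditions — combinations of medium, atmosphere,
temperature, supplements and specimen pre-treatment — and identifying
every colony. The approach recovers hundreds of species per study, but
each added condition multiplies the colonies that must be picked and
identified. Most conditions are redundant: the species they grow are
also grown elsewhere. The question this package answers is *which small
subset of conditions preserves the captured diversity*, together with
the descriptive contrasts that justify the choice (atmosphere,
supplements, condition groups).

The substrate is a binary **incidence matrix** \(X \in \{0,1\}^{S
\times C}\): \(x_{ij} = 1\) when species \(i\) was isolated at least
once under condition \(j\). Abundances and per-specimen structure are
deliberately ignored — recovery is what matters for panel design.

## Ranking and greedy panel selection

The **richness** of condition \(j\) is \(r_j = \sum_i x_{ij}\), the
number of distinct species it isolated; `rank_by_richness()` sorts
conditions by \(r_j\) (ties by ascending id, so the ranking is
reproducible).

Panel selection is the classical greedy rule for maximum coverage /
set cover. Writing \(S_j\) for the species set of condition \(j\) and
\(U_t\) for the union covered after \(t\) picks, step \(t + 1\) selects

\[ j_{t+1} = \arg\max_j \; |S_j \setminus U_t|, \]

the condition adding the most species not yet isolated by the panel
(`marginal_gain()`), stopping when the covered fraction reaches the
target (`target_fraction`, default 1 for the full-coverage panel; 0.98
for the reduced panel). Coverage is submodular, so the sequence of
marginal gains is non-increasing — asserted on every `cover_result` in
the test-suite — and the greedy \(k\)-step coverage is at least
\(1 - 1/e\) of the best achievable with \(k\) conditions, which the
tests verify against exhaustive search on small instances. For
instances with at most 20 conditions, `exact_min_cover()` provides the
exact optimum by subset enumeration; greedy never beats it and the
tests check it never needs fewer steps than the optimum's size.

Three design choices the selection rule leaves open were fixed as
follows:

* **Tie-breaks.** At equal marginal gain the condition with larger
  standalone richness wins, then ascending id. This keeps results
  deterministic and prefers generally productive media, which is how
  practitioners read such rankings.
* **Seeding.** `seed_condition` forces the first pick, mirroring
  analyses that anchor the panel at a historically trusted condition.
  Since such a condition is typically also the richest, seeding it is
  equivalent to pure greedy — a property the tests assert.
* **Manual additions.** Real recommended panels sometimes append a
  selective medium the greedy rule would skip (it targets a taxon, not
  bulk coverage). `force_include` appends such conditions after the
  stopping point with their marginal gain evaluated at append time, so
  the report stays arithmetically consistent.

`panel_report()` renders a cover as the familiar recommendation table:
species added, standalone richness, cumulative count, cumulative
percent. Percentages are rounded **half-up** to integers; with 487 of
497 species covered this prints 98%, matching how such tables are
conventionally reported. The numeric method accepts a bare gain column
plus a total, so a published table's arithmetic can be checked without
the underlying matrix.

`accumulation_curve()` contrasts the greedy ordering with random
condition orderings (seeded, mean/min/max over permutations) — the
standard visual argument that an optimized panel saturates richness
faster than unplanned condition accumulation.

## Group partitions and contrasts

`species_partition()` splits the species union of two or three
condition groups (tagged in the condition metadata) into Venn regions
by membership signature; counts always sum to the union, and for three
groups the triple-intersection share of the union is reported as a
rounded percentage. `added_and_specific()` gives the two numbers
typically quoted against a baseline group: species added beyond the
baseline, and how many of those no other group recovered.
`compare_to_catalogue()` counts species absent from an external
reference list (normalized exact name match); such catalogues are
distributed separately and are treated as optional input, never
bundled.

`paired_supplement_contrast()` compares two disjoint condition arms —
designed for a set of media with a supplement against the same media
without it. Each arm is reduced to its species union; the 2×2 table

\[ \begin{pmatrix} \text{specific}_A & \text{shared} \\
                   \text{specific}_B & \text{shared} \end{pmatrix} \]

is tested with the classical Pearson chi-square (`pearson_chi2()`,
df = 1, expected counts from the margins, upper-tail p-value via
`pchisq`). Published analyses of this design usually print only the
arm totals and the larger arm's specific count; the table above is the
reconstruction convention this package adopts, and the constructor
records the full table in its output so the reconstruction is
explicit. The Yates continuity correction is off by default — the
classical statistic is what such studies report — but available as a
flag; for the effect sizes involved the conclusion is
correction-robust. Arms with identical species sets have nothing
arm-specific to compare and return chi-square 0, p 1, rather than a
degenerate-table error.

`atmosphere_crosstab()` assigns every species to exactly one recovery
class — anaerobic-only, aerobic-only, or both, by union over
same-atmosphere conditions — and crosses the classes with the species'
oxygen phenotype. "Oxygen tolerant" deliberately aggregates
facultative and aerotolerant organisms: recovery data supports a
two-way physiological split, not finer grades. Species without a
phenotype are tallied under "unknown", never dropped.

## Taxon-novelty thresholds

`classify_identity()` encodes the 16S rRNA identity rule used to flag
novel taxa in culturomics: identity below 95% to the nearest named
species suggests a new genus, below 98.65% a new species, otherwise a
known species. Both thresholds are strict inequalities; equality falls
in the higher class (98.65 is a known species, 95 a new species). The
classifier is a total function on [0, 100], and the boundary behaviour
is pinned exactly in the tests. Computing percent identity (alignment,
BLAST) is out of scope — the number is an input.

## The synthetic generator

`generate_incidence()` draws each cell independently as Bernoulli with

\[ p_{ij} = \min\!\big(1,\; b_i \, e_j \, m_{ij}\big), \]

where \(b_i\) is a log-normal per-species baseline detectability
(heavy-tailed: a few ubiquitous species, a long tail of rare ones),
\(e_j\) a log-normal per-condition effect, and \(m_{ij}\) the product
of modifiers: the dominant condition replaces \(e_j\) with a fixed
baseline multiplier; rumen-supplemented conditions are boosted;
aerobic conditions are damped; alcohol pre-treatment (selective for
spore-formers) is damped further; and strict anaerobes are penalized
under aerobic conditions. Rows that come out all-zero are redrawn (a
species is only ever observed because it was isolated somewhere), with
a retry cap of 100 per species; conditioning the row distribution on
non-emptiness would be exact but the redraw bias is negligible at
default parameters and the code stays simple.

`study_shaped_fixture()` is the preset the tests and the acceptance
script run on: 497 species × 58 conditions (40 anaerobic / 18
aerobic), group tags sized 18/18/22 (a standard panel, a new-media
panel, and an alcohol-pre-treatment panel), 67% strict anaerobes, one
dominant anaerobic rumen-and-blood bottle, and seven rumen-supplemented
conditions each matched by the identical condition without rumen
(matched pairs share their base condition effect, so the arms differ
only by the supplement).

Defaults were calibrated once, by Monte-Carlo over seeds, to the
survey structure the preset emulates — dominant-condition richness
close to 62% of all species (held to ±5% on average across seeds),
anaerobic conditions jointly capturing ≈99% of species, a rapidly
decaying marginal-gain profile, and a supplemented arm that out-riches
its matched arm essentially always — and then frozen. The calibration
targets are structural, not exact: group unions, the triple
intersection and the full-coverage panel size land near, not on, any
particular survey's values.

What the generator does **not** emulate: co-occurrence structure
(cells are independent given the margins — real conditions share media
chemistry and real species co-associate), donor/specimen structure
(no per-specimen breakdown), abundances or enrichment-time dynamics
(presence/absence only), and taxonomic signal in the phenotype flags.
Passing tests therefore demonstrate the pipeline's correctness and the
stated distributional properties, not performance guarantees on any
real survey.

## Numerical and interface conventions

* Species identity is normalized exact string match: trimmed,
  internal whitespace collapsed, case-insensitive, first-seen casing
  kept for display. No synonym resolution.
* A condition that grew nothing is legal (richness 0, kept); a species
  with no detections is rejected at construction. Duplicate detection
  records collapse to a single 1.
* Long TSV (`species<TAB>condition`) is the canonical interchange; wide
  0/1 CSV is supported for spreadsheets. The long format stores no
  order for empty columns or column sequence, so lossless order
  round-trips are guaranteed by the wide format only.
* All printed percentages round half-up to integers.
* `exact_min_cover()` refuses instances above 20 conditions: subset
  enumeration beyond 2^20 is no longer a desk-scale oracle.
* Every stochastic entry point takes an explicit integer seed and is
  bitwise deterministic given it; the RNG state of the caller is left
  untouched.

## Problem sizes used in the checks

The test-suite exercises the property sweeps at small instance sizes —
hundreds to a thousand random matrices of 5–25 species × 3–8
conditions for greedy/oracle properties, a thousand random 2×2 tables
against the reference chi-square, and ~100 fixture replicates for the
supplement-boost and calibration checks; the full study-shaped preset
(497 × 58) is used directly for the end-to-end pipeline runs. These
sizes were chosen so the whole suite completes in well under a minute
while still giving the exhaustive oracles room to bite.

## Known limitations

* The greedy panel is a heuristic; for instances beyond the exact
  oracle's reach its optimality gap is only bounded by theory
  (\(1 - 1/e\) per panel size), not measured.
* Name-based species identity inherits every inconsistency of the
  input taxonomy; two labels for one organism count as two species.
* The chi-square contrast treats species as independent observations,
  as the original analyses do; phylogenetic correlation is ignored.
* `species_partition()` supports at most three groups — the
  inclusion-exclusion report mirrors the three-way group designs it
  was built for, and a general k-way partition was not needed.
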