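---
title: "Methods: from genome tables to niche projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from genome tables to niche projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magscape)
```

This vignette explains what each stage of the pipeline computes, the
assumptions behind the models, the parameters that matter, and the design
choices made where more than one defensible option existed. The package
operates strictly downstream of assembly, binning, gene prediction, read
mapping, ANI computation, homology search and climate modelling: all of
those arrive as tabular inputs, and nothing here re-derives them.

## Dereplication

Two genomes are redundant when their average nucleotide identity exceeds
98% **and** more than 25% of the smaller genome is aligned. Both
inequalities are strict: a pair at exactly ANI = 98 or alignment
fraction = 0.25 is kept as distinct. Redundancy is then treated as
*transitive*: redundant pairs form a graph, its connected components are
the redundancy groups, and the longest member represents each group. The
pairwise rule alone does not force transitivity — A~B and B~C do not imply
A~C — but grouping is the natural reading of "a group of redundant
genomes", and at a 98% ANI cut chains that bridge genuinely distinct
populations are rare. Because the choice is nonetheless real, a greedy
pairwise alternative (`mode = "pairwise"`: visit genomes longest-first,
drop any genome redundant with an already-kept one) is provided; on
chain-free inputs the two agree. Representative length ties break
lexicographically by genome id so results are deterministic.

## Detection, filtered and projected reads

Breadth of coverage — the fraction of a genome covered by at least one
read — separates genuine presence from non-specific recruitment far more
reliably than read counts, because conserved or repetitive regions attract
reads from relatives. Detection therefore requires breadth strictly above
0.25; all recruited reads from non-detected genome/sample combinations are
set to zero before any downstream use. Filtered counts are projected to
completeness as `reads × 100 / completion` to compare genomes of very
different completeness on one scale; below a completion floor of 10% the
raw count is preserved, since dividing by a tiny, noisy completion
estimate would amplify error without bound. Projections are rounded
half-up to whole reads. The upstream 90% read-mapping identity criterion
is carried as configuration metadata only — the package never sees
alignments.

The cosmopolitan score of a genome is the fraction of a designated
station subset at which it is detected, where a station counts as detected
if *any* of its metagenomes (depths, size fractions) is detected. The raw
detected-station count is emitted alongside, as the two are monotone
equivalents and summaries in the field use both. The fraction of the
sequencing effort recruited is reported pooled and per metagenome, since
the pooled number hides strong per-sample variation.

## Marker novelty

Up to six marker genes per genome — the two largest subunits of the three
DNA-dependent RNA polymerases — each carry a best-hit percent identity
against a reference protein database. The novelty score is 100 minus their
unweighted arithmetic mean (an average identity of 64% gives a score
of 36). No length weighting is applied; the markers are all multi-kilobase
genes of comparable information content. When a genome carries several
curated copies of one marker, copies are averaged within the marker first,
then across markers, and the case is logged — this keeps one unusually
duplicated marker from dominating the mean. For display the score is
clipped to [30, 60], the window used in the figure layers; the raw value
is always emitted next to it. Genomes without any marker are excluded and
listed, not scored.

## Functional landscape

The occurrence matrix counts genes per genome and orthologous group;
genes without an assigned group are ignored (they return through the
gene-cluster route below). *Functional redundancy* of a genome is the
fraction of its annotated genes whose function occurs at least twice in
that genome — high redundancy is what makes functional profiles of
incomplete genomes usable at all, because a function present in many
copies survives moderate genome incompleteness.

Before clustering, two filters apply: explicit genome exclusions (e.g.
lineages with unreliable gene prediction, low-completion outliers), and
function columns that occur more than 500 times (strictly) in a designated
giga-scale reference genome **and** are flagged retrotransposon-linked.
Both conditions are required: high occurrence alone is legitimate biology
(e.g. dioxygenase radiations), and the flag alone without extreme
occurrence does not connect unrelated genomes. The flag is an input
column, as identifying retrotransposon linkage is a curation task.

Clustering uses Euclidean distance with Ward linkage (`ward.D2`, the
variant that correctly implements Ward's criterion on unsquared
distances). Raw counts are clustered by default; a `log10(x+1)` transform
is available because displays conventionally use it, but the stated method
operates on occurrence, so raw is the default. Outgroup genomes (small
animals, used to root the display dendrogram) participate in the full
clustering but group extraction happens on a dendrogram rebuilt from the
non-outgroup genomes, cut into `group_count = 4` groups — a deterministic
proxy for reading groups off the tree by eye. Group labels A–D follow
first appearance in dendrogram leaf order; rows are sorted internally so
the partition is invariant to input order.

Per-function differences between groups use Welch's heteroscedastic
ANOVA: with $w_i = n_i/s_i^2$ and $\bar{x}_w = \sum w_i\bar{x}_i/\sum w_i$,

$$F = \frac{\sum_i w_i(\bar{x}_i-\bar{x}_w)^2/(k-1)}
{1 + \frac{2(k-2)}{k^2-1}\sum_i \frac{(1-w_i/\sum w)^2}{n_i-1}},
\qquad df_2 = \frac{k^2-1}{3\sum_i (1-w_i/\sum w)^2/(n_i-1)}.$$

Occurrence counts violate the equal-variance assumption of classical
ANOVA badly (group variance grows with group mean), which is why the
heteroscedastic form is used; when variances and group sizes are equal it
reduces to the classical F, and the test suite checks numerical agreement
with `stats::oneway.test` on every random instance. Significance uses the
raw p < 1e-5 rule with **no** multiple-testing correction — that is the
published decision rule — but Benjamini–Hochberg q-values are reported in
the same table for transparency. Functions with a zero-variance group are
skipped with a recorded reason rather than given a fabricated p-value.
Significant functions receive Games-Howell pairwise comparisons:
$t = (\bar{x}_i-\bar{x}_j)/\sqrt{s_i^2/n_i+s_j^2/n_j}$ with
Welch–Satterthwaite degrees of freedom, referred to the studentized-range
distribution with $q = |t|\sqrt{2}$ and $k$ groups.

Remote-homology gene clusters receive a consensus annotation by strict
majority: the orthologous-group label carried by more than half of the
annotated member genes, else "unresolved" (treated as unknown function).
The quorum fraction is not fixed by the published description beyond
"majority voting"; strict majority is the choice here because it is the
smallest quorum that guarantees a unique winner without tie-break
arbitrariness. Clusters with an identical resolved consensus merge into
one group; unknown-function clusters pass through unmerged. Groups present
in strictly less than 2% of the analyzed genomes are excluded (a group in
exactly 2% is kept).

## Niche models and projections

Genomes detected at fewer than five stations are excluded from niche
fitting — below that, seven-parameter envelope estimates are noise. For
the rest, the seven parameters (SST in °C, salinity in PSU, silicate,
nitrate and phosphate in µmol/L, iron in model units, and the
dimensionless nitrate seasonality index in [0, 1]) are standardized by the
training-station mean and standard deviation, so parameters with different
units contribute comparably. The niche is a Gaussian envelope: center =
mean of the presence stations, per-parameter spread = their standard
deviation, floored at 0.5 standardized units. The floor matters when
presence stations happen to share nearly identical values of one
parameter; without it the envelope collapses to a delta function and
projects presence nowhere.

The published analysis delegates its niche models to an ensemble approach
described in prior work and supplementary material; this package instead
defines one fully explicit, recoverable default. The probability of
presence of a grid cell with standardized environment $z$ is

$$P = \exp\!\left(-\tfrac{1}{2}\,\kappa\,\cdot\tfrac{1}{7}
\sum_{j=1}^{7}\left(\frac{z_j-m_j}{s_j}\right)^2\right)$$

with $\kappa$ calibrated per genome so the *mean* presence-station squared
distance maps to exactly P = 0.5 — matching the legend convention that
green (0.5) marks the niche boundary, red (1) its center. P = 1 holds
exactly at the optimum and P → 0 far from it. The presence surface sums
spherical cell areas $R^2\,\Delta\lambda\,(\sin\phi_{top}-\sin\phi_{bot})$
(R = 6371 km; ≈ 12 364 km² for a 1°×1° equatorial cell) over ocean cells
with P strictly above 0.5.

ΔP = P(period 2) − P(period 1) per cell; cells with |ΔP| strictly above
0.1 are expansion (positive) or reduction (negative) regions. Driver
attribution substitutes, one parameter at a time, the period-2 value into
the period-1 environment and recomputes P; the parameter with the largest
|ΔP_j| is the cell's first-rank driver (ties break lexicographically and
are counted). This one-at-a-time scheme is the simplest attribution
consistent with "parameters driving the projected shifts"; it ignores
interaction terms, which a Shapley-style decomposition would capture at
much higher cost. Region-level shares are flagged-cell-count weighted by
default, with |ΔP|-magnitude weighting available, because the published
percentages do not state their weighting.

## The synthetic-data generator

`simulate_bundle()` emulates the *structure* of the study's data, not its
biology: genome lengths log-uniform between 10 Mbp and 1.3 Gbp (the span
of the real collection), disjoint redundant pairs planted at
ANI ~ U(98.1, 99.9) with all other pairs below 97, function counts
Poisson(λ = 1) with each planted group's marker functions raised by +5 in
member genomes (half the markers designated known-function, half unknown,
so both matrix slices carry the signal), three retrotransposon-flagged
functions at 600 copies in the largest genome, and Gaussian niches
centered on a randomly chosen home station with widths of 0.6–1.2
across-station standard deviations. Recruitment breadth is drawn
U(0.3, 0.9) inside the planted niche and U(0, 0.2) outside, deliberately
clear of the 0.25 threshold so detection truth is unambiguous. Environments
are smooth analytic fields (SST decreasing poleward, nutrients increasing,
longitudinally varying iron) on a 1° grid with a two-rectangle land mask;
period 2 adds a configurable per-parameter offset (default +2 °C SST
only). Every generator is a pure function of the spec, including its seed.

What passing tests on these data do **not** show: robustness to
overdispersed or zero-inflated counts, to breadth values near the
detection threshold, to correlated environmental parameters (real nutrient
fields co-vary strongly), to non-Gaussian or multimodal niches, or to the
patchiness of real ocean sampling. The generator's Poisson/Gaussian
choices are the simplest models that make the planted structure exactly
recoverable, which is what the validation needs — they are stand-ins, not
claims about the study system.

## Numerical and interface choices

* All thresholds sit in one validated `pipeline_config()`; every boundary
  comparison in the package is strict or non-strict exactly as the rules
  state (ANI > 98, alignment > 0.25, breadth > 0.25, completion < 10
  preserved, occurrence > 500, prevalence < 2% excluded, ≥ 5 stations,
  |ΔP| > 0.1, P > 0.5).
* Read projection rounds half-up (`floor(x + 0.5)`) rather than using
  banker's rounding, so counts are integral and platform-stable.
* Intermediates are headered TSVs with strict schema validation; a
  permissive flag downgrades row errors to warnings. No intermediate file
  format is inherited from the study, so the schemas are this package's
  own contract.
* Determinism: same config + seed + inputs give byte-identical outputs;
  the orchestrator logs a config hash and seed per run.
* Test problem sizes (the package's own validation scale): dereplication
  oracles at n ≤ 12 over 200 random instances; Welch null calibration at
  4 × 30 observations × 10 000 functions; group recovery at 100 genomes ×
  500 functions; niche recovery at 200 presence stations; attribution
  oracles on a 10-cell grid. These sizes make every check exact or
  tightly calibrated while keeping the full suite under half a minute.
* The CLI (`inst/cli/magscape.R`) is a thin wrapper over `run_pipeline()`;
  single-stage subcommands run the shared orchestrator and point at that
  stage's outputs, since all stages are cheap at desk scale and share
  validated inputs.

## Known limitations

The niche model is a single Gaussian envelope, not an ensemble of
distribution models; its probabilities are calibrated geometrically, not
fitted to presence/absence likelihood. Driver shares depend on the
declared weighting and ignore parameter interactions. The cosmopolitan
score assumes the station subset is meaningful for all genomes (size
fractions are not modelled separately). And the whole pipeline trusts its
inputs: ANI, breadth, completion and annotations are taken as given, so
upstream biases propagate untouched.
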