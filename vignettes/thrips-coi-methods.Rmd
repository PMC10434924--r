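---
title: "Methods: COI-barcode population genetics of onion thrips"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: COI-barcode population genetics of onion thrips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ThripsCOI)
```

This vignette documents the models, conventions and design choices behind
the package: what each stage assumes, which knobs matter, what the
synthetic generator does and does not emulate, and the numerical edge
cases. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The data and the barcode window

The unit of observation is one mitochondrial COI sequence per individual
insect. All analyses run on a 434-nt fragment of the gene. Coordinates
follow a 1-based, start-inclusive / end-exclusive convention, so the
window is `[341, 775)`: 775 − 341 = 434, which is the only reading of the
stated bounds consistent with the fragment length, and the one
`windowTrim()` implements. Whether those bounds are gene or amplicon
coordinates is immaterial here because the packaged fixture carries the
434-nt fragment directly.

Characters other than `A/C/G/T` (alignment gaps, `N`, IUPAC ambiguity
codes) are treated as *missing* for distance computation and QC, but kept
ambiguity-aware for primer matching. QC (`qcFilter()`) discards a record
iff it misses more than five nucleotides at the beginning or at the end of
the window; records with up to five terminal missing sites are retained
and handled downstream by pairwise deletion.

## Haplotypes

`collapseHaplotypes()` partitions records by exact string identity
(default `missingPolicy = "strict"`), matching the practice of collapsing
full consensus sequences. The `"merge"` policy joins a record to the first
existing haplotype with which it agrees at every mutually resolved site;
because that compatibility relation is not transitive, merging is
first-match in input order, which is deterministic but order-dependent —
the reason it is not the default.

`nameHaplotypes()` names shared haplotypes `H1..Hm` by descending count
(ties by first occurrence) and singletons `HU(m+1)..HUn`. Whether the
historical numbering of the published panel reflects frequency or
discovery order is not documented anywhere we could verify, so the generic
namer uses frequency order and the packaged fixture simply carries the
published names verbatim.

`variableSites()` returns exactly the alignment columns with two or more
states among haplotypes, in the conventional dot notation relative to a
reference haplotype; `reconstructHaplotypes()` inverts it, laying the
listed states over a seeded invariant background. Since every haplotype
shares the background, pairwise differences are exactly the differences
among listed states, independent of the background seed.

## Distance models

All distances are numbers of base substitutions per site, computed per
pair over the mutually resolved sites (pairwise deletion; `"complete"`
deletion is available). With `p` the proportion of differing sites,
`P1`/`P2` the purine/pyrimidine transition proportions and `Q` the
transversion proportion:

- **p**: `p` itself; a metric on fully resolved sequences.
- **JC69**: `−(3/4) ln(1 − 4p/3)`, undefined (error) at `p ≥ 3/4`.
- **K2P**: `−(1/2) ln((1 − 2P − Q) √(1 − 2Q))`.
- **MCL**: a composite-likelihood-style estimator in Tamura–Nei form,
  using the empirical base frequencies of the two sequences over their
  compared sites. The exact internals of the original software's
  "Maximum Composite Likelihood" distances are not published at
  implementation granularity; the TN93 form with pair-specific frequencies
  shares its structure (separate purine/pyrimidine transition terms,
  frequency weighting), converges to `p` as `p → 0`, and stays within a
  few percent of JC69 at the ≤ 0.05 divergences that occur within the
  species. The study-scale tolerance (±0.002 absolute on mean distances)
  absorbs the residual difference.

Degenerate compositions are handled by dropping terms whose frequency
coefficient is zero (their substitution counts are necessarily zero too);
log arguments ≤ 0 raise an error rather than returning a clipped value.
A pair with no mutually resolved site is an error, as is diversity of an
n = 1 sample (undefined, not zero).

Nei within-sample diversity is the mean distance over all unordered
pairs; between-sample distance is the mean over all cross pairs. Both
collapse duplicate sequences first and weight by multiplicities — an
exact rewrite that makes population-scale permutation tests cheap. Note
the self-consistency relation: for a sample compared with itself the
cross-pair mean includes the n zero self-pairs, so within-diversity
equals the self-cross mean times n/(n−1).

## Neighbor-Joining and lineage groups

`neighborJoining()` is the standard Saitou–Nei agglomeration: join the
pair minimising `Q(i,j) = (n−2) d(i,j) − r(i) − r(j)`, with ties broken
by the lowest (row, column) index pair so trees are bit-reproducible.
Negative branch lengths — an artefact NJ can produce on non-additive
input — are clamped to zero by default for presentation parity with
mainstream software; `clampNegative = FALSE` retains them (the additive
tree-recovery property tests run unclamped). On distances derived from
any additive tree, NJ reproduces that tree exactly; the suite verifies
this on random trees up to 12 taxa and checks topological agreement with
an independent implementation on non-additive matrices.

Lineage groups are assigned by explicit anchoring rather than automatic
two-clustering, because the groups are defined by reference to haplotypes
of known reproductive mode. Each group's clade is the smallest rooted
clade containing all of its anchor leaves; a clade that swallows another
group's anchors is an error with a diagnostic, and leaves outside every
anchor clade are `ungrouped`. Anchor sets of two or more spread members
are advisable — a single anchor defines only its own leaf.

One finding worth recording: on distances reconstructed from the
published variable-site table, group 2 is a clean 34-tip clade, but
group 1 is *not* monophyletic — the H6/H7/H34/H35/HU48 subcluster is
closer to group 2 (H7 differs from H28 at 4 sites versus 12 from H1).
The published tree figure places that subcluster in group 1; that
placement is not recoverable from the printed polymorphic sites alone,
so the package's fixture carries the published group column as
annotation, and tree-based tests assert only what the printed data
support (group 2 monophyly, H28 in group 2, HU58 in neither group).

## Reproductive-mode typing

The assay uses one universal reverse primer (TCOR) and two forward
primers: TCOC amplifies a 451-nt product from thelytokous mitotypes and
TCOS a 261-nt product from arrhenotokous mitotypes; both products
together indicate heteroplasmy (two mitotypes in one individual).
`matchPrimer()` is IUPAC-aware (a primer code matches a template base iff
the base belongs to the code's set) and `inSilicoPCR()` reports product
lengths measured 5'-of-forward through 5'-of-reverse inclusive — the
gel-observed length including both primer footprints. Mode-specific
primers default to zero mismatches, since exact specificity is the
assay's point; `classifyAmplicons(tol = 3)` offers a gel-resolution
tolerance, off by default in tests.

`callMode()` maps `{451} → thelytokous`, `{261} → arrhenotokous`,
`{451, 261} → heteroplasmic` and `{} → undetermined`; heteroplasmic calls
resolve through the phylogenetic group (group 1 → thelytokous, group 2 →
arrhenotokous) and stay undetermined for ungrouped haplotypes.
Heteroplasmy is a property of an individual's mitochondrial population,
so the package models each individual as a *set* of assay templates (two
mitotypes iff heteroplasmic).

## Geostatistics

Geographic distances are haversine great circles on a sphere of mean
radius 6371.0088 km — the differences from any particular GIS
implementation are negligible against between-location distances of
hundreds to thousands of km. Repeated samplings of one location are
separate populations at geographic distance zero.

The Mantel statistic is the Pearson correlation over upper-triangle
entries, with the null built by jointly permuting rows and columns of one
matrix. The p-value uses the +1/+1 rule (observed statistic counted as an
exceedance), which avoids p = 0. Whether the classical implementations
report one- or two-sided p-values is ambiguous, so both are offered;
two-sided on |r| is the default, and a seed is a required argument of
every permutation routine. The suite calibrates the test empirically:
nominal type-I error over 200 null simulations and ≥ 90% power under the
generator's isolation-by-distance setting.

Mode homogeneity across L locations uses the Pearson chi-square on the
2 × L table of thelytokous/arrhenotokous counts (no continuity
correction, df = L − 1, expected counts from margins, via
`stats::chisq.test`). Individuals with an undetermined resolved mode are
excluded before tabulation, so N counts only mode-resolved individuals;
zero-total locations are dropped with a warning.

The sampling-design helper is the closed form `1 − (1 − f)^n`: 33
individuals detect any haplotype at frequency 0.1 with probability
1 − 0.9³³ ≈ 0.969, and 29 is the smallest n reaching 95%.

## Species assignment

Queries take the species of their nearest reference iff the distance is
at most 0.05 — the observed within-species ceiling for thrips COI —
while distances of 0.15 and beyond fall in the between-species range
(~0.19–0.20 observed); the interval between is reported as the barcode
*gap*. The original workflow used database homology search with no
explicit numeric cutoff; the defaults encode its reported empirical gap
and are configurable. Ties on best distance keep the first reference in
panel order, with a warning.

## The synthetic generator

`simConfig()`/`simulateThrips()` emulate the study design the analysis
assumes; the defaults are the study conditions, not tuning knobs:

- 14 locations, 33 individuals each with a single 16 (the one
  under-sampled collection in the design);
- two lineage cores differing at 13 of 434 sites (the fixed difference
  count between the two published group cores, obtained by counting);
- AT-rich background (70% AT), resembling insect mitochondrial DNA —
  documented because composite-likelihood distances depend weakly on
  composition;
- sparse private mutations, per-site rate 0.0015 per individual (≈ 0.65
  expected mutations per barcode), chosen to give the within-group
  haplotype sprawl of one to a few substitutions that field panels show;
- per-location mode compositions drawn from four archetypes (pure
  thelytokous through arrhenotoky-dominated sympatry) allotted 5:4:3:2
  across locations, so heteroplasmy occurs only where the lineages are
  sympatric;
- panmictic geography by default (seeded worldwide coordinates unrelated
  to genetics); `isolation_by_distance` instead builds a single-lineage
  cline along an equatorial transect (~333 km per step, `ibdStep`
  mutations accumulated per step), giving genetic distance linear in
  geographic distance;
- optionally, interspecific contaminants diverged ~19% from the ingroup.

Assay templates embed the barcode-independent mode-assay region: the
thelytokous 451-nt fragment and arrhenotokous 261-nt fragment share their
reverse-primer end, and the thelytokous fragment carries the arrhenotoky
primer site *corrupted by a T insertion at fragment position 212* (the
site overlap begins at position 191), so a pure thelytokous template can
never yield the 261-nt product. The original primer coordinates lie on
the full COI gene and cannot be placed exactly within the 434-nt barcode
window, so templates are built as pad + fragment + pad with documented
offsets rather than inside the barcode.

What the generator does *not* emulate: coalescent genealogies, selection,
migration dynamics, recombination between heteroplasmic mitotypes,
sequencing error and chromatogram artefacts. Passing tests therefore
demonstrate correctness of the estimators and callers under idealised
two-lineage structure, not robustness to real-data noise.

## Problem sizes and determinism

The test suite runs everything at desk scale: the 58-haplotype fixture
for the published constants; random trees ≤ 12 taxa (100 replicates) for
NJ; 50 random alignments for the distance oracle; 200 null and 100
isolation-by-distance simulations (199 permutations each) for Mantel
calibration; 500 simulated individuals for mode-typing recovery; 50
populations of 20 for diversity-estimator recovery. Every stochastic
routine takes an explicit seed, simulations are pure functions of their
config seed, and reports rerun bit-identically for a fixed seed.

## Known limitations

- The `merge` missing-data policy is order-dependent (documented above).
- `MCL` is a frequency-aware approximation, not a reimplementation of any
  specific software's composite-likelihood distance; agreement is to the
  study-scale tolerance, not to machine precision.
- Group assignment requires sensible anchors; it does not discover groups
  de novo.
- The fixture's per-location compositions include only those printed in
  the main text (Tulancingo de Bravo, Huron); the remaining populations'
  compositions were published as supplementary material only and are
  flagged unavailable rather than invented, so location-resolved
  statistics of the original study (its chi-square and Mantel values) are
  exercised at study scale on generated worlds instead.
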