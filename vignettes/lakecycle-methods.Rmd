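---
title: "Methods and design of lakecycle"
author: "lakecycle authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of lakecycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakecycle)
```

`lakecycle` analyses depth-discrete, genome-resolved metagenomes from
stratified lakes: which organisms are where along the redox gradient, and
what carbon, nitrogen and sulfur transformations they could catalyse. This
vignette explains each method, the parameters that matter, the numerical
choices made where conventions diverge, and what the synthetic-data tests
do and do not demonstrate.

## Genome quality selection

MAGs enter the pipeline with externally estimated completeness and
contamination (a CheckM-style sidecar table); the package never recomputes
them. Selection applies the MIMAG medium-quality rule exactly as commonly
phrased: completeness **≥ 50%** (inclusive) and contamination **< 10%**
(strict). Genomes with unknown quality are excluded with a warning — an
unknown value never defaults to a passing one, because a permissive default
would silently admit junk bins. The filter is idempotent and
order-independent, and both thresholds are arguments.

## Sketch-based ANI

Alignment-based ANI is accurate but quadratic and heavy; a MinHash bottom
sketch gives a well-characterized estimator at interactive cost. Each
genome is reduced to the `sketchSize` (default 5000) smallest 64-bit hashes
of its canonical k-mers (default k = 21; the lexicographic minimum of each
k-mer and its reverse complement, so sketches are strand-invariant).
Ambiguity codes terminate k-mer runs: sketching is over ACGT only, the
community convention, while the letters still count toward genome size.
The hash function (splitmix64 with a fixed package seed) is a constant, not
a parameter — sketches must be mutually comparable and reproducible across
sessions.

For two sketches the Jaccard index $J$ is estimated from the merged bottom
sketch (the $s$ smallest hashes of the union), and converted via the Mash
distance
$$D = -\frac{1}{k}\ln\frac{2J}{1+J}, \qquad \widehat{ANI} = 100(1-D),$$
clamped to $[0,100]$. The estimator assumes approximately Poisson-placed
substitutions and unique k-mers; both hold well for 100 kb–5 Mb genomes
above ~90% identity. Below ~90% the Jaccard signal collapses, so estimates
under a **75% floor** (configurable) are reported as explicit below-floor
markers rather than numbers, and pairs with $J = 0$ likewise. In tests
against direct positional identity on 100-kb genomes the estimator is
within ±0.5 percentage points over the 95–100% range (typically ±0.2);
accuracy degrades below that range, which is why the floor exists.

## Dereplication

Replicated genomes across samples are collapsed greedily in one stage:
genomes are ranked by $\mathrm{score} = \mathrm{completeness} - 5 \times
\mathrm{contamination}$ (the familiar dRep-style default; weights are
arguments), the best unassigned genome founds a cluster and becomes its
representative, and every unassigned genome with ANI ≥ 99% (default) to
that representative joins. Ties break deterministically by larger genome
size, then lexicographic id, so runs are reproducible. A single-stage
single-threshold design was chosen over two-stage schemes because it is
auditable and its one knob is explicit; the soundness properties (members
within threshold of their representative; founders mutually below it in
founding order) are tested against a brute-force checker.

## Relative read abundance (RAR)

Coverage tables carry per-scaffold, per-sample mean fold coverage plus
scaffold lengths and the scaffold-to-genome map from binning. Two
genome-level aggregations are provided:

- `"sum"` (default): the sum of per-scaffold mean coverages per MAG — the
  convention when mapping tables are combined by MAG identifier. It is
  scaffold-count sensitive: splitting a genome into more scaffolds inflates
  the sum.
- `"length_weighted"`: $\sum_i c_i \ell_i / \sum_i \ell_i$ — the unbiased
  genome-wide depth estimate. Recovery tests use this mode, since it is the
  one with an exact relationship to true genome abundance.

Values are then divided by each sample's **total read count** (the
per-metagenome normalization; whether that count is raw, quality-filtered
or mapped reads is a property of the input table the user must document —
the package treats it as opaque), and converted to percentages of the
per-sample sum over MAGs. The denominator is MAG-relative: unbinned
community mass is excluded, so columns sum to 100 by construction and all
percentages are shares *of the recovered genomes*, not of the whole
community. A detection floor (default: genome-level coverage < 0.01× is
zeroed, configurable, 0 disables) suppresses sub-read-level mapping noise;
exact-recovery checks disable it, as any floor is a deliberate distortion
of tiny true abundances.

## Metabolic capability calls

Reaction definitions are YAML configuration: each reaction has a cycle, a
substrate/product with oxidation states, and logic given as AND-of-OR
groups over HMM model ids. A genome is scored 1 for a reaction iff **every**
group has at least one hit meeting its model's bit-score cutoff — one copy
of each representative gene suffices; extra copies change nothing. Cutoffs
default to per-model trusted cutoffs from the definition file, with a
global floor (default 50 bits) for models without one; a referenced model
with no resolvable cutoff is an error rather than a silent pass.

The shipped `pathways.yml` covers the classic water-column reactions of the
three cycles (organic carbon oxidation through methanogenesis and
methanotrophy; fixation through the denitrification ladder, DNRA, anammox
and comammox; the sulfur oxidation/reduction pairs and thiosulfate
disproportionation) with METABOLIC-style marker names. These gene sets are
explicitly configuration, not code: marker choice is a scientific decision
the file makes visible and editable. Comammox is intentionally the
conjunction of the ammonia- and nitrite-oxidation gene sets — it arises
whenever one genome carries both.

Manual curations are expressed as an override table: `relabel` rewrites a
hit's model id (e.g. an amoA call reassigned to pmoA) and re-evaluates the
affected reactions; `force_present`/`force_absent` set cells directly.
Every change is logged with its reason, so curation is reviewable. CAZyme
profiles count hits per CAZy class and normalize by genome size (hits per
Mbp), making small- and large-genome heterotrophs comparable.

## Depth zones and reaction profiles

Samples are classified oxic / sub-oxic / anoxic purely by depth bounds
(defaults 50 m and 120 m), reflecting a steep oxycline with oxygen
saturation reaching zero near 100 m in the system this models. The bounds
are configuration because oxyclines move; no printed rule ties them to
fixed depths. Reaction profiles report, per reaction, the number of capable
genomes **over the whole dereplicated set** (a global count) and the summed
RAR of capable genomes per sample; since genome counts and abundances
answer different questions, a per-sample detected-genome count is also
emitted. No detection threshold is applied before RAR summation by default.
Taxon-level tables mark a reaction present in a taxon iff any member genome
has it.

## Marker supermatrices

Multi-copy resolution follows two rules: candidates occupying disjoint
alignment-column ranges are fragments of a split gene and are merged
column-wise; overlapping candidates keep the copy covering the most
non-gap columns. "Disjoint" tolerates an overlap of up to 10% of the
smaller fragment's non-gap length (configurable) — real fragment ends are
ragged, so exact disjointness would almost never trigger the merge rule.
Gap masking removes columns whose gap fraction exceeds the threshold
(default 0.5). A 0.9 threshold under this semantics is permissive; because
"90% masking" is also sometimes read as "keep ≥90% occupancy" (stringent),
both semantics are selectable, with gap-fraction the default.
Concatenation pads genomes missing a marker with gaps, drops genomes with
fewer than `minMarkers` markers (default 8 of 16 — no printed convention
exists, so half the marker set is used and logged), and emits 1-based
inclusive partitions that tile the matrix exactly; splitting by partitions
recovers every masked alignment. Alignment computation and tree inference
are out of scope: the package reads and writes aligned FASTA and
RAxML-style partition files.

## The synthetic community generator

The generator exists so every stage can be validated against known truth
without downloads. Defaults emulate a depth-stratified tropical lake cast
at desk scale: **50 genomes** over **8 samples at 0, 10, 50, 80, 120, 150,
600 and 1200 m**, with five planted 3-member ANI clusters (pairwise
within-cluster identity 99.5%; unrelated genomes share essentially no
k-mers) and genome lengths drawn from 100–500 kb. The length range is a
deliberate scale-down — study-scale 1–5 Mb genomes are reachable through
`genome_length_range` and change nothing structurally, but small genomes
keep the default test suite fast while leaving thousands of k-mers per
sketch, far above the sketch size.

Each genome receives a Gaussian depth niche: abundance at depth $d$ is
proportional to $b_g\exp(-(d-\mu_g)^2/2\sigma_g^2)$ with log-normal
baseline $b_g$, renormalized per sample. Surface-guild genomes
($\mu_g \le 60$ m) carry CO2 fixation and organic carbon oxidation;
deep-guild genomes ($\mu_g \ge 500$ m) carry methanogenesis, sulfite
reduction and anammox; generalists span the column. Background reactions
are added at random, excluding the guild markers, so guild contrasts stay
interpretable. Scaffold coverage is abundance × a per-sample
sequencing-depth factor × multiplicative Gaussian noise truncated at 0
(read-level simulation would cost much and test no additional code path,
since the pipeline consumes coverage tables). Hit tables contain one
above-cutoff hit per required gene of each planted reaction plus Poisson
decoy hits at half the cutoff, exercising the threshold logic; marker
alignments include configured fractions of split copies, shorter duplicate
copies and gap columns. Function truth is computed by the generator's own
closure over the planted gene sets, independent of the pathway engine, so
comparisons between the two remain a genuine dual route.

What passing these tests shows: the estimators and rules are implemented
correctly and invert the generative model exactly at zero noise. What they
do not show: robustness to real-data pathologies the generator omits —
uneven within-genome coverage, chimeric bins, homologous gene transfer
between lineages, HMM scores near the cutoff, alignment error. Results on
real tables inherit the quality of the upstream mapping and annotation.

## Numerical and testing choices

- Coverage values round-trip through text at full precision (`%.17g`);
  zero-noise recovery checks pass at $10^{-9}$ absolute error on the
  percent scale.
- RAR conservation is asserted at $10^{-6}$ per column; taxon aggregation
  preserves sums to floating-point reordering error.
- All-zero abundance columns remain zero (with a warning) instead of
  producing NaN.
- The test suite and the acceptance script run on communities of 16–50
  genomes of 40–500 kb over 3–8 depths; these sizes were chosen as the
  smallest that exercise every code path (multi-member clusters, all three
  guilds and zones, split/duplicate markers) with comfortable margins.
- Randomized property tests fix their seeds; the generator guarantees
  byte-identical output files for identical (config, seed).

## Known limitations

Sketch ANI is unreliable below ~90% identity and unusable below the 75%
floor; cross-lake comparisons of distant pairs should treat below-floor
markers as "unrelated", not as numbers. Greedy single-threshold
dereplication can split a chain of genomes that pairwise straddle the
threshold (any single-linkage-style alternative has the converse problem);
the threshold is exposed rather than hidden. Capability is potential, not
activity — presence of a pathway's genes says nothing about expression.
The RAR denominator excludes unbinned community mass, so percentages are
relative to the genome catalogue, and total read counts are whatever the
input metadata says they are.
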