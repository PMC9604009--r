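---
title: "Methods: detecting shared vaginal strains and dating their divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting shared vaginal strains and dating their divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`strainshare` asks two nested questions about mother-daughter (or any
household) pairs: do their vaginal microbial *communities* look alike, and
do they carry the same bacterial *strains*? The first is answered on 16S
phylotype profiles, the second on genome-resolved metagenomes. This
vignette documents the models behind each stage, the parameters that
matter, the design choices made where the methodology was genuinely open,
and what the synthetic-data validation does and does not demonstrate.

## 1. Compositional similarity and the permutation null

Profiles are wide tables (one row per sample, one numeric column per
phylotype) with `sample_id`, `family_id`, `role`, `age` metadata columns.
Two filters mirror standard amplicon practice:

* `filter_samples(min_reads = 500)` — samples with *fewer than* 500 reads
  are dropped; a sample with exactly 500 is kept. It refuses
  relative-abundance input, because a read-count filter on proportions is
  meaningless.
* `filter_phylotypes(min_mean_relabund = 1e-4)` — phylotypes whose
  study-wide mean relative abundance is *strictly below* 1e-4 are removed
  and rows are renormalised, so downstream similarity always sees
  compositions summing to 1 (± 1e-9).

Similarity is the Yue-Clayton θ. Its useful properties — symmetry, range
[0, 1], θ = 1 exactly on identical compositions, θ = 0 on disjoint support
— are verified in the tests against an independently coded brute-force
evaluation on random simplex vectors.

The permutation test shuffles at the *sample* level: mother profiles are
permuted among mother samples and daughter profiles among daughter samples,
so roles are preserved while the family pairing is broken (a
daughters-only shuffle is available via `shuffle = "daughters"`). Pair θ
values are binned into half-open width-0.1 bins with the final bin closed,
so θ = 1 is counted. Per bin we report the null mean, the 2.5% and 97.5%
null quantiles, and an empirical one-sided p-value:

> p = (number of permutations whose count is as or more extreme than the
> observed count, in the direction of the observed deviation from the null
> mean) / n_perm,

with p = 1 when the observed count equals the null mean, and an optional
`plus_one` correction giving (count + 1) / (n_perm + 1).

**Calibration.** Because the direction is chosen *after* seeing the
deviation, this p-value behaves like the smaller of two one-sided
p-values: its per-bin size at level α is bounded by 2α, not α. The test
suite therefore checks calibration two ways: (a) randomized upper-tail
p-values — `P(null > obs) + U · P(null = obs)`, the standard construction
for discrete statistics — are uniform (Kolmogorov-Smirnov, α = 0.01,
200 simulated exchangeable-null cohorts), and (b) the pooled fraction of
bins with p < 0.05 under the null stays below the 2α = 0.10 bound. Users
comparing against a fixed α should keep the doubling in mind or use the
`plus_one` estimate.

**CST labels.** Community state types are assigned with a deliberately
simple dominance heuristic: I, II, III or V when *L. crispatus*,
*L. gasseri*, *L. iners* or *L. jensenii* respectively exceeds 50% relative
abundance (strict), IV otherwise. This is a documented stand-in for
nearest-centroid classifiers, which require external reference centroids;
the 50% cutoff is our choice and only affects labelling, never θ or the
permutation machinery.

## 2. Synthetic cohorts

`gen_profile_table(cohort_design(...))` emulates a metropolitan
mother-daughter cohort. Each family's mother draws a community state
archetype from `cst_weights` (default: III and IV most common, as in
cohorts of reproductive-age Black American women), then a family-level
base composition from a Dirichlet centred on the archetype with
concentration `concentration_archetype` (default 5). A mother-daughter
pair is flagged *sharing* with probability `sharing_probability`
(default 0.3, matching roughly a quarter to a third of families sharing
strains); sharing daughters draw their profile around the *same* family
base with concentration `concentration_member` (default 200), non-sharing
daughters draw their own archetype and base. Counts are multinomial at
log-normal depths (median ≈ 15,000 reads, spread wide enough that an
occasional sample fails the 500-read filter). Random streams are split per
family, so enlarging a cohort never changes the draws of earlier families.

With these defaults the pair-θ distribution is strongly bimodal — most
pairs below 0.1 or above 0.9 — with a cohort mean around 0.35-0.45. Real
cohorts report mean mother-daughter θ near 0.3 *without* an excess over
chance; the synthetic mean sits a little higher because the generator
couples compositional and strain sharing by design (sharing pairs are
compositionally correlated), which real pairs need not be. Passing tests on
these cohorts therefore demonstrates the machinery's correctness and
calibration, not that real mother-daughter pairs are compositionally
coupled.

The generator does **not** model read-level sequencing error, PCR/primer
bias, chimeras, plasmids or horizontal transfer.

## 3. Genome pairs, contigs, and markers

`evolve_pair(L, mu, t_years, seed)` models vertical transmission at birth:
one ancestral genome, then two lineages each accumulating a
Poisson(μ·L·t) number of substitutions at uniform positions, each to a
uniformly chosen different base. Positions are sampled with replacement,
so multiple hits and coincident hits occur at their natural O((μt)²) rate
and are left uncorrected — at the regimes used here (μt ≤ 2.5e-3 per site)
the bias is below 0.2%. There are no indels: the downstream SNP metric
counts substitutions only. The realised differences between the two
derived genomes are recorded as ground truth.

`fragment_genome()` tiles a genome into non-overlapping contigs (random
lengths above `min_len`) and assigns coverages from either a constant
model or a `two_strain` mixture (two depths, log-normal jitter) whose true
strain of origin is recorded — the planted truth for bin-splitting tests.
`plant_markers()` places `m` non-overlapping single-copy marker intervals;
dropping a contig removes its markers, duplicating one duplicates them,
giving exact completeness and contamination truth.

## 4. Binning and MAG quality

Reference-guided binning keeps contigs with mean coverage ≥ 5× and
annotation purity ≥ 0.90 (both inclusive — "at least"), groups them by
taxon, and sends everything else to an explicit `unbinned` sink so the
result is always a partition. Purity is interpreted as the *read* fraction
agreeing with the contig's taxon (supplied in the annotation table; the
package never re-maps reads).

Species bins are split into MAGs by 1-D gap clustering on log2 coverage:
contigs are sorted by log2(mean coverage) and a cut is placed at every
adjacent gap larger than `log2_gap` (default 1.0, i.e. a 2-fold depth
difference). This is the simplest deterministic, auditable reading of
"split by coverage differences"; the threshold is exposed in the
configuration. Clusters shorter than `min_mag_length` (default 50 kb,
scaled to the synthetic genomes) return to the sink rather than posing as
MAGs. Splitting an already-uniform bin is the identity.

Quality is assessed against planted markers: completeness is the
percentage of markers present at least once, contamination the percentage
of extra copies. MAGs are kept at completeness ≥ 80% and contamination
**strictly below** 5% — the boundary is asymmetric on purpose, following
the usual "at least 80% complete, less than 5% contaminated" convention.
Real-data users can substitute their own marker table in the same
interval schema.

## 5. Strain comparison and sharing calls

`anchor_align()` is a desk-scale, deterministic substitute for read-mapping
pipelines: k-mers (k = 31) unique in each genome and shared between them
become anchors; the longest chain strictly increasing in both coordinates
is kept (O(n log n), leftmost-lowest tie-break); same-diagonal anchors are
merged when the intervening region has ≤ 10% mismatches; blocks are
extended outwards until more than 10 mismatches fall in a trailing 100-bp
window, then trimmed to the last matching base; finally blocks are trimmed
to be non-overlapping in both sequences (earlier block wins).

`compare_genomes()` summarises: SNPs are mismatches inside aligned blocks;
coverage overlap is aligned bp over the *shorter* genome's length (a
documented simplification — read-based tools use positions with sufficient
depth, which is unavailable without reads); identity is
1 − SNPs/compared bp; density is reported per Mbp. Identity is
consensus-level (one allele per genome); on clonal synthetic strains this
coincides with population-level identity. An empty alignment is recorded
as *not comparable* (identity NA), never as identity 0.

A pair is a **shared strain** when overlap ≥ 0.70 and identity ≥ 0.999,
both inclusive. The geometry links the thresholds to divergence time:
a pair is callable while realised divergence 2μt stays below 1e-3, so at
μ = 1e-5/site/yr calls flip around t ≈ 50 yr. `all_vs_all()` evaluates
every participant pair over same-species MAG pairs and reports the squared
participant count as the profile tally; self-comparisons never produce
sharing calls. Ward-linkage cluster summarisation of read-profile sets is
out of scope: the preserved contract is the (overlap, identity) pair per
comparison.

## 6. Network and rates

Each sharing call is one edge (parallel edges preserved — pairs can share
several species). Edges are classified from node metadata alone into
within-family mother-daughter, between-family mother-daughter,
mother-mother, and daughter-daughter; sisters sharing a strain get their
own `within_family_DD` class rather than being forced into a four-class
scheme. Counts always partition the edge total, and the number of
*distinct* within-family pairs is reported separately.

For within-family calls, the substitution rate is SNP density divided by
twice the daughter's age (`total_branch`, the default): both populations
accumulate substitutions after transmission, so the separating branch
length is 2t. Published tables of such rates cannot disambiguate this
factor because the underlying SNP densities are rarely printed;
`single_branch` (divide by t) is selectable to reproduce the other
reading. Group contrasts use `stats::wilcox.test` (two-sided, ties
mid-ranked, exact for small tie-free samples) for SNP densities and a
pooled-variance two-sample t-test (Welch by flag) for daughter ages; an
exhaustive-enumeration oracle in the tests confirms the rank-sum statistic
and p-value for all group sizes up to 6.

## 7. Pipeline, determinism, and problem sizes

`pipeline_config()` is the single source of truth for every threshold
(defaults above); it validates domains, round-trips losslessly through
YAML, and hashes into the output manifest. `run_pipeline()` chains
simulate → profiles → binning → comparison → network → rates, writes
CSV/TSV/JSON/GraphML artifacts, and aborts with the stage name on any
failure. Every random draw derives from the master seed via fixed integer
splits, so reruns are byte-identical.

Validation problem sizes were chosen to make Monte-Carlo noise small
relative to the tested tolerances while keeping the suite quick: 1 Mb
genomes × 100 replicates for substitution-rate recovery (worst-cell
relative standard error ≈ 3%, tested band 5%), 100-300 kb genomes for
alignment and split-recovery checks, 15-20-family cohorts × 50-200
replicates for permutation calibration, and 1000 random simplex vectors
for the θ oracle. The demo pipeline runs 20 families with 100 kb genomes.

## 8. Known limitations

* The aligner is substitution-oriented: indels, rearrangements and repeats
  beyond unique-k-mer anchoring are out of scope (a deletion appears as
  two blocks on different diagonals, not as a gapped alignment).
* Coverage overlap uses the shorter-genome denominator; with very
  incomplete MAGs this can overstate overlap relative to depth-aware
  definitions.
* The CST heuristic is not a nearest-centroid classifier; labels near the
  50% boundary are unstable by construction.
* Synthetic cohorts validate correctness and calibration, not ecological
  realism: real profiles have hundreds of phylotypes, within-CST structure
  the Dirichlet does not capture, and compositional similarity that is not
  coupled to strain sharing.
* Completeness/contamination against planted markers emulate, but are not,
  lineage-specific marker-gene estimates.
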