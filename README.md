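# strainshare

Do mothers and their daughters carry the same vaginal bacteria?
`strainshare` implements the full inference chain for answering that
question from microbiome data: compositional similarity of 16S phylotype
profiles with a permutation null, reference-guided binning of metagenomic
contigs into metagenome-assembled genomes (MAGs), genome-wide strain
comparison with stringent sharing thresholds, classification of the
resulting sharing network by family relationship, and substitution-rate
estimation under the hypothesis of vertical transmission at birth. Because
raw sequence data for such cohorts is rarely shareable, the package ships a
first-class synthetic-data generator that produces cohorts and genome pairs
with known ground truth, so every stage is validated against planted truth.

It is aimed at microbial ecologists and bioinformaticians studying strain
transmission — mother–infant, household, or biogeographic — who want a
tested, desk-scale reference implementation of these methods.

## The statistics at the core

**Compositional similarity.** Two relative-abundance vectors *p*, *q* are
compared with the Yue–Clayton theta,

  θ = Σᵢ pᵢqᵢ / (Σᵢ pᵢ² + Σᵢ qᵢ² − Σᵢ pᵢqᵢ),

which is 1 for identical compositions and 0 for disjoint ones. Whether
mother–daughter pairs are more similar than chance is tested by shuffling
mother profiles among mothers and daughter profiles among daughters,
re-computing all pair θ values, and binning them in 0.1-wide bins: each bin
gets a null mean, 2.5%/97.5% null quantiles, and a one-sided empirical
p-value in the direction of the observed deviation.

**Strain sharing.** Genomes are aligned with a deterministic k-mer
anchor-chaining aligner; a pair of strains is *shared* when the coverage
overlap is at least 70% of the shorter genome and genome-wide identity is
at least 99.9% — stringent enough that remaining differences are consistent
with post-transmission divergence. Sharing calls become edges of a
participant network classified into within-family mother–daughter,
between-family mother–daughter, mother–mother and daughter–daughter edges.

**Substitution rate.** Under transmission at birth both populations evolve
independently for the daughter's lifetime, so with SNP density *d* (per bp)
and daughter age *t*, the per-site per-year rate is μ̂ = d / (2t).

## Worked example

```r
library(strainshare)
library(dplyr)

# simulate a mother-daughter cohort with known sharing truth
cohort <- gen_profile_table(cohort_design(n_families = 8, seed = 42))
rel <- cohort$profiles |> filter_samples() |> filter_phylotypes()
pair_similarities(rel)
#> # A tibble: 8 × 5
#>   family_id mother_sample daughter_sample  theta daughter_cst
#> 1 F01       F01M          F01D1           0.999  III
#> 2 F02       F02M          F02D1           0.999  V
#> 3 F03       F03M          F03D1           0.0695 I
#> 4 F04       F04M          F04D1           0.0206 II
#> # 4 more rows
```

Families 1 and 2 were simulated as truly sharing (θ ≈ 1); most others have
unrelated compositions. The permutation test summarises whether the
observed pairing beats chance:

```r
glance(permutation_test(rel, n_perm = 100, seed = 1))
#>   n_pairs n_perm bin_width n_bins min_p mean_theta
#> 1       8    100       0.1     10     0      0.533
```

Genome-level sharing, on a simulated mother-daughter strain pair
(100 kb, μ = 1e-5 per site per year, transmitted 15 years ago):

```r
lp  <- evolve_pair(1e5, mu = 1e-5, t_years = 15, seed = 7)
cmp <- compare_genomes(lp$genome_a, lp$genome_b)
cmp
#>   compared_bp coverage_overlap snp_count identity snp_density_per_mbp
#> 1       1e+05                1        27  0.99973                 270
call_shared(cmp)$shared                       # TRUE: >= 0.70 and >= 0.999
substitution_rate(cmp$snp_count / cmp$compared_bp, 15)
#> 9e-06    # recovers the simulated 1e-5 within Poisson noise
```

The bundled table of published mother-daughter shared-strain records
reproduces the reported rate range:

```r
s <- summarize_rates(mother_daughter_strains())
c(s$min_rate, s$max_rate)
#> 1.05e-06 3.24e-05
```

`run_pipeline(pipeline_config(seed = 1), "out/")` chains every stage —
simulate, filter, permutation test, bin, QC, compare, network, rates — and
writes TSV/JSON/GraphML artifacts plus a manifest with the seed, thresholds
and config hash; reruns are byte-identical.

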