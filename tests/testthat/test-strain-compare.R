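test_that("identical sequences align as one full-length block", {
  g <- random_genome(5000, seed = 1)
  bl <- anchor_align(g, g)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$start_a, 1)
  expect_equal(bl$start_b, 1)
  expect_equal(bl$length, 5000)
})

test_that("unrelated sequences share no anchors", {
  a <- random_genome(2000, seed = 2)
  b <- random_genome(2000, seed = 3)
  bl <- anchor_align(a, b)
  expect_equal(nrow(bl), 0)
  expect_equal(attr(bl, "total_aligned_bp"), 0L)
  expect_error(anchor_align("ACGT", "ACGT", k = 31), "k exceeds")
})

test_that("lineage pairs align nearly fully with consistent SNP counts", {
  lp <- evolve_pair(1e5, mu = 1e-5, t_years = 15, seed = 7)
  bl <- anchor_align(lp$genome_a, lp$genome_b)
  expect_gte(sum(bl$length) / lp$length, 0.99)
  cmp <- compare_genomes(lp$genome_a, lp$genome_b)
  # SNPs inside blocks match the brute-force Hamming diff restricted to
  # the aligned positions (here: full coordinates, substitutions only)
  truth <- length(lp$true_snp_positions)
  expect_lte(cmp$snp_count, truth)
  expect_gte(cmp$snp_count, truth - 2) # at most edge SNPs trimmed
})

test_that("translocated homologous segments still chain colinearly", {
  core <- random_genome(30000, seed = 9)
  a <- core
  # b: same content in two swapped halves is NOT colinear; instead test a
  # deletion: b lacks a middle segment, blocks must bridge around it
  b <- paste0(substring(core, 1, 12000), substring(core, 18001, 30000))
  bl <- anchor_align(a, b)
  expect_gte(sum(bl$length), 23000)
  # blocks do not overlap in either sequence
  o <- order(bl$start_a)
  expect_true(all(diff(bl$start_a[o]) > 0))
  expect_true(all(bl$start_a[o][-1] > (bl$start_a + bl$length - 1)[o][-nrow(bl)]))
  ob <- order(bl$start_b)
  expect_true(all(bl$start_b[ob][-1] > (bl$start_b + bl$length - 1)[ob][-nrow(bl)]))
})

test_that("comparison fields are symmetric and internally consistent", {
  lp <- evolve_pair(4e4, mu = 2e-5, t_years = 20, seed = 11)
  ab <- compare_genomes(lp$genome_a, lp$genome_b)
  ba <- compare_genomes(lp$genome_b, lp$genome_a)
  expect_equal(ab$snp_count, ba$snp_count)
  expect_equal(ab$compared_bp, ba$compared_bp)
  expect_equal(ab$coverage_overlap, ba$coverage_overlap)
  expect_equal(ab$identity, ba$identity)
  expect_equal(ab$snp_density_per_mbp,
               1e6 * (1 - ab$identity), tolerance = 1e-9)
})

test_that("identical genomes give identity 1, overlap 1, density 0", {
  g <- random_genome(5e4, seed = 13)
  cmp <- compare_genomes(g, g)
  expect_equal(cmp$identity, 1)
  expect_equal(cmp$coverage_overlap, 1)
  expect_equal(cmp$snp_density_per_mbp, 0)
})

test_that("unalignable pairs are flagged not comparable", {
  cmp <- compare_genomes(random_genome(2000, seed = 1),
                         random_genome(2000, seed = 99))
  expect_false(cmp$comparable)
  expect_true(is.na(cmp$identity))
  expect_equal(cmp$coverage_overlap, 0)
  calls <- call_shared(cmp)
  expect_false(calls$shared)
})

test_that("shared-strain thresholds are inclusive at 0.70 and 0.999", {
  mk <- function(overlap, identity) tibble::tibble(
    id_a = "x", id_b = "y", compared_bp = 1e5,
    coverage_overlap = overlap, snp_count = 0L, identity = identity,
    snp_density_per_mbp = 1e6 * (1 - identity), comparable = TRUE
  )
  expect_true(call_shared(mk(0.70, 0.9990))$shared)
  expect_false(call_shared(mk(0.69, 1.0))$shared)
  expect_false(call_shared(mk(1.0, 0.9989))$shared)
})

test_that("raising the identity threshold never adds shared calls", {
  cohort <- toy_strain_cohort(n_families = 3, k_shared = 2, L = 1e4,
                              seed = 55)
  res <- all_vs_all(cohort$mags)
  thresholds <- c(0.995, 0.999, 0.9999, 1)
  n_calls <- vapply(thresholds, function(th) {
    sum(call_shared(res$comparisons, min_identity = th)$shared)
  }, numeric(1))
  expect_true(all(diff(n_calls) <= 0))
})

test_that("all-vs-all reports squared profile counts and planted truth", {
  cohort <- toy_strain_cohort(n_families = 4, k_shared = 2, L = 2e4,
                              mu = 1e-5, age = 15, seed = 77)
  res <- all_vs_all(cohort$mags)
  expect_equal(res$n_profiles, 64) # 8 participants squared
  shared <- dplyr::filter(res$calls, shared)
  # exactly the two planted mother-daughter transmissions are recovered
  expect_equal(nrow(shared), 2)
  expect_setequal(
    paste(shared$participant_a, shared$participant_b),
    c("F01M F01D", "F02M F02D")
  )
})

test_that("participants with no species in common yield no comparisons", {
  mags <- tibble::tibble(
    participant_id = c("p1", "p2"),
    mag_id = c("m1", "m2"),
    taxon_label = c("A", "B"),
    sequence = c(random_genome(2000, seed = 1),
                 random_genome(2000, seed = 2))
  )
  res <- all_vs_all(mags)
  expect_equal(nrow(res$comparisons), 0)
  expect_equal(res$n_profiles, 4)
  expect_error(all_vs_all(mags[1, ]), "2 participants")
})
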