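contig_row <- function(id, cov, purity = 1, taxon = "A", len = 1000) {
  tibble::tibble(contig_id = id, mean_coverage = cov, taxon_label = taxon,
                 purity = purity, length = len,
                 sequence = strrep("A", len))
}

test_that("binning boundaries are inclusive at 5x coverage and 90% purity", {
  contigs <- dplyr::bind_rows(
    contig_row("c1", 4.9), contig_row("c2", 5.0),
    contig_row("c3", 10, purity = 0.89), contig_row("c4", 10, purity = 0.90),
    contig_row("c5", 10, taxon = "B"),
    contig_row("c6", 10, taxon = NA)
  )
  out <- filter_and_bin(contigs)
  expect_equal(out$bin, c("unbinned", "A", "unbinned", "A", "B", "unbinned"))
})

test_that("every contig ends in exactly one bin or the sink", {
  withr::with_seed(3, {
    contigs <- dplyr::bind_rows(lapply(1:50, function(i) {
      contig_row(paste0("c", i), runif(1, 0, 20), runif(1, 0.8, 1),
                 sample(c("A", "B", "C"), 1))
    }))
  })
  out <- filter_and_bin(contigs)
  expect_equal(nrow(out), 50)
  expect_false(any(is.na(out$bin)))
})

test_that("coverage splitting cuts at log2 gaps above the threshold", {
  contigs <- dplyr::bind_rows(purrr::map2(
    paste0("c", 1:6), c(10, 11, 12, 48, 50, 52),
    ~ contig_row(.x, .y, len = 30000)
  ))
  contigs$bin <- "A"
  # gap log2(48) - log2(12) = 2 > 1 splits; within-cluster gaps < 1 do not
  out <- split_bin_by_coverage(contigs, log2_gap = 1, min_mag_length = 5e4)
  mags <- unique(out$mag_id)
  expect_length(mags, 2)
  expect_equal(length(unique(out$mag_id[out$mean_coverage < 20])), 1)
})

test_that("uniform-coverage bins stay together and splitting is idempotent", {
  contigs <- dplyr::bind_rows(purrr::map(
    paste0("c", 1:5), ~ contig_row(.x, 20, len = 20000)
  ))
  contigs$bin <- "A"
  out <- split_bin_by_coverage(contigs, min_mag_length = 5e4)
  expect_length(unique(out$mag_id), 1)
  out2 <- split_bin_by_coverage(dplyr::select(out, -"mag_id"),
                                min_mag_length = 5e4)
  expect_equal(sort(out2$contig_id), sort(out$contig_id))
  expect_length(unique(out2$mag_id), 1)
})

test_that("short clusters fall back to the sink", {
  contigs <- dplyr::bind_rows(
    contig_row("c1", 10, len = 60000),
    contig_row("c2", 160, len = 2000) # isolated, too short for a MAG
  )
  contigs$bin <- "A"
  out <- split_bin_by_coverage(contigs, min_mag_length = 5e4)
  expect_false(is.na(out$mag_id[out$contig_id == "c1"]))
  expect_true(is.na(out$mag_id[out$contig_id == "c2"]))
})

test_that("planted two-strain mixtures are split by strain of origin", {
  g <- random_genome(2e5, seed = 31)
  ct <- fragment_genome(
    g, n_contigs = 40, min_len = 2000,
    coverage_model = list(type = "two_strain", depths = c(10, 50),
                          prob = 0.5, sd_log = 0.1),
    seed = 17
  )
  ct$bin <- ct$taxon_label
  out <- split_bin_by_coverage(ct, log2_gap = 1, min_mag_length = 1e4)
  # length-weighted assignment accuracy vs strain truth
  out$called <- as.integer(factor(out$mag_id))
  tab <- table(out$called, out$strain)
  # map each called MAG to its majority strain and count matching length
  correct <- sum(vapply(unique(out$called[!is.na(out$called)]), function(cl) {
    rows <- out[!is.na(out$called) & out$called == cl, ]
    maj <- as.integer(names(which.max(tapply(rows$length, rows$strain, sum))))
    sum(rows$length[rows$strain == maj])
  }, numeric(1)))
  acc <- correct / sum(out$length)
  expect_gte(acc, 0.95)
  expect_length(unique(stats::na.omit(out$mag_id)), 2)
})

test_that("marker-based quality arithmetic is exact", {
  g_len <- 50000
  mk <- plant_markers(g_len, m = 100, marker_len = 100, seed = 5)
  full <- tibble::tibble(start = 1, end = g_len, length = g_len)
  q <- assess_mag_quality(full, mk)
  expect_equal(q$completeness, 100)
  expect_equal(q$contamination, 0)

  # drop contigs covering 20 markers -> completeness 80
  keep <- mk[21:100, ]
  partial <- tibble::tibble(start = keep$start, end = keep$end)
  q2 <- assess_mag_quality(partial, mk)
  expect_equal(q2$completeness, 80)
  expect_equal(q2$contamination, 0)

  # duplicating contigs carrying 5 markers -> contamination 5
  dup <- dplyr::bind_rows(full, tibble::tibble(start = mk$start[1:5],
                                               end = mk$end[1:5]))
  q3 <- assess_mag_quality(dup, mk)
  expect_equal(q3$completeness, 100)
  expect_equal(q3$contamination, 5)

  expect_error(assess_mag_quality(full, mk[0, ]), "no markers")
})

test_that("MAG quality filter uses asymmetric boundaries", {
  mags <- tibble::tibble(
    mag_id = c("a", "b", "c", "d"),
    completeness = c(80.0, 79.9, 100, 95),
    contamination = c(4.9, 0, 5.0, 0)
  )
  out <- filter_mags(mags)
  expect_setequal(out$mag_id, c("a", "d")) # 80/4.9 kept; 79.9 and 5.0 dropped
})

test_that("MAG summaries report length-weighted coverage and abundance", {
  contigs <- dplyr::bind_rows(
    contig_row("c1", 10, len = 1000), contig_row("c2", 30, len = 3000),
    contig_row("c3", 50, len = 1000, taxon = "B")
  )
  contigs$bin <- contigs$taxon_label
  contigs$mag_id <- c("A_MAG1", "A_MAG1", NA)
  s <- summarize_mags(contigs)
  expect_equal(s$total_length, 4000)
  expect_equal(s$mean_coverage, (1000 * 10 + 3000 * 30) / 4000)
  expect_equal(s$relative_abundance,
               100 * (1000 * 10 + 3000 * 30) /
                 (1000 * 10 + 3000 * 30 + 1000 * 50))
})
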