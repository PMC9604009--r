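test_that("profile tables load, and malformed ones are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tiny_profile_table(), path)
  tbl <- load_profile_table(path)
  expect_equal(nrow(tbl), 4)
  expect_equal(tbl$Lactobacillus_crispatus[1], 800)

  dup <- tiny_profile_table()
  dup$sample_id[2] <- "F01M"
  readr::write_csv(dup, path)
  expect_error(load_profile_table(path), "F01M")

  writeLines("sample_id,family_id,role,age,taxon", path)
  expect_error(load_profile_table(path), "no samples")

  bad <- tiny_profile_table()
  bad$Lactobacillus_crispatus <- as.character(bad$Lactobacillus_crispatus)
  bad$Lactobacillus_crispatus[1] <- "many"
  readr::write_csv(bad, path)
  expect_error(load_profile_table(path), "non-numeric")
})

test_that("sample filter drops below-threshold samples, keeps the boundary", {
  tbl <- tiny_profile_table()
  # totals 499, 500, 501, 1000
  tbl[1, 5:7] <- list(299, 100, 100)
  tbl[2, 5:7] <- list(300, 100, 100)
  tbl[3, 5:7] <- list(301, 100, 100)
  out <- filter_samples(tbl, min_reads = 500)
  expect_setequal(out$sample_id, c("F01D1", "F02M", "F02D1"))

  expect_identical(filter_samples(tiny_profile_table()),
                   tiny_profile_table())

  expect_warning(empty <- filter_samples(tbl, min_reads = 1e6), "fewer than")
  expect_equal(nrow(empty), 0)

  rel <- tiny_profile_table()
  rel[, 5:7] <- rel[, 5:7] / rowSums(rel[, 5:7])
  expect_error(filter_samples(rel), "relative")
})

test_that("phylotype filter removes rare taxa and renormalises", {
  tbl <- tiny_profile_table()
  # craft exact study-wide mean relative abundances: every sample totals
  # 1000, so at_thresh has mean 4e-4/4 = 1e-4 and below has mean 9e-5
  tbl[, 5:7] <- list(c(1000, 1000, 1000, 1000), c(0, 0, 0, 0), c(0, 0, 0, 0))
  tbl$at_thresh <- c(0.4, 0, 0, 0)
  tbl$below <- c(0.36, 0, 0, 0)
  tbl$Lactobacillus_crispatus <- c(1000 - 0.76, 1000, 1000, 1000)
  out <- filter_phylotypes(tbl, min_mean_relabund = 1e-4)
  cols <- setdiff(names(out), c("sample_id", "family_id", "role", "age"))
  expect_true("at_thresh" %in% cols)
  expect_false("below" %in% cols)
  expect_false("Lactobacillus_iners" %in% cols) # all-zero taxon removed
  m <- as.matrix(out[, cols])
  expect_equal(unname(rowSums(m)), rep(1, 4), tolerance = 1e-9)
})

test_that("a single surviving phylotype normalises to 1", {
  tbl <- tiny_profile_table()[, 1:5]
  out <- filter_phylotypes(tbl)
  expect_equal(out$Lactobacillus_crispatus, rep(1, 4))
})

test_that("Yue-Clayton theta matches hand evaluation and the oracle", {
  expect_equal(yue_clayton_theta(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 1)
  expect_equal(yue_clayton_theta(c(1, 0), c(0, 1)), 0)
  expect_equal(yue_clayton_theta(c(0.5, 0.5, 0), c(0.5, 0, 0.5)), 1 / 3)
  expect_error(yue_clayton_theta(c(1, 0), c(1, 0, 0)), "length")
  expect_error(yue_clayton_theta(c(0, 0), c(1, 0)), "zero")

  withr::with_seed(11, {
    for (i in 1:50) {
      p <- random_simplex(8); q <- random_simplex(8)
      th <- yue_clayton_theta(p, q)
      expect_equal(th, theta_oracle(p, q))
      expect_equal(th, yue_clayton_theta(q, p))
      expect_true(th >= 0 && th <= 1)
    }
  })
})

test_that("heuristic CST labels follow strict 50% dominance", {
  p <- c(Lactobacillus_crispatus = 0.8, Lactobacillus_iners = 0.2)
  expect_equal(assign_cst(p), "I")
  q <- c(Gardnerella_vaginalis = 0.4, Prevotella_bivia = 0.3,
         Lactobacillus_iners = 0.3)
  expect_equal(assign_cst(q), "IV")
  r <- c(Lactobacillus_iners = 0.5, Gardnerella_vaginalis = 0.5)
  expect_equal(assign_cst(r), "IV") # exactly 50% is not dominance
  expect_equal(assign_cst(c(Lactobacillus_gasseri = 0.6,
                            Lactobacillus_iners = 0.4)), "II")
  expect_equal(assign_cst(c(Lactobacillus_jensenii = 0.51,
                            Lactobacillus_iners = 0.49)), "V")

  tbl <- assign_cst(tiny_profile_table())
  expect_equal(tbl$cst, c("I", "I", "IV", "IV"))
})

test_that("pair similarities produce one record per daughter", {
  tbl <- tiny_profile_table()
  extra <- tbl[2, ]
  extra$sample_id <- c("F01D2")
  tbl <- dplyr::bind_rows(tbl, extra,
                          dplyr::mutate(extra, sample_id = "F01D3"))
  sims <- pair_similarities(tbl)
  expect_equal(sum(sims$family_id == "F01"), 3)
  expect_equal(nrow(sims), 4)

  # identical mother/daughter profiles give theta 1
  same <- tiny_profile_table()
  same[2, 5:7] <- same[1, 5:7]
  sims2 <- pair_similarities(same)
  expect_equal(sims2$theta[sims2$family_id == "F01"], 1)

  empty <- tiny_profile_table()[0, ]
  expect_equal(nrow(pair_similarities(empty)), 0)

  # family without a mother is skipped with a warning
  nomom <- tiny_profile_table()[-1, ]
  expect_warning(sims3 <- pair_similarities(nomom), "F01")
  expect_equal(sims3$family_id, "F02")
})
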