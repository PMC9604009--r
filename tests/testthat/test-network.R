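toy_manifest <- function(n_fam = 3) {
  tibble::tibble(
    participant_id = c(rbind(sprintf("F%dM", 1:n_fam),
                             sprintf("F%dD", 1:n_fam))),
    family_id = rep(sprintf("F%d", 1:n_fam), each = 2),
    role = rep(c("mother", "daughter"), n_fam),
    age = rep(c(40, 16), n_fam)
  )
}

toy_call <- function(a, b, taxon = "L_crispatus", shared = TRUE) {
  tibble::tibble(participant_a = a, participant_b = b, taxon = taxon,
                 shared = shared)
}

test_that("an empty call set builds an edgeless graph over all nodes", {
  net <- build_network(toy_call(character(0), character(0)), toy_manifest())
  expect_equal(igraph::vcount(net), 6)
  expect_equal(igraph::ecount(net), 0)
  cls <- classify_and_count(net)
  expect_equal(cls$n_edges, 0L)
  expect_equal(cls$distinct_within_family_pairs, 0L)
})

test_that("edges are classified by family and role", {
  calls <- dplyr::bind_rows(
    toy_call("F1M", "F1D"),                    # within-family MD
    toy_call("F1M", "F2D"),                    # between-family MD
    toy_call("F1M", "F2M"),                    # between-family MM
    toy_call("F1D", "F3D"),                    # between-family DD
    toy_call("F2M", "F3M", taxon = "G_vaginalis")
  )
  net <- build_network(calls, toy_manifest())
  cls <- classify_and_count(net)
  counts <- setNames(cls$counts$n, cls$counts$edge_class)
  expect_equal(unname(counts["within_family_MD"]), 1)
  expect_equal(unname(counts["between_family_MD"]), 1)
  expect_equal(unname(counts["between_family_MM"]), 2)
  expect_equal(unname(counts["between_family_DD"]), 1)
  expect_equal(sum(cls$counts$n), cls$n_edges)
})

test_that("multi-edges are retained and distinct pairs deduplicated", {
  calls <- dplyr::bind_rows(
    toy_call("F1M", "F1D", taxon = "A"),
    toy_call("F1M", "F1D", taxon = "B"),
    toy_call("F1D", "F1M", taxon = "C"), # same pair, either orientation
    toy_call("F2M", "F2D", taxon = "A")
  )
  net <- build_network(calls, toy_manifest())
  cls <- classify_and_count(net)
  expect_equal(cls$n_edges, 4L)
  expect_equal(cls$distinct_within_family_pairs, 2L)
})

test_that("classification ignores edge insertion order", {
  calls <- dplyr::bind_rows(
    toy_call("F1M", "F1D"), toy_call("F1M", "F2M"), toy_call("F2D", "F3D")
  )
  withr::with_seed(8, {
    for (i in 1:5) {
      shuffled <- calls[sample.int(nrow(calls)), ]
      cls <- classify_and_count(build_network(shuffled, toy_manifest()))
      expect_equal(sort(cls$edges$edge_class),
                   c("between_family_DD", "between_family_MM",
                     "within_family_MD"))
    }
  })
})

test_that("unknown participants and self-calls are rejected", {
  expect_error(build_network(toy_call("F1M", "ghost"), toy_manifest()),
               "ghost")
  expect_error(build_network(toy_call("F1M", "F1M"), toy_manifest()),
               "self")
})

test_that("class counts conserve edge totals on random synthetic networks", {
  withr::with_seed(30, {
    for (rep in 1:10) {
      man <- toy_manifest(n_fam = 5)
      n_edges <- sample(1:15, 1)
      ends <- t(replicate(n_edges,
                          sample(man$participant_id, 2, replace = FALSE)))
      calls <- toy_call(ends[, 1], ends[, 2],
                        taxon = sample(letters[1:3], n_edges, replace = TRUE))
      cls <- classify_and_count(build_network(calls, man))
      expect_equal(sum(cls$counts$n), n_edges)
      expect_false(any(cls$edges$edge_class == "other"))
    }
  })
})

test_that("sister sharing gets its own within-family class", {
  man <- dplyr::bind_rows(
    toy_manifest(2),
    tibble::tibble(participant_id = "F1D2", family_id = "F1",
                   role = "daughter", age = 14)
  )
  cls <- classify_and_count(build_network(toy_call("F1D", "F1D2"), man))
  expect_equal(cls$counts$edge_class, "within_family_DD")
  expect_equal(cls$distinct_within_family_pairs, 0L)
})

test_that("network plotting and serialisation round-trip", {
  net <- build_network(toy_call("F1M", "F1D"), toy_manifest())
  expect_s3_class(autoplot(net), "ggplot")
  gml <- withr::local_tempfile(fileext = ".graphml")
  js <- withr::local_tempfile(fileext = ".json")
  write_network(net, gml, js)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), 6)
  expect_equal(igraph::ecount(g2), 1)
  nl <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(nl$nodes), 6)
  expect_equal(nl$links$taxon, "L_crispatus")
})
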