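#' Pipeline configuration
#'
#' Single source of truth for every stage threshold, with the published
#' printed values as defaults, plus the synthetic-cohort parameters used
#' when the pipeline simulates its own inputs.
#'
#' @param min_reads sample read-count filter (default 500).
#' @param min_mean_relabund study-wide mean relative-abundance filter
#'   (default 1e-4).
#' @param min_cov,min_purity contig binning filters (defaults 5x, 0.90).
#' @param min_completeness,max_contamination MAG quality filters in percent
#'   (defaults 80, 5; contamination boundary exclusive).
#' @param min_overlap,min_identity shared-strain thresholds (defaults 0.70,
#'   0.999).
#' @param n_perm permutations for the similarity test (default 100).
#' @param log2_gap coverage-gap threshold for MAG splitting (default 1.0).
#' @param min_mag_length minimum MAG length in bp (default 50 kb).
#' @param rate_convention `"total_branch"` or `"single_branch"`.
#' @param k anchor k-mer size for genome comparison (default 31).
#' @param seed master seed; all stage seeds derive from it.
#' @param sim list of synthetic-cohort parameters: `n_families`,
#'   `daughters_per_family`, `sharing_probability`, `genome_length`,
#'   `n_contigs`, `contig_min_len`, `mu` (substitutions/site/year),
#'   `n_markers`, `marker_len`, `n_biogeo_pairs` (planted between-family
#'   shared strains).
#' @param input_profile_csv optional path to an existing profile CSV; when
#'   given the cohort is loaded instead of simulated (genome stages still
#'   run on simulated genomes).
#' @return a validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_reads = 500,
                            min_mean_relabund = 1e-4,
                            min_cov = 5,
                            min_purity = 0.90,
                            min_completeness = 80,
                            max_contamination = 5,
                            min_overlap = 0.70,
                            min_identity = 0.999,
                            n_perm = 100,
                            log2_gap = 1.0,
                            min_mag_length = 5e4,
                            rate_convention = "total_branch",
                            k = 31,
                            seed = 1L,
                            sim = list(),
                            input_profile_csv = NULL) {
  sim_defaults <- list(
    n_families = 20, daughters_per_family = 1, sharing_probability = 0.3,
    genome_length = 1e5, n_contigs = 8, contig_min_len = 5e3,
    mu = 1e-5, n_markers = 50, marker_len = 300, n_biogeo_pairs = 1
  )
  sim <- utils::modifyList(sim_defaults, sim)
  cfg <- structure(
    list(
      min_reads = min_reads, min_mean_relabund = min_mean_relabund,
      min_cov = min_cov, min_purity = min_purity,
      min_completeness = min_completeness,
      max_contamination = max_contamination,
      min_overlap = min_overlap, min_identity = min_identity,
      n_perm = as.integer(n_perm), log2_gap = log2_gap,
      min_mag_length = min_mag_length,
      rate_convention = rate_convention, k = as.integer(k),
      seed = as.integer(seed), sim = sim,
      input_profile_csv = input_profile_csv
    ),
    class = "pipeline_config"
  )
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  in_range <- function(x, lo, hi, name, hi_ok = TRUE) {
    bad <- !is.numeric(x) || length(x) != 1 || x < lo ||
      (if (hi_ok) x > hi else x >= hi)
    if (bad) abort(sprintf("config: %s = %s is outside [%s, %s]",
                           name, format(x), format(lo), format(hi)))
  }
  in_range(cfg$min_reads, 0, Inf, "min_reads")
  in_range(cfg$min_mean_relabund, 0, 1, "min_mean_relabund")
  in_range(cfg$min_cov, 0, Inf, "min_cov")
  in_range(cfg$min_purity, 0, 1, "min_purity")
  in_range(cfg$min_completeness, 0, 100, "min_completeness")
  in_range(cfg$max_contamination, 0, 100, "max_contamination")
  in_range(cfg$min_overlap, 0, 1, "min_overlap")
  in_range(cfg$min_identity, 0, 1, "min_identity")
  in_range(cfg$n_perm, 1, Inf, "n_perm")
  in_range(cfg$log2_gap, 0, Inf, "log2_gap")
  in_range(cfg$sim$sharing_probability, 0, 1, "sim$sharing_probability")
  if (!cfg$rate_convention %in% c("total_branch", "single_branch")) {
    abort("config: rate_convention must be 'total_branch' or 'single_branch'")
  }
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> seed =", x$seed, "\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML round-trip is lossless: `read_pipeline_config(write_pipeline_config(cfg, f))`
#' reproduces `cfg` (it is re-validated on read).
#'
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns the `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  sim <- raw$sim %||% list()
  raw$sim <- NULL
  do.call(pipeline_config, c(raw, list(sim = sim)))
}

config_hash <- function(cfg) rlang::hash(unclass(cfg))

# pick each sample's dominant phylotype (focal species for genome stages)
dominant_taxon <- function(tbl) {
  m <- profile_matrix(normalize_profiles(tbl))
  colnames(m)[max.col(m, ties.method = "first")]
}

#' Run the full strain-sharing pipeline
#'
#' Executes simulate -> profile filtering and permutation test -> contig
#' binning and MAG quality control -> all-versus-all strain comparison ->
#' sharing-network classification -> substitution-rate estimation, writing
#' every artifact plus a manifest (package version, seed, thresholds,
#' config hash, per-stage record counts) to `out_dir`. Deterministic:
#' rerunning with the same config produces identical files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) abort("config must be a pipeline_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  counts <- list()

  # -- simulate ------------------------------------------------------------
  cohort <- stage("simulate", {
    if (!is.null(config$input_profile_csv)) {
      if (!file.exists(config$input_profile_csv)) {
        abort(paste0("input profile table not found: ",
                     config$input_profile_csv))
      }
      list(profiles = load_profile_table(config$input_profile_csv),
           truth = NULL)
    } else {
      gen_profile_table(cohort_design(
        n_families = config$sim$n_families,
        daughters_per_family = config$sim$daughters_per_family,
        sharing_probability = config$sim$sharing_probability,
        seed = split_seed(config$seed, 1L, salt = 11L)
      ))
    }
  })
  write_profile_table(cohort$profiles, file.path(out_dir, "profiles.csv"))
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  }
  counts$samples_in <- nrow(cohort$profiles)

  # -- profiles ------------------------------------------------------------
  res_prof <- stage("profiles", {
    filtered <- filter_samples(cohort$profiles, config$min_reads)
    rel <- filter_phylotypes(filtered, config$min_mean_relabund)
    sims <- suppressWarnings(pair_similarities(rel))
    perm <- permutation_test(rel, n_perm = config$n_perm,
                             seed = split_seed(config$seed, 2L, salt = 12L))
    list(filtered = rel, similarities = sims, permutation = perm)
  })
  counts$samples_kept <- nrow(res_prof$filtered)
  counts$phylotypes_kept <- length(phylotype_cols(res_prof$filtered))
  counts$pairs <- nrow(res_prof$similarities)
  readr::write_tsv(res_prof$similarities,
                   file.path(out_dir, "similarity.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(summary = tidy.perm_summary(res_prof$permutation),
         n_perm = res_prof$permutation$n_perm,
         n_pairs = res_prof$permutation$n_pairs),
    file.path(out_dir, "permutation.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  # -- genomes + binning ---------------------------------------------------
  genome_res <- stage("binning", {
    simulate_and_bin_genomes(cohort, config)
  })
  counts$contigs <- nrow(genome_res$contigs)
  counts$mags <- nrow(genome_res$mags)
  readr::write_tsv(
    dplyr::select(genome_res$contigs, -"sequence"),
    file.path(out_dir, "contig_annotations.tsv"), progress = FALSE
  )
  readr::write_tsv(genome_res$mags, file.path(out_dir, "mag_inventory.tsv"),
                   progress = FALSE)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    seqs <- Biostrings::DNAStringSet(
      setNames(genome_res$mag_seqs$sequence, genome_res$mag_seqs$seq_id)
    )
    Biostrings::writeXStringSet(seqs, file.path(out_dir, "mags.fasta"))
  }

  # -- strain comparison ---------------------------------------------------
  ava <- stage("compare", {
    all_vs_all(genome_res$mag_seqs_tbl, min_overlap = config$min_overlap,
               min_identity = config$min_identity, k = config$k)
  })
  counts$comparisons <- nrow(ava$comparisons)
  counts$profiles_all_vs_all <- ava$n_profiles
  readr::write_tsv(ava$comparisons, file.path(out_dir, "comparisons.tsv"),
                   progress = FALSE)
  readr::write_tsv(ava$calls, file.path(out_dir, "calls.tsv"),
                   progress = FALSE)

  # -- network -------------------------------------------------------------
  net_res <- stage("network", {
    net <- build_network(ava$calls, genome_res$manifest)
    list(network = net, classes = classify_and_count(net))
  })
  counts$shared_edges <- net_res$classes$n_edges
  readr::write_tsv(net_res$classes$counts,
                   file.path(out_dir, "edge_counts.tsv"), progress = FALSE)
  write_network(net_res$network,
                graphml_path = file.path(out_dir, "network.graphml"),
                json_path = file.path(out_dir, "network.json"))

  # -- rates ---------------------------------------------------------------
  rate_res <- stage("rates", {
    pipeline_rates(ava, net_res$classes, genome_res$manifest, config)
  })
  counts$rate_records <- nrow(rate_res$records)
  readr::write_tsv(rate_res$records, file.path(out_dir, "rates.tsv"),
                   progress = FALSE)
  jsonlite::write_json(rate_res$comparisons,
                       file.path(out_dir, "group_comparisons.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package = "strainshare",
    version = as.character(utils::packageVersion("strainshare")),
    seed = config$seed,
    config_hash = config_hash(config),
    thresholds = unclass(config)[c(
      "min_reads", "min_mean_relabund", "min_cov", "min_purity",
      "min_completeness", "max_contamination", "min_overlap",
      "min_identity", "n_perm", "log2_gap", "min_mag_length",
      "rate_convention", "k"
    )],
    record_counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    cohort = cohort, profiles = res_prof, genomes = genome_res,
    comparison = ava, network = net_res, rates = rate_res,
    manifest = manifest, out_dir = out_dir
  ))
}

# simulate per-participant genomes consistent with the cohort truth, then
# fragment, bin, split and QC them
simulate_and_bin_genomes <- function(cohort, config) {
  sim <- config$sim
  prof <- cohort$profiles
  truth <- cohort$truth
  focal <- dominant_taxon(prof)
  manifest <- tibble(
    participant_id = prof$sample_id,
    family_id = prof$family_id,
    role = prof$role,
    age = prof$age
  )

  genomes <- list() # per participant: list of (taxon, sequence, genome_id)
  add_genome <- function(pid, taxon, seq, gid) {
    genomes[[pid]] <<- c(genomes[[pid]], list(list(
      taxon = taxon, sequence = seq, genome_id = gid
    )))
  }

  fams <- split(seq_len(nrow(prof)), prof$family_id)
  for (fi in seq_along(fams)) {
    rows <- fams[[fi]]
    fam_id <- prof$family_id[rows[1]]
    mother_row <- rows[prof$role[rows] == "mother"]
    d_rows <- rows[prof$role[rows] == "daughter"]
    m_id <- prof$sample_id[mother_row]
    m_taxon <- focal[mother_row]
    m_has_genome <- FALSE
    for (dr in d_rows) {
      d_id <- prof$sample_id[dr]
      sharing <- if (is.null(truth)) FALSE else {
        isTRUE(truth$sharing[truth$daughter_sample == d_id])
      }
      lseed <- split_seed(config$seed, fi * 100L + which(d_rows == dr),
                          salt = 21L)
      if (sharing) {
        lp <- evolve_pair(sim$genome_length, mu = sim$mu,
                          t_years = prof$age[dr], seed = lseed)
        add_genome(m_id, m_taxon, lp$genome_a, paste0(fam_id, "_", m_taxon, "_M"))
        add_genome(d_id, m_taxon, lp$genome_b, paste0(fam_id, "_", m_taxon, "_D"))
        m_has_genome <- TRUE
      } else {
        d_taxon <- focal[dr]
        add_genome(d_id, d_taxon,
                   random_genome(sim$genome_length, seed = lseed),
                   paste0(fam_id, "_", d_taxon, "_D"))
      }
    }
    if (!m_has_genome) {
      add_genome(m_id, m_taxon,
                 random_genome(sim$genome_length,
                               seed = split_seed(config$seed, fi, salt = 22L)),
                 paste0(fam_id, "_", m_taxon, "_M"))
    }
  }

  # planted between-family shared strains (biogeography)
  n_bio <- sim$n_biogeo_pairs %||% 0
  if (!is.null(truth) && n_bio > 0) {
    mothers <- manifest$participant_id[manifest$role == "mother"]
    for (b in seq_len(min(n_bio, floor(length(mothers) / 2)))) {
      pa <- mothers[2 * b - 1]; pb <- mothers[2 * b]
      lp <- evolve_pair(sim$genome_length, mu = sim$mu, t_years = 10,
                        seed = split_seed(config$seed, b, salt = 23L))
      # a species outside the focal-dominant set, so the planted strain
      # never shares a bin with a participant's own genome
      tx <- "Lactobacillus_mulieris"
      add_genome(pa, tx, lp$genome_a, paste0("bio", b, "_", tx, "_A"))
      add_genome(pb, tx, lp$genome_b, paste0("bio", b, "_", tx, "_B"))
    }
  }

  contigs <- dplyr::bind_rows(purrr::imap(genomes, function(gl, pid) {
    dplyr::bind_rows(purrr::imap(gl, function(g, gi) {
      ct <- fragment_genome(
        g$sequence, n_contigs = sim$n_contigs, min_len = sim$contig_min_len,
        coverage_model = list(type = "constant", depth = 20, sd_log = 0.15),
        taxon_label = g$taxon, purity = 1.0,
        source_genome_id = g$genome_id,
        seed = split_seed(config$seed, gi, salt = 31L + nchar(pid))
      )
      ct$participant_id <- pid
      ct
    }))
  }))

  binned <- filter_and_bin(contigs, min_cov = config$min_cov,
                           min_purity = config$min_purity)
  assigned <- dplyr::bind_rows(purrr::map(
    split(binned, binned$participant_id),
    split_bin_by_coverage, log2_gap = config$log2_gap,
    min_mag_length = config$min_mag_length
  ))

  # per-genome planted markers for quality control
  markers <- purrr::map(
    setNames(unique(assigned$source_genome), unique(assigned$source_genome)),
    function(gid) plant_markers(sim$genome_length, m = sim$n_markers,
                                marker_len = sim$marker_len,
                                seed = split_seed(config$seed,
                                                  nchar(gid), salt = 41L))
  )

  mag_rows <- dplyr::filter(assigned, !is.na(.data$mag_id))
  mag_rows$mag_uid <- paste(mag_rows$participant_id, mag_rows$mag_id,
                            sep = ":")
  mags <- dplyr::bind_rows(purrr::map(
    split(mag_rows, mag_rows$mag_uid),
    function(g) {
      q <- assess_mag_quality(g, markers[[g$source_genome[1]]])
      tibble(
        mag_uid = g$mag_uid[1],
        participant_id = g$participant_id[1],
        taxon_label = g$bin[1],
        n_contigs = nrow(g),
        total_length = sum(g$length),
        mean_coverage = sum(g$length * g$mean_coverage) / sum(g$length),
        completeness = q$completeness,
        contamination = q$contamination
      )
    }
  ))
  mags <- dplyr::arrange(mags, .data$participant_id, .data$mag_uid)
  kept <- filter_mags(mags, min_completeness = config$min_completeness,
                      max_contamination = config$max_contamination)

  mag_seqs <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(mag_rows, .data$mag_uid %in% kept$mag_uid),
      .data$mag_uid
    ),
    participant_id = .data$participant_id[1],
    taxon_label = .data$bin[1],
    sequence = paste(.data$sequence[order(.data$start)], collapse = ""),
    .groups = "drop"
  )
  mag_seqs_tbl <- tibble(
    participant_id = mag_seqs$participant_id,
    mag_id = mag_seqs$mag_uid,
    taxon_label = mag_seqs$taxon_label,
    sequence = mag_seqs$sequence
  )

  list(
    contigs = assigned,
    mags = mags,
    mags_kept = kept,
    mag_seqs = tibble(seq_id = mag_seqs$mag_uid,
                      sequence = mag_seqs$sequence),
    mag_seqs_tbl = mag_seqs_tbl,
    manifest = manifest,
    markers = markers
  )
}

pipeline_rates <- function(ava, classes, manifest, config) {
  edges <- classes$edges
  calls <- ava$calls
  if (nrow(calls) > 0) {
    ia <- match(calls$participant_a, manifest$participant_id)
    ib <- match(calls$participant_b, manifest$participant_id)
    calls$edge_class <- edge_class_of(
      manifest$family_id[ia], manifest$role[ia],
      manifest$family_id[ib], manifest$role[ib]
    )
  } else {
    calls$edge_class <- character(0)
  }
  shared <- dplyr::filter(calls, .data$shared)
  wf <- dplyr::filter(shared, .data$edge_class == "within_family_MD")

  records <- if (nrow(wf) > 0) {
    d_id <- ifelse(
      manifest$role[match(wf$participant_a, manifest$participant_id)] ==
        "daughter", wf$participant_a, wf$participant_b
    )
    m_id <- ifelse(d_id == wf$participant_a, wf$participant_b,
                   wf$participant_a)
    d_age <- manifest$age[match(d_id, manifest$participant_id)]
    tibble(
      taxon = wf$taxon,
      family_id = manifest$family_id[match(d_id, manifest$participant_id)],
      daughter_age = d_age,
      mother_age = manifest$age[match(m_id, manifest$participant_id)],
      snp_density = wf$snp_count / wf$compared_bp,
      snp_density_per_mbp = wf$snp_density_per_mbp,
      substitution_rate = substitution_rate(
        wf$snp_count / wf$compared_bp, d_age,
        convention = config$rate_convention
      )
    )
  } else {
    tibble(taxon = character(0), family_id = character(0),
           daughter_age = numeric(0), mother_age = numeric(0),
           snp_density = numeric(0), snp_density_per_mbp = numeric(0),
           substitution_rate = numeric(0))
  }

  within_d <- dplyr::filter(shared, .data$edge_class == "within_family_MD")
  between_d <- dplyr::filter(shared,
                             !.data$edge_class %in% c("within_family_MD",
                                                      "within_family_DD"))
  comparisons <- list()
  if (nrow(within_d) > 0 && nrow(between_d) > 0) {
    gc <- compare_snp_densities(within_d$snp_density_per_mbp,
                                between_d$snp_density_per_mbp)
    comparisons$snp_density <- list(statistic = gc$statistic,
                                    p_value = gc$p_value)
  }
  daughters <- manifest$participant_id[manifest$role == "daughter"]
  sharing_d <- unique(c(
    within_d$participant_a[within_d$participant_a %in% daughters],
    within_d$participant_b[within_d$participant_b %in% daughters]
  ))
  nonsharing_d <- setdiff(daughters, sharing_d)
  if (length(sharing_d) >= 2 && length(nonsharing_d) >= 2) {
    gc <- compare_daughter_ages(
      manifest$age[match(sharing_d, manifest$participant_id)],
      manifest$age[match(nonsharing_d, manifest$participant_id)]
    )
    comparisons$daughter_age <- list(statistic = gc$statistic,
                                     p_value = gc$p_value,
                                     means = gc$summaries$mean)
  }

  list(records = records, comparisons = comparisons)
}
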