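#' Read a taxonomic profile table
#'
#' Reads a CSV in the wide cohort dialect: metadata columns `sample_id`,
#' `family_id`, `role`, `age`, followed by one numeric column per
#' phylotype. Counts are preserved as given (no normalisation).
#'
#' @param path path to a CSV file.
#' @return a tibble validated as a profile table.
#' @export
load_profile_table <- function(path) {
  if (!file.exists(path)) abort(paste0("profile table not found: ", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tbl) == 0) abort("no samples: profile table is empty")
  check_profile_table(tbl)
  tbl
}

#' Write a taxonomic profile table
#'
#' @param tbl profile table tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(tbl, path) {
  check_profile_table(tbl)
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Drop shallow samples from a count table
#'
#' Removes samples whose total sequence count is below `min_reads`;
#' a sample with exactly `min_reads` reads is kept. Refuses tables that
#' look like relative abundances, since the read-count filter is only
#' meaningful on counts.
#'
#' @param tbl profile table of counts.
#' @param min_reads minimum total reads per sample (default 500).
#' @return the filtered profile table.
#' @export
filter_samples <- function(tbl, min_reads = 500) {
  check_profile_table(tbl)
  if (!is_count_table(tbl)) {
    abort("filter_samples needs count data; this table looks like relative abundances")
  }
  tot <- rowSums(profile_matrix(tbl))
  keep <- tot >= min_reads
  if (!any(keep)) {
    warn(sprintf("all samples have fewer than %s reads; returning an empty table",
                 format(min_reads)))
  }
  tbl[keep, , drop = FALSE]
}

#' Drop study-wide rare phylotypes and renormalise
#'
#' Computes each phylotype's mean relative abundance across all samples and
#' removes those with mean strictly below `min_mean_relabund`; a phylotype
#' at exactly the threshold is kept. Rows are renormalised to sum to 1
#' afterwards, so the output is a relative-abundance table.
#'
#' @param tbl profile table (counts or relative abundances).
#' @param min_mean_relabund study-wide mean relative-abundance threshold
#'   (default `1e-4`).
#' @return the filtered, renormalised profile table.
#' @export
filter_phylotypes <- function(tbl, min_mean_relabund = 1e-4) {
  check_profile_table(tbl)
  rel <- normalize_profiles(tbl)
  m <- profile_matrix(rel)
  keep <- colMeans(m) >= min_mean_relabund
  if (!any(keep)) abort("no phylotypes pass the abundance filter")
  out <- dplyr::bind_cols(
    rel[, PROFILE_META_COLS],
    as_tibble(m[, keep, drop = FALSE] / rowSums(m[, keep, drop = FALSE]))
  )
  out
}

#' Yue-Clayton theta similarity between two compositions
#'
#' \deqn{\theta = \frac{\sum_i p_i q_i}{\sum_i p_i^2 + \sum_i q_i^2 - \sum_i p_i q_i}}
#'
#' equal to 1 for identical relative-abundance vectors and 0 for vectors
#' with disjoint support.
#'
#' @param p,q numeric relative-abundance vectors on the same phylotype
#'   index, each summing to 1.
#' @return theta in `[0, 1]`.
#' @export
#' @examples
#' yue_clayton_theta(c(0.5, 0.5, 0), c(0.5, 0, 0.5)) # 1/3
yue_clayton_theta <- function(p, q) {
  if (length(p) != length(q)) abort("p and q must have the same length")
  if (sum(p) == 0 || sum(q) == 0) abort("zero vectors have no composition")
  cross <- sum(p * q)
  cross / (sum(p^2) + sum(q^2) - cross)
}

# vectorised theta for row-aligned matrices (one value per row pair)
theta_rows <- function(P, Q) {
  cross <- rowSums(P * Q)
  cross / (rowSums(P^2) + rowSums(Q^2) - cross)
}

#' Assign a heuristic community state type
#'
#' A deliberately simple stand-in for nearest-centroid CST classifiers:
#' a profile is CST I, II, III or V when *L. crispatus*, *L. gasseri*,
#' *L. iners* or *L. jensenii* respectively exceeds 50% relative abundance
#' (strict inequality), and IV otherwise. Dominance is checked on the
#' row-normalised profile.
#'
#' @param x a named relative-abundance vector, or a profile table (metadata
#'   columns + phylotypes).
#' @return for a vector, a single label in `c("I","II","III","IV","V")`;
#'   for a table, the table with a `cst` column appended.
#' @export
assign_cst <- function(x) {
  UseMethod("assign_cst")
}

cst_dominants <- c(
  I = "Lactobacillus_crispatus",
  II = "Lactobacillus_gasseri",
  III = "Lactobacillus_iners",
  V = "Lactobacillus_jensenii"
)

#' @export
assign_cst.numeric <- function(x) {
  p <- x / sum(x)
  for (cst in names(cst_dominants)) {
    taxon <- cst_dominants[[cst]]
    if (!is.na(p[taxon] %||% NA) && isTRUE(p[taxon] > 0.5)) return(cst)
  }
  "IV"
}

#' @export
assign_cst.data.frame <- function(x) {
  check_profile_table(x)
  m <- profile_matrix(normalize_profiles(x))
  labels <- vapply(seq_len(nrow(m)), function(i) assign_cst(m[i, ]),
                   character(1))
  dplyr::mutate(x, cst = labels)
}

#' Mother-daughter compositional similarity per family
#'
#' Pairs every daughter with her family's mother and computes the
#' Yue-Clayton theta between their (row-normalised) profiles, plus the
#' daughter's heuristic CST. Families with several daughters contribute one
#' record per daughter; families lacking a mother or lacking daughters are
#' skipped with a warning.
#'
#' @param tbl profile table with `role` in `c("mother", "daughter")`.
#' @return a tibble `family_id`, `mother_sample`, `daughter_sample`,
#'   `theta`, `daughter_cst`.
#' @export
pair_similarities <- function(tbl) {
  check_profile_table(tbl)
  if (nrow(tbl) == 0) {
    return(tibble(family_id = character(0), mother_sample = character(0),
                  daughter_sample = character(0), theta = numeric(0),
                  daughter_cst = character(0)))
  }
  rel <- normalize_profiles(tbl)
  m <- profile_matrix(rel)

  pairs <- purrr::map(split(rel, rel$family_id), function(fam) {
    mothers <- fam$sample_id[fam$role == "mother"]
    daughters <- fam$sample_id[fam$role == "daughter"]
    if (length(mothers) != 1 || length(daughters) < 1) {
      warn(sprintf("family %s skipped: needs exactly one mother and >= 1 daughter",
                   fam$family_id[1]))
      return(NULL)
    }
    tibble(family_id = fam$family_id[1], mother_sample = mothers,
           daughter_sample = daughters)
  })
  pairs <- dplyr::bind_rows(pairs)
  if (nrow(pairs) == 0) {
    return(tibble(family_id = character(0), mother_sample = character(0),
                  daughter_sample = character(0), theta = numeric(0),
                  daughter_cst = character(0)))
  }
  M <- m[pairs$mother_sample, , drop = FALSE]
  D <- m[pairs$daughter_sample, , drop = FALSE]
  pairs$theta <- unname(theta_rows(M, D))
  pairs$daughter_cst <- vapply(
    seq_len(nrow(D)), function(i) assign_cst(D[i, ]), character(1)
  )
  pairs
}
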