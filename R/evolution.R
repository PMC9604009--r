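#' Per-site per-year substitution rate under vertical transmission
#'
#' Under transmission at birth the mother's and daughter's strain
#' populations evolve independently for the daughter's lifetime, so the
#' SNP density between them accumulates along a total branch length of
#' twice the daughter's age. The default `"total_branch"` convention
#' therefore divides by `2 * daughter_age`; `"single_branch"` divides by
#' the age alone, reproducing the alternative reading in which the whole
#' divergence is attributed to one lineage.
#'
#' @param snp_density SNP differences per base pair of compared sequence
#'   (>= 0); vectorised.
#' @param daughter_age years since the hypothesised transmission (> 0).
#' @param convention `"total_branch"` (default) or `"single_branch"`.
#' @return substitution rate per base pair per year.
#' @export
#' @examples
#' substitution_rate(3e-4, 15) # 1e-5
substitution_rate <- function(snp_density, daughter_age,
                              convention = c("total_branch",
                                             "single_branch")) {
  convention <- match.arg(convention)
  if (any(snp_density < 0, na.rm = TRUE)) abort("snp_density must be >= 0")
  if (any(daughter_age <= 0, na.rm = TRUE)) abort("daughter_age must be > 0")
  divisor <- if (convention == "total_branch") 2 * daughter_age
             else daughter_age
  snp_density / divisor
}

#' Summarise substitution-rate records
#'
#' @param records tibble with at least a `substitution_rate` column
#'   (typically also `taxon`, `family_id`, `daughter_age`,
#'   `rel_abund_daughter`, `mother_age`, `rel_abund_mother`).
#' @return a list: `min_rate`, `max_rate`, and `table` — the records
#'   ordered and restricted to the canonical column order (taxon, family,
#'   daughter age and abundance, mother age and abundance, rate).
#' @export
summarize_rates <- function(records) {
  if (nrow(records) == 0) abort("no rate records")
  if (!"substitution_rate" %in% names(records)) {
    abort("records need a 'substitution_rate' column")
  }
  canonical <- c("taxon", "family_id", "daughter_age", "rel_abund_daughter",
                 "mother_age", "rel_abund_mother", "substitution_rate")
  cols <- intersect(canonical, names(records))
  list(
    min_rate = min(records$substitution_rate, na.rm = TRUE),
    max_rate = max(records$substitution_rate, na.rm = TRUE),
    table = dplyr::select(records, all_of(cols), dplyr::everything())
  )
}

new_group_comparison <- function(stat_name, statistic, p_value, summaries,
                                 method) {
  structure(
    list(statistic_name = stat_name, statistic = unname(statistic),
         p_value = p_value, summaries = summaries, method = method),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>", x$method, "\n ",
      x$statistic_name, "=", format(x$statistic), ", p =",
      format.pval(x$p_value), "\n")
  print(x$summaries)
  invisible(x)
}

#' Tidy a two-group comparison
#'
#' @param x a `group_comparison`.
#' @param ... unused.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(statistic_name = x$statistic_name, statistic = x$statistic,
         p_value = x$p_value)
}

#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$summaries, names_from = "group",
    values_from = dplyr::any_of(c("mean", "median", "n"))
  )
  dplyr::bind_cols(tidy.group_comparison(x), wide)
}

#' Compare SNP densities of within- vs between-family shared strains
#'
#' Two-sided Wilcoxon rank-sum test (ties mid-ranked; exact null for small
#' tie-free samples, normal approximation with tie correction otherwise)
#' of the SNP-per-Mbp densities of strains shared within families against
#' those shared between families.
#'
#' @param within_family,between_family numeric vectors of SNP densities
#'   per Mbp (both non-empty).
#' @return a `group_comparison` with the W statistic.
#' @export
compare_snp_densities <- function(within_family, between_family) {
  if (length(within_family) == 0 || length(between_family) == 0) {
    abort("both groups must be non-empty")
  }
  ht <- suppressWarnings(
    wilcox.test(within_family, between_family, alternative = "two.sided")
  )
  new_group_comparison(
    "W", ht$statistic, ht$p.value,
    tibble(
      group = c("within_family", "between_family"),
      n = c(length(within_family), length(between_family)),
      median = c(stats::median(within_family), stats::median(between_family)),
      mean = c(mean(within_family), mean(between_family))
    ),
    "Wilcoxon rank sum test"
  )
}

#' Compare daughter ages between sharing and non-sharing pairs
#'
#' Two-sample t test (pooled variance by default; `var_equal = FALSE` for
#' Welch) of the ages of daughters in mother-daughter pairs found to share
#' strains against those in pairs that do not. Supply one age per pair.
#'
#' @param sharing_ages,nonsharing_ages numeric age vectors, each with at
#'   least 2 values.
#' @param var_equal pooled-variance t test when `TRUE` (default).
#' @return a `group_comparison` with the t statistic and group means.
#' @export
compare_daughter_ages <- function(sharing_ages, nonsharing_ages,
                                  var_equal = TRUE) {
  if (length(sharing_ages) < 2 || length(nonsharing_ages) < 2) {
    abort("each group needs at least 2 ages for a t statistic")
  }
  ht <- t.test(sharing_ages, nonsharing_ages, var.equal = var_equal)
  new_group_comparison(
    "t", ht$statistic, ht$p.value,
    tibble(
      group = c("sharing", "nonsharing"),
      n = c(length(sharing_ages), length(nonsharing_ages)),
      mean = c(mean(sharing_ages), mean(nonsharing_ages))
    ),
    if (var_equal) "Two-sample t test (pooled variance)"
    else "Welch two-sample t test"
  )
}

#' Bundled mother-daughter shared-strain records
#'
#' A small bundled table of shared-strain records observed between
#' mother-daughter pairs in a published vaginal-microbiota cohort: one row
#' per shared MAG, with the taxon, family, participant ages, the strain's
#' relative abundance in each community (percent) and the per-base-pair
#' per-year substitution rate estimated under vertical transmission at
#' birth. One mother's age is missing in the source and is kept `NA`.
#'
#' @return a tibble with columns `taxon`, `family_id`, `daughter_age`,
#'   `rel_abund_daughter`, `mother_age`, `rel_abund_mother`,
#'   `substitution_rate`.
#' @export
mother_daughter_strains <- function() {
  path <- system.file("extdata", "mother_daughter_strains.tsv",
                      package = "strainshare", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  na = "NA")
}
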