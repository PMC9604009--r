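#' Binned permutation test of mother-daughter similarity
#'
#' Tests whether the observed distribution of mother-daughter Yue-Clayton
#' theta values differs from that expected by chance. Each permutation
#' reshuffles mother profiles among mother samples and daughter profiles
#' among daughter samples (roles preserved, family pairing broken;
#' `shuffle = "daughters"` shuffles daughters only), recomputes every pair's
#' theta and bins the values into width-`bin_width` bins over `[0, 1]`
#' (half-open bins, final bin closed so theta = 1 is counted). Per bin the
#' null mean, the 2.5% and 97.5% null quantiles and a one-sided empirical
#' p-value are reported: p is the fraction of permutations whose count is
#' as or more extreme than the observed count, in the direction of the
#' observed deviation from the null mean (a bin whose observed count equals
#' its null mean gets p = 1). With `plus_one = TRUE` the estimate is
#' `(count + 1) / (n_perm + 1)`.
#'
#' @param tbl profile table (counts or relative; normalised internally)
#'   covering at least 2 families.
#' @param n_perm number of permutations (default 100).
#' @param bin_width similarity bin width (default 0.1).
#' @param seed integer seed.
#' @param shuffle `"both"` (default) or `"daughters"`.
#' @param plus_one add-one correction to the empirical p-value.
#' @param keep_null retain the `n_perm x n_bins` null count matrix (in
#'   `$null_counts`) for calibration work.
#' @return an object of class `perm_summary`; see [tidy.perm_summary()].
#' @export
permutation_test <- function(tbl, n_perm = 100, bin_width = 0.1, seed = 1L,
                             shuffle = c("both", "daughters"),
                             plus_one = FALSE, keep_null = FALSE) {
  shuffle <- match.arg(shuffle)
  if (n_perm < 1) abort("n_perm must be >= 1")
  check_profile_table(tbl)
  if (length(unique(tbl$family_id)) < 2) {
    abort("permutation test needs at least 2 families")
  }
  rel <- normalize_profiles(tbl)
  m <- profile_matrix(rel)
  pairs <- suppressWarnings(pair_similarities(rel))
  if (nrow(pairs) < 2) abort("permutation test needs at least 2 pairs")

  mother_samples <- rel$sample_id[rel$role == "mother"]
  daughter_samples <- rel$sample_id[rel$role == "daughter"]

  n_bins <- as.integer(ceiling(1 / bin_width - 1e-9))
  edges <- c(seq(0, by = bin_width, length.out = n_bins), 1)
  bin_of <- function(theta) {
    theta <- pmin(pmax(theta, 0), 1)
    pmin(floor(theta / bin_width) + 1L, n_bins)
  }
  count_bins <- function(theta) tabulate(bin_of(theta), nbins = n_bins)

  obs_counts <- count_bins(pairs$theta)

  mi <- match(pairs$mother_sample, rownames(m))
  di <- match(pairs$daughter_sample, rownames(m))
  m_pool <- match(mother_samples, rownames(m))
  d_pool <- match(daughter_samples, rownames(m))

  null_counts <- withr::with_seed(as.integer(seed), {
    t(vapply(seq_len(n_perm), function(b) {
      # new_row[i] = profile row now sitting at sample i's slot
      perm_m <- seq_len(nrow(m))
      perm_m[m_pool] <- m_pool[sample.int(length(m_pool))]
      if (shuffle == "both") {
        perm_d <- seq_len(nrow(m))
        perm_d[d_pool] <- d_pool[sample.int(length(d_pool))]
      } else {
        perm_d <- seq_len(nrow(m))
        perm_d[d_pool] <- d_pool[sample.int(length(d_pool))]
        perm_m <- seq_len(nrow(m))
      }
      theta <- theta_rows(m[perm_m[mi], , drop = FALSE],
                          m[perm_d[di], , drop = FALSE])
      count_bins(theta)
    }, integer(n_bins)))
  })

  null_mean <- colMeans(null_counts)
  q_lo <- apply(null_counts, 2, quantile, probs = 0.025)
  q_hi <- apply(null_counts, 2, quantile, probs = 0.975)

  p <- vapply(seq_len(n_bins), function(b) {
    dev <- obs_counts[b] - null_mean[b]
    if (dev == 0) return(1)
    extreme <- if (dev > 0) sum(null_counts[, b] >= obs_counts[b])
               else sum(null_counts[, b] <= obs_counts[b])
    if (plus_one) (extreme + 1) / (n_perm + 1) else extreme / n_perm
  }, numeric(1))

  structure(
    list(
      summary = tibble(
        bin_low = edges[-length(edges)],
        bin_high = edges[-1],
        observed = obs_counts,
        null_mean = null_mean,
        null_q2.5 = unname(q_lo),
        null_q97.5 = unname(q_hi),
        p_value = p
      ),
      observed_pairs = pairs,
      n_perm = as.integer(n_perm),
      n_pairs = nrow(pairs),
      bin_width = bin_width,
      shuffle = shuffle,
      plus_one = plus_one,
      seed = as.integer(seed),
      null_counts = if (keep_null) null_counts else NULL
    ),
    class = "perm_summary"
  )
}

#' @export
print.perm_summary <- function(x, ...) {
  cat("<perm_summary>", x$n_pairs, "pairs,", x$n_perm,
      "permutations, bin width", x$bin_width, "\n")
  print(x$summary, ...)
  invisible(x)
}

#' Tidy a permutation-test summary
#'
#' @param x a `perm_summary`.
#' @param ... unused.
#' @return the per-bin summary tibble (`bin_low`, `bin_high`, `observed`,
#'   `null_mean`, `null_q2.5`, `null_q97.5`, `p_value`).
#' @method tidy perm_summary
#' @export
tidy.perm_summary <- function(x, ...) x$summary

#' One-row summary of a permutation test
#'
#' @param x a `perm_summary`.
#' @param ... unused.
#' @method glance perm_summary
#' @export
glance.perm_summary <- function(x, ...) {
  tibble(
    n_pairs = x$n_pairs, n_perm = x$n_perm, bin_width = x$bin_width,
    n_bins = nrow(x$summary), min_p = min(x$summary$p_value),
    mean_theta = mean(x$observed_pairs$theta)
  )
}

#' Plot a permutation-test summary
#'
#' Observed per-bin pair counts (stars) against the permutation null
#' (points with 2.5%-97.5% quantile bars).
#'
#' @param object a `perm_summary`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot perm_summary
#' @export
autoplot.perm_summary <- function(object, ...) {
  s <- dplyr::mutate(object$summary, mid = (.data$bin_low + .data$bin_high) / 2)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$null_q2.5, ymax = .data$null_q97.5),
      width = 0.02
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$null_mean), size = 2) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$observed), shape = 8, colour = "goldenrod",
      size = 3, stroke = 1.2
    ) +
    ggplot2::labs(
      x = "Yue-Clayton similarity bin",
      y = "number of mother-daughter pairs",
      title = "Observed pair similarity vs. permutation null"
    ) +
    ggplot2::theme_minimal()
}
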