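#' Filter contigs and group them into species bins
#'
#' Reference-guided binning: contigs with mean coverage of at least
#' `min_cov` and with at least `min_purity` of their reads mapping to
#' catalog genes of their own taxon are grouped by taxon label into species
#' bins (both boundaries inclusive). Everything else — including contigs
#' with a missing taxon annotation — goes to the `"unbinned"` sink, so the
#' output is a partition of the input contigs.
#'
#' @param contigs tibble of annotated contigs with at least `contig_id`,
#'   `mean_coverage`, `taxon_label`, `purity` (and usually `length`,
#'   `sequence`).
#' @param min_cov minimum mean coverage (default 5).
#' @param min_purity minimum read-annotation purity (default 0.90).
#' @return the contig tibble with a `bin` column (taxon label or
#'   `"unbinned"`).
#' @export
filter_and_bin <- function(contigs, min_cov = 5.0, min_purity = 0.90) {
  need <- c("contig_id", "mean_coverage", "taxon_label", "purity")
  miss <- setdiff(need, names(contigs))
  if (length(miss) > 0) {
    abort(paste0("contig table missing columns: ", paste(miss, collapse = ", ")))
  }
  dplyr::mutate(
    contigs,
    bin = dplyr::if_else(
      !is.na(.data$taxon_label) &
        .data$mean_coverage >= min_cov &
        .data$purity >= min_purity,
      .data$taxon_label,
      "unbinned"
    )
  )
}

#' Split species bins into MAGs by coverage
#'
#' Within each species bin, contigs are sorted by `log2(mean_coverage)` and
#' a cut is placed at every adjacent gap larger than `log2_gap` (default
#' 1.0, i.e. a 2-fold depth difference) — simple deterministic 1-D gap
#' clustering. Each resulting cluster whose total contig length reaches
#' `min_mag_length` becomes a MAG; shorter clusters are sent back to the
#' sink. Splitting an already-uniform bin returns it as one MAG.
#'
#' @param contigs output of [filter_and_bin()] (or any contig tibble with a
#'   `bin` column); rows with `bin == "unbinned"` pass through untouched.
#' @param log2_gap log2-coverage gap opening a new MAG (default 1.0).
#' @param min_mag_length minimum MAG length in bp (default 50 kb, scaled to
#'   the synthetic genomes this package simulates).
#' @return the contig tibble with a `mag_id` column (`NA` for sink
#'   contigs).
#' @export
split_bin_by_coverage <- function(contigs, log2_gap = 1.0,
                                  min_mag_length = 5e4) {
  if (!"bin" %in% names(contigs)) abort("run filter_and_bin() first (no 'bin' column)")
  if (!"length" %in% names(contigs)) {
    contigs$length <- nchar(contigs$sequence)
  }
  split_one <- function(g) {
    if (g$bin[1] == "unbinned") {
      g$mag_cluster <- NA_integer_
      return(g)
    }
    ord <- order(log2(g$mean_coverage), g$contig_id)
    lc <- log2(g$mean_coverage)[ord]
    new_cluster <- c(TRUE, diff(lc) > log2_gap)
    cl <- cumsum(new_cluster)
    g$mag_cluster[ord] <- cl
    g
  }
  out <- contigs
  out$mag_cluster <- NA_integer_
  out <- dplyr::bind_rows(purrr::map(split(out, out$bin), split_one))
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$bin, .data$mag_cluster),
    cluster_length = sum(.data$length)
  )
  out <- dplyr::ungroup(dplyr::mutate(
    out,
    mag_id = dplyr::if_else(
      !is.na(.data$mag_cluster) & .data$cluster_length >= min_mag_length,
      sprintf("%s_MAG%d", .data$bin, .data$mag_cluster),
      NA_character_
    )
  ))
  dplyr::select(out, -"mag_cluster", -"cluster_length")
}

#' Summarise MAGs from an assigned contig table
#'
#' @param contigs contig tibble with a `mag_id` column (see
#'   [split_bin_by_coverage()]).
#' @return one row per MAG: `mag_id`, `taxon_label`, `n_contigs`,
#'   `total_length`, `mean_coverage` (length-weighted), and
#'   `relative_abundance` — the percent of the sample's reads
#'   (length x coverage over all input contigs) attributed to the MAG.
#' @export
summarize_mags <- function(contigs) {
  if (!"mag_id" %in% names(contigs)) abort("no 'mag_id' column; split bins first")
  if (!"length" %in% names(contigs)) contigs$length <- nchar(contigs$sequence)
  total_reads <- sum(contigs$length * contigs$mean_coverage)
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(contigs, !is.na(.data$mag_id)), .data$mag_id),
    taxon_label = .data$taxon_label[1],
    n_contigs = dplyr::n(),
    total_length = sum(.data$length),
    mean_coverage = sum(.data$length * .data$mean_coverage) / sum(.data$length),
    relative_abundance = 100 * sum(.data$length * .data$mean_coverage) /
      total_reads,
    .groups = "drop"
  )
  out
}

#' Marker-based MAG quality
#'
#' Completeness and contamination against a planted single-copy marker set:
#' a marker is present when its genome interval is fully contained in one
#' of the MAG's contigs (contig `start`/`end` coordinates on the source
#' genome). Completeness is the percentage of markers present at least
#' once; contamination is the percentage of extra marker copies
#' (`100 * sum(copies - 1) / m` over markers present more than once).
#'
#' @param mag_contigs contig tibble for one MAG, with `start` and `end`
#'   source-genome coordinates.
#' @param markers marker tibble from [plant_markers()].
#' @return a one-row tibble `completeness`, `contamination` (percent).
#' @export
assess_mag_quality <- function(mag_contigs, markers) {
  if (nrow(markers) == 0) abort("no markers: cannot assess MAG quality")
  if (!all(c("start", "end") %in% names(mag_contigs))) {
    abort("mag contigs need source-genome 'start' and 'end' coordinates")
  }
  copies <- vapply(seq_len(nrow(markers)), function(i) {
    sum(mag_contigs$start <= markers$start[i] &
          mag_contigs$end >= markers$end[i])
  }, numeric(1))
  m <- nrow(markers)
  tibble(
    completeness = 100 * sum(copies >= 1) / m,
    contamination = 100 * sum(pmax(copies - 1, 0)) / m
  )
}

#' Keep near-complete, low-contamination MAGs
#'
#' Retains MAGs with completeness of at least `min_completeness` percent
#' and contamination strictly below `max_contamination` percent (the
#' boundary is asymmetric: completeness at the threshold passes,
#' contamination at the threshold fails).
#'
#' @param mags tibble with `completeness` and `contamination` columns.
#' @param min_completeness percent, default 80.
#' @param max_contamination percent, default 5.
#' @return the filtered tibble.
#' @export
filter_mags <- function(mags, min_completeness = 80, max_contamination = 5) {
  if (!all(c("completeness", "contamination") %in% names(mags))) {
    abort("mags need 'completeness' and 'contamination' columns")
  }
  dplyr::filter(
    mags,
    .data$completeness >= min_completeness,
    .data$contamination < max_contamination
  )
}
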