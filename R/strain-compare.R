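#' Anchor-based ungapped alignment of two genomes
#'
#' A deterministic, desk-scale pairwise aligner for closely related
#' (substitution-diverged) genomes. K-mers that occur exactly once in each
#' sequence and are shared between them become anchors; anchors are chained
#' colinearly (longest chain strictly increasing in both coordinates,
#' leftmost-lowest tie-break), merged along a common diagonal when the
#' intervening region has at most 10% mismatches, and extended outwards
#' until the mismatch density in a trailing 100-bp window exceeds 10%.
#' Blocks are trimmed so they never overlap in either sequence.
#'
#' @param seq_a,seq_b character strings (non-empty).
#' @param k anchor k-mer size (default 31); must not exceed either
#'   sequence.
#' @param window,max_mismatch extension stop rule: stop once more than
#'   `max_mismatch` mismatches fall inside the trailing `window` bp.
#' @return a tibble of ungapped blocks `start_a`, `start_b`, `length`
#'   (1-based), with attribute `total_aligned_bp`.
#' @export
anchor_align <- function(seq_a, seq_b, k = 31, window = 100,
                         max_mismatch = 10) {
  na <- nchar(seq_a); nb <- nchar(seq_b)
  if (na == 0 || nb == 0) abort("sequences must be non-empty")
  if (k > na || k > nb) abort("k exceeds a sequence length")

  unique_kmers <- function(s, n) {
    km <- substring(s, 1:(n - k + 1), k:n)
    dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
    list(kmer = km[!dup], pos = which(!dup))
  }
  ua <- unique_kmers(seq_a, na)
  ub <- unique_kmers(seq_b, nb)
  hit <- match(ua$kmer, ub$kmer)
  keep <- !is.na(hit)
  pa <- ua$pos[keep]
  pb <- ub$pos[hit[keep]]

  empty <- tibble(start_a = integer(0), start_b = integer(0),
                  length = integer(0))
  attr(empty, "total_aligned_bp") <- 0L
  if (length(pa) == 0) return(empty)

  ord <- order(pa)
  pa <- pa[ord]; pb <- pb[ord]

  # longest chain strictly increasing in both coordinates (pa already
  # strictly increasing); fast path when pb is already monotone
  if (is.unsorted(pb, strictly = TRUE)) {
    idx <- lis_indices(pb)
    pa <- pa[idx]; pb <- pb[idx]
  }

  ra <- charToRaw(seq_a); rb <- charToRaw(seq_b)
  gap_ok <- function(a_from, b_from, len) {
    if (len <= 0) return(TRUE)
    mism <- sum(ra[a_from:(a_from + len - 1)] != rb[b_from:(b_from + len - 1)])
    mism <= 0.1 * len
  }

  # merge chained anchors along a common diagonal
  diag <- pb - pa
  blocks <- list()
  bs_a <- pa[1]; bs_b <- pb[1]; be_a <- pa[1] + k - 1L
  for (i in seq_along(pa)[-1]) {
    gap <- pa[i] - be_a - 1L
    if (diag[i] == diag[i - 1] &&
        (gap <= 0 || gap_ok(be_a + 1L, be_a + 1L + diag[i], gap))) {
      be_a <- max(be_a, pa[i] + k - 1L)
    } else {
      blocks[[length(blocks) + 1]] <- c(bs_a, bs_b, be_a - bs_a + 1L)
      bs_a <- pa[i]; bs_b <- pb[i]; be_a <- pa[i] + k - 1L
    }
  }
  blocks[[length(blocks) + 1]] <- c(bs_a, bs_b, be_a - bs_a + 1L)
  bl <- do.call(rbind, blocks)

  # extend each block until mismatch density in a trailing window is
  # exceeded, then trim back to the last matching base
  extend_len <- function(mism) {
    if (length(mism) == 0) return(0L)
    cm <- cumsum(mism)
    w <- cm - c(rep(0L, min(window, length(mism))),
                cm[seq_len(max(0, length(mism) - window))])
    stop_at <- which(w > max_mismatch)
    lim <- if (length(stop_at) == 0) length(mism) else stop_at[1] - 1L
    if (lim == 0) return(0L)
    last_match <- which(!mism[seq_len(lim)])
    if (length(last_match) == 0) 0L else last_match[length(last_match)]
  }
  out <- matrix(0L, nrow(bl), 3)
  for (i in seq_len(nrow(bl))) {
    sa <- bl[i, 1]; sb <- bl[i, 2]; len <- bl[i, 3]
    ea <- sa + len - 1L; eb <- sb + len - 1L
    # rightwards
    mr <- min(na - ea, nb - eb)
    if (mr > 0) {
      mism <- ra[(ea + 1):(ea + mr)] != rb[(eb + 1):(eb + mr)]
      ea <- ea + extend_len(mism)
    }
    # leftwards
    ml <- min(sa - 1L, sb - 1L)
    if (ml > 0) {
      mism <- rev(ra[(sa - ml):(sa - 1)] != rb[(sb - ml):(sb - 1)])
      ext <- extend_len(mism)
      sa <- sa - ext; sb <- sb - ext
    }
    out[i, ] <- c(sa, sb, ea - sa + 1L)
  }

  # enforce non-overlap in both sequences (earlier block wins)
  res <- list()
  prev_ea <- 0L; prev_eb <- 0L
  for (i in seq_len(nrow(out))) {
    sa <- out[i, 1]; sb <- out[i, 2]; len <- out[i, 3]
    cut <- max(prev_ea - sa + 1L, prev_eb - sb + 1L, 0L)
    sa <- sa + cut; sb <- sb + cut; len <- len - cut
    if (len > 0) {
      res[[length(res) + 1]] <- c(sa, sb, len)
      prev_ea <- sa + len - 1L
      prev_eb <- sb + len - 1L
    }
  }
  if (length(res) == 0) return(empty)
  res <- do.call(rbind, res)
  bl_tbl <- tibble(start_a = res[, 1], start_b = res[, 2], length = res[, 3])
  attr(bl_tbl, "total_aligned_bp") <- sum(bl_tbl$length)
  bl_tbl
}

# O(n log n) longest strictly increasing subsequence; returns indices.
lis_indices <- function(x) {
  n <- length(x)
  tails <- numeric(0)      # smallest tail value of chains of each length
  tails_idx <- integer(0)
  prev <- integer(n)
  for (i in seq_len(n)) {
    j <- findInterval(x[i] - 0.5, tails) + 1L  # first chain tail >= x[i]
    prev[i] <- if (j > 1L) tails_idx[j - 1L] else 0L
    tails[j] <- x[i]
    tails_idx[j] <- i
    length(tails) <- max(length(tails), j)
  }
  idx <- integer(0)
  i <- tails_idx[length(tails_idx)]
  while (i > 0L) {
    idx <- c(i, idx)
    i <- prev[i]
  }
  idx
}

#' Genome-wide strain comparison
#'
#' Aligns two genomes with [anchor_align()] and summarises the comparison:
#' SNPs are mismatches inside aligned blocks, coverage overlap is the
#' aligned fraction of the shorter genome, identity is
#' `1 - snp_count / compared_bp` and SNP density is reported per megabase
#' pair of compared sequence. An empty alignment yields a record flagged
#' not comparable (identity `NA`, overlap 0).
#'
#' @param seq_a,seq_b genome sequences (character strings).
#' @param id_a,id_b identifiers carried into the record.
#' @param k anchor k-mer size passed to [anchor_align()].
#' @return a one-row tibble: `id_a`, `id_b`, `compared_bp`,
#'   `coverage_overlap`, `snp_count`, `identity`, `snp_density_per_mbp`,
#'   `comparable`.
#' @export
compare_genomes <- function(seq_a, seq_b, id_a = "a", id_b = "b", k = 31) {
  blocks <- anchor_align(seq_a, seq_b, k = k)
  compared <- sum(blocks$length)
  if (compared == 0) {
    return(tibble(
      id_a = id_a, id_b = id_b, compared_bp = 0L, coverage_overlap = 0,
      snp_count = NA_integer_, identity = NA_real_,
      snp_density_per_mbp = NA_real_, comparable = FALSE
    ))
  }
  ra <- charToRaw(seq_a); rb <- charToRaw(seq_b)
  snp <- sum(vapply(seq_len(nrow(blocks)), function(i) {
    sa <- blocks$start_a[i]; sb <- blocks$start_b[i]
    len <- blocks$length[i]
    sum(ra[sa:(sa + len - 1)] != rb[sb:(sb + len - 1)])
  }, numeric(1)))
  tibble(
    id_a = id_a, id_b = id_b,
    compared_bp = compared,
    coverage_overlap = compared / min(nchar(seq_a), nchar(seq_b)),
    snp_count = as.integer(snp),
    identity = 1 - snp / compared,
    snp_density_per_mbp = 1e6 * snp / compared,
    comparable = TRUE
  )
}

#' Call shared strains at coverage and identity thresholds
#'
#' A comparison is a shared-strain call when it is comparable, its coverage
#' overlap is at least `min_overlap` and its identity is at least
#' `min_identity` (both boundaries inclusive). Defaults are the stringent
#' thresholds used for detecting recent transmission: 70% coverage overlap
#' and 99.9% sequence identity.
#'
#' @param comparisons tibble of [compare_genomes()] records.
#' @param min_overlap minimum coverage overlap (default 0.70).
#' @param min_identity minimum sequence identity (default 0.999).
#' @return the tibble with a logical `shared` column and the thresholds as
#'   `min_overlap` / `min_identity` attributes.
#' @export
call_shared <- function(comparisons, min_overlap = 0.70,
                        min_identity = 0.999) {
  out <- dplyr::mutate(
    comparisons,
    shared = .data$comparable &
      .data$coverage_overlap >= min_overlap &
      !is.na(.data$identity) & .data$identity >= min_identity
  )
  attr(out, "min_overlap") <- min_overlap
  attr(out, "min_identity") <- min_identity
  out
}

#' All-versus-all strain comparison across participants
#'
#' Compares the MAGs of every pair of participants, species by species:
#' each same-taxon MAG pair is aligned and summarised, and shared-strain
#' calls are made at the given thresholds. Following the all-versus-all
#' profile bookkeeping of read-mapping workflows, `n_profiles` reports the
#' square of the participant count; self-comparisons are excluded from the
#' sharing calls.
#'
#' @param mags tibble with one row per MAG: `participant_id`, `mag_id`,
#'   `taxon_label`, `sequence`.
#' @param min_overlap,min_identity thresholds for [call_shared()].
#' @param k anchor k-mer size.
#' @return a list: `comparisons` (per evaluated pair, with participant and
#'   MAG ids and taxon), `calls` (comparisons plus `shared`), and
#'   `n_profiles`.
#' @export
all_vs_all <- function(mags, min_overlap = 0.70, min_identity = 0.999,
                       k = 31) {
  need <- c("participant_id", "mag_id", "taxon_label", "sequence")
  miss <- setdiff(need, names(mags))
  if (length(miss) > 0) {
    abort(paste0("mag table missing columns: ", paste(miss, collapse = ", ")))
  }
  participants <- unique(mags$participant_id)
  if (length(participants) < 2) abort("all_vs_all needs >= 2 participants")

  pairs <- utils::combn(participants, 2, simplify = FALSE)
  comparisons <- purrr::map(pairs, function(pr) {
    ma <- dplyr::filter(mags, .data$participant_id == pr[1])
    mb <- dplyr::filter(mags, .data$participant_id == pr[2])
    shared_taxa <- intersect(ma$taxon_label, mb$taxon_label)
    if (length(shared_taxa) == 0) return(NULL)
    purrr::map(shared_taxa, function(tx) {
      mta <- dplyr::filter(ma, .data$taxon_label == tx)
      mtb <- dplyr::filter(mb, .data$taxon_label == tx)
      grid <- tidyr::expand_grid(i = seq_len(nrow(mta)), j = seq_len(nrow(mtb)))
      purrr::map(seq_len(nrow(grid)), function(r) {
        i <- grid$i[r]; j <- grid$j[r]
        cmp <- compare_genomes(mta$sequence[i], mtb$sequence[j],
                               id_a = mta$mag_id[i], id_b = mtb$mag_id[j],
                               k = k)
        dplyr::bind_cols(
          tibble(participant_a = pr[1], participant_b = pr[2], taxon = tx),
          cmp
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  calls <- if (nrow(comparisons) > 0) {
    call_shared(comparisons, min_overlap = min_overlap,
                min_identity = min_identity)
  } else {
    dplyr::mutate(comparisons, shared = logical(0))
  }
  list(
    comparisons = comparisons,
    calls = calls,
    n_profiles = length(participants)^2
  )
}
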