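#' Random nucleotide genome
#'
#' @param length genome length in bp.
#' @param seed integer seed (optional; draws from the current RNG stream
#'   when `NULL`).
#' @param gc GC content (default 0.5).
#' @return a single character string over `ACGT`.
#' @export
random_genome <- function(length, seed = NULL, gc = 0.5) {
  stopifnot(length >= 1)
  draw <- function() {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

# apply n uniform substitutions to a raw-encoded sequence; each hit changes
# the current base to a uniformly chosen *different* base. Positions are
# sampled with replacement (multiple hits coincide with probability
# O((mu t)^2), the usual infinite-sites slippage, left uncorrected).
mutate_raw <- function(r, n) {
  if (n == 0) return(r)
  bases <- charToRaw(paste(DNA_BASES, collapse = ""))
  pos <- sample.int(length(r), n, replace = TRUE)
  for (p in pos) {
    alt <- bases[bases != r[p]]
    r[p] <- alt[sample.int(3L, 1L)]
  }
  r
}

#' Evolve a mother-daughter genome pair from a common ancestor
#'
#' Models vertical transmission at birth: a single ancestral strain genome
#' is transmitted, after which the mother's and daughter's populations
#' evolve independently for `t_years`. Each lineage receives a
#' `Poisson(mu * L * t_years)` number of substitutions at uniform positions,
#' each to a uniformly chosen different base. The realised single-nucleotide
#' differences between the two derived genomes are recorded as ground truth.
#'
#' @param ancestor_length genome length in bp (ignored when `ancestor` is
#'   supplied).
#' @param mu substitution rate per site per year (>= 0).
#' @param t_years years since divergence, i.e. the daughter's age under the
#'   at-birth transmission hypothesis (>= 0). Total branch length separating
#'   the two genomes is `2 * t_years`.
#' @param seed integer seed.
#' @param ancestor optional ancestor sequence (character string); generated
#'   randomly when missing.
#' @return an object of class `lineage_pair`: a list with `ancestor`,
#'   `genome_a`, `genome_b` (character strings of equal length), `mu`,
#'   `t_years`, `length`, and `true_snp_positions` (1-based positions at
#'   which the two derived genomes differ).
#' @export
#' @examples
#' lp <- evolve_pair(10000, mu = 1e-5, t_years = 15, seed = 7)
#' length(lp$true_snp_positions)
evolve_pair <- function(ancestor_length = NULL, mu, t_years, seed,
                        ancestor = NULL) {
  if (mu < 0) abort("mu must be >= 0")
  if (t_years < 0) abort("t_years must be >= 0")
  if (is.null(ancestor) && is.null(ancestor_length)) {
    abort("supply ancestor_length or an ancestor sequence")
  }
  withr::with_seed(as.integer(seed), {
    if (is.null(ancestor)) {
      ancestor <- paste(sample(DNA_BASES, ancestor_length, replace = TRUE),
                        collapse = "")
    }
    r0 <- charToRaw(ancestor)
    L <- length(r0)
    n_a <- rpois(1, mu * L * t_years)
    n_b <- rpois(1, mu * L * t_years)
    ra <- mutate_raw(r0, n_a)
    rb <- mutate_raw(r0, n_b)
    structure(
      list(
        ancestor = ancestor,
        genome_a = rawToChar(ra),
        genome_b = rawToChar(rb),
        mu = mu,
        t_years = t_years,
        length = L,
        true_snp_positions = which(ra != rb)
      ),
      class = "lineage_pair"
    )
  })
}

#' @export
print.lineage_pair <- function(x, ...) {
  cat("<lineage_pair>", x$length, "bp, mu =", x$mu, ", t =", x$t_years,
      "yr,", length(x$true_snp_positions), "true SNPs\n")
  invisible(x)
}

#' Fragment a genome into annotated synthetic contigs
#'
#' Tiles the genome into `n_contigs` non-overlapping pieces (each at least
#' `min_len` bp; random lengths otherwise) and assigns each a mean read
#' coverage from a coverage model, a taxon label and a purity (the fraction
#' of mapped reads agreeing with the label). The `two_strain` coverage model
#' emulates a species bin containing contigs from two co-occurring strains
#' at different depths, recording each contig's true strain of origin for
#' split-recovery testing.
#'
#' @param genome character string.
#' @param n_contigs number of contigs.
#' @param min_len minimum contig length; `n_contigs * min_len` must not
#'   exceed the genome length.
#' @param coverage_model a list: `list(type = "constant", depth = 20,
#'   sd_log = 0.1)` or `list(type = "two_strain", depths = c(10, 50),
#'   prob = 0.5, sd_log = 0.1)` (log-normal jitter around the model depth).
#' @param taxon_label taxon annotation given to every contig.
#' @param purity per-contig purity in `[0, 1]`.
#' @param source_genome_id identifier recorded in the `source_genome`
#'   column.
#' @param seed integer seed.
#' @return a tibble with columns `contig_id`, `start`, `end`, `length`,
#'   `sequence`, `mean_coverage`, `taxon_label`, `purity`, `strain`,
#'   `source_genome`.
#' @export
fragment_genome <- function(genome, n_contigs, min_len,
                            coverage_model = list(type = "constant",
                                                  depth = 20, sd_log = 0.1),
                            taxon_label = "taxon",
                            purity = 1.0,
                            source_genome_id = "genome",
                            seed = 1L) {
  L <- nchar(genome)
  n_contigs <- as.integer(n_contigs)
  if (n_contigs < 1) abort("n_contigs must be >= 1")
  if (n_contigs * min_len > L) {
    abort(sprintf(
      "infeasible tiling: %d contigs of >= %d bp exceed genome length %d",
      n_contigs, min_len, L
    ))
  }
  if (purity < 0 || purity > 1) abort("purity must be in [0, 1]")
  withr::with_seed(as.integer(seed), {
    slack <- L - n_contigs * min_len
    cuts <- if (n_contigs > 1) sort(runif(n_contigs - 1)) else numeric(0)
    extra <- diff(c(0, cuts, 1)) * slack
    lens <- min_len + floor(extra)
    # floor() may leave a remainder: leave it as a terminal gap
    ends <- cumsum(lens)
    starts <- ends - lens + 1
    sequences <- substring(genome, starts, ends)

    cm <- coverage_model
    if (identical(cm$type, "constant")) {
      strain <- rep(1L, n_contigs)
      depth0 <- rep(cm$depth, n_contigs)
    } else if (identical(cm$type, "two_strain")) {
      prob <- cm$prob %||% 0.5
      strain <- sample(c(1L, 2L), n_contigs, replace = TRUE,
                       prob = c(prob, 1 - prob))
      depth0 <- cm$depths[strain]
    } else {
      abort("coverage_model$type must be 'constant' or 'two_strain'")
    }
    sd_log <- cm$sd_log %||% 0
    depth <- depth0 * exp(rnorm(n_contigs, 0, sd_log))

    tibble(
      contig_id = sprintf("%s_c%03d", source_genome_id, seq_len(n_contigs)),
      start = starts,
      end = ends,
      length = lens,
      sequence = sequences,
      mean_coverage = depth,
      taxon_label = taxon_label,
      purity = purity,
      strain = strain,
      source_genome = source_genome_id
    )
  })
}

#' Plant single-copy marker intervals in a genome
#'
#' Places `m` non-overlapping intervals of `marker_len` bp at random
#' positions. The markers are single-copy by construction: dropping a
#' contig removes the markers it carries (completeness ground truth) and
#' duplicating a contig duplicates them (contamination ground truth). They
#' stand in for lineage-specific single-copy marker genes used by MAG
#' quality estimators.
#'
#' @param genome genome sequence (character string) or its length in bp.
#' @param m number of markers.
#' @param marker_len marker length in bp; `m * marker_len` must not exceed
#'   the genome length.
#' @param seed integer seed.
#' @return a tibble `marker_id`, `start`, `end` (1-based, inclusive,
#'   non-overlapping).
#' @export
plant_markers <- function(genome, m, marker_len, seed = 1L) {
  L <- if (is.character(genome)) nchar(genome) else as.integer(genome)
  m <- as.integer(m)
  if (m < 0) abort("m must be >= 0")
  if (m == 0) {
    return(tibble(marker_id = character(0), start = integer(0),
                  end = integer(0)))
  }
  if (m * marker_len > L) {
    abort(sprintf(
      "infeasible placement: %d markers of %d bp exceed genome length %d",
      m, marker_len, L
    ))
  }
  withr::with_seed(as.integer(seed), {
    slack <- L - m * marker_len
    cuts <- sort(runif(m))
    offs <- floor(diff(c(0, cuts)) * slack)
    gaps <- cumsum(offs)
    starts <- (seq_len(m) - 1L) * marker_len + gaps + 1L
    tibble(
      marker_id = sprintf("mk%04d", seq_len(m)),
      start = as.integer(starts),
      end = as.integer(starts + marker_len - 1L)
    )
  })
}
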