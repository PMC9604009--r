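#' Reference community-state-type archetype compositions
#'
#' Fixed reference composition vectors for the five vaginal community state
#' types (CSTs): I, II, III and V are dominated by *Lactobacillus crispatus*,
#' *L. gasseri*, *L. iners* and *L. jensenii* respectively, while IV is an
#' even mixture of obligate and facultative anaerobes (*Gardnerella*,
#' *Atopobium/Fannyhessea*, *Prevotella*, "*Ca.* Lachnocurva vaginae" and
#' others). The vectors are stand-ins for nearest-centroid CST reference
#' profiles: loosely modelled on the dominant taxa reported for
#' reproductive-age cohorts, not fitted centroids. A handful of rare taxa
#' carry tiny mass so that abundance-filtering steps have something to do.
#'
#' @return a tibble with one row per archetype (column `cst`) and one numeric
#'   column per phylotype; each row sums to 1.
#' @export
#' @examples
#' cst_archetypes()
cst_archetypes <- function() {
  taxa <- c(
    "Lactobacillus_crispatus", "Lactobacillus_gasseri", "Lactobacillus_iners",
    "Lactobacillus_jensenii", "Gardnerella_vaginalis", "Fannyhessea_vaginae",
    "Ca_Lachnocurva_vaginae", "Prevotella_bivia", "Prevotella_timonensis",
    "Sneathia_amnii", "Sneathia_sanguinegens", "Megasphaera_sp",
    "Mobiluncus_curtisii", "Dialister_micraerophilus",
    # rare background taxa (exercise the study-wide abundance filter)
    "Peptoniphilus_sp", "Anaerococcus_sp", "Finegoldia_magna",
    "Corynebacterium_sp", "Streptococcus_anginosus", "Ureaplasma_sp"
  )
  base <- rep(5e-5, length(taxa))
  names(base) <- taxa
  mk <- function(x) {
    v <- base
    v[names(x)] <- x
    v / sum(v)
  }
  rows <- list(
    I = mk(c(
      Lactobacillus_crispatus = 0.86, Lactobacillus_iners = 0.06,
      Lactobacillus_jensenii = 0.04, Gardnerella_vaginalis = 0.02,
      Streptococcus_anginosus = 0.005
    )),
    II = mk(c(
      Lactobacillus_gasseri = 0.82, Lactobacillus_crispatus = 0.06,
      Lactobacillus_iners = 0.05, Gardnerella_vaginalis = 0.04,
      Ureaplasma_sp = 0.005
    )),
    III = mk(c(
      Lactobacillus_iners = 0.85, Gardnerella_vaginalis = 0.07,
      Lactobacillus_crispatus = 0.03, Fannyhessea_vaginae = 0.02,
      Prevotella_bivia = 0.01
    )),
    IV = mk(c(
      Gardnerella_vaginalis = 0.26, Fannyhessea_vaginae = 0.14,
      Ca_Lachnocurva_vaginae = 0.14, Prevotella_bivia = 0.09,
      Prevotella_timonensis = 0.09, Sneathia_amnii = 0.06,
      Sneathia_sanguinegens = 0.04, Megasphaera_sp = 0.06,
      Mobiluncus_curtisii = 0.03, Dialister_micraerophilus = 0.03,
      Lactobacillus_iners = 0.05
    )),
    V = mk(c(
      Lactobacillus_jensenii = 0.81, Lactobacillus_crispatus = 0.07,
      Lactobacillus_iners = 0.05, Gardnerella_vaginalis = 0.03,
      Corynebacterium_sp = 0.005
    ))
  )
  out <- as_tibble(do.call(rbind, rows))
  dplyr::bind_cols(tibble(cst = names(rows)), out)
}

#' Describe a synthetic mother-daughter cohort
#'
#' Bundles and validates the parameters of the compositional cohort
#' generator. Defaults emulate a metropolitan mother-daughter cohort:
#' 40 families with one post-menarcheal daughter each (a minority of
#' families can be given 2-3 daughters via `daughters_per_family`),
#' CST frequencies weighted towards III and IV, and a 0.3 probability that
#' a mother-daughter pair truly shares its community (drawn from one
#' family-level composition rather than two independent ones).
#'
#' @param n_families number of families (>= 1).
#' @param daughters_per_family integer, recycled across families; each entry
#'   >= 1.
#' @param sharing_probability probability in `[0, 1]` that a mother-daughter
#'   pair is generated as truly sharing.
#' @param cst_weights named numeric vector of archetype weights over
#'   `c("I","II","III","IV","V")` (or the rows of `archetypes`); must sum
#'   to 1 within 1e-9. Used for mothers, and for daughters unless
#'   `daughter_cst_weights` is given.
#' @param daughter_cst_weights optional separate archetype weights for
#'   non-sharing daughters.
#' @param archetypes archetype composition tibble in the format of
#'   [cst_archetypes()]; defaults to it.
#' @param concentration_archetype Dirichlet concentration pulling a family's
#'   base composition towards its archetype (larger = tighter).
#' @param concentration_member Dirichlet concentration pulling an
#'   individual's profile towards its base composition; `Inf` copies the
#'   base exactly.
#' @param depth_meanlog,depth_sdlog log-normal parameters of per-sample
#'   sequencing depth (reads); defaults centre near 15,000 reads with a
#'   spread wide enough that occasional samples fall under typical
#'   minimum-read filters.
#' @param seed integer seed; every draw is a pure function of the design.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(n_families = 40,
                          daughters_per_family = 1,
                          sharing_probability = 0.3,
                          cst_weights = c(I = 0.25, II = 0.05, III = 0.30,
                                          IV = 0.30, V = 0.10),
                          daughter_cst_weights = NULL,
                          archetypes = cst_archetypes(),
                          concentration_archetype = 5,
                          concentration_member = 200,
                          depth_meanlog = log(15000),
                          depth_sdlog = 0.6,
                          seed = 1L) {
  if (!is.numeric(n_families) || n_families < 1) abort("n_families must be >= 1")
  if (any(daughters_per_family < 1)) abort("daughters_per_family entries must be >= 1")
  if (!is.numeric(sharing_probability) ||
      sharing_probability < 0 || sharing_probability > 1) {
    abort("sharing_probability must be in [0, 1]")
  }
  if (abs(sum(cst_weights) - 1) > 1e-9) {
    abort("cst_weights must sum to 1 (within 1e-9)")
  }
  if (!is.null(daughter_cst_weights) &&
      abs(sum(daughter_cst_weights) - 1) > 1e-9) {
    abort("daughter_cst_weights must sum to 1 (within 1e-9)")
  }
  if (!"cst" %in% names(archetypes)) abort("archetypes needs a 'cst' column")
  if (is.null(names(cst_weights))) names(cst_weights) <- archetypes$cst
  if (!all(names(cst_weights) %in% archetypes$cst)) {
    abort("cst_weights names must match archetype labels")
  }
  structure(
    list(
      n_families = as.integer(n_families),
      daughters_per_family = as.integer(
        rep_len(daughters_per_family, n_families)
      ),
      sharing_probability = sharing_probability,
      cst_weights = cst_weights,
      daughter_cst_weights = daughter_cst_weights %||% cst_weights,
      archetypes = archetypes,
      concentration_archetype = concentration_archetype,
      concentration_member = concentration_member,
      depth_meanlog = depth_meanlog,
      depth_sdlog = depth_sdlog,
      seed = as.integer(seed)
    ),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design>", x$n_families, "families,",
      sum(x$daughters_per_family), "daughters, sharing_probability =",
      x$sharing_probability, ", seed =", x$seed, "\n")
  invisible(x)
}

# one Dirichlet profile around `base` at concentration `conc`
draw_member <- function(base, conc) {
  if (is.infinite(conc)) return(base)
  drop(rdirichlet_mat(1, conc * base))
}

#' Generate a CST-structured mother-daughter profile table
#'
#' Simulates one 16S-style count profile per mother and per daughter.
#' Each family's mother draws an archetype from `cst_weights`, then a
#' family-level base composition from a Dirichlet centred on that
#' archetype. Mother-daughter pairs flagged as sharing (probability
#' `sharing_probability`) draw both members around the *same* base
#' composition; non-sharing daughters draw their own archetype and base.
#' Counts are multinomial at a log-normal per-sample depth. Random streams
#' are split per family, so extending the cohort never perturbs earlier
#' families.
#'
#' @param design a [cohort_design()].
#' @return a list with elements `profiles` (tibble: `sample_id`,
#'   `family_id`, `role`, `age`, then one count column per phylotype) and
#'   `truth` (tibble: `family_id`, `daughter_sample`, `mother_sample`,
#'   `sharing`, `mother_cst`, `daughter_cst`).
#' @export
#' @examples
#' cohort <- gen_profile_table(cohort_design(n_families = 5, seed = 42))
#' cohort$truth
gen_profile_table <- function(design) {
  if (!inherits(design, "cohort_design")) {
    abort("design must be a cohort_design object")
  }
  arch <- design$archetypes
  arch_m <- as.matrix(arch[, setdiff(names(arch), "cst"), drop = FALSE])
  rownames(arch_m) <- arch$cst
  taxa <- colnames(arch_m)

  fam <- purrr::map(seq_len(design$n_families), function(f) {
    withr::with_seed(split_seed(design$seed, f, salt = 1L), {
      fid <- sprintf("F%02d", f)
      nd <- design$daughters_per_family[f]
      m_cst <- sample(names(design$cst_weights), 1,
                      prob = design$cst_weights)
      m_base <- draw_member(arch_m[m_cst, ], design$concentration_archetype)
      m_prof <- draw_member(m_base, design$concentration_member)
      m_age <- round(runif(1, 32, 51))

      sharing <- runif(nd) < design$sharing_probability
      d <- purrr::map(seq_len(nd), function(j) {
        if (sharing[j]) {
          d_cst <- m_cst
          d_prof <- draw_member(m_base, design$concentration_member)
        } else {
          d_cst <- sample(names(design$daughter_cst_weights), 1,
                          prob = design$daughter_cst_weights)
          d_base <- draw_member(arch_m[d_cst, ],
                                design$concentration_archetype)
          d_prof <- draw_member(d_base, design$concentration_member)
        }
        list(cst = d_cst, prof = d_prof, age = round(runif(1, 14, 27)))
      })

      profs <- rbind(m_prof, do.call(rbind, purrr::map(d, "prof")))
      depths <- pmax(50, round(rlnorm(nrow(profs), design$depth_meanlog,
                                      design$depth_sdlog)))
      counts <- t(vapply(
        seq_len(nrow(profs)),
        function(i) drop(rmultinom(1, depths[i], profs[i, ])),
        numeric(ncol(profs))
      ))
      colnames(counts) <- taxa
      ids <- c(paste0(fid, "M"), paste0(fid, "D", seq_len(nd)))
      profiles <- dplyr::bind_cols(
        tibble(
          sample_id = ids,
          family_id = fid,
          role = c("mother", rep("daughter", nd)),
          age = c(m_age, vapply(d, function(z) z$age, numeric(1)))
        ),
        as_tibble(counts)
      )
      truth <- tibble(
        family_id = fid,
        daughter_sample = ids[-1],
        mother_sample = ids[1],
        sharing = sharing,
        mother_cst = m_cst,
        daughter_cst = vapply(d, function(z) z$cst, character(1))
      )
      list(profiles = profiles, truth = truth)
    })
  })

  list(
    profiles = dplyr::bind_rows(purrr::map(fam, "profiles")),
    truth = dplyr::bind_rows(purrr::map(fam, "truth"))
  )
}
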