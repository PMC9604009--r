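# small fixtures built in code, shared across test files

# a hand-sized profile table: 2 families, counts
tiny_profile_table <- function() {
  tibble::tibble(
    sample_id = c("F01M", "F01D1", "F02M", "F02D1"),
    family_id = c("F01", "F01", "F02", "F02"),
    role = c("mother", "daughter", "mother", "daughter"),
    age = c(40, 15, 45, 18),
    Lactobacillus_crispatus = c(800, 700, 10, 5),
    Lactobacillus_iners = c(100, 200, 100, 80),
    Gardnerella_vaginalis = c(100, 100, 890, 915)
  )
}

# brute-force Yue-Clayton theta, written independently of the package
theta_oracle <- function(p, q) {
  num <- 0; sp <- 0; sq <- 0
  for (i in seq_along(p)) {
    num <- num + p[i] * q[i]
    sp <- sp + p[i]^2
    sq <- sq + q[i]^2
  }
  num / (sp + sq - num)
}

# random point on the simplex
random_simplex <- function(k) {
  x <- -log(runif(k))
  x / sum(x)
}

# position-by-position Hamming difference of two equal-length strings
hamming_diff <- function(a, b) {
  which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# exhaustive-enumeration Wilcoxon rank-sum: statistic W (rank sum of x
# minus n1(n1+1)/2) and two-sided p over all label assignments
wilcoxon_enum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  all_vals <- c(x, y)
  r <- rank(all_vals)
  W_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  Ws <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- mean(Ws)
  p <- mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-12)
  list(W = W_obs, p = p)
}

# manifest + MAG table for a toy all-vs-all cohort; k_shared planted
# transmissions at small divergence, everyone else unrelated
toy_strain_cohort <- function(n_families = 4, k_shared = 2, L = 2e4,
                              mu = 1e-5, age = 15, seed = 100) {
  manifest <- tibble::tibble(
    participant_id = c(rbind(sprintf("F%02dM", 1:n_families),
                             sprintf("F%02dD", 1:n_families))),
    family_id = rep(sprintf("F%02d", 1:n_families), each = 2),
    role = rep(c("mother", "daughter"), n_families),
    age = rep(c(40, age), n_families)
  )
  mags <- list()
  for (f in seq_len(n_families)) {
    fid <- sprintf("F%02d", f)
    if (f <= k_shared) {
      lp <- evolve_pair(L, mu = mu, t_years = age, seed = seed + f)
      ga <- lp$genome_a; gb <- lp$genome_b
    } else {
      ga <- random_genome(L, seed = seed + 1000 + f)
      gb <- random_genome(L, seed = seed + 2000 + f)
    }
    mags[[length(mags) + 1]] <- tibble::tibble(
      participant_id = paste0(fid, "M"), mag_id = paste0(fid, "M_mag"),
      taxon_label = "Lactobacillus_crispatus", sequence = ga
    )
    mags[[length(mags) + 1]] <- tibble::tibble(
      participant_id = paste0(fid, "D"), mag_id = paste0(fid, "D_mag"),
      taxon_label = "Lactobacillus_crispatus", sequence = gb
    )
  }
  list(manifest = manifest, mags = dplyr::bind_rows(mags))
}
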