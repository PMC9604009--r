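#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows across all_of row_number n
#' @importFrom stats rpois rgamma rlnorm rmultinom runif quantile ks.test
#'   wilcox.test t.test rnorm setNames
NULL

# metadata columns that every profile table carries ahead of the phylotypes
PROFILE_META_COLS <- c("sample_id", "family_id", "role", "age")

DNA_BASES <- c("A", "C", "G", "T")

#' Deterministic child seed for a named random stream
#'
#' Generators split their seed per family / per lineage so that adding one
#' more unit of work never perturbs the draws of earlier units. The split is
#' a fixed integer hash of (seed, index, salt), kept inside 32-bit range.
#'
#' @param seed parent integer seed.
#' @param index integer index of the stream (family number, lineage number).
#' @param salt small integer separating stream kinds.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
split_seed <- function(seed, index, salt = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(index) * 16807 +
    as.numeric(salt) * 69621 + 1
  as.integer(s %% (m - 1) + 1)
}

# Dirichlet draws by gamma normalisation; alpha entries of 0 stay exactly 0.
rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(0, n, k)
  pos <- alpha > 0
  x[, pos] <- matrix(
    rgamma(n * sum(pos), shape = rep(alpha[pos], each = n)),
    n, sum(pos)
  )
  sw <- rowSums(x)
  sw[sw == 0] <- 1
  x / sw
}

# phylotype (abundance) columns of a profile table
phylotype_cols <- function(tbl) {
  setdiff(names(tbl), PROFILE_META_COLS)
}

# numeric matrix of abundances, rownames = sample ids
profile_matrix <- function(tbl) {
  cols <- phylotype_cols(tbl)
  m <- as.matrix(tbl[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tbl$sample_id
  m
}

# row-normalise a profile table to relative abundances
normalize_profiles <- function(tbl) {
  cols <- phylotype_cols(tbl)
  m <- profile_matrix(tbl)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    abort("cannot normalize: some samples have zero total abundance")
  }
  tbl[, cols] <- as_tibble(m / tot)
  tbl
}

is_count_table <- function(tbl) {
  m <- profile_matrix(tbl)
  max(rowSums(m)) > 1 + 1e-6
}

check_profile_table <- function(tbl, call = rlang::caller_env()) {
  miss <- setdiff(PROFILE_META_COLS, names(tbl))
  if (length(miss) > 0) {
    abort(
      paste0("profile table is missing metadata columns: ",
             paste(miss, collapse = ", ")),
      call = call
    )
  }
  cols <- phylotype_cols(tbl)
  if (length(cols) == 0) abort("profile table has no phylotype columns", call = call)
  bad <- cols[!vapply(tbl[cols], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("non-numeric abundance columns: ", paste(bad, collapse = ", ")),
          call = call)
  }
  if (any(profile_matrix(tbl) < 0)) abort("negative abundances found", call = call)
  dup <- tbl$sample_id[duplicated(tbl$sample_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sample_id: ", paste(unique(dup), collapse = ", ")),
          call = call)
  }
  invisible(tbl)
}
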