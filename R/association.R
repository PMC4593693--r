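#' Dyadic sufficient statistics from sampling periods
#'
#' Reduces binary sampling-period observations to the per-dyad counts that
#' every estimator in the package consumes: `d`, the number of sampling units
#' in which the dyad was together, and `s`, the number of units in which the
#' dyad was sampled at all. For simulated sampling periods every dyad is
#' sampled in every period, so `s` equals the number of periods.
#'
#' @param obs A `sampling_periods` object from [sample_observations()].
#' @return A `dyad_counts` tibble with columns `node_i`, `node_j`, `d`, `s`;
#'   node IDs and the number of sampling units are carried as attributes.
#' @examples
#' net <- generate_true_network(5, seed = 1)
#' sample_observations(net, 20, seed = 2) |> counts_from_periods() |> sri()
#' @export
counts_from_periods <- function(obs) {
  stopifnot(inherits(obs, "sampling_periods"))
  idx <- dyad_index(length(obs$node_ids))
  new_edge_tbl(
    tibble::tibble(
      node_i = obs$node_ids[idx$i],
      node_j = obs$node_ids[idx$j],
      d = as.integer(colSums(obs$together)),
      s = obs$n_periods
    ),
    obs$node_ids, "dyad_counts",
    n_units = obs$n_periods
  )
}

#' Dyadic sufficient statistics from a group-by-individual matrix
#'
#' Gambit-of-the-group data record which individuals co-occurred in each
#' observed group (e.g. a foraging flock). Each group is one sampling unit:
#' a dyad is together (`d`) in every group containing both individuals, and
#' sampled (`s`) in every group containing at least one of them. The SRI
#' computed from these counts is the probability the two were observed
#' together given at least one was observed.
#'
#' @param gbi A K x N binary matrix or data frame (rows = groups, columns =
#'   individuals) with individual IDs as column names.
#' @return A `dyad_counts` tibble (see [counts_from_periods()]).
#' @examples
#' gbi <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 1, 0))
#' colnames(gbi) <- c("A", "B", "C")
#' counts_from_gbi(gbi) |> sri()
#' @export
counts_from_gbi <- function(gbi) {
  m <- as.matrix(gbi)
  storage.mode(m) <- "numeric"
  if (is.null(colnames(m))) colnames(m) <- sprintf("n%02d", seq_len(ncol(m)))
  if (anyDuplicated(colnames(m))) abort("duplicate individual IDs in GBI columns")
  if (any(is.na(m)) || !all(m %in% c(0, 1))) abort("GBI entries must be 0/1")
  if (ncol(m) < 2) abort("need at least 2 individuals")
  ids <- colnames(m)
  idx <- dyad_index(ncol(m))
  both <- crossprod(m)                 # groups containing both i and j
  seen <- colSums(m)                   # groups containing each individual
  d <- both[cbind(idx$i, idx$j)]
  s <- seen[idx$i] + seen[idx$j] - d   # inclusion-exclusion: i or j present
  new_edge_tbl(
    tibble::tibble(node_i = ids[idx$i], node_j = ids[idx$j],
                   d = as.integer(d), s = as.integer(s)),
    ids, "dyad_counts",
    n_units = nrow(m)
  )
}

#' Assemble dyadic counts from a data frame
#'
#' Constructor for user-supplied dyadic data: one row per unordered dyad
#' with columns `node_i`, `node_j`, `d` (times together) and `s` (times
#' sampled).
#'
#' @param df A data frame with columns `node_i`, `node_j`, `d`, `s`.
#' @return A `dyad_counts` tibble.
#' @export
dyad_counts <- function(df) {
  req <- c("node_i", "node_j", "d", "s")
  if (!all(req %in% names(df))) abort("need columns node_i, node_j, d, s")
  ids <- unique(c(df$node_i, df$node_j))
  out <- new_edge_tbl(
    tibble::tibble(node_i = as.character(df$node_i),
                   node_j = as.character(df$node_j),
                   d = as.integer(df$d), s = as.integer(df$s)),
    ids, "dyad_counts",
    n_units = max(df$s)
  )
  validate_counts(out)
}

validate_counts <- function(counts) {
  if (!inherits(counts, "dyad_counts")) abort("expected a `dyad_counts` table")
  if (any(counts$d > counts$s) || any(counts$d < 0))
    abort("invalid counts: need 0 <= d <= s for every dyad")
  invisible(counts)
}

#' Simple ratio index network
#'
#' Computes the simple ratio index (SRI) `d / s` for every dyad: the observed
#' probability that the two individuals were together given that at least one
#' was sampled. Dyads that were never sampled (`s = 0`, possible only with
#' group-by-individual input) get an SRI of 0 together with an `unsampled`
#' flag, so "never seen together" and "never sampled" stay distinguishable
#' downstream; unsampled dyads are excluded from empirical-prior fitting.
#'
#' @param counts A `dyad_counts` tibble.
#' @return An `sri_network` tibble: `node_i`, `node_j`, `d`, `s`, `weight`,
#'   `unsampled`. Use [as_adjacency_matrix()] for the matrix form.
#' @export
sri <- function(counts) {
  validate_counts(counts)
  new_edge_tbl(
    dplyr::mutate(tibble::as_tibble(counts),
                  weight = ifelse(.data$s > 0, .data$d / pmax(.data$s, 1L), 0),
                  unsampled = .data$s == 0L),
    node_ids_of(counts), "sri_network",
    n_units = attr(counts, "n_units", exact = TRUE)
  )
}

#' Read a group-by-individual matrix from CSV
#'
#' Expects rows = observed groups, columns = individuals, 0/1 entries, and a
#' header row of individual IDs.
#'
#' @param path CSV file path.
#' @return A binary matrix suitable for [counts_from_gbi()].
#' @export
read_gbi <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "numeric"
  m
}
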