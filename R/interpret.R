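as_params <- function(model) {
  if (inherits(model, "average_rbm")) model$params
  else if (inherits(model, "trained_rbm")) model$params
  else if (inherits(model, "rbm_params")) model
  else stop("expected an rbm_params, trained_rbm or average_rbm", call. = FALSE)
}

#' Hidden-state frequencies over a dataset
#'
#' The frequency of each of the `2^N_h` hidden states is the dataset
#' average of the posterior `prod_j p(h_j = s_j | v)` -- i.e. how often the
#' model is "in" that state when shown the data.  The model prior `p(h)`
#' (exact marginal) is reported alongside for comparison.
#'
#' @param model An [rbm_params], `trained_rbm` or `average_rbm`.
#' @param samples Stretch table or spin matrix (non-empty).
#' @returns Tibble with `state` (list-column), `state_label`, `frequency`
#'   (posterior average, sums to 1) and `prior` (exact model marginal).
#' @export
state_frequencies <- function(model, samples) {
  params <- as_params(model)
  check_exact_nh(params)
  if (is.data.frame(samples)) samples <- encode_one_hot(samples)
  samples <- as_spin_matrix(samples, params$n_visible)
  if (nrow(samples) == 0) stop("empty dataset", call. = FALSE)
  p <- hidden_conditional(params, samples)          # n x N_h, P(h_j = +1 | v)
  H <- hidden_states(params$n_hidden)
  lp <- log(p); lq <- log1p(-p)
  up <- t(H > 0)                                    # N_h x 2^K
  f <- colMeans(exp(lp %*% up + lq %*% (!up)))
  marg <- exact_hidden_marginal(params)
  tibble::tibble(state = marg$state, state_label = marg$state_label,
                 frequency = f, prior = marg$prob)
}

#' Per-state residue probability tables
#'
#' For every hidden state `s`, the `20 x Gamma` column-stochastic table
#' whose column `gamma` is the block conditional `p(k | h = s)`.
#'
#' @inheritParams state_frequencies
#' @returns Tibble with `state`, `state_label` and list-column `table`
#'   (each a `20 x Gamma` matrix, rows named by [aa_alphabet]).
#' @export
state_tables <- function(model) {
  params <- as_params(model)
  check_exact_nh(params)
  H <- hidden_states(params$n_hidden)
  tibble::tibble(
    state = lapply(seq_len(nrow(H)), function(i) H[i, ]),
    state_label = apply(H, 1, state_label),
    table = lapply(seq_len(nrow(H)), function(i) {
      block_probs(params, H[i, , drop = FALSE])
    }))
}

#' Decompose a model into ranked hidden-state modes
#'
#' Combines [state_frequencies()] and [state_tables()] and ranks the
#' states by decreasing frequency (ties broken by lexicographic state
#' order, `+1` before `-1`), labelling them `S1`, `S2`, ....
#'
#' @inheritParams state_frequencies
#' @param prefix Label prefix (default `"S"`).
#' @returns A tibble of class `state_decomposition` with columns `label`,
#'   `state`, `state_label`, `frequency`, `prior`, `table`, ordered by
#'   rank.
#' @export
state_decomposition <- function(model, samples, prefix = "S") {
  freq <- state_frequencies(model, samples)
  tabs <- state_tables(model)
  out <- dplyr::bind_cols(freq, tabs["table"])
  # hidden_states() is already lexicographic, so order() ties resolve to it
  out <- out[order(-out$frequency), ]
  out$label <- paste0(prefix, seq_len(nrow(out)))
  out <- out[c("label", "state", "state_label", "frequency", "prior", "table")]
  class(out) <- c("state_decomposition", class(out))
  out
}

#' Mixture reconstruction of the single-site statistics
#'
#' The frequency-weighted average `sum_s f_s P_s` of the per-state residue
#' tables: the model's prediction for the probability of each amino acid
#' at each position.
#'
#' @param decomposition A `state_decomposition` (or any tibble with
#'   `frequency` and `table` columns).
#' @returns A `20 x Gamma` column-stochastic matrix.
#' @export
mixture_reconstruction <- function(decomposition) {
  stopifnot(all(c("frequency", "table") %in% names(decomposition)))
  Reduce(`+`, purrr::map2(decomposition$frequency, decomposition$table, `*`))
}

#' Empirical residue frequencies
#'
#' Column-normalised counts of amino acids at each of the `Gamma`
#' positions of a sample set.
#'
#' @param samples Stretch table or spin matrix.
#' @returns A `20 x Gamma` column-stochastic matrix (rows = [aa_alphabet]).
#' @export
empirical_frequencies <- function(samples) {
  if (is.data.frame(samples)) samples <- encode_one_hot(samples)
  if (is.null(dim(samples)) || nrow(samples) == 0) stop("empty dataset", call. = FALSE)
  gamma <- ncol(samples) %/% 20L
  counts <- colSums(samples == 1)
  m <- matrix(counts, nrow = 20L)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- aa_alphabet
  colnames(m) <- seq_len(gamma)
  m
}

#' Compare two frequency tables by per-position total variation
#'
#' @param table_a,table_b `20 x Gamma` column-stochastic matrices.
#' @returns Tibble with `position`, `tv` (half the L1 distance of the
#'   columns); attribute `max_tv`.
#' @export
compare_frequency_tables <- function(table_a, table_b) {
  if (!all(dim(table_a) == dim(table_b))) {
    stop("tables have different shapes", call. = FALSE)
  }
  tv <- colSums(abs(table_a - table_b)) / 2
  out <- tibble::tibble(position = seq_along(tv), tv = unname(tv))
  attr(out, "max_tv") <- max(tv)
  out
}

#' Two-site correlations of one-hot indicators
#'
#' The classical baseline: the `(20 Gamma)^2` matrix of pairwise Pearson
#' correlations between the one-hot indicator variables across samples.
#' Within-block pairs are negative by one-hot exclusivity; the diagonal is
#' 1.  Indicators with zero variance (a residue never / always seen at a
#' position) give `NA` off the diagonal.
#'
#' @param samples Stretch table or spin matrix (>= 2 samples).
#' @returns A symmetric `20*Gamma` square matrix with unit diagonal;
#'   dimnames `"<residue><position>"`.
#' @export
two_site_correlations <- function(samples) {
  if (is.data.frame(samples)) samples <- encode_one_hot(samples)
  if (is.null(dim(samples)) || nrow(samples) < 2) {
    stop("need at least 2 samples", call. = FALSE)
  }
  gamma <- ncol(samples) %/% 20L
  r <- suppressWarnings(stats::cor(samples))
  diag(r) <- 1
  nm <- paste0(rep(aa_alphabet, gamma), rep(seq_len(gamma), each = 20L))
  dimnames(r) <- list(nm, nm)
  r
}
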