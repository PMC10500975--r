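# Exact small-model quantities: these enumerate the 2^N_h hidden states and
# are therefore restricted to N_h <= 12.

MAX_EXACT_HIDDEN <- 12L

check_exact_nh <- function(params) {
  if (params$n_hidden > MAX_EXACT_HIDDEN) {
    stop("exact enumeration requires N_h <= ", MAX_EXACT_HIDDEN,
         " (got ", params$n_hidden, ")", call. = FALSE)
  }
}

#' All hidden spin states
#'
#' @param n_hidden Number of hidden units (<= 12).
#' @returns A `2^n_hidden x n_hidden` matrix of `+1/-1` rows, in
#'   lexicographic order with `+1` before `-1`.
#' @export
hidden_states <- function(n_hidden) {
  if (n_hidden == 0) return(matrix(numeric(), nrow = 1, ncol = 0))
  g <- expand.grid(rep(list(c(1, -1)), n_hidden))[, rev(seq_len(n_hidden)), drop = FALSE]
  m <- as.matrix(g)
  dimnames(m) <- NULL
  m[order(-m %*% 2^((n_hidden - 1):0)), , drop = FALSE]
}

logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

# Per-hidden-state log weight of the one-hot-restricted model:
# s(h) = (b - c).h - sum_i a_i + sum_gamma log sum_k exp(2 phi_k(h)),
# where c_j = sum_i w_ij collects the -1 background of each one-hot block.
state_log_weights <- function(params) {
  check_exact_nh(params)
  H <- hidden_states(params$n_hidden)
  cc <- colSums(params$w)
  phi2 <- 2 * local_fields(params, H)                      # 2^K x N_v
  lse <- vapply(seq_len(params$gamma), function(g) {
    blk <- phi2[, visible_index(g, 1:20), drop = FALSE]
    mx <- matrixStats_rowMaxs(blk)
    mx + log(rowSums(exp(blk - mx)))
  }, numeric(nrow(H)))
  lse <- matrix(lse, nrow = nrow(H))
  drop(H %*% (params$b - cc)) - sum(params$a) + rowSums(lse)
}

#' Exact log partition function
#'
#' Sums the Boltzmann weight `exp(-E(v, h))` over all one-hot visible
#' configurations and all `2^N_h` hidden states.  The visible sum is done
#' analytically per block; only the hidden states are enumerated, so the
#' model must have `N_h <= 12`.
#'
#' @param params An [rbm_params] object.
#' @returns `log Z` as a single number.
#' @export
exact_log_partition <- function(params) {
  logsumexp(state_log_weights(params))
}

#' Exact hidden-state marginal
#'
#' `p(h)` of the one-hot-restricted model, by enumeration.
#'
#' @inheritParams exact_log_partition
#' @returns Tibble with the state matrix (`state`, list-column of spin
#'   vectors), a compact `state_label` such as `"(+1 -1)"`, and `prob`.
#' @export
exact_hidden_marginal <- function(params) {
  lw <- state_log_weights(params)
  H <- hidden_states(params$n_hidden)
  tibble::tibble(
    state = lapply(seq_len(nrow(H)), function(i) H[i, ]),
    state_label = apply(H, 1, state_label),
    prob = exp(lw - logsumexp(lw))
  )
}

state_label <- function(h) paste0("(", paste(ifelse(h > 0, "+1", "-1"), collapse = " "), ")")

#' Generate sequences from an RBM
#'
#' Exact ancestral sampling: hidden states are drawn from their exact
#' marginal (enumerated over `2^N_h` states, no burn-in), then each residue
#' block is drawn from its categorical conditional given `h`.
#'
#' @inheritParams exact_log_partition
#' @param n_samples Number of sequences to generate.
#' @param seed Integer seed.
#' @returns A stretch table of generated sequences (`element_kind` and
#'   `terminus` set to `"generated"`/`"start"`, `protein_id = "rbm"`).
#' @export
rbm_generate <- function(params, n_samples, seed = 1L) {
  check_exact_nh(params)
  marg <- exact_hidden_marginal(params)
  H <- hidden_states(params$n_hidden)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (n_samples == 0) {
    return(stretch_table(character(), element_kind = "generated"))
  }
  s_idx <- sample.int(nrow(H), n_samples, replace = TRUE, prob = marg$prob)
  v <- matrix(-1, nrow = n_samples, ncol = params$n_visible)
  for (s in sort(unique(s_idx))) {
    rows <- which(s_idx == s)
    v[rows, ] <- sample_visible(params, H[rep(s, length(rows)), , drop = FALSE])
  }
  stretch_table(decode_one_hot(v), protein_id = "rbm",
                element_kind = "generated", terminus = "start")
}

#' Pseudo-log-likelihood
#'
#' Mean over samples of `sum_gamma log p(k_gamma | v_{-gamma})`: for each
#' residue position the exact conditional probability of the observed
#' residue given all other positions, computed from the free energy by
#' renormalising over the 20 candidate residues of that block (the hidden
#' layer is marginalised analytically).  Reported in nats per sample; the
#' zero-parameter model gives `Gamma * log(1/20)`.
#'
#' @param params An [rbm_params] object with `N_h <=` 12 (the exact hidden
#'   marginalisation bound).
#' @param v Spin matrix of samples (or a stretch table, which is encoded).
#' @returns Mean PLL (single number), with attribute `per_sample` holding
#'   the individual values.
#' @export
pseudo_log_likelihood <- function(params, v) {
  if (is.data.frame(v)) v <- encode_one_hot(v)
  v <- as_spin_matrix(v, params$n_visible)
  check_exact_nh(params)
  n <- nrow(v)
  if (n == 0) stop("no samples", call. = FALSE)
  u <- hidden_input(params, v)                       # n x N_h
  av <- drop(v %*% params$a)
  total <- numeric(n)
  for (g in seq_len(params$gamma)) {
    cols <- visible_index(g, 1:20)
    kk <- max.col(v[, cols, drop = FALSE])           # observed residue index
    wb <- params$w[cols, , drop = FALSE]             # 20 x N_h
    ab <- params$a[cols]
    # baseline: block set entirely to -1
    u0 <- u - 2 * wb[kk, , drop = FALSE]
    a0 <- av - 2 * ab[kk]
    s <- vapply(1:20, function(l) {
      a0 + 2 * ab[l] + rowSums(log2cosh(u0 + rep(2 * wb[l, ], each = n)))
    }, numeric(n))
    s <- matrix(s, nrow = n)
    mx <- matrixStats_rowMaxs(s)
    total <- total + s[cbind(seq_len(n), kk)] - mx - log(rowSums(exp(s - mx)))
  }
  out <- mean(total)
  attr(out, "per_sample") <- total
  out
}

#' Exact mean log-likelihood and its gradient
#'
#' For models small enough to enumerate the hidden states exactly
#' (`N_h <= 12`), the mean data log-likelihood
#' `mean(-F(v)) - log Z` and its analytic gradient
#' `<moment>_data - <moment>_model` for `w`, `a` and `b`.  Data-side hidden
#' statistics are the exact expectations `tanh(u_j)`; model-side moments
#' are computed from the enumerated hidden marginal and the per-block
#' conditionals.
#'
#' @inheritParams pseudo_log_likelihood
#' @returns A list with `loglik` and gradients `dw`, `da`, `db`.
#' @export
exact_loglik_grad <- function(params, v) {
  if (is.data.frame(v)) v <- encode_one_hot(v)
  v <- as_spin_matrix(v, params$n_visible)
  check_exact_nh(params)
  n <- nrow(v)
  loglik <- mean(-free_energy(params, v)) - exact_log_partition(params)

  th <- tanh(hidden_input(params, v))                # n x N_h
  data_vh <- crossprod(v, th) / n                    # N_v x N_h
  data_v <- colMeans(v)
  data_h <- colMeans(th)

  marg <- exact_hidden_marginal(params)
  H <- hidden_states(params$n_hidden)
  p <- marg$prob
  # E[v_i | h] = 2 * blockprob_i - 1 for the one-hot block containing i
  Ev_h <- t(vapply(seq_len(nrow(H)), function(s) {
    2 * as.vector(block_probs(params, H[s, , drop = FALSE])) - 1
  }, numeric(params$n_visible)))                     # 2^K x N_v
  model_v <- drop(p %*% Ev_h)
  model_h <- drop(p %*% H)
  model_vh <- t(Ev_h * p) %*% H                      # N_v x N_h

  list(loglik = loglik,
       dw = data_vh - model_vh,
       da = data_v - model_v,
       db = data_h - model_h)
}
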