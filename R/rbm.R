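#' Spin-RBM parameters
#'
#' A restricted Boltzmann machine over `N_v = 20 * Gamma` visible spins
#' (one-hot residue blocks) and `N_h` hidden spins, all valued in
#' `{-1, +1}`.  The statistical weight of a configuration `(v, h)` is
#' `exp(-E)` with energy
#' `E(v, h) = - sum_i a_i v_i - sum_j b_j h_j - sum_ij w_ij v_i h_j`.
#'
#' @param w `N_v x N_h` weight matrix.
#' @param a Visible bias vector (length `N_v`, `N_v` divisible by 20).
#' @param b Hidden bias vector (length `N_h`).
#' @returns An object of class `rbm_params` (list with `w`, `a`, `b`,
#'   `gamma`, `n_visible`, `n_hidden`).
#' @export
rbm_params <- function(w, a, b) {
  w <- as.matrix(w)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (nrow(w) != length(a) || ncol(w) != length(b)) {
    stop("inconsistent parameter shapes: w is ", nrow(w), "x", ncol(w),
         ", a has length ", length(a), ", b has length ", length(b),
         call. = FALSE)
  }
  if (length(a) %% 20 != 0) stop("N_v must be divisible by 20", call. = FALSE)
  if (!all(is.finite(w)) || !all(is.finite(a)) || !all(is.finite(b))) {
    stop("non-finite RBM parameter", call. = FALSE)
  }
  structure(list(w = unname(w), a = unname(a), b = unname(b),
                 gamma = length(a) %/% 20L,
                 n_visible = length(a), n_hidden = length(b)),
            class = "rbm_params")
}

#' @export
print.rbm_params <- function(x, ...) {
  cat("<rbm_params> N_v =", x$n_visible, "(Gamma =", x$gamma,
      "blocks), N_h =", x$n_hidden, "\n")
  invisible(x)
}

as_spin_matrix <- function(v, n_visible) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  if (ncol(v) != n_visible) {
    stop("visible configuration has ", ncol(v), " units, model expects ",
         n_visible, call. = FALSE)
  }
  v
}

as_hidden_matrix <- function(h, n_hidden) {
  if (is.null(dim(h))) h <- matrix(h, nrow = 1)
  if (ncol(h) != n_hidden) {
    stop("hidden configuration has ", ncol(h), " units, model expects ",
         n_hidden, call. = FALSE)
  }
  h
}

# log(2*cosh(x)), overflow-safe
log2cosh <- function(x) abs(x) + log1p(exp(-2 * abs(x)))

#' RBM energy
#'
#' `E(v, h) = - a.v - b.h - v' W h`; the Boltzmann weight of `(v, h)` is
#' proportional to `exp(-E)`.
#'
#' @param params An [rbm_params] object.
#' @param v Visible spin vector or matrix (rows = configurations).
#' @param h Hidden spin vector or matrix (rows matched to `v`).
#' @returns Numeric vector of energies, one per row.
#' @export
rbm_energy <- function(params, v, h) {
  v <- as_spin_matrix(v, params$n_visible)
  h <- as_hidden_matrix(h, params$n_hidden)
  if (nrow(v) != nrow(h)) {
    if (nrow(v) == 1) v <- v[rep(1, nrow(h)), , drop = FALSE]
    else if (nrow(h) == 1) h <- h[rep(1, nrow(v)), , drop = FALSE]
    else stop("v and h must have matching numbers of rows", call. = FALSE)
  }
  -(drop(v %*% params$a) + drop(h %*% params$b) +
      rowSums((v %*% params$w) * h))
}

# Hidden-unit inputs u_j = b_j + sum_i w_ij v_i, one row per sample.
hidden_input <- function(params, v) {
  v <- as_spin_matrix(v, params$n_visible)
  u <- v %*% params$w
  u + rep(params$b, each = nrow(u))
}

#' Hidden-unit conditional probabilities
#'
#' With spin units, `p(h_j = +1 | v) = exp(u_j) / (2 cosh u_j)` where
#' `u_j = b_j + sum_i w_ij v_i`; computed in the overflow-safe logistic
#' form `1 / (1 + exp(-2 u_j))`.
#'
#' @inheritParams rbm_energy
#' @returns Matrix (`nrow(v) x N_h`) of probabilities in (0, 1).
#' @export
hidden_conditional <- function(params, v) {
  stats::plogis(2 * hidden_input(params, v))
}

#' Local fields on the visible units
#'
#' `phi_i(h) = a_i + sum_j w_ij h_j`.
#'
#' @inheritParams rbm_energy
#' @returns Matrix (`nrow(h) x N_v`) of local fields.
#' @export
local_fields <- function(params, h) {
  h <- as_hidden_matrix(h, params$n_hidden)
  phi <- h %*% t(params$w)
  phi + rep(params$a, each = nrow(phi))
}

#' Per-block residue probabilities given a hidden state
#'
#' Within the 20-unit block of position `gamma`, flipping the one-hot spin
#' from residue `l` to residue `k` changes the energy by `2(phi_l - phi_k)`,
#' so the conditional over the 20 candidate residues is the softmax of
#' `2 phi_k(h)` restricted to the block; columns sum to 1.
#'
#' @inheritParams rbm_energy
#' @param gamma Optional block index (1-based).  If `NULL`, probabilities
#'   for all blocks are returned.
#' @returns For a single hidden state: a `20 x Gamma` matrix (rows named by
#'   [aa_alphabet]); with `gamma` given, the single 20-vector column.
#' @export
block_probs <- function(params, h, gamma = NULL) {
  h <- as_hidden_matrix(h, params$n_hidden)
  if (nrow(h) != 1) stop("block_probs expects a single hidden state", call. = FALSE)
  phi <- 2 * drop(local_fields(params, h))
  m <- matrix(phi, nrow = 20L)
  m <- exp(sweep(m, 2, apply(m, 2, max)))
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- aa_alphabet
  colnames(m) <- seq_len(params$gamma)
  if (is.null(gamma)) return(m)
  if (gamma < 1 || gamma > params$gamma) stop("gamma out of range", call. = FALSE)
  m[, gamma]
}

#' Sample hidden units given visible spins
#'
#' Independent per-unit draws from [hidden_conditional()].  Uses R's
#' global random number stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @inheritParams rbm_energy
#' @returns Matrix of `+1/-1` hidden spins, one row per row of `v`.
#' @export
sample_hidden <- function(params, v) {
  p <- hidden_conditional(params, v)
  matrix(ifelse(stats::runif(length(p)) < p, 1, -1), nrow = nrow(p))
}

#' Sample visible one-hot blocks given hidden spins
#'
#' Draws each of the `Gamma` residue blocks independently from its
#' categorical conditional (softmax of `2 phi` within the block), so the
#' one-hot manifold is preserved exactly.
#'
#' @inheritParams rbm_energy
#' @returns Spin matrix of shape `nrow(h) x N_v`.
#' @export
sample_visible <- function(params, h) {
  h <- as_hidden_matrix(h, params$n_hidden)
  m <- nrow(h)
  gamma <- params$gamma
  phi2 <- 2 * local_fields(params, h)             # m x N_v
  # stack blocks: (m*gamma) x 20, block-major (rows 1..m are block 1)
  p <- matrix(0, m * gamma, 20L)
  for (g in seq_len(gamma)) {
    p[((g - 1L) * m + 1L):(g * m), ] <- phi2[, visible_index(g, 1:20)]
  }
  if (max(p) > 500) p <- p - matrixStats_rowMaxs(p)  # only center when needed
  p <- exp(p)
  p <- p / rowSums(p)
  cs <- p %*% upper.tri(diag(20L), diag = TRUE)   # row-wise cumulative sums
  k <- 1L + as.integer(rowSums(cs < stats::runif(nrow(p))))
  v <- matrix(-1, nrow = m, ncol = params$n_visible)
  blk <- rep(seq_len(gamma), each = m)
  row <- rep(seq_len(m), times = gamma)
  v[cbind(row, visible_index(blk, k))] <- 1
  v
}

# rowMaxs without matrixStats
matrixStats_rowMaxs <- function(x) do.call(pmax, as.data.frame(x))

#' Free energy of visible configurations
#'
#' `F(v) = - a.v - sum_j log(2 cosh(b_j + sum_i w_ij v_i))`, so that
#' `p(v) = exp(-F(v)) / Z` after summing out the hidden spins.
#'
#' @inheritParams rbm_energy
#' @returns Numeric vector, one free energy per row of `v`.
#' @export
free_energy <- function(params, v) {
  v <- as_spin_matrix(v, params$n_visible)
  -(drop(v %*% params$a) + rowSums(log2cosh(hidden_input(params, v))))
}

#' Gauge flip of hidden units
#'
#' Flipping `(w_.j, b_j) -> (-w_.j, -b_j)` together with `h_j -> -h_j`
#' leaves the energy, and hence `p(v)`, unchanged.  This helper applies the
#' parameter half of the flip for the given units.
#'
#' @inheritParams rbm_energy
#' @param units Integer indices of hidden units to flip.
#' @returns A new [rbm_params] object.
#' @export
gauge_flip <- function(params, units) {
  w <- params$w; b <- params$b
  w[, units] <- -w[, units]
  b[units] <- -b[units]
  rbm_params(w, params$a, b)
}
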