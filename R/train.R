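#' Training configuration
#'
#' Defaults: Adam with learning rate 5e-3 and the standard moment decays
#' (0.9 / 0.999), minibatches of 128, CD-1, weights initialised i.i.d.
#' Gaussian with sd `init_scale = 0.01`, biases zero.  With
#' `persistent = TRUE` the model-side Gibbs chains (one per minibatch
#' slot) persist across updates and epochs (PCD-n).
#'
#' @param cd_steps Number of alternating block-Gibbs steps `n` in CD-n.
#' @param persistent Use persistent chains (PCD-n)?
#' @param epochs Training epochs.
#' @param learning_rate Adam step size.
#' @param final_learning_rate Optional end-of-training step size: when set,
#'   the learning rate is annealed linearly from `learning_rate` (epoch 1)
#'   to this value (last epoch).  Because Adam's normalised steps keep a
#'   noise floor of order the step size, annealing shrinks the residual
#'   parameter jitter and tightens the hidden-unit clusters of an
#'   ensemble.  `NULL` (default) keeps the rate constant.
#' @param batch_size Minibatch size (also the number of persistent chains).
#' @param seed Integer seed controlling initialisation, minibatch order and
#'   all Gibbs sampling.
#' @param init_scale Sd of the Gaussian weight initialisation.
#' @param init_visible_bias Initialise the visible bias at the data
#'   log-odds (`0.5 * log(p/(1-p))` of the smoothed empirical spin-up
#'   frequencies)?  Off by default: learning the single-site means from
#'   zero gives every hidden unit a large structured transient gradient
#'   that reliably moves it away from the `w_j = 0` saddle (at which a
#'   mean-matched model is stationary); datasets with extremely skewed
#'   marginals may instead need this on, or a larger learning rate, to
#'   keep units from being spent on the means themselves.
#' @param pll_samples Cap on the number of train/validation samples used
#'   for the per-epoch PLL monitor (the PLL itself is exact on that
#'   subset).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decays and jitter.
#' @returns A list of class `train_config`.
#' @export
train_config <- function(cd_steps = 1L, persistent = FALSE, epochs = 50L,
                         learning_rate = 5e-3, final_learning_rate = NULL,
                         batch_size = 128L, seed = 1L,
                         init_scale = 0.01, init_visible_bias = FALSE,
                         pll_samples = 2000L,
                         adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8) {
  stopifnot(cd_steps >= 1, epochs >= 1, learning_rate >= 0, batch_size >= 1,
            init_scale > 0)
  structure(list(cd_steps = as.integer(cd_steps), persistent = persistent,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 final_learning_rate = final_learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 init_scale = init_scale, init_visible_bias = init_visible_bias,
                 pll_samples = pll_samples,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps),
            class = "train_config")
}

#' Contrastive-divergence gradient estimate
#'
#' Estimates the gradient of the mean data log-likelihood as
#' `<v_i h_j>_data - <v_i h_j>_model` (and the analogous bias terms).  On
#' the data side the hidden statistics are the exact expectations
#' `tanh(u_j)` (Rao-Blackwellised); on the model side the chains are
#' advanced by `n` alternating block-Gibbs sweeps (hidden draw, then
#' block-categorical visible draw) and the final chain moments are used,
#' again with `tanh` on the last hidden step.
#'
#' @param params An [rbm_params] object.
#' @param batch Spin matrix of data samples (rows).
#' @param n Number of Gibbs steps.
#' @param chains Chain start: the data batch for plain CD (`NULL`, default)
#'   or the persistent chain state for PCD.
#' @returns List with gradients `dw`, `da`, `db` and the advanced `chains`.
#' @export
cd_gradient <- function(params, batch, n = 1L, chains = NULL) {
  batch <- as_spin_matrix(batch, params$n_visible)
  if (nrow(batch) == 0) stop("empty batch", call. = FALSE)
  th_data <- tanh(hidden_input(params, batch))
  vc <- if (is.null(chains)) batch else as_spin_matrix(chains, params$n_visible)
  for (t in seq_len(n)) {
    hc <- sample_hidden(params, vc)
    vc <- sample_visible(params, hc)
  }
  th_model <- tanh(hidden_input(params, vc))
  m <- nrow(batch); mc <- nrow(vc)
  list(dw = crossprod(batch, th_data) / m - crossprod(vc, th_model) / mc,
       da = colMeans(batch) - colMeans(vc),
       db = colMeans(th_data) - colMeans(th_model),
       chains = vc)
}

init_rbm <- function(n_visible, n_hidden, config, data = NULL) {
  w <- matrix(stats::rnorm(n_visible * n_hidden, sd = config$init_scale),
              nrow = n_visible)
  a <- numeric(n_visible)
  if (isTRUE(config$init_visible_bias) && !is.null(data)) {
    p <- (colSums(data == 1) + 1) / (nrow(data) + 2)
    a <- 0.5 * log(p / (1 - p))
  }
  rbm_params(w, a, numeric(n_hidden))
}

#' Train an RBM by CD-n / PCD-n with Adam
#'
#' Runs `epochs` passes of minibatch contrastive-divergence updates with
#' the Adam optimiser and records the exact pseudo-log-likelihood of the
#' training and validation sets (capped at `config$pll_samples` samples
#' each) after every epoch.  Fully deterministic given `config$seed` and
#' the split.
#'
#' @param split A list with spin matrices `train` and `valid`, as returned
#'   by [split_train_valid()] applied to a spin matrix (a stretch-table
#'   split is encoded on the fly).
#' @param n_hidden Number of hidden units.
#' @param config A [train_config()].
#' @returns An object of class `trained_rbm`: list with `params`,
#'   `pll_train`, `pll_valid` (length-`epochs` series), `config`,
#'   `split_seed`.
#' @export
rbm_train <- function(split, n_hidden, config = train_config()) {
  tr <- split$train; va <- split$valid
  if (is.data.frame(tr)) tr <- encode_one_hot(tr)
  if (is.data.frame(va)) va <- encode_one_hot(va)
  if (is.null(dim(tr)) || nrow(tr) == 0) stop("empty training split", call. = FALSE)
  if (is.null(va)) va <- tr[0, , drop = FALSE]

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  params <- init_rbm(ncol(tr), n_hidden, config, data = tr)

  n <- nrow(tr)
  bs <- min(config$batch_size, n)
  n_batch <- n %/% bs
  chains <- if (config$persistent) tr[sample.int(n, bs), , drop = FALSE] else NULL
  pll_tr_idx <- seq_len(min(n, config$pll_samples))
  pll_va_idx <- seq_len(min(nrow(va), config$pll_samples))

  mw <- vw <- matrix(0, nrow(params$w), ncol(params$w))
  ma <- va_ <- numeric(length(params$a))
  mb <- vb <- numeric(length(params$b))
  b1 <- config$adam_beta1; b2 <- config$adam_beta2; eps <- config$adam_eps
  t_step <- 0
  pll_train <- pll_valid <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    lr <- config$learning_rate
    if (!is.null(config$final_learning_rate) && config$epochs > 1) {
      frac <- (ep - 1) / (config$epochs - 1)
      lr <- (1 - frac) * lr + frac * config$final_learning_rate
    }
    ord <- sample.int(n)
    for (bi in seq_len(n_batch)) {
      batch <- tr[ord[((bi - 1) * bs + 1):(bi * bs)], , drop = FALSE]
      g <- cd_gradient(params, batch, n = config$cd_steps,
                       chains = if (config$persistent) chains else NULL)
      if (config$persistent) chains <- g$chains
      t_step <- t_step + 1
      corr <- sqrt(1 - b2^t_step) / (1 - b1^t_step)
      mw <- b1 * mw + (1 - b1) * g$dw; vw <- b2 * vw + (1 - b2) * g$dw^2
      ma <- b1 * ma + (1 - b1) * g$da; va_ <- b2 * va_ + (1 - b2) * g$da^2
      mb <- b1 * mb + (1 - b1) * g$db; vb <- b2 * vb + (1 - b2) * g$db^2
      w_new <- params$w + lr * corr * mw / (sqrt(vw) + eps)
      a_new <- params$a + lr * corr * ma / (sqrt(va_) + eps)
      b_new <- params$b + lr * corr * mb / (sqrt(vb) + eps)
      if (!all(is.finite(w_new)) || !all(is.finite(a_new)) || !all(is.finite(b_new))) {
        stop("training diverged (non-finite parameter) at epoch ", ep,
             call. = FALSE)
      }
      params <- rbm_params(w_new, a_new, b_new)
    }
    pll_train[ep] <- as.numeric(
      pseudo_log_likelihood(params, tr[pll_tr_idx, , drop = FALSE]))
    pll_valid[ep] <- if (length(pll_va_idx)) as.numeric(
      pseudo_log_likelihood(params, va[pll_va_idx, , drop = FALSE])) else NA_real_
  }

  structure(list(params = params, pll_train = pll_train, pll_valid = pll_valid,
                 config = config, split_seed = split$seed %||% NA_integer_),
            class = "trained_rbm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trained_rbm <- function(x, ...) {
  cat("<trained_rbm> N_v =", x$params$n_visible, ", N_h =", x$params$n_hidden,
      ",", length(x$pll_train), "epochs\n")
  cat("  final PLL: train", signif(utils::tail(x$pll_train, 1), 5),
      "valid", signif(utils::tail(x$pll_valid, 1), 5), "\n")
  invisible(x)
}
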