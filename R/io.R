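#' Write / read an RBM as JSON
#'
#' Single JSON document with fields `n_visible`, `n_hidden`, `gamma`,
#' `alphabet`, `weights` (row-major `N_v x N_h`, i.e. a list of `N_v`
#' rows), `visible_bias`, `hidden_bias`, plus optional `config` and
#' `pll_history` when a `trained_rbm` is written, and `group_sizes` /
#' `noise_fraction` / `source` when an `average_rbm` is written.
#'
#' @param model An `rbm_params`, `trained_rbm` or `average_rbm`.
#' @param path Output file path.
#' @returns `write_rbm()` returns `model` invisibly; `read_rbm()` the
#'   reconstructed object (an `rbm_params`, or `average_rbm` if group
#'   provenance is present).
#' @export
write_rbm <- function(model, path) {
  params <- as_params(model)
  doc <- list(n_visible = params$n_visible, n_hidden = params$n_hidden,
              gamma = params$gamma, alphabet = aa_alphabet,
              weights = lapply(seq_len(params$n_visible),
                               function(i) params$w[i, ]),
              visible_bias = params$a, hidden_bias = params$b)
  if (inherits(model, "trained_rbm")) {
    doc$config <- unclass(model$config)
    doc$pll_history <- list(train = model$pll_train, valid = model$pll_valid)
  }
  if (inherits(model, "average_rbm")) {
    doc$group_sizes <- model$group_sizes
    doc$noise_fraction <- model$noise_fraction
    doc$source <- model$source
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname write_rbm
#' @export
read_rbm <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- if (is.matrix(doc$weights)) doc$weights else
    matrix(unlist(doc$weights), nrow = doc$n_visible, byrow = TRUE)
  if (doc$n_hidden == 1 && is.null(dim(doc$weights))) {
    w <- matrix(doc$weights, ncol = 1)
  }
  params <- rbm_params(w, doc$visible_bias, doc$hidden_bias)
  if (!is.null(doc$group_sizes)) {
    return(structure(list(params = params,
                          group_sizes = as.integer(doc$group_sizes),
                          n_groups = length(doc$group_sizes),
                          noise_fraction = doc$noise_fraction,
                          source = doc$source),
                     class = "average_rbm"))
  }
  params
}
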