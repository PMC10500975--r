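#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy RBM parameters into a long tibble
#'
#' @param x An `rbm_params` object.
#' @param ... Unused.
#' @returns Tibble with one row per weight (`term = "weight"`, `residue`,
#'   `position`, `unit`, `value`) plus the visible and hidden biases
#'   (`term = "visible_bias"` / `"hidden_bias"`).
#' @export
tidy.rbm_params <- function(x, ...) {
  gamma <- x$gamma
  w <- tidyr::expand_grid(unit = seq_len(x$n_hidden),
                          position = seq_len(gamma),
                          residue = aa_alphabet) |>
    dplyr::mutate(term = "weight",
                  value = x$w[cbind(visible_index(.data$position,
                                                  match(.data$residue, aa_alphabet)),
                                    .data$unit)])
  a <- tidyr::expand_grid(position = seq_len(gamma), residue = aa_alphabet) |>
    dplyr::mutate(term = "visible_bias", unit = NA_integer_,
                  value = x$a[visible_index(.data$position,
                                            match(.data$residue, aa_alphabet))])
  b <- tibble::tibble(term = "hidden_bias", unit = seq_len(x$n_hidden),
                      position = NA_integer_, residue = NA_character_,
                      value = x$b)
  dplyr::bind_rows(w, a, b)[c("term", "unit", "position", "residue", "value")]
}

#' @rdname tidy.rbm_params
#' @export
tidy.trained_rbm <- function(x, ...) tidy(x$params, ...)

#' @rdname tidy.rbm_params
#' @export
tidy.average_rbm <- function(x, ...) tidy(x$params, ...)

#' One-line training summary
#'
#' @param x A `trained_rbm`.
#' @param ... Unused.
#' @returns Tibble with `n_visible`, `n_hidden`, `epochs`, `cd_steps`,
#'   `persistent`, `pll_train`, `pll_valid` (final values).
#' @export
glance.trained_rbm <- function(x, ...) {
  tibble::tibble(n_visible = x$params$n_visible,
                 n_hidden = x$params$n_hidden,
                 epochs = length(x$pll_train),
                 cd_steps = x$config$cd_steps,
                 persistent = x$config$persistent,
                 pll_train = utils::tail(x$pll_train, 1),
                 pll_valid = utils::tail(x$pll_valid, 1))
}

#' @rdname glance.trained_rbm
#' @export
glance.average_rbm <- function(x, ...) {
  tibble::tibble(n_groups = x$n_groups,
                 noise_fraction = x$noise_fraction,
                 R = x$source$R,
                 n_hidden_source = x$source$n_hidden)
}

#' Tidy the per-epoch PLL history
#'
#' @param x A `trained_rbm`.
#' @returns Tibble with `epoch`, `set` (`train`/`valid`), `pll`.
#' @export
pll_history <- function(x) {
  stopifnot(inherits(x, "trained_rbm"))
  tibble::tibble(epoch = rep(seq_along(x$pll_train), 2),
                 set = rep(c("train", "valid"), each = length(x$pll_train)),
                 pll = c(x$pll_train, x$pll_valid))
}

#' Tidy a state decomposition
#'
#' @param x A `state_decomposition`.
#' @param ... Unused.
#' @returns Long tibble: `label`, `state_label`, `frequency`, `residue`,
#'   `position`, `prob`.
#' @export
tidy.state_decomposition <- function(x, ...) {
  purrr::pmap_dfr(list(x$label, x$state_label, x$frequency, x$table),
                  function(lab, sl, f, tab) {
                    tibble::tibble(label = lab, state_label = sl, frequency = f,
                                   residue = rep(aa_alphabet, ncol(tab)),
                                   position = rep(seq_len(ncol(tab)), each = 20),
                                   prob = as.vector(tab))
                  })
}

#' @rdname tidy.rbm_params
#' @export
tidy.group_pca <- function(x, ...) x$coords
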