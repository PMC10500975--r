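#' Default polar / hydrophobic residue partition
#'
#' The two-class residue dichotomy that the planted generators use by
#' default: hydrophobic class `H` = C, F, I, L, M, V, W, Y; polar/charged
#' class `P` = D, E, H, K, N, P, Q, R, S, T; A and G neutral.  (Tyr is
#' grouped hydrophobic and Pro polar, matching the behaviour the trained
#' models expose on real boundary stretches; Ala and Gly commit to neither
#' class.)  Fully overridable in [planted_spec()].
#'
#' @returns Named character vector over [aa_alphabet] with values
#'   `"H"`, `"P"` or `"neutral"`.
#' @export
default_residue_classes <- function() {
  cls <- rep("neutral", 20)
  names(cls) <- aa_alphabet
  cls[c("C", "F", "I", "L", "M", "V", "W", "Y")] <- "H"
  cls[c("D", "E", "H", "K", "N", "P", "Q", "R", "S", "T")] <- "P"
  cls
}

#' Specification of a planted RBM
#'
#' Describes an RBM with hand-planted weight structure: hidden unit `u`
#' carries weight `amplitude[u] * pattern[k]` for residue `k` at each
#' position in its mask and zero elsewhere, where the unit's residue
#' pattern is by default the `H`/`P` class dichotomy (`+1` hydrophobic,
#' `-1` polar, `0` neutral).
#'
#' The defaults define a `Gamma = 5`, `K = 3` model emulating the mode
#' structure seen at secondary-structure boundaries: two period-2
#' polarity-alternation units in opposite phase (odd positions `{1,3,5}`
#' and even positions `{2,4}`, amplitude 1.0) plus an Ala-mode unit over
#' all positions with the residue pattern `+1` for Ala, `-1` for Gly
#' (amplitude 1.2).  A unit must induce correlation *across* positions to
#' be statistically meaningful (a single-position unit is absorbable into
#' the visible bias), and the three default units are mutually orthogonal
#' in weight space, which keeps the planted modes identifiable.  The
#' amplitudes also order the modes strictly by strength (odd alternation,
#' then even alternation, then the Ala mode); that ordering matters for
#' under-capacity compression, where every training realization should
#' agree on *which* modes to keep — near-tied strengths make the ensemble
#' split between subsets.  Distinct hidden biases give the hidden-state
#' frequencies a unique rank order.
#'
#' @param gamma Stretch length.
#' @param masks List of integer position masks, one per hidden unit.
#' @param amplitude Positive weight amplitude(s), recycled over units.
#' @param classes Residue classification (named vector over
#'   [aa_alphabet] with values `"H"`, `"P"`, `"neutral"`) used for units
#'   without an explicit pattern.
#' @param patterns Optional list (one element per unit) of length-20
#'   numeric residue patterns in [aa_alphabet] order; `NULL` entries fall
#'   back to the class dichotomy.
#' @param hidden_bias Hidden biases (length `K`), expressed in the
#'   one-hot-restricted gauge (see [make_planted_rbm()]).
#' @param visible_bias `20 x gamma` matrix of visible biases (default 0).
#' @returns A list of class `planted_spec`.
#' @export
planted_spec <- function(gamma = 5L,
                         masks = list(c(1L, 3L, 5L), c(2L, 4L), seq_len(gamma)),
                         amplitude = c(1.0, 1.0, 1.2),
                         classes = default_residue_classes(),
                         patterns = NULL,
                         hidden_bias = c(0.5, -0.3, 0.5),
                         visible_bias = NULL) {
  K <- length(masks)
  if (K > MAX_EXACT_HIDDEN) stop("K must be <= ", MAX_EXACT_HIDDEN, call. = FALSE)
  amplitude <- rep_len(amplitude, K)
  if (any(amplitude < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  if (any(!vapply(masks, length, 1L))) stop("masks must be non-empty", call. = FALSE)
  if (any(unlist(masks) < 1 | unlist(masks) > gamma)) {
    stop("mask positions must lie in 1..gamma", call. = FALSE)
  }
  if (!setequal(names(classes), aa_alphabet) ||
      !all(classes %in% c("H", "P", "neutral"))) {
    stop("classes must map every canonical residue to H, P or neutral",
         call. = FALSE)
  }
  if (is.null(patterns)) {
    patterns <- vector("list", K)
    if (missing(masks) && K == 3) {
      # the documented default third unit: an Ala-vs-Gly mode
      ala <- stats::setNames(rep(0, 20), aa_alphabet)
      ala[c("A", "G")] <- c(1, -1)
      patterns[[3]] <- ala
    }
  }
  if (length(patterns) != K) stop("need one pattern (or NULL) per unit", call. = FALSE)
  cls_sgn <- c(H = 1, P = -1, neutral = 0)[classes[aa_alphabet]]
  patterns <- lapply(patterns, function(p) {
    if (is.null(p)) return(unname(cls_sgn))
    if (length(p) != 20) stop("patterns must have length 20", call. = FALSE)
    unname(p)
  })
  hidden_bias <- rep_len(hidden_bias, K)
  if (is.null(visible_bias)) visible_bias <- matrix(0, 20, gamma)
  stopifnot(nrow(visible_bias) == 20, ncol(visible_bias) == gamma)
  structure(list(gamma = as.integer(gamma), n_hidden = K, masks = masks,
                 amplitude = amplitude, classes = classes[aa_alphabet],
                 patterns = patterns,
                 hidden_bias = hidden_bias, visible_bias = visible_bias),
            class = "planted_spec")
}

#' Build the planted RBM parameters
#'
#' The spec's `hidden_bias` is expressed in the one-hot-restricted gauge:
#' because every block carries a `-1` background on its 19 unchosen
#' units, the raw model bias is shifted by `sum_i w_ij` so that
#' `hidden_bias` directly sets the (approximate) log-odds of the unit's
#' state over the data -- without the shift, any unbalanced residue
#' classification pins every hidden unit to one sign and the planted
#' modes never alternate.
#'
#' @param spec A [planted_spec()].
#' @returns An [rbm_params] object with the planted weights and biases.
#' @export
make_planted_rbm <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  w <- matrix(0, nrow = 20L * spec$gamma, ncol = spec$n_hidden)
  for (u in seq_len(spec$n_hidden)) {
    for (g in spec$masks[[u]]) {
      w[visible_index(g, 1:20), u] <- spec$amplitude[u] * spec$patterns[[u]]
    }
  }
  rbm_params(w, as.vector(spec$visible_bias), spec$hidden_bias + colSums(w))
}

#' Sample stretches from a planted RBM
#'
#' Exact ancestral sampling via [rbm_generate()] (enumerate the `2^K`
#' hidden states, then block-categorical residue draws); reproducible by
#' seed.
#'
#' @param params An [rbm_params] (typically from [make_planted_rbm()]).
#' @param n_samples Number of stretches.
#' @param seed Integer seed.
#' @returns A stretch table with `protein_id = "planted"`.
#' @export
sample_planted <- function(params, n_samples, seed = 1L) {
  out <- rbm_generate(params, n_samples, seed = seed)
  if (nrow(out)) out$protein_id <- "planted"
  out
}

#' Specification of a latent-mode mixture generator
#'
#' A simpler generator than the planted RBM: each sample first draws a
#' latent mode, then draws each of its `Gamma` residues independently from
#' that mode's `20 x Gamma` column-stochastic profile.  Default: three
#' amphiphilic modes built from the default residue classes (period-2
#' polarity alternation starting polar, the same starting hydrophobic,
#' and period-1 uniform-class), with non-uniform mode probabilities
#' (0.5 / 0.3 / 0.2) and a `noise` floor mixing each column with the
#' uniform distribution.
#'
#' @param profiles List of `20 x Gamma` column-stochastic matrices.
#' @param probabilities Mode probabilities (simplex).
#' @param noise Mixing weight of the uniform distribution added to every
#'   column (0 = pure modes).
#' @returns A list of class `mode_mixture_spec`.
#' @export
mode_mixture_spec <- function(profiles = NULL, probabilities = NULL,
                              noise = 0.1) {
  if (is.null(profiles)) {
    cls <- default_residue_classes()
    col_for <- function(class) {
      p <- ifelse(cls == class, 1, 0)
      if (sum(p) == 0) stop("empty class", call. = FALSE)
      p / sum(p)
    }
    pol <- col_for("P"); hyd <- col_for("H")
    per2a <- cbind(pol, hyd, pol, hyd, pol)
    per2b <- cbind(hyd, pol, hyd, pol, hyd)
    per1 <- cbind(hyd, hyd, hyd, hyd, hyd)
    profiles <- list(per2a, per2b, per1)
  }
  if (is.null(probabilities)) probabilities <- c(0.5, 0.3, 0.2)[seq_along(profiles)]
  probabilities <- probabilities / sum(probabilities)
  stopifnot(length(profiles) == length(probabilities), noise >= 0, noise < 1)
  profiles <- lapply(profiles, function(m) {
    if (any(m < 0) || any(abs(colSums(m) - 1) > 1e-8)) {
      stop("mode profiles must be column-stochastic", call. = FALSE)
    }
    (1 - noise) * m + noise / 20
  })
  structure(list(profiles = profiles, probabilities = probabilities,
                 noise = noise),
            class = "mode_mixture_spec")
}

#' Sample stretches from a latent-mode mixture
#'
#' @param spec A [mode_mixture_spec()].
#' @param n_samples Number of stretches.
#' @param seed Integer seed.
#' @returns A stretch table with `protein_id = "mixture"`; attribute
#'   `mode` records each sample's latent mode.
#' @export
sample_mode_mixture <- function(spec, n_samples, seed = 1L) {
  stopifnot(inherits(spec, "mode_mixture_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (n_samples == 0) {
    out <- stretch_table(character(), protein_id = character())
    attr(out, "mode") <- integer()
    return(out)
  }
  gamma <- ncol(spec$profiles[[1]])
  mode <- sample.int(length(spec$profiles), n_samples, replace = TRUE,
                     prob = spec$probabilities)
  seqs <- character(n_samples)
  for (m in seq_along(spec$profiles)) {
    rows <- which(mode == m)
    if (!length(rows)) next
    draws <- vapply(seq_len(gamma), function(g) {
      sample(aa_alphabet, length(rows), replace = TRUE,
             prob = spec$profiles[[m]][, g])
    }, character(length(rows)))
    draws <- matrix(draws, nrow = length(rows))
    seqs[rows] <- apply(draws, 1, paste, collapse = "")
  }
  out <- stretch_table(seqs, protein_id = "mixture")
  attr(out, "mode") <- mode
  out
}
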