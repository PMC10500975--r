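#' Train an ensemble of independent RBM realizations
#'
#' Trains `R` RBMs of the same size on the same sample pool.  Realization
#' `r` (0-based) uses seed `config$seed + r` both for its own 80/20
#' train/validation split and for weight initialisation and Gibbs
#' sampling, so realizations differ only by those seeds and the whole
#' ensemble is reproducible.  Realizations that diverge are dropped (not
#' retrained) and counted.
#'
#' @param samples Stretch table or spin matrix: the full sample pool.
#' @param n_hidden Number of hidden units per realization.
#' @param config A [train_config()]; its `seed` is the ensemble base seed.
#' @param R Number of realizations (>= 2).
#' @param split_fraction Training fraction of each realization's split.
#' @returns An object of class `rbm_ensemble`: list with `rbms` (list of
#'   `trained_rbm`), `n_hidden`, `R`, `n_diverged`, `config`.
#' @export
train_ensemble <- function(samples, n_hidden, config = train_config(), R = 30L,
                           split_fraction = 0.8) {
  if (R < 2) stop("R must be >= 2", call. = FALSE)
  if (is.data.frame(samples)) samples <- encode_one_hot(samples)
  rbms <- vector("list", R)
  diverged <- logical(R)
  for (r in seq_len(R) - 1L) {
    seed_r <- config$seed + r
    cfg <- config
    cfg$seed <- seed_r
    split <- split_train_valid(samples, fraction = split_fraction, seed = seed_r)
    fit <- tryCatch(rbm_train(split, n_hidden, cfg),
                    error = function(e) {
                      if (grepl("diverged", conditionMessage(e))) NULL else stop(e)
                    })
    if (is.null(fit)) diverged[r + 1L] <- TRUE else rbms[[r + 1L]] <- fit
  }
  structure(list(rbms = rbms[!diverged], n_hidden = as.integer(n_hidden),
                 R = as.integer(R), n_diverged = sum(diverged),
                 config = config),
            class = "rbm_ensemble")
}

#' @export
print.rbm_ensemble <- function(x, ...) {
  cat("<rbm_ensemble>", length(x$rbms), "of", x$R, "realizations (N_h =",
      x$n_hidden, ");", x$n_diverged, "diverged\n")
  invisible(x)
}

#' Pool the hidden units of an ensemble
#'
#' @param ensemble An `rbm_ensemble`.
#' @returns Tibble with one row per hidden unit: `rbm_index` (0-based),
#'   `unit_index` (0-based), `bias`, and a list-column `weights` of
#'   `N_v`-vectors.
#' @export
pool_hidden_units <- function(ensemble) {
  purrr::imap_dfr(ensemble$rbms, function(fit, r) {
    p <- fit$params
    tibble::tibble(rbm_index = r - 1L,
                   unit_index = seq_len(p$n_hidden) - 1L,
                   bias = p$b,
                   weights = lapply(seq_len(p$n_hidden), function(j) p$w[, j]))
  })
}

#' Pairwise distances between hidden units
#'
#' Euclidean distance between weight vectors.  With `sign_align = TRUE`
#' (the default) the gauge ambiguity `(w, b) ~ (-w, -b)` is removed by
#' using `min(||w_j - w_m||, ||w_j + w_m||)`, so a unit and its gauge
#' flip are at distance zero.
#'
#' @param units Tibble from [pool_hidden_units()], or a plain matrix with
#'   one unit weight vector per row.
#' @param sign_align Identify antipodal units?
#' @returns A symmetric distance matrix with zero diagonal; attribute
#'   `sign_align` records the choice.
#' @export
unit_distance_matrix <- function(units, sign_align = TRUE) {
  W <- if (is.matrix(units)) units else do.call(rbind, units$weights)
  if (nrow(W) < 2) stop("need at least 2 units", call. = FALSE)
  g <- W %*% t(W)
  sq <- diag(g)
  d2_minus <- outer(sq, sq, "+") - 2 * g
  if (sign_align) {
    d2_plus <- outer(sq, sq, "+") + 2 * g
    d2 <- pmin(d2_minus, d2_plus)
  } else {
    d2 <- d2_minus
  }
  d <- sqrt(pmax(d2, 0))
  diag(d) <- 0
  d <- (d + t(d)) / 2
  attr(d, "sign_align") <- sign_align
  d
}

# Classic DBSCAN on a precomputed distance matrix.  Core points have at
# least min_samples neighbours (self included) within eps; clusters are the
# connected components of core points under eps-reachability; border points
# join the first cluster that reaches them; the rest is noise (label 0).
dbscan_labels <- function(d, eps, min_samples) {
  n <- nrow(d)
  nb <- d <= eps
  core <- rowSums(nb) >= min_samples
  labels <- integer(n)          # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      q <- queue[[1]]
      queue <- queue[-1]
      reach <- which(nb[q, ] & labels == 0L)
      labels[reach] <- cl
      queue <- c(queue, reach[core[reach]])
    }
  }
  labels
}

# Automatic eps from the sorted k-NN distance curve (distance to the k-th
# point of a would-be core neighbourhood, self included, matching the core
# rule rowSums(d <= eps) >= k).  Units belonging to reproducible groups sit
# on a low, slowly-varying stretch of the curve; units without a
# neighbourhood (noise) produce a large multiplicative jump.  eps is set
# just above the last value before the first such jump in the upper half of
# the curve, or just above the curve's maximum when there is no jump (then
# every unit can be a core point and groups are separated purely by the
# much larger between-group distances).
auto_eps <- function(d, k, jump = 3) {
  knn <- apply(d, 1, function(row) sort(row)[k])
  y <- sort(knn)
  n <- length(y)
  if (y[n] <= 0) return(.Machine$double.eps)
  floor_ <- max(y[n] * 1e-6, .Machine$double.eps)
  for (i in seq(max(2, ceiling(n / 2)), n - 1)) {
    if (y[i + 1] > jump * max(y[i], floor_)) return(max(y[i] * 1.05, floor_))
  }
  y[n] * 1.05
}

#' Cluster pooled hidden units (DBSCAN with a noise class)
#'
#' Groups the ensemble's hidden units by density-based clustering of the
#' pairwise weight distances.  Units not assigned to any group are labelled
#' noise (group 0).  Groups are renumbered 1, 2, ... by decreasing size.
#' Within each group a sign factor is fixed by a reference pass: the
#' largest-norm member is the reference and every member is oriented to
#' have a non-negative inner product with it (only meaningful when the
#' distance matrix was built with `sign_align = TRUE`).
#'
#' @param units Tibble from [pool_hidden_units()] (or weight matrix).
#' @param d Distance matrix from [unit_distance_matrix()]; computed if
#'   missing.
#' @param eps Neighbourhood radius; `"auto"` (default) derives it from the
#'   sorted `min_samples`-nearest-neighbour distance curve: the cut is
#'   placed just above the last value before the first large multiplicative
#'   jump (units beyond a jump have no neighbourhood and become noise), or
#'   just above the curve's maximum when the curve is smooth.
#' @param min_samples Core-point threshold; `"auto"` uses
#'   `max(3, floor(R / 3))` where `R` is the number of distinct source
#'   RBMs (or `3` for a bare matrix).
#' @returns An object of class `unit_clustering`: tibble `units` with
#'   added columns `group` (0 = noise) and `sign`, plus fields `d`, `eps`,
#'   `min_samples`, `n_groups`, `noise_fraction`.
#' @export
cluster_units <- function(units, d = NULL, eps = "auto", min_samples = "auto") {
  if (is.matrix(units)) {
    units <- tibble::tibble(rbm_index = NA_integer_,
                            unit_index = seq_len(nrow(units)) - 1L,
                            bias = NA_real_,
                            weights = lapply(seq_len(nrow(units)),
                                             function(i) units[i, ]))
  }
  if (is.null(d)) d <- unit_distance_matrix(units)
  if (identical(min_samples, "auto")) {
    Rn <- length(unique(units$rbm_index[!is.na(units$rbm_index)]))
    min_samples <- max(3L, if (Rn > 0) Rn %/% 3L else 3L)
  }
  if (identical(eps, "auto")) eps <- auto_eps(d, min_samples)
  if (!is.numeric(eps) || eps <= 0) stop("eps must be > 0", call. = FALSE)

  raw <- dbscan_labels(d, eps, min_samples)
  # renumber groups by decreasing size (ties: first-appearance order)
  sizes <- sort(table(raw[raw > 0]), decreasing = TRUE)
  remap <- stats::setNames(seq_along(sizes), names(sizes))
  group <- ifelse(raw > 0, remap[as.character(raw)], 0L)
  group <- as.integer(group)

  W <- do.call(rbind, units$weights)
  sign <- rep(1, nrow(W))
  if (isTRUE(attr(d, "sign_align"))) {
    for (g in setdiff(unique(group), 0L)) {
      idx <- which(group == g)
      ref <- idx[which.max(rowSums(W[idx, , drop = FALSE]^2))]
      ip <- W[idx, , drop = FALSE] %*% W[ref, ]
      sign[idx] <- ifelse(ip < 0, -1, 1)
    }
  }
  units$group <- group
  units$sign <- sign
  structure(list(units = units, d = d, eps = eps,
                 min_samples = as.integer(min_samples),
                 n_groups = length(sizes),
                 noise_fraction = mean(group == 0L)),
            class = "unit_clustering")
}

#' @export
print.unit_clustering <- function(x, ...) {
  cat("<unit_clustering>", nrow(x$units), "units ->", x$n_groups,
      "groups; noise fraction", signif(x$noise_fraction, 3),
      "(eps =", signif(x$eps, 4), ", min_samples =", x$min_samples, ")\n")
  invisible(x)
}

#' Build the average RBM (aRBM) of a clustered ensemble
#'
#' Each hidden-unit group becomes one hidden unit of the consensus model:
#' its weight vector is the mean of the sign-aligned member weight vectors
#' and its bias the mean of the sign-aligned member biases.  The visible
#' bias is the mean of `a` over all ensemble realizations.  Noise units are
#' excluded.
#'
#' @param ensemble The `rbm_ensemble` the units came from.
#' @param clustering A `unit_clustering` over [pool_hidden_units()] of the
#'   same ensemble.
#' @returns An object of class `average_rbm`: list with `params` (an
#'   [rbm_params] with one hidden unit per group, ordered by group label),
#'   `group_sizes`, `n_groups`, `noise_fraction`, `source` (R, n_hidden).
#' @export
build_arbm <- function(ensemble, clustering) {
  units <- clustering$units
  groups <- sort(setdiff(unique(units$group), 0L))
  if (length(groups) == 0) stop("all units are noise; no aRBM", call. = FALSE)
  W <- do.call(rbind, units$weights)
  gw <- vapply(groups, function(g) {
    idx <- which(units$group == g)
    colMeans(W[idx, , drop = FALSE] * units$sign[idx])
  }, numeric(ncol(W)))
  gb <- vapply(groups, function(g) {
    idx <- which(units$group == g)
    mean(units$bias[idx] * units$sign[idx])
  }, numeric(1))
  a_bar <- rowMeans(vapply(ensemble$rbms, function(f) f$params$a,
                           numeric(ncol(W))))
  sizes <- vapply(groups, function(g) sum(units$group == g), integer(1))
  structure(list(params = rbm_params(gw, a_bar, gb),
                 group_sizes = sizes, n_groups = length(groups),
                 noise_fraction = clustering$noise_fraction,
                 source = list(R = ensemble$R, n_hidden = ensemble$n_hidden)),
            class = "average_rbm")
}

#' @export
print.average_rbm <- function(x, ...) {
  cat("<average_rbm>", x$n_groups, "groups (sizes",
      paste(x$group_sizes, collapse = ", "), ") from R =", x$source$R,
      "realizations of N_h =", x$source$n_hidden, "\n")
  cat("  hidden bias:", paste(signif(x$params$b, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Model-complexity scan over the number of hidden units
#'
#' For each candidate `N_h`, trains an ensemble, clusters its pooled
#' hidden units, and records the number of groups, the noise fraction and
#' the ensemble-mean final train/validation PLL.  The recommended `N_h`
#' is the largest value whose group count equals `N_h` with noise fraction
#' below `noise_threshold` -- the most complex model on which the ensemble
#' still agrees unit-for-unit.
#'
#' @param samples Stretch table or spin matrix.
#' @param n_hidden_values Integer vector of `N_h` values to scan.
#' @param config A [train_config()].
#' @param R Realizations per ensemble.
#' @param noise_threshold Maximum admissible noise fraction.
#' @param eps,min_samples Passed to [cluster_units()].
#' @returns A tibble of class `complexity_scan` with one row per `N_h`:
#'   `n_hidden`, `n_groups`, `noise_fraction`, `pll_train`, `pll_valid`;
#'   attributes `recommended` (the selected `N_h`, or `NA`) and
#'   `ensembles` (named list of the fitted ensembles and clusterings).
#' @export
scan_model_complexity <- function(samples, n_hidden_values,
                                  config = train_config(), R = 10L,
                                  noise_threshold = 0.1,
                                  eps = "auto", min_samples = "auto") {
  if (length(n_hidden_values) == 0) stop("no n_hidden values", call. = FALSE)
  if (is.data.frame(samples)) samples <- encode_one_hot(samples)
  fits <- list()
  rows <- purrr::map_dfr(n_hidden_values, function(nh) {
    ens <- train_ensemble(samples, nh, config, R = R)
    cl <- cluster_units(pool_hidden_units(ens), eps = eps,
                        min_samples = min_samples)
    fits[[as.character(nh)]] <<- list(ensemble = ens, clustering = cl)
    tibble::tibble(
      n_hidden = as.integer(nh),
      n_groups = cl$n_groups,
      noise_fraction = cl$noise_fraction,
      pll_train = mean(vapply(ens$rbms, function(f) utils::tail(f$pll_train, 1),
                              numeric(1))),
      pll_valid = mean(vapply(ens$rbms, function(f) utils::tail(f$pll_valid, 1),
                              numeric(1))))
  })
  ok <- rows$n_groups == rows$n_hidden & rows$noise_fraction < noise_threshold
  attr(rows, "recommended") <- if (any(ok)) max(rows$n_hidden[ok]) else NA_integer_
  attr(rows, "ensembles") <- fits
  class(rows) <- c("complexity_scan", class(rows))
  rows
}
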