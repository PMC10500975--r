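# small planted dataset shared by the ensemble tests: the two amphiphilic
# alternation phases (odd/even masks) over the default H/P dichotomy
planted_toy <- function(n = 4000, seed = 21) {
  spec <- planted_spec(gamma = 5, masks = list(c(1L, 3L, 5L), c(2L, 4L)),
                       amplitude = 1.0, hidden_bias = c(0.3, -0.1))
  params <- make_planted_rbm(spec)
  list(params = params, data = sample_planted(params, n, seed = seed))
}

test_that("ensemble realizations derive distinct seeds and are reproducible", {
  toy <- planted_toy(800)
  cfg <- train_config(epochs = 2, seed = 50, pll_samples = 200)
  ens <- train_ensemble(toy$data, 2, cfg, R = 3)
  expect_length(ens$rbms, 3L)
  expect_equal(ens$n_diverged, 0L)
  # per-realization splits differ
  expect_true(ens$rbms[[1]]$split_seed != ens$rbms[[2]]$split_seed)
  # seed + r scheme: realization r of a seed-(50) run equals realization
  # r-1 of a seed-(51) run
  ens2 <- train_ensemble(toy$data, 2, train_config(epochs = 2, seed = 51,
                                                   pll_samples = 200), R = 2)
  expect_equal(ens$rbms[[2]]$params, ens2$rbms[[1]]$params)
  expect_true(all(vapply(ens$rbms, function(f) is.finite(f$pll_valid[2]), TRUE)))
  expect_error(train_ensemble(toy$data, 2, cfg, R = 1), "R must be")
})

test_that("unit distances are Euclidean, symmetric and gauge-aware", {
  W <- rbind(c(1, 0), c(0, 1))
  d <- unit_distance_matrix(W, sign_align = FALSE)
  expect_equal(d[1, 2], sqrt(2))
  expect_equal(d, t(d))
  expect_equal(diag(d), c(0, 0))
  # sign alignment identifies w and -w
  W2 <- rbind(c(1, 2, -1), c(-1, -2, 1), c(1, 2, -1))
  d2 <- unit_distance_matrix(W2, sign_align = TRUE)
  expect_equal(d2[1, 2], 0)
  expect_equal(d2[1, 3], 0)
  d2n <- unit_distance_matrix(W2, sign_align = FALSE)
  expect_equal(d2n[1, 2], 2 * sqrt(6))
  expect_error(unit_distance_matrix(W[1, , drop = FALSE]), "at least 2")
})

test_that("DBSCAN clustering finds constructed bundles and flags outliers", {
  set.seed(60)
  mk_bundle <- function(center, n) {
    t(replicate(n, center + stats::rnorm(length(center), sd = 0.02)))
  }
  c1 <- c(rep(2, 5), rep(0, 5)); c2 <- c(rep(0, 5), rep(-2, 5))
  W <- rbind(mk_bundle(c1, 15), mk_bundle(c2, 15))
  cl <- cluster_units(W, eps = 0.5, min_samples = 3)
  expect_equal(cl$n_groups, 2L)
  expect_equal(cl$noise_fraction, 0)
  expect_equal(as.integer(sort(table(cl$units$group))), c(15L, 15L))
  # one far outlier becomes noise
  W3 <- rbind(W, rep(10, 10))
  cl3 <- cluster_units(W3, eps = 0.5, min_samples = 3)
  expect_equal(cl3$units$group[31], 0L)
  expect_equal(cl3$n_groups, 2L)
  # all units identical -> one group
  cl4 <- cluster_units(matrix(1, 6, 4), eps = 0.5, min_samples = 3)
  expect_equal(cl4$n_groups, 1L)
  expect_error(cluster_units(W, eps = -1), "eps")
})

test_that("clustering is invariant to unit order and (aligned) sign flips", {
  set.seed(61)
  W <- rbind(t(replicate(10, c(rep(1.5, 4), rep(0, 4)) + rnorm(8, sd = 0.05))),
             t(replicate(10, c(rep(0, 4), rep(-1.5, 4)) + rnorm(8, sd = 0.05))))
  base <- cluster_units(W, eps = 0.6, min_samples = 3)
  perm <- sample(nrow(W))
  flip <- sample(c(-1, 1), nrow(W), TRUE)
  Wp <- W[perm, ] * flip
  cl <- cluster_units(Wp, eps = 0.6, min_samples = 3)
  expect_equal(cl$n_groups, base$n_groups)
  # same partition after undoing the permutation
  relabeled <- cl$units$group[order(perm)]
  tab <- table(relabeled, base$units$group)
  expect_equal(sum(apply(tab, 1, max)), nrow(W))  # one-to-one group match
})

test_that("the aRBM averages sign-aligned members and all biases", {
  toy <- planted_toy(600)
  cfg <- train_config(epochs = 2, seed = 70, pll_samples = 100)
  ens <- train_ensemble(toy$data, 2, cfg, R = 3)
  units <- pool_hidden_units(ens)
  # identical copies of one RBM -> aRBM equals it exactly
  ens_same <- ens
  ens_same$rbms <- rep(ens$rbms[1], 3)
  u_same <- pool_hidden_units(ens_same)
  cl_same <- cluster_units(u_same, eps = 1e-6, min_samples = 2)
  ar <- build_arbm(ens_same, cl_same)
  expect_equal(ar$n_groups, 2L)
  p1 <- ens$rbms[[1]]$params
  expect_equal(ar$params$a, p1$a)
  # each group weight equals one column of the source model, up to group sign
  match_col <- function(gw) min(apply(p1$w, 2, function(col)
    min(sum((gw - col)^2), sum((gw + col)^2))))
  expect_lt(max(vapply(seq_len(2), function(g) match_col(ar$params$w[, g]),
                       numeric(1))), 1e-20)
  expect_equal(ar$group_sizes, c(3L, 3L))
  # group {w, -w} with alignment averages to +-w, not zero
  Wpm <- rbind(c(1, -2, 3), c(-1, 2, -3))
  clpm <- cluster_units(Wpm, eps = 0.1, min_samples = 2)
  expect_equal(clpm$n_groups, 1L)
  expect_equal(abs(clpm$units$sign %*% c(1, 1))[1], 0)  # opposite signs assigned
  # all units noise -> error
  Wn <- matrix(seq_len(40), 4, 10) * 5
  cln <- cluster_units(Wn, eps = 0.01, min_samples = 3)
  expect_error(build_arbm(ens, cln), "noise")
})

test_that("aRBM of a randomly gauge-flipped ensemble matches up to group signs", {
  toy <- planted_toy(2000)
  cfg <- train_config(epochs = 4, seed = 80, pll_samples = 200)
  ens <- train_ensemble(toy$data, 2, cfg, R = 4)
  flip_ens <- ens
  set.seed(81)
  flip_ens$rbms <- lapply(ens$rbms, function(f) {
    units <- which(stats::runif(f$params$n_hidden) < 0.5)
    if (length(units)) f$params <- gauge_flip(f$params, units)
    f
  })
  cl <- cluster_units(pool_hidden_units(ens))
  clf <- cluster_units(pool_hidden_units(flip_ens))
  a1 <- build_arbm(ens, cl)
  a2 <- build_arbm(flip_ens, clf)
  expect_equal(a1$n_groups, a2$n_groups)
  expect_equal(a1$params$a, a2$params$a)
  for (g in seq_len(a1$n_groups)) {
    dmin <- min(sum((a1$params$w[, g] - a2$params$w[, g])^2),
                sum((a1$params$w[, g] + a2$params$w[, g])^2))
    expect_lt(dmin, 1e-20)
  }
})

test_that("the complexity scan reports one row per N_h and recovers planted order", {
  toy <- planted_toy(10000, seed = 22)
  cfg <- train_config(epochs = 20, seed = 90, pll_samples = 400)
  scan <- scan_model_complexity(toy$data, 1:2, cfg, R = 3)
  expect_equal(scan$n_hidden, 1:2)
  expect_equal(nrow(scan), 2L)
  expect_equal(scan$n_groups[1], 1L)
  expect_equal(scan$n_groups[2], 2L)
  # valid PLL improves up to the planted order
  expect_gt(scan$pll_valid[2], scan$pll_valid[1])
  # recovered group weights correlate with the planted units
  e2 <- attr(scan, "ensembles")[["2"]]
  ar <- build_arbm(e2$ensemble, e2$clustering)
  cm <- abs(stats::cor(ar$params$w, toy$params$w))
  expect_true(all(apply(cm, 2, max) >= 0.9))
})
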