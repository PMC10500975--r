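test_that("energy evaluates the bilinear spin form and its symmetries", {
  # all parameters zero -> E = 0 for every configuration
  z <- rbm_params(matrix(0, 20, 2), numeric(20), numeric(2))
  v <- encode_one_hot("M")
  expect_equal(rbm_energy(z, v, c(1, -1)), 0)
  # hand value, gamma = 1, N_h = 1: a has 0.5 on the +1 site (residue A),
  # w column is +1 on site 1, -1 on site 2, b = 0.2, v = one-hot A, h = +1:
  # E = -(a.v) - b - v.w = -(0.5 - 0) - 0.2 - (1*1 + (-1)*(-1) + 18*0*(-1))
  w <- matrix(0, 20, 1); w[1, 1] <- 1; w[2, 1] <- -1
  a <- numeric(20); a[1] <- 0.5
  p <- rbm_params(w, a, 0.2)
  vA <- encode_one_hot("A")
  expect_equal(rbm_energy(p, vA, 1), -(0.5) - 0.2 - (1 + 1))
  # gauge symmetry: flipping (w_.j, b_j, h_j) leaves E unchanged
  set.seed(5)
  q <- random_params(2, 2)
  v2 <- encode_one_hot("KW")
  h <- c(1, -1)
  qf <- gauge_flip(q, 2)
  expect_equal(rbm_energy(q, v2, h), rbm_energy(qf, v2, h * c(1, -1)))
  expect_error(rbm_energy(q, v2, c(1, 1, 1)), "hidden")
})

test_that("hidden conditionals match two-state enumeration and are monotone in b", {
  z <- rbm_params(matrix(0, 20, 3), numeric(20), numeric(3))
  v <- encode_one_hot("C")
  expect_equal(drop(hidden_conditional(z, v)), rep(0.5, 3))
  set.seed(7)
  p <- random_params(1, 2)
  joint <- oracle_joint(p)
  for (res in c("A", "K", "Y")) {
    v <- drop(encode_one_hot(res))
    expect_equal(drop(hidden_conditional(p, v)),
                 oracle_hidden_conditional(joint, v), tolerance = 1e-12)
  }
  # p(h_j = +1 | v) strictly increases with b_j
  p2 <- rbm_params(p$w, p$a, p$b + c(0.5, 0))
  expect_gt(hidden_conditional(p2, v)[1], hidden_conditional(p, v)[1])
  expect_equal(hidden_conditional(p2, v)[2], hidden_conditional(p, v)[2])
  # overflow guard: huge fields give probabilities 0/1, not NaN
  wbig <- matrix(0, 20, 1); wbig[1, 1] <- 1000
  big <- rbm_params(wbig, numeric(20), 0)
  expect_equal(drop(hidden_conditional(big, encode_one_hot("A"))), 1)
  expect_equal(drop(hidden_conditional(big, encode_one_hot("C"))), 0)
})

test_that("local fields are affine in h and mirror about a", {
  set.seed(8)
  p <- random_params(1, 2)
  expect_equal(drop(local_fields(rbm_params(p$w * 0, p$a, p$b), c(1, -1))), p$a)
  f1 <- drop(local_fields(p, c(1, -1)))
  f2 <- drop(local_fields(p, c(-1, 1)))
  expect_equal((f1 + f2) / 2, p$a)
  # hand value: phi = a + w %*% h
  expect_equal(f1, p$a + drop(p$w %*% c(1, -1)))
})

test_that("block probabilities are the 20-state Boltzmann conditionals", {
  z <- rbm_params(matrix(0, 40, 1), numeric(40), 0)
  expect_equal(unname(block_probs(z, 1, gamma = 1)), rep(1/20, 20))
  set.seed(9)
  for (i in 1:5) {
    p <- random_params(2, 2)
    h <- sample(c(-1, 1), 2, TRUE)
    bp <- block_probs(p, h)
    expect_equal(unname(colSums(bp)), c(1, 1), tolerance = 1e-12)
    for (g in 1:2) {
      expect_equal(unname(bp[, g]), oracle_block_conditional(p, h, g),
                   tolerance = 1e-10)
    }
  }
})

test_that("samplers agree with their closed-form conditionals", {
  set.seed(10)
  p <- random_params(1, 2, sd = 0.6)
  v <- encode_one_hot("L")[rep(1, 20000), ]
  h <- sample_hidden(p, v)
  emp <- colMeans(h == 1)
  th <- drop(hidden_conditional(p, encode_one_hot("L")))
  se <- sqrt(th * (1 - th) / 20000)
  expect_true(all(abs(emp - th) < 4 * se))
  # visible draws: frequencies match block_probs within multinomial error
  hfix <- matrix(c(1, -1), 1)
  vs <- sample_visible(p, hfix[rep(1, 20000), , drop = FALSE])
  expect_true(all(rowSums(vs == 1) == 1))  # one-hot preserved (gamma = 1)
  emp2 <- as.vector(empirical_frequencies(vs))
  th2 <- unname(block_probs(p, hfix, gamma = 1))
  expect_true(all(abs(emp2 - th2) < 4 * sqrt(th2 * (1 - th2) / 20000) + 1e-3))
})

test_that("free energy and log partition match full enumeration", {
  set.seed(11)
  for (dims in list(c(1, 1), c(1, 2), c(2, 2))) {
    p <- random_params(dims[1], dims[2])
    joint <- oracle_joint(p)
    expect_equal(exact_log_partition(p), joint$logZ, tolerance = 1e-10)
    # p(v) from free energy vs enumeration
    pv <- oracle_marginal_v(joint)
    idx <- sample(nrow(joint$V), 5)
    expect_equal(-free_energy(p, joint$V[idx, ]) - joint$logZ,
                 log(pv[idx]), tolerance = 1e-10)
    # hidden marginal
    expect_equal(exact_hidden_marginal(p)$prob, unname(oracle_marginal_h(joint)),
                 tolerance = 1e-10)
  }
})

test_that("PLL is exact, gauge invariant, and Gamma*log(1/20) at zero", {
  z <- rbm_params(matrix(0, 100, 2), numeric(100), numeric(2))
  v <- encode_one_hot(c("ACDEF", "MKVLA"))
  expect_equal(as.numeric(pseudo_log_likelihood(z, v)), 5 * log(1/20))
  set.seed(12)
  p <- random_params(2, 2)
  vv <- encode_one_hot(c("AC", "KW", "YY"))
  expect_equal(as.numeric(pseudo_log_likelihood(p, vv)), oracle_pll(p, vv),
               tolerance = 1e-10)
  pf <- gauge_flip(p, 1)
  expect_equal(as.numeric(pseudo_log_likelihood(pf, vv)),
               as.numeric(pseudo_log_likelihood(p, vv)), tolerance = 1e-12)
  expect_error(pseudo_log_likelihood(random_params(1, 2), vv), "units")
})

test_that("analytic exact-likelihood gradient matches central differences", {
  set.seed(13)
  V <- encode_one_hot(sample(aa_alphabet, 30, TRUE))
  for (rep in 1:3) {
    p <- random_params(1, 2, sd = 0.5)
    g <- exact_loglik_grad(p, V)
    eps <- 1e-5
    # spot-check a handful of coordinates in each parameter block
    for (idx in list(c(1, 1), c(5, 2), c(20, 1))) {
      pp <- p$w; pp[idx[1], idx[2]] <- pp[idx[1], idx[2]] + eps
      pm <- p$w; pm[idx[1], idx[2]] <- pm[idx[1], idx[2]] - eps
      fd <- (exact_loglik_grad(rbm_params(pp, p$a, p$b), V)$loglik -
               exact_loglik_grad(rbm_params(pm, p$a, p$b), V)$loglik) / (2 * eps)
      expect_equal(g$dw[idx[1], idx[2]], fd, tolerance = 1e-5)
    }
    for (i in c(3, 17)) {
      ap <- p$a; ap[i] <- ap[i] + eps; am <- p$a; am[i] <- am[i] - eps
      fd <- (exact_loglik_grad(rbm_params(p$w, ap, p$b), V)$loglik -
               exact_loglik_grad(rbm_params(p$w, am, p$b), V)$loglik) / (2 * eps)
      expect_equal(g$da[i], fd, tolerance = 1e-5)
    }
    bp <- p$b; bp[2] <- bp[2] + eps; bm <- p$b; bm[2] <- bm[2] - eps
    fd <- (exact_loglik_grad(rbm_params(p$w, p$a, bp), V)$loglik -
             exact_loglik_grad(rbm_params(p$w, p$a, bm), V)$loglik) / (2 * eps)
    expect_equal(g$db[2], fd, tolerance = 1e-5)
  }
})

test_that("CD gradients vanish on model-generated data and approach the exact gradient", {
  set.seed(14)
  p <- random_params(1, 2, sd = 0.5)
  V <- encode_one_hot(rbm_generate(p, 20000, seed = 3))
  # stationarity: many-step chains from data average to ~zero gradient
  g <- cd_gradient(p, V[1:2000, ], n = 20)
  # Monte-Carlo scale of a +-1 moment difference over 2000 chains is
  # ~sqrt(2/2000) = 0.032 per coordinate; allow ~3 sigma on the max
  expect_lt(max(abs(g$dw)), 0.1)
  expect_lt(max(abs(g$da)), 0.1)
  expect_lt(max(abs(g$db)), 0.1)
  # CD with long chains ~ exact enumeration gradient at a mismatched model
  q <- random_params(1, 2, sd = 0.5)
  gx <- exact_loglik_grad(q, V[1:4000, ])
  gc <- cd_gradient(q, V[1:4000, ], n = 60)
  expect_lt(max(abs(gc$dw - gx$dw)), 0.08)
  expect_error(cd_gradient(p, V[0, , drop = FALSE]), "empty")
})

test_that("training is deterministic, inert at zero learning rate, and improves PLL", {
  pl <- make_planted_rbm(planted_spec(gamma = 2, masks = list(1L:2L),
                                      amplitude = 1, hidden_bias = 0.2))
  dat <- encode_one_hot(sample_planted(pl, 3000, seed = 5))
  sp <- split_train_valid(dat, 0.8, seed = 5)
  cfg0 <- train_config(epochs = 2, seed = 9, learning_rate = 0, pll_samples = 400)
  f0 <- rbm_train(sp, 1, cfg0)
  cfg0b <- train_config(epochs = 5, seed = 9, learning_rate = 0, pll_samples = 400)
  f0b <- rbm_train(sp, 1, cfg0b)
  expect_equal(f0$params, f0b$params)  # zero learning rate leaves the init untouched
  cfg <- train_config(epochs = 8, seed = 9, pll_samples = 400,
                      learning_rate = 1e-2)
  f1 <- rbm_train(sp, 1, cfg)
  f2 <- rbm_train(sp, 1, cfg)
  expect_identical(f1$params, f2$params)        # bit-identical trajectories
  expect_length(f1$pll_train, 8L)
  expect_gt(utils::tail(f1$pll_valid, 1), f1$pll_valid[1])
})

test_that("persistent chains carry over and give finite training", {
  pl <- make_planted_rbm(planted_spec(gamma = 2, masks = list(1L:2L),
                                      amplitude = 1, hidden_bias = 0.2))
  dat <- encode_one_hot(sample_planted(pl, 2000, seed = 6))
  sp <- split_train_valid(dat, 0.8, seed = 6)
  f <- rbm_train(sp, 2, train_config(epochs = 4, seed = 2, persistent = TRUE,
                                     cd_steps = 2, pll_samples = 300))
  expect_true(all(is.finite(f$params$w)))
  expect_true(all(is.finite(f$pll_valid)))
})

test_that("exact generation reproduces model statistics and respects the gauge", {
  set.seed(15)
  p <- random_params(2, 2, sd = 0.5)
  st <- rbm_generate(p, 30000, seed = 4)
  expect_equal(nrow(st), 30000L)
  # single-site frequencies match the mixture reconstruction of the model
  dec <- state_decomposition(p, encode_one_hot(st))
  mix <- mixture_reconstruction(dec)
  emp <- empirical_frequencies(st)
  expect_lt(attr(compare_frequency_tables(mix, emp), "max_tv"), 0.015)
  # gauge-flipped model generates the same sequence distribution
  st2 <- rbm_generate(gauge_flip(p, 1:2), 30000, seed = 44)
  tab1 <- table(factor(st$sequence, levels = union(st$sequence, st2$sequence)))
  tab2 <- table(factor(st2$sequence, levels = union(st$sequence, st2$sequence)))
  keep <- (tab1 + tab2) >= 10
  chi <- suppressWarnings(stats::chisq.test(rbind(tab1[keep], tab2[keep])))
  expect_gt(chi$p.value, 0.01)
  # zero-parameter model: uniform residue frequencies
  z <- rbm_params(matrix(0, 40, 1), numeric(40), 0)
  fz <- empirical_frequencies(rbm_generate(z, 20000, seed = 8))
  expect_true(all(abs(fz - 1/20) < 4 * sqrt(0.05 * 0.95 / 20000)))
})

test_that("model JSON serialization round-trips", {
  set.seed(16)
  p <- random_params(2, 3)
  f <- tempfile(fileext = ".json")
  write_rbm(p, f)
  q <- read_rbm(f)
  expect_equal(q$w, p$w)
  expect_equal(q$a, p$a)
  expect_equal(q$b, p$b)
  # single hidden unit (scalar-row corner case)
  p1 <- random_params(1, 1)
  write_rbm(p1, f)
  expect_equal(read_rbm(f)$w, p1$w)
})
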