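# Brute-force enumeration oracle for tiny models (Gamma <= 2, N_h <= 2).
# Everything here goes through rbm_energy() term sums only -- independent of
# the analytic free-energy / partition / conditional code paths it checks.

# all one-hot visible configurations for a given number of blocks
oracle_visible_configs <- function(gamma) {
  ks <- expand.grid(rep(list(1:20), gamma))
  t(apply(ks, 1, function(k) {
    v <- rep(-1, 20 * gamma)
    v[20 * (seq_len(gamma) - 1) + as.integer(k)] <- 1
    v
  }))
}

# joint p(v, h) table by direct energy evaluation
oracle_joint <- function(params) {
  V <- oracle_visible_configs(params$gamma)
  H <- hidden_states(params$n_hidden)
  E <- matrix(0, nrow(V), nrow(H))
  for (s in seq_len(nrow(H))) {
    E[, s] <- rbm_energy(params, V, H[rep(s, nrow(V)), , drop = FALSE])
  }
  w <- exp(-E)
  list(V = V, H = H, p = w / sum(w), logZ = log(sum(w)))
}

oracle_marginal_v <- function(joint) rowSums(joint$p)
oracle_marginal_h <- function(joint) colSums(joint$p)

# p(h_j = +1 | v) for one visible row
oracle_hidden_conditional <- function(joint, v_row) {
  i <- which(apply(joint$V, 1, function(x) all(x == v_row)))
  pj <- joint$p[i, ] / sum(joint$p[i, ])
  vapply(seq_len(ncol(joint$H)), function(j) sum(pj[joint$H[, j] == 1]),
         numeric(1))
}

# p(k at block g | h fixed) over the 20 candidates
oracle_block_conditional <- function(params, h_row, g) {
  V <- oracle_visible_configs(params$gamma)
  E <- rbm_energy(params, V, matrix(h_row, 1)[rep(1, nrow(V)), , drop = FALSE])
  w <- exp(-E)
  k_of <- apply(V[, 20 * (g - 1) + 1:20, drop = FALSE], 1, which.max)
  p <- vapply(1:20, function(k) sum(w[k_of == k]), numeric(1))
  p / sum(p)
}

# PLL by brute-force block conditionals
oracle_pll <- function(params, v) {
  joint <- oracle_joint(params)
  pv <- oracle_marginal_v(joint)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  per <- vapply(seq_len(nrow(v)), function(r) {
    tot <- 0
    for (g in seq_len(params$gamma)) {
      cols <- 20 * (g - 1) + 1:20
      same_rest <- apply(joint$V[, -cols, drop = FALSE], 1,
                         function(x) all(x == v[r, -cols]))
      num <- pv[same_rest & apply(joint$V[, cols, drop = FALSE], 1,
                                  function(x) all(x == v[r, cols]))]
      tot <- tot + log(num / sum(pv[same_rest]))
    }
    tot
  }, numeric(1))
  mean(per)
}

# small random model for property loops
random_params <- function(gamma, n_hidden, sd = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rbm_params(matrix(stats::rnorm(20 * gamma * n_hidden, sd = sd), 20 * gamma),
             stats::rnorm(20 * gamma, sd = sd),
             stats::rnorm(n_hidden, sd = sd))
}
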