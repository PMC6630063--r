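# small shared fixtures, built in code at test time

# tiny sequence data with strong per-area marginal signal
tiny_marginal_sim <- function(seed = 3, beta = 3, n_train = 200, n_val = 100,
                              K = 8, beta_rel = 0) {
  cfg <- sim_config(n_train = n_train, n_val = n_val, voxels_per_area = K,
                    snr = 10, beta_marginal = rep(beta, 5),
                    beta_relational = beta_rel, seed = seed)
  h <- make_label_hierarchy(cfg$seed)
  c(simulate_area_sequences(cfg, h), list(config = cfg, hierarchy = h))
}

# quick training settings used by unit (non-acceptance) tests
quick_brnn <- function(sim, epochs = 60, seed = 1, ...) {
  brnn(sim$train, sim$val, level = "coarse", epochs = epochs, seed = seed,
       hidden_dim = 8, ...)
}

# 99% Monte-Carlo bound for shuffled-label validation accuracy around chance.
# With clustered class signal the effective granularity is the 23 fine
# clusters (each cluster's memorized majority label is right or wrong as a
# unit), plus per-sample binomial noise; averaging R shuffle repeats shrinks
# both.
shuffled_chance_bound <- function(n_val, R = 1) {
  2.576 * sqrt((0.2 * 0.8 / 23 + 0.2 * 0.8 / n_val) / R)
}

# exhaustive best-subset least-squares residual oracle
best_subset_rss <- function(X, y, k) {
  best <- Inf
  for (cmb in utils::combn(ncol(X), k, simplify = FALSE)) {
    rss <- sum(stats::lsfit(X[, cmb, drop = FALSE], y, intercept = FALSE)$residuals^2)
    if (rss < best) best <- rss
  }
  best
}

# scalar hand-rolled LSTM cell oracle, written independently of the package
# implementation: plain loops over components.
oracle_cell <- function(x_t, h_prev, c_prev, W, b) {
  H <- length(h_prev)
  a <- c(h_prev, x_t)
  z <- numeric(4 * H)
  for (j in seq_len(4 * H)) {
    acc <- b[j]
    for (i in seq_along(a)) acc <- acc + W[i, j] * a[i]
    z[j] <- acc
  }
  sg <- function(v) 1 / (1 + exp(-v))
  f <- sg(z[1:H]); i <- sg(z[H + 1:H]); o <- sg(z[2 * H + 1:H])
  g <- tanh(z[3 * H + 1:H])
  c_t <- f * c_prev + i * g
  h_t <- o * tanh(c_t)
  list(h = h_t, c = c_t, f = f, i = i, o = o, g = g)
}
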