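test_that("the cell reduces to known values at zero weights and saturates gates", {
  p <- init_lstm_params(3, 2)
  p$W[] <- 0; p$b[] <- 0
  st <- lstm_cell_step(c(1, -1, 2), list(h = c(0, 0), c = c(0, 0)), p)
  expect_equal(st$gates$f, c(0.5, 0.5))
  expect_equal(st$gates$i, c(0.5, 0.5))
  expect_equal(st$gates$o, c(0.5, 0.5))
  expect_equal(st$state$c, c(0, 0))
  expect_equal(st$state$h, c(0, 0))
  # saturate forget open / input closed: memory passthrough
  H <- 2
  p$b[1:H] <- 30        # forget ~ 1
  p$b[H + 1:H] <- -30   # input ~ 0
  prev <- list(h = c(0.3, -0.2), c = c(1.5, -0.7))
  st <- lstm_cell_step(c(1, -1, 2), prev, p)
  expect_lt(max(abs(st$state$c - prev$c)), 1e-6)
})

test_that("the cell matches an independent scalar oracle on random instances", {
  set.seed(14)
  worst <- 0
  for (i in 1:100) {
    H <- sample(2:4, 1); K <- sample(2:4, 1)
    W <- matrix(rnorm((K + H) * 4 * H, sd = 0.5), K + H, 4 * H)
    b <- rnorm(4 * H, sd = 0.5)
    p <- structure(list(W = W, b = b, input_dim = K, hidden_dim = H),
                   class = "lstm_params")
    x <- rnorm(K); h0 <- rnorm(H, sd = 0.5); c0 <- rnorm(H, sd = 0.5)
    got <- lstm_cell_step(x, list(h = h0, c = c0), p)
    want <- oracle_cell(x, h0, c0, W, b)
    worst <- max(worst,
                 max(abs(got$state$h - want$h)), max(abs(got$state$c - want$c)),
                 max(abs(got$gates$f - want$f)), max(abs(got$gates$candidate - want$g)))
  }
  expect_lt(worst, 1e-10)
})

test_that("gate and state bounds hold on random inputs", {
  set.seed(15)
  ok_open <- TRUE; ok_closed <- TRUE
  for (i in 1:50) {
    p <- init_lstm_params(4, 3)
    st <- list(h = runif(3, -0.9, 0.9), c = rnorm(3))
    out <- lstm_cell_step(rnorm(4), st, p)
    gates <- c(out$gates$f, out$gates$i, out$gates$o)
    ok_open <- ok_open && all(gates > 0 & gates < 1) &&
      all(abs(out$gates$candidate) < 1) && all(abs(out$state$h) < 1)
    # under extreme weights the bounds still hold (allowing float saturation)
    pw <- p; pw$W[] <- rnorm(length(pw$W), sd = 20)
    outw <- lstm_cell_step(rnorm(4, sd = 3), st, pw)
    gw <- c(outw$gates$f, outw$gates$i, outw$gates$o)
    ok_closed <- ok_closed && all(gw >= 0 & gw <= 1) &&
      all(abs(outw$gates$candidate) <= 1) && all(abs(outw$state$h) <= 1)
  }
  expect_true(ok_open)
  expect_true(ok_closed)
  expect_error(lstm_cell_step(c(NA, 1, 1, 1), st, p), "non-finite")
})

test_that("direction runs compose cells correctly", {
  set.seed(16)
  p <- init_lstm_params(3, 4)
  s <- matrix(rnorm(15), 5, 3)
  # zero weights: zero final state
  pz <- p; pz$W[] <- 0; pz$b[] <- 0
  expect_equal(run_direction(s, pz, "forward"), rep(0, 4))
  # backward on s == forward on reversed s
  expect_equal(run_direction(s, p, "backward"),
               run_direction(s[5:1, ], p, "forward"))
  # L = 1 is exactly one cell step
  one <- lstm_cell_step(s[1, ], list(h = rep(0, 4), c = rep(0, 4)), p)
  expect_equal(run_direction(s[1, , drop = FALSE], p, "forward"), one$state$h)
  expect_error(run_direction(s[0, , drop = FALSE], p), "empty")
  # batched forward agrees with the per-sample loop
  x <- array(rnorm(6 * 5 * 3), c(6, 5, 3))
  batch_h <- visseq:::lstm_forward_batch(x, p)$h
  for (i in 1:6)
    expect_equal(unname(batch_h[i, ]), run_direction(x[i, , ], p, "forward"))
})

test_that("bidirectional encoding concatenates both directions, forward first", {
  set.seed(17)
  sim <- tiny_marginal_sim(seed = 1, n_train = 70, n_val = 30)
  m16 <- brnn(sim$train, level = "coarse", hidden_dim = 16, epochs = 1, seed = 1)
  s <- sim$val$x[1, , ]
  feat <- bidirectional_encode(s, m16)
  expect_length(feat, 32L)
  expect_equal(feat[1:16], run_direction(s, m16$params$fwd, "forward"))
  expect_equal(feat[17:32], run_direction(s, m16$params$bwd, "backward"))
  # zero parameters in both directions give a zero feature
  mz <- m16
  mz$params$fwd$W[] <- 0; mz$params$fwd$b[] <- 0
  mz$params$bwd$W[] <- 0; mz$params$bwd$b[] <- 0
  expect_equal(bidirectional_encode(s, mz), rep(0, 32))
  # perturbing only the V1 node changes both halves
  s2 <- s; s2[1, ] <- s2[1, ] + 1
  feat2 <- bidirectional_encode(s2, m16)
  expect_false(isTRUE(all.equal(feat[1:16], feat2[1:16])))
  expect_false(isTRUE(all.equal(feat[17:32], feat2[17:32])))
})

test_that("softmax head probabilities behave like a softmax", {
  set.seed(18)
  z <- rnorm(5)
  p <- softmax(z)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p > 0))
  expect_equal(softmax(z + 3), p) # shift invariance
  expect_equal(softmax(rep(0, 5)), rep(0.2, 5)) # zero logits: uniform
  Z <- matrix(rnorm(12), 3, 4)
  expect_equal(rowSums(softmax(Z)), rep(1, 3), tolerance = 1e-9)
})

test_that("focal loss recovers cross-entropy at gamma 0 and known values", {
  set.seed(19)
  for (i in 1:25) {
    C <- sample(3:6, 1)
    p <- softmax(rnorm(C))
    y <- sample(C, 1)
    expect_equal(focal_loss(p, y, gamma = 0), -log(p[y]), tolerance = 1e-12)
  }
  onehot <- c(1, 0, 0)
  expect_equal(focal_loss(onehot, 1, gamma = 5), 0)
  expect_equal(focal_loss(c(0.5, 0.5), 1, gamma = 5), 0.5^5 * log(2),
               tolerance = 1e-9)
  # batch form is the mean of per-sample losses
  P <- rbind(c(0.5, 0.5), c(0.9, 0.1))
  expect_equal(focal_loss(P, c(1, 1), gamma = 2),
               mean(c(0.5^2 * log(2), 0.1^2 * -log(0.9))), tolerance = 1e-12)
  expect_message(focal_loss(c(0, 1), 1, gamma = 2), "clamping")
})

test_that("trainable parameter counts match the architecture arithmetic", {
  p <- init_lstm_params(100, 16)
  expect_identical(n_params_lstm(p), 7488L)
  sim <- tiny_marginal_sim(seed = 2, n_train = 60, n_val = 20, K = 8)
  m <- brnn(sim$train, level = "coarse", hidden_dim = 16, epochs = 1, seed = 1)
  per_dir <- length(m$theta$fwd_W) + length(m$theta$fwd_b)
  expect_identical(per_dir, 4L * ((8L + 16L) * 16L + 16L))
  expect_identical(per_dir, length(m$theta$bwd_W) + length(m$theta$bwd_b))
})

test_that("analytic gradients match finite differences", {
  set.seed(20)
  n <- 6; L <- 5; K <- 3; H <- 3; C <- 5
  x <- array(rnorm(n * L * K), c(n, L, K))
  y <- sample(1:C, n, replace = TRUE)
  pf <- init_lstm_params(K, H); pb <- init_lstm_params(K, H)
  theta <- list(fwd_W = pf$W, fwd_b = pf$b, bwd_W = pb$W, bwd_b = pb$b,
                head_W = matrix(runif(2 * H * C, -0.3, 0.3), 2 * H, C),
                head_b = rnorm(C))
  lg <- visseq:::brnn_loss_grad(theta, x, y, gamma = 5, bidirectional = TRUE)
  eps <- 1e-6
  for (rep in 1:20) {
    nm <- sample(names(theta), 1)
    i <- sample(length(theta[[nm]]), 1)
    tp <- theta; tp[[nm]][i] <- tp[[nm]][i] + eps
    tm <- theta; tm[[nm]][i] <- tm[[nm]][i] - eps
    num <- (visseq:::brnn_loss_grad(tp, x, y, 5, TRUE)$loss -
              visseq:::brnn_loss_grad(tm, x, y, 5, TRUE)$loss) / (2 * eps)
    ana <- lg$grads[[nm]][i]
    expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-8), 1e-4)
  }
})
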