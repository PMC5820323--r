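test_that("NMSE matches its defining oracles", {
  set.seed(2)
  y <- stats::rnorm(50)
  expect_equal(nmse(y, y), 0)
  # predicting the mean scores exactly 1 (numerator = M * population variance)
  expect_equal(nmse(rep(mean(y), 50), y), 1)
  out <- y + stats::rnorm(50, sd = 0.1)
  expect_equal(nmse(3.7 * out, 3.7 * y), nmse(out, y))
  expect_error(nmse(y, rep(1, 50)), "variance")
  expect_error(nmse(y, y[1:10]), "length")
})

test_that("readout training solves the linear system exactly when it can", {
  # 3 equations, 2 unknowns, consistent: states (1,0),(0,1),(1,1),
  # atanh-targets 0.3, 0.5, 0.8 -> weights (0.3, 0.5), zero residual
  states <- rbind(c(1, 0), c(0, 1), c(1, 1))
  targets <- c(0, tanh(c(0.3, 0.5, 0.8)))   # target for row n is sample n+1
  tc <- training_config(n_train = 3, washout = 0, horizon = 2,
                        sigma_discard = 1, sigma_window = 1)
  ro <- train_readout(as_traj(states, mu = 1, driven = TRUE), targets, tc)
  expect_equal(ro$w_out, c(0.3, 0.5), tolerance = 1e-12)
  expect_equal(ro$training_nmse, 0, tolerance = 1e-20)
  expect_equal(ro$effective_rank, 2L)
  expect_error(train_readout(as_traj(states, mu = 1), c(0, 0.2, 1.0, 0.5), tc),
               "< 1")
})

test_that("the pseudoinverse readout is least-squares optimal", {
  set.seed(9)
  states <- matrix(stats::rnorm(60 * 4), 60, 4)
  truth <- tanh(states %*% c(0.2, -0.1, 0.4, 0)) + stats::rnorm(60, sd = 0.05)
  truth <- pmax(pmin(truth, 0.95), -0.95)
  targets <- c(0, truth)
  tc <- training_config(n_train = 60, washout = 0, horizon = 2,
                        sigma_discard = 1, sigma_window = 1)
  ro <- train_readout(as_traj(states, mu = 1, driven = TRUE), targets, tc)
  resid <- function(w) mean((states %*% w - atanh(truth))^2)
  base <- resid(ro$w_out)
  for (i in 1:25) {
    expect_gte(resid(ro$w_out + stats::rnorm(4, sd = 0.02)), base)
  }
  # selecting a single node can never beat the full regression
  node1 <- train_readout(as_traj(cbind(atanh(truth), stats::rnorm(60)),
                                 mu = 1, driven = TRUE), targets, tc)
  expect_lte(node1$training_nmse, 1e-20)
})

test_that("closed-loop prediction rejects degenerate teachers and flags saturation", {
  rc <- reservoir_config(n_nodes = 20, mu = 0.5, alpha = 0.8, seed = 3)
  w <- build_weights(rc)
  tc <- training_config(n_train = 200, washout = 20)
  expect_error(predict_closed_loop(w, rc, rep(0.1, 300), tc), "variance")
  expect_error(predict_closed_loop(w, rc, rep(0.1, 100), tc), "n_train")
  rc0 <- reservoir_config(n_nodes = 20, mu = 0.5, alpha = 0, seed = 3)
  expect_error(predict_closed_loop(build_weights(rc0), rc0,
                                   as.numeric(mg_5000())[1:300], tc),
               "alpha")
})

test_that("free-running error exceeds the training error on average", {
  teacher <- as.numeric(mg_5000())
  tc <- training_config(n_train = 800, washout = 100)
  ratio <- vapply(1:5, function(s) {
    rc <- reservoir_config(n_nodes = 120, mu = 0.9, alpha = 0.8, seed = s)
    w <- build_weights(rc)
    pred <- predict_closed_loop(w, rc, teacher, tc)
    pred$nmse / max(pred$readout$training_nmse, .Machine$double.xmin)
  }, numeric(1))
  expect_gt(mean(log(ratio)), 0)
})

test_that("sigma_alpha0 measures the variance of the untrained-input output", {
  teacher <- as.numeric(mg_5000())[1:300]
  tc <- training_config(n_train = 250, washout = 20)
  rc <- reservoir_config(n_nodes = 30, mu = 0.5, alpha = 0.8, seed = 6)
  w <- build_weights(rc)
  pred <- predict_closed_loop(w, rc, teacher, tc)
  s <- sigma_alpha0(pred, w, rc, teacher, tc)
  expect_gte(s, 0)
  # a zero readout makes the output exactly constant -> zero variation
  pred0 <- pred
  pred0$readout$w_out <- rep(0, 30)
  expect_equal(sigma_alpha0(pred0, w, rc, teacher, tc), 0)
  # mu = 0 freezes the autonomous network at the offset point: constant output
  rcf <- reservoir_config(n_nodes = 30, mu = 0, alpha = 0.8, seed = 6)
  predf <- pred
  expect_equal(sigma_alpha0(predf, w, rcf, teacher, tc), 0)
})
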