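test_that("synchronization error matches its closed forms", {
  # identical nodes: zero spread
  traj <- as_traj(matrix(rep(sin(1:40), 3), 40, 3), mu = 2)
  expect_equal(sync_error(traj)$delta, rep(0, 40))
  # two antisymmetric nodes (+a, -a): population sd is a, so delta = a / mu
  two <- as_traj(cbind(rep(1, 10), rep(-1, 10)), mu = 2)
  expect_equal(sync_error(two)$delta, rep(0.5, 10))
  # homogeneity in the states, invariance under a common shift
  set.seed(4)
  st <- matrix(stats::rnorm(60), 20, 3)
  d1 <- sync_error(as_traj(st, mu = 1.5))$delta
  expect_equal(sync_error(as_traj(3 * st, mu = 1.5))$delta, 3 * d1)
  expect_equal(sync_error(as_traj(st + 7, mu = 1.5))$delta, d1)
  expect_error(sync_error(as_traj(st, mu = 0)), "mu")
})

test_that("delay embedding has the prescribed geometry", {
  s <- stats::rnorm(100)
  expect_equal(delay_embed(s, delay = 5, dim = 1), matrix(s, ncol = 1))
  emb <- delay_embed(s, delay = 12, dim = 4)
  expect_equal(nrow(emb), 64)   # 100 - 3 * 12
  expect_equal(emb[1, ], s[c(37, 25, 13, 1)])
  const <- delay_embed(rep(2, 50), delay = 3, dim = 4)
  expect_true(all(const == 2))
  expect_error(delay_embed(s[1:30], delay = 12, dim = 4), "short")
})

test_that("auto-MI delay selection finds the first minimum of the lag curve", {
  # sinusoid: the binned auto-MI has a broad minimum between the immediate
  # decorrelation and the half-period recurrence; the selected lag must fall
  # well inside it, not at a trivially small or aliased value
  p <- 100
  s <- sin(2 * pi * seq_len(4000) / p)
  lag <- estimate_delay(s, max_lag = 60)
  expect_gt(lag, p / 10)
  expect_lt(lag, p / 2)
  # i.i.d. noise: MI starts at its floor, so an immediate lag is selected
  set.seed(12)
  expect_lte(estimate_delay(stats::rnorm(3000)), 3L)
})

test_that("false-nearest-neighbour dimension matches geometric oracles", {
  # a circle embeds in the plane
  s <- sin(2 * pi * seq_len(3000) / 40)
  expect_equal(estimate_dimension(s, delay = 10), 2L)
  # a pure line unfolds in one dimension
  ramp <- seq(0, 1, length.out = 2000)
  expect_equal(estimate_dimension(ramp, delay = 5), 1L)
})

test_that("the divergence-rate estimator recovers the logistic-map exponent", {
  x <- logistic_series(5000)
  est <- max_lyapunov(x, delay = 1, dim = 2, theiler = 10)
  expect_true(est$valid)
  expect_lt(abs(est$lambda_max - log(2)) / log(2), 0.10)
})

test_that("the MG estimate agrees with the tangent-space ground truth", {
  # Benettin iteration of the analytic Jacobian is a fully independent route
  truth <- benettin_mg_lambda()
  est <- max_lyapunov(as.numeric(mg_5000()), delay = 12, dim = 4)
  expect_true(est$valid)
  expect_lt(abs(est$lambda_max - truth) / truth, 0.25)
})

test_that("degenerate and periodic records do not yield positive exponents", {
  expect_false(max_lyapunov(rep(1, 2000), delay = 1, dim = 2)$valid)
  per <- sin(2 * pi * seq_len(3000) / 25)
  est <- max_lyapunov(per, delay = 6, dim = 2)
  expect_true(!est$valid || est$lambda_max <= 0.005)
})

test_that("network exponent is the maximum over valid node estimates", {
  x <- logistic_series(3000)
  per <- sin(2 * pi * seq_len(3000) / 25)
  same <- as_traj(cbind(x, x), mu = 1)
  nl <- network_lyapunov(same, delay = 1, dim = 2, theiler = 10)
  single <- max_lyapunov(x, delay = 1, dim = 2, theiler = 10)
  expect_equal(nl$lambda_max, single$lambda_max)
  mixed <- as_traj(cbind(x, per), mu = 1)
  nm <- network_lyapunov(mixed, delay = 1, dim = 2, theiler = 10,
                         max_invalid_frac = 0.6)
  expect_lt(abs(nm$lambda_max - log(2)) / log(2), 0.10)
})

test_that("regime classification follows amplitude and divergence evidence", {
  expect_equal(classify_regime(rep(0.3, 1500), mu = 1)$label, "fixed_point")
  per <- sin(2 * pi * seq_len(1500) / 30)
  expect_equal(classify_regime(per, mu = 1)$label, "periodic")
  expect_equal(classify_regime(logistic_series(1500), mu = 1)$label, "chaotic")
})
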