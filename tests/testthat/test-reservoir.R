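test_that("weight construction honours connectivity, bounds and the seed", {
  rc <- reservoir_config(n_nodes = 40, connectivity = 1, seed = 5)
  w <- build_weights(rc)
  expect_true(all(w$W > 0))
  rc2 <- reservoir_config(n_nodes = 40, connectivity = 0.9, seed = 5)
  w2 <- build_weights(rc2)
  expect_equal(sum(w2$W == 0), floor(0.1 * 40^2))
  expect_true(all(w2$W >= 0 & w2$W <= 1))
  expect_true(all(w2$w_off >= -1 & w2$w_off <= 1))
  expect_true(all(w2$w_fb >= 0 & w2$w_fb <= 1))
  # normalized dominant eigenvalue
  expect_equal(abs(eigen(w2$W, only.values = TRUE)$values[1]), 1,
               tolerance = 1e-8)
  w3 <- build_weights(rc2)
  expect_identical(w2$W, w3$W)
  expect_identical(w2$w_fb, w3$w_fb)
})

test_that("full-size construction zeroes exactly the prescribed entry count", {
  w <- build_weights(reservoir_config(seed = 1))
  expect_equal(sum(w$W == 0), 2500)       # floor(0.01 * 500^2)
  expect_equal(dim(w$W), c(500L, 500L))
})

test_that("a single step follows mu * sin(W x + W_off b + W_fb alpha u)", {
  rc <- reservoir_config(n_nodes = 1, mu = 1, offset_b = 0, alpha = 0, seed = 1)
  w <- manual_weights(pi / 2, w_off = 0, w_fb = 0, config = rc)
  # superstable fixed point at the sine's extremum: sin(pi/2 * 1) = 1
  expect_equal(reservoir_step(1, 0, w, rc), 1)
  # mu = 0 collapses any state to zero
  rc0 <- reservoir_config(n_nodes = 3, mu = 0, seed = 1)
  w0 <- manual_weights(diag(3), w_off = rep(1, 3), w_fb = rep(1, 3), config = rc0)
  expect_equal(reservoir_step(c(9, -3, 2), 5, w0, rc0), c(0, 0, 0))
  expect_error(reservoir_step(c(NaN, 0, 0), 0, w0, rc0), "NaN")
})

test_that("states are bounded by mu for the sine activation", {
  set.seed(3)
  for (mu in c(0.3, 1, 4, 20)) {
    rc <- reservoir_config(n_nodes = 30, mu = mu, alpha = 0.8,
                           seed = sample.int(1000, 1))
    w <- build_weights(rc)
    traj <- run_reservoir(w, rc, input = stats::rnorm(200), n_steps = 200)
    expect_lte(max(abs(traj$states)), mu)
  }
})

test_that("autonomous runs ignore any supplied input when alpha is zero", {
  rc <- reservoir_config(n_nodes = 25, mu = 2, alpha = 0, seed = 8)
  w <- build_weights(rc)
  t1 <- run_reservoir(w, rc, n_steps = 100)
  t2 <- run_reservoir(w, rc, input = stats::runif(100), n_steps = 100)
  expect_identical(t1$states, t2$states)
  expect_false(t2$driven)
  # mu = 0 from the origin stays at the origin
  rc0 <- reservoir_config(n_nodes = 25, mu = 0, seed = 8)
  expect_true(all(run_reservoir(build_weights(rc0), rc0, n_steps = 20)$states == 0))
})

test_that("identical seed and config reproduce the trajectory bit for bit", {
  rc <- reservoir_config(n_nodes = 50, mu = 3, alpha = 0, seed = 123)
  a <- run_reservoir(build_weights(rc), rc, n_steps = 150)
  b <- run_reservoir(build_weights(rc), rc, n_steps = 150)
  expect_identical(a$states, b$states)
})

test_that("the second regular window hosts periodic, spatially synchronized dynamics", {
  rc <- reservoir_config(mu = 5, alpha = 0, seed = 2)
  w <- build_weights(rc)
  traj <- run_reservoir(w, rc, n_steps = 1700)
  post <- as_traj(traj$states[501:1700, ], mu = 5)
  cls <- classify_regime(post$states[, 34], mu = 5)
  expect_equal(cls$label, "periodic")
  # strong spatial synchronization: phase spread well below the chaotic level
  expect_lt(sync_error(post)$mean_delta, 0.06)
})

test_that("a trivial grid yields a fixed-point window at zero", {
  rc <- reservoir_config(n_nodes = 20, mu = 0, alpha = 0, seed = 4)
  w <- build_weights(rc)
  bd <- bifurcation_scan(w, rc, mu_grid = 0, node_index = 1,
                         transient = 50, n_sampled = 20, n_classify = 100)
  expect_equal(bd$regimes$regime, "fixed_point")
  expect_equal(bd$windows$mu_lo, 0)
  expect_equal(bd$windows$mu_hi, 0)
  expect_true(all(bd$samples$state == 0))
  expect_error(bifurcation_scan(w, rc, mu_grid = numeric(0)), "empty")
})

test_that("the first window's upper boundary is stable across realizations", {
  # the edge detected on a 0.1 grid should agree to within 0.3 in mu
  edges <- vapply(1:10, function(s) {
    rc <- reservoir_config(mu = 1, alpha = 0, seed = s)
    w <- build_weights(rc)
    bd <- bifurcation_scan(w, rc, mu_grid = seq(2.4, 3.2, 0.1))
    first_chaotic <- bd$regimes$mu[
      !bd$regimes$regime %in% c("fixed_point", "periodic")][1]
    first_chaotic - 0.1
  }, numeric(1))
  expect_lt(diff(range(edges, na.rm = TRUE)), 0.3 + 1e-9)
})
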