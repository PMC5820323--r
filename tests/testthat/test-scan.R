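# A deliberately small profile so scan plumbing is exercised in seconds:
# 60-node reservoir, short teacher, two mu values.
small_scan_config <- function(mu_grid = c(0.8, 1.0), n_realizations = 2,
                              base_seed = 7L, metrics = c("nmse", "sigma", "delta")) {
  tc <- training_config(n_train = 300, washout = 50)
  scan_config(
    mu_grid = mu_grid, n_realizations = n_realizations, base_seed = base_seed,
    metrics = metrics, training = tc,
    reservoir = reservoir_config(n_nodes = 60, alpha = 0.8),
    mg = mg_config(length = tc$n_train + tc$horizon, transient = 300),
    autonomous_steps = 200, classify_regimes = TRUE
  )
}

test_that("a scan is reproducible and summarizes its own cells", {
  cfg <- small_scan_config()
  r1 <- run_scan(cfg)
  r2 <- run_scan(cfg)
  expect_identical(r1$cells, r2$cells)
  expect_equal(nrow(r1$cells), 4)
  expect_true(all(is.na(r1$cells$error)))
  # summary agrees with hand-aggregation
  by_mu <- tapply(r1$cells$nmse, r1$cells$mu, mean)
  expect_equal(unname(r1$summary$nmse_mean), unname(as.numeric(by_mu)))
})

test_that("a single-realization summary equals its row", {
  cfg <- small_scan_config(mu_grid = 0.9, n_realizations = 1)
  r <- run_scan(cfg)
  expect_equal(nrow(r$cells), 1)
  expect_equal(r$summary$nmse_mean, r$cells$nmse)
  expect_equal(r$summary$delta_mean_driven_mean, r$cells$delta_mean_driven)
  expect_true(is.na(r$summary$nmse_sd))
})

test_that("per-cell failures are recorded without aborting the scan", {
  cfg <- small_scan_config(mu_grid = c(0.8, 1.0), n_realizations = 1)
  cfg$training <- training_config(n_train = 400, washout = 50)   # teacher too short
  r <- run_scan(cfg)
  expect_true(all(!is.na(r$cells$error)))
  expect_equal(nrow(r$cells), 2)
})

test_that("window detection groups consecutive non-chaotic grid points", {
  fake <- function(mu, regime) {
    structure(list(cells = tibble::tibble(mu = mu, regime = regime)),
              class = "scan_result")
  }
  grid <- seq(4.5, 5.7, 0.1)
  lab <- ifelse(grid >= 4.8 - 1e-9 & grid <= 5.4 + 1e-9, "periodic", "chaotic")
  w <- detect_windows(fake(grid, lab))
  expect_equal(w$mu_lo, 4.8)
  expect_equal(w$mu_hi, 5.4)
  expect_equal(nrow(detect_windows(fake(grid, rep("chaotic", length(grid))))), 0)
  # mixed labels: fixed points count as non-chaotic too
  lab2 <- c("fixed_point", "fixed_point", "periodic", rep("chaotic", 10))
  expect_equal(detect_windows(fake(grid, lab2))$mu_hi, 4.7)
})

test_that("scan results round-trip through CSV plus JSON sidecar", {
  cfg <- small_scan_config(mu_grid = 0.9, n_realizations = 1)
  r <- run_scan(cfg)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  write_scan(r, path)
  back <- read_scan(path)
  expect_equal(back$cells$nmse, r$cells$nmse)
  expect_equal(back$config$mu_grid, cfg$mu_grid)
  expect_equal(back$config$training$n_train, 300L)
  expect_equal(back$summary$nmse_mean, r$summary$nmse_mean)
})

test_that("tidiers expose cells and plot methods return ggplot objects", {
  cfg <- small_scan_config(mu_grid = 0.9, n_realizations = 1)
  r <- run_scan(cfg)
  expect_s3_class(tidy(r), "tbl_df")
  expect_equal(glance(r)$n_failed, 0L)
  expect_s3_class(autoplot(r), "ggplot")
})
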