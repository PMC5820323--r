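# Independent oracles and small fixture builders used across the suite.

# Chaotic logistic map at r = 4: analytic maximal Lyapunov exponent ln 2.
logistic_series <- function(n, x0 = 0.2) {
  x <- numeric(n)
  x[1] <- x0
  for (i in 2:n) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x
}

# Ground-truth maximal Lyapunov exponent of the discrete Mackey-Glass map by
# tangent-space (Benettin) iteration: the map's state is its last 171
# iterates, the Jacobian is analytic, and the exponent is the mean log
# growth of a co-evolved tangent vector. Returned per retained sample
# (10 map iterates). Entirely independent of the package's
# neighbour-divergence estimator.
benettin_mg_lambda <- function(n_iter = 3e5, n_trans = 2e4) {
  d <- 0.1
  L <- 170
  yb <- rep(1.2, L + 1)
  vb <- sin(seq_len(L + 1))   # fixed, generic tangent direction
  vb <- vb / sqrt(sum(vb^2))
  cur <- L + 1
  lsum <- 0
  cnt <- 0
  for (n in seq_len(n_trans + n_iter)) {
    i_old <- cur %% (L + 1) + 1
    ycur <- yb[cur]; yold <- yb[i_old]
    a <- 1 - 0.1 * d
    b <- d * 0.2 * (1 - 9 * yold^10) / (1 + yold^10)^2
    yb[i_old] <- a * ycur + d * 0.2 * yold / (1 + yold^10)
    vb[i_old] <- a * vb[cur] + b * vb[i_old]
    cur <- i_old
    if (n %% 500 == 0) {
      nv <- sqrt(sum(vb^2))
      if (n > n_trans) {
        lsum <- lsum + log(nv)
        cnt <- cnt + 500
      }
      vb <- vb / nv
    }
  }
  10 * lsum / cnt
}

# Plug-in entropy (bits) under the same equal-width binning as the MI
# estimator, for bound checks.
binned_entropy <- function(x, bins) {
  r <- range(x)
  if (r[1] == r[2]) return(0)
  ix <- pmin(bins, floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L)
  p <- tabulate(ix, nbins = bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Hand-assembled single-node weight set for analytic stepping checks.
manual_weights <- function(W, w_off, w_fb, config) {
  structure(list(W = matrix(W, config$n_nodes, config$n_nodes),
                 w_off = w_off, w_fb = w_fb,
                 spectral_radius = NA_real_, seed = config$seed,
                 config = config),
            class = "reservoir_weights")
}

# Wrap a plain matrix as a trajectory (time x nodes).
as_traj <- function(states, mu, driven = FALSE, input = NULL) {
  sinres:::new_state_trajectory(as.matrix(states), mu = mu, driven = driven,
                                input_used = input)
}

# One shared default Mackey-Glass series per test run (generation is fast
# but not free; several files embed or analyse the same series).
mg_5000 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- center_mg(generate_mg(mg_config(length = 5000)))
    cache
  }
})
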