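#' Reservoir configuration
#'
#' Parameters of the random recurrent network
#' \deqn{x_{n+1} = \mu\, f(W x_n + W^{off} b + W^{fb}\, \alpha\, y_n),}
#' with \eqn{f} the sine (default) or tanh activation, \eqn{W} an
#' \eqn{N \times N} random matrix with entries uniform on \eqn{[0, 1]} and a
#' fixed fraction of entries zeroed, and \eqn{W^{off}}, \eqn{W^{fb}} random
#' N-vectors with the same distribution. \eqn{\mu} is the feedback gain and
#' the single bifurcation parameter of the system.
#'
#' @param n_nodes Number of nodes N (default 500).
#' @param mu Feedback gain \eqn{\mu \ge 0}.
#' @param offset_b Scalar offset b applied through \eqn{W^{off}} (default 0.2).
#' @param alpha Input scaling \eqn{\alpha \ge 0} (0 = autonomous, 0.8 = driven
#'   default).
#' @param connectivity Fraction of nonzero entries in W (default 0.99).
#' @param activation "sine" (default) or "tanh".
#' @param seed Integer RNG seed for weight construction.
#' @return An object of class \code{reservoir_config}.
#' @export
reservoir_config <- function(n_nodes = 500, mu = 1, offset_b = 0.2,
                             alpha = 0, connectivity = 0.99,
                             activation = c("sine", "tanh"), seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(n_nodes >= 1, connectivity > 0, connectivity <= 1,
            alpha >= 0, mu >= 0)
  structure(
    list(n_nodes = as.integer(n_nodes), mu = mu, offset_b = offset_b,
         alpha = alpha, connectivity = connectivity, activation = activation,
         seed = as.integer(seed)),
    class = "reservoir_config"
  )
}

activation_fun <- function(config) {
  switch(config$activation, sine = sin, tanh = tanh)
}

#' Build the random weight triple of a reservoir
#'
#' Draws \eqn{W} (N x N), \eqn{W^{off}} and \eqn{W^{fb}} (N-vectors) with
#' entries uniform on \eqn{[0, 1]}; a uniformly random set of
#' \eqn{\lfloor (1 - c) N^2 \rfloor} entries of W is zeroed to realize
#' connectivity \eqn{c}. Following echo-state convention, W is then divided
#' by its spectral radius, so that \eqn{\mu} is the effective feedback gain
#' of the recurrent loop and the network destabilizes near \eqn{\mu = 1}
#' (entries stay inside \eqn{[0, 1]}; the raw spectral radius of a dense
#' uniform matrix is about \eqn{N/2}, which would otherwise bury the gain
#' scale). The offset weights \eqn{W^{off}} are drawn uniform on
#' \eqn{[-1, 1]}: the product \eqn{W^{off}b} sets each node's operating
#' phase on the sine, and signed offsets give the nodes the phase diversity
#' a useful reservoir needs (with all-positive offsets the node responses
#' are nearly collinear and the readout degenerates). The input weights
#' \eqn{W^{fb}} stay uniform on \eqn{[0, 1]}. Fully reproducible from
#' \code{config$seed}.
#'
#' @param config A [reservoir_config()].
#' @return An object of class \code{reservoir_weights}: list with \code{W}
#'   (normalized), \code{w_off}, \code{w_fb}, \code{spectral_radius} (of the
#'   raw draw), \code{seed}, \code{config}.
#' @export
build_weights <- function(config) {
  stopifnot(inherits(config, "reservoir_config"))
  n <- config$n_nodes
  set.seed(config$seed)
  W <- matrix(stats::runif(n * n), n, n)
  # guard the floor against float noise in (1 - connectivity)
  n_zero <- floor((1 - config$connectivity) * n * n + 1e-9)
  if (n_zero > 0) {
    W[sample.int(n * n, n_zero)] <- 0
  }
  w_off <- stats::runif(n, -1, 1)
  w_fb <- stats::runif(n)
  rho <- spectral_radius(W)
  if (rho > 0) W <- W / rho
  structure(
    list(W = W, w_off = w_off, w_fb = w_fb, spectral_radius = rho,
         seed = config$seed, config = config),
    class = "reservoir_weights"
  )
}

# Dominant eigenvalue modulus. The entrywise-nonnegative draws have a real
# positive Perron eigenvalue, so power iteration converges fast; fall back to
# a full eigendecomposition if it does not.
spectral_radius <- function(W) {
  n <- nrow(W)
  if (n == 1) return(abs(W[1]))
  v <- rep(1 / sqrt(n), n)
  rho <- 0
  for (it in 1:200) {
    wv <- W %*% v
    nv <- sqrt(sum(wv^2))
    if (nv == 0) return(0)
    v <- as.numeric(wv / nv)
    if (abs(nv - rho) < 1e-12 * nv) return(nv)
    rho <- nv
  }
  abs(eigen(W, only.values = TRUE)$values[1])
}

#' @export
print.reservoir_weights <- function(x, ...) {
  cat(sprintf("<reservoir_weights> N = %d, connectivity = %.3g, seed = %d\n",
              x$config$n_nodes, mean(x$W != 0), x$seed))
  invisible(x)
}

#' One reservoir update step
#'
#' Applies \eqn{x' = \mu\, f(W x + W^{off} b + W^{fb} \alpha u)}. With the
#' sine activation every component of the next state is bounded by \eqn{\mu}
#' in magnitude.
#'
#' @param x Current state (length-N numeric).
#' @param u Scalar input sample (0 in autonomous mode).
#' @param weights A [build_weights()] result.
#' @param config A [reservoir_config()] supplying \eqn{\mu}, b, \eqn{\alpha}
#'   and the activation.
#' @return The next state vector.
#' @export
reservoir_step <- function(x, u, weights, config = weights$config) {
  if (anyNA(x) || is.na(u)) stop("NaN in state or input", call. = FALSE)
  stopifnot(length(x) == config$n_nodes, length(u) == 1)
  f <- activation_fun(config)
  drive <- weights$W %*% x + weights$w_off * config$offset_b +
    weights$w_fb * (config$alpha * u)
  as.numeric(config$mu * f(drive))
}

new_state_trajectory <- function(states, mu, driven, input_used = NULL) {
  structure(
    list(states = states, mu = mu, driven = driven, input_used = input_used),
    class = "state_trajectory"
  )
}

#' Run the reservoir for many steps
#'
#' Iterates [reservoir_step()] from \code{x0}. In driven mode
#' (\code{config$alpha > 0} and an input supplied) the update producing row
#' \eqn{n+1} of the trajectory consumes input sample \eqn{y_n}: the trained
#' readout of state \eqn{x_{n+1}} then targets \eqn{y_{n+1}}, the one-step
#' prediction. With \eqn{\alpha = 0} the input (if any) has no effect.
#'
#' @param weights A [build_weights()] result.
#' @param config A [reservoir_config()].
#' @param input Optional numeric input series, length \eqn{\ge} \code{n_steps}.
#' @param n_steps Number of update steps (trajectory rows).
#' @param x0 Initial state; default all zeros.
#' @return A \code{state_trajectory}: list with \code{states} (n_steps x N
#'   matrix, row n is \eqn{x_{n+1}} after consuming input sample n), \code{mu},
#'   \code{driven} flag and \code{input_used}.
#' @export
run_reservoir <- function(weights, config = weights$config, input = NULL,
                          n_steps = if (!is.null(input)) length(input) else 1000,
                          x0 = NULL) {
  stopifnot(inherits(weights, "reservoir_weights"))
  n <- config$n_nodes
  if (is.null(x0)) x0 <- numeric(n)
  stopifnot(length(x0) == n)
  driven <- config$alpha > 0 && !is.null(input)
  if (driven && length(input) < n_steps) {
    stop("driven run needs input length >= n_steps", call. = FALSE)
  }
  u <- if (driven) as.numeric(input)[seq_len(n_steps)] else numeric(n_steps)
  f <- activation_fun(config)
  states <- matrix(0, n_steps, n)
  x <- x0
  bias <- weights$w_off * config$offset_b
  for (s in seq_len(n_steps)) {
    x <- as.numeric(config$mu * f(weights$W %*% x + bias +
                                    weights$w_fb * (config$alpha * u[s])))
    if (anyNA(x)) stop("state diverged to NaN at step ", s, call. = FALSE)
    states[s, ] <- x
  }
  new_state_trajectory(states, mu = config$mu, driven = driven,
                       input_used = if (driven) u else NULL)
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("<state_trajectory> %d steps x %d nodes, mu = %g, %s\n",
              nrow(x$states), ncol(x$states), x$mu,
              if (x$driven) "driven" else "autonomous"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.state_trajectory <- function(x, nodes = NULL, ...) {
  if (is.null(nodes)) nodes <- seq_len(ncol(x$states))
  tibble::tibble(
    step = rep(seq_len(nrow(x$states)), times = length(nodes)),
    node = rep(as.integer(nodes), each = nrow(x$states)),
    state = as.numeric(x$states[, nodes])
  )
}

#' Bifurcation scan of the autonomous reservoir
#'
#' For each \eqn{\mu} on the grid, runs the autonomous network
#' (\eqn{\alpha = 0}) past a transient, samples one node's values (the
#' bifurcation diagram), and classifies the regime at that \eqn{\mu} with
#' [classify_regime()]. Contiguous non-chaotic grid runs are reported as
#' regular windows at the grid resolution.
#'
#' @param weights A [build_weights()] result.
#' @param config A [reservoir_config()] with \code{alpha = 0}.
#' @param mu_grid Strictly increasing vector of \eqn{\mu} values.
#' @param node_index Node whose values are sampled (default 34).
#' @param transient Steps discarded before sampling (default 1000).
#' @param n_sampled Post-transient states retained for the diagram
#'   (default 200).
#' @param n_classify Post-transient node samples used by the regime
#'   classifier (default 1200; the classifier's Lyapunov estimator needs a
#'   longer record than the diagram does).
#' @return An object of class \code{bifurcation_diagram}: list with
#'   \code{samples} (tibble: mu, sample_index, state), \code{regimes} (tibble:
#'   mu, regime, lambda_max), \code{windows} (tibble: mu_lo, mu_hi of
#'   non-chaotic runs), \code{node_index}, \code{mu_grid}.
#' @export
bifurcation_scan <- function(weights, config = weights$config, mu_grid,
                             node_index = 34, transient = 1000,
                             n_sampled = 200, n_classify = 1200) {
  stopifnot(inherits(weights, "reservoir_weights"))
  if (length(mu_grid) == 0) stop("empty mu grid", call. = FALSE)
  if (is.unsorted(mu_grid, strictly = TRUE)) {
    stop("mu_grid must be strictly increasing", call. = FALSE)
  }
  if (config$alpha != 0) stop("bifurcation scan requires alpha = 0", call. = FALSE)
  n_run <- transient + max(n_sampled, n_classify)
  rows <- vector("list", length(mu_grid))
  regs <- vector("list", length(mu_grid))
  for (k in seq_along(mu_grid)) {
    cfg_k <- config
    cfg_k$mu <- mu_grid[k]
    traj <- run_reservoir(weights, cfg_k, n_steps = n_run)
    node_series <- traj$states[(transient + 1):n_run, node_index]
    samp <- node_series[seq_len(n_sampled)]
    cls <- classify_regime(node_series[seq_len(min(n_classify, length(node_series)))],
                           mu = mu_grid[k])
    rows[[k]] <- tibble::tibble(mu = mu_grid[k],
                                sample_index = seq_len(n_sampled),
                                state = samp)
    regs[[k]] <- tibble::tibble(mu = mu_grid[k], regime = cls$label,
                                lambda_max = cls$evidence$lambda_max %||% NA_real_)
  }
  regimes <- dplyr::bind_rows(regs)
  structure(
    list(samples = dplyr::bind_rows(rows),
         regimes = regimes,
         windows = nonchaotic_windows(regimes$mu, regimes$regime),
         node_index = node_index, mu_grid = mu_grid),
    class = "bifurcation_diagram"
  )
}

# Maximal runs of consecutive non-chaotic grid points as closed intervals.
# Runs of a single grid point are dropped: at grid resolution d-mu an
# isolated point has zero measurable width and cannot be distinguished from
# one of the measure-thin periodic slivers that pepper the chaotic gaps.
nonchaotic_windows <- function(mu, regime, min_points = 2L) {
  min_points <- min(min_points, length(mu))
  ok <- regime %in% c("fixed_point", "periodic")
  if (!any(ok)) {
    return(tibble::tibble(mu_lo = numeric(0), mu_hi = numeric(0)))
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_points
  tibble::tibble(mu_lo = mu[starts[keep]], mu_hi = mu[ends[keep]])
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("<bifurcation_diagram> node %d, %d mu values in [%g, %g]\n",
              x$node_index, length(x$mu_grid), min(x$mu_grid), max(x$mu_grid)))
  cat("non-chaotic windows:\n")
  print(x$windows)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bifurcation_diagram <- function(x, ...) x$samples

#' @exportS3Method generics::glance
glance.bifurcation_diagram <- function(x, ...) {
  tibble::tibble(n_mu = length(x$mu_grid), n_windows = nrow(x$windows),
                 node_index = x$node_index)
}

#' Plot a bifurcation diagram
#'
#' Sampled node states against \eqn{\mu}, with detected non-chaotic windows
#' shaded.
#'
#' @param object A \code{bifurcation_diagram}.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bifurcation_diagram <- function(object, ...) {
  p <- ggplot2::ggplot(object$samples, ggplot2::aes(x = .data$mu, y = .data$state)) +
    ggplot2::geom_point(size = 0.1, alpha = 0.3) +
    ggplot2::labs(x = expression(mu),
                  y = sprintf("node %d state", object$node_index))
  if (nrow(object$windows) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$windows,
      ggplot2::aes(xmin = .data$mu_lo, xmax = .data$mu_hi,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.15
    )
  }
  p
}
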