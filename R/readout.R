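#' Training configuration for the readout layer
#'
#' @param n_train Teacher samples used for training (default 2000).
#' @param washout Initial training samples excluded from the regression
#'   (default 100; removes initial-state bias).
#' @param horizon Closed-loop free-run length in steps (default 35, twice the
#'   Mackey-Glass delay).
#' @param sigma_discard Transient free-run samples discarded before the
#'   autonomous-output variation is measured (default 10).
#' @param sigma_window Samples over which the autonomous-output variation is
#'   measured (default 25). \code{horizon = sigma_discard + sigma_window}.
#' @return An object of class \code{training_config}.
#' @export
training_config <- function(n_train = 2000, washout = 100, horizon = 35,
                            sigma_discard = 10, sigma_window = 25) {
  stopifnot(n_train > washout, washout >= 0, horizon >= 1,
            horizon == sigma_discard + sigma_window)
  structure(
    list(n_train = as.integer(n_train), washout = as.integer(washout),
         horizon = as.integer(horizon), sigma_discard = as.integer(sigma_discard),
         sigma_window = as.integer(sigma_window)),
    class = "training_config"
  )
}

#' Train the tanh-limited linear readout
#'
#' The readout produces \eqn{y^{out}_{n+1} = \tanh(W^{out} x_{n+1})}. Because
#' the centered teacher lies strictly inside \eqn{(-1, 1)}, the nonlinear
#' least-squares problem is linearized exactly: the regression targets are
#' \eqn{\mathrm{atanh}(y^T_{n+1})} and \eqn{W^{out}} solves the resulting
#' linear problem by SVD pseudoinverse, with singular values below
#' \code{max(dim) * eps * d1} truncated (the effective rank is reported).
#' No ridge regularization is applied.
#'
#' @param traj A driven \code{state_trajectory} on the teacher (row n is the
#'   state after consuming teacher sample n).
#' @param targets The teacher series; target for trajectory row n is sample
#'   \eqn{n + 1}. All values must satisfy \eqn{|y| < 1}.
#' @param tc A [training_config()].
#' @return An object of class \code{readout_weights}: list with \code{w_out}
#'   (length N), \code{training_nmse} (of \eqn{\tanh(W^{out} x)} against the
#'   teacher over the regression rows), \code{effective_rank}.
#' @export
train_readout <- function(traj, targets, tc = training_config()) {
  stopifnot(inherits(traj, "state_trajectory"))
  targets <- as.numeric(targets)
  n_rows <- min(nrow(traj$states), length(targets) - 1L)
  if (n_rows <= tc$washout) stop("trajectory too short for washout", call. = FALSE)
  rows <- (tc$washout + 1):n_rows
  y <- targets[rows + 1L]
  if (any(abs(y) >= 1)) {
    stop("all targets must satisfy |y| < 1 for the tanh readout (center the series)",
         call. = FALSE)
  }
  X <- traj$states[rows, , drop = FALSE]
  z <- atanh(y)
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  keep <- sv$d > tol
  w_out <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% z) / sv$d[keep])
  w_out <- as.numeric(w_out)
  fit <- tanh(X %*% w_out)
  structure(
    list(w_out = w_out, training_nmse = nmse(as.numeric(fit), y),
         effective_rank = sum(keep)),
    class = "readout_weights"
  )
}

#' @export
print.readout_weights <- function(x, ...) {
  cat(sprintf("<readout_weights> N = %d, training NMSE = %.3g, rank = %d\n",
              length(x$w_out), x$training_nmse, x$effective_rank))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.readout_weights <- function(x, ...) {
  tibble::tibble(training_nmse = x$training_nmse,
                 effective_rank = x$effective_rank,
                 n_weights = length(x$w_out))
}

#' Normalized mean squared error
#'
#' Mean squared difference between output and target, divided by the
#' population variance of the target:
#' \deqn{NMSE = \frac{\frac{1}{M}\sum_n (y^{out}_n - y^T_n)^2}{\sigma^2(y^T)}.}
#' Scale-invariant: scaling both sequences by the same nonzero factor leaves
#' it unchanged; an output pinned at the target mean scores exactly 1.
#'
#' @param output,target Equal-length numeric sequences; the target must be
#'   non-constant.
#' @return The NMSE (scalar \eqn{\ge 0}).
#' @export
nmse <- function(output, target) {
  output <- as.numeric(output); target <- as.numeric(target)
  if (length(output) != length(target) || length(target) == 0) {
    stop("output and target must have equal nonzero length", call. = FALSE)
  }
  v <- mean(target^2) - mean(target)^2
  if (v == 0) stop("target variance is zero; NMSE undefined", call. = FALSE)
  mean((output - target)^2) / v
}

#' Closed-loop free-running prediction
#'
#' Teacher-forces the reservoir through the training block, then cuts the
#' input and for \code{horizon} steps feeds the readout's own output back as
#' the input (scaled by \eqn{\alpha} exactly as the teacher was). The
#' prediction error is the NMSE between the free-run outputs and the true
#' teacher continuation. Saturation of the tanh output (\eqn{|y^{out}|}
#' within 1e-6 of 1) for more than half the horizon is flagged as divergence;
#' the NMSE is still reported.
#'
#' @param weights A [build_weights()] result.
#' @param config The driven [reservoir_config()] (\code{alpha > 0}).
#' @param teacher Centered teacher series of length \eqn{\ge}
#'   \code{tc$n_train + tc$horizon}.
#' @param tc A [training_config()].
#' @param readout Optional pretrained \code{readout_weights}; trained on the
#'   teacher-forced block when missing.
#' @param traj Optional precomputed teacher-forced \code{state_trajectory}
#'   over the training block (avoids re-running the reservoir when the caller
#'   already has it); must match \code{weights}, \code{config} and
#'   \code{teacher}.
#' @return An object of class \code{prediction_result}: list with
#'   \code{free_run}, \code{truth}, \code{nmse}, \code{diverged},
#'   \code{readout}, \code{mu}, \code{seed}, and \code{final_state} (the
#'   network state after the training block, from which [sigma_alpha0()]
#'   continues).
#' @export
predict_closed_loop <- function(weights, config = weights$config, teacher,
                                tc = training_config(), readout = NULL,
                                traj = NULL) {
  teacher <- as.numeric(teacher)
  if (length(teacher) < tc$n_train + tc$horizon) {
    stop("teacher must supply n_train + horizon samples", call. = FALSE)
  }
  if (config$alpha <= 0) stop("closed-loop prediction needs alpha > 0", call. = FALSE)
  if (is.null(traj)) {
    traj <- run_reservoir(weights, config, input = teacher, n_steps = tc$n_train)
  }
  stopifnot(nrow(traj$states) >= tc$n_train)
  if (is.null(readout)) readout <- train_readout(traj, teacher, tc)
  f <- activation_fun(config)
  bias <- weights$w_off * config$offset_b
  x <- traj$states[tc$n_train, ]
  free_run <- numeric(tc$horizon)
  # the readout of the last forced state is already the one-step prediction:
  # it is the first free-run sample, and the input for the first unforced step
  y_fb <- tanh(sum(readout$w_out * x))
  free_run[1] <- y_fb
  for (s in seq_len(tc$horizon - 1L)) {
    x <- as.numeric(config$mu * f(weights$W %*% x + bias +
                                    weights$w_fb * (config$alpha * y_fb)))
    y_fb <- tanh(sum(readout$w_out * x))
    free_run[s + 1L] <- y_fb
  }
  truth <- teacher[tc$n_train + seq_len(tc$horizon)]
  diverged <- longest_run(abs(free_run) > 1 - 1e-6) > tc$horizon / 2
  structure(
    list(free_run = free_run, truth = truth,
         nmse = nmse(free_run, truth), diverged = diverged,
         readout = readout, mu = config$mu, seed = weights$seed,
         final_state = traj$states[tc$n_train, ]),
    class = "prediction_result"
  )
}

longest_run <- function(flags) {
  if (!any(flags)) return(0L)
  r <- rle(flags)
  max(r$lengths[r$values])
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> mu = %g, NMSE = %.4g over %d free-run steps%s\n",
              x$mu, x$nmse, length(x$free_run),
              if (x$diverged) " [diverged]" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.prediction_result <- function(x, ...) {
  tibble::tibble(step = seq_along(x$free_run),
                 predicted = x$free_run, truth = x$truth)
}

#' @exportS3Method generics::glance
glance.prediction_result <- function(x, ...) {
  tibble::tibble(mu = x$mu, nmse = x$nmse, diverged = x$diverged,
                 training_nmse = x$readout$training_nmse,
                 horizon = length(x$free_run))
}

#' Plot a closed-loop prediction against the truth
#'
#' @param object A \code{prediction_result}.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.prediction_result <- function(object, ...) {
  df <- tidy.prediction_result(object) |>
    tidyr::pivot_longer(c("predicted", "truth"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "free-run step", y = "output",
                  title = sprintf("mu = %g, NMSE = %.3g", object$mu, object$nmse))
}

#' Autonomous-output suppression index
#'
#' Measures how well training suppressed the reservoir's spontaneous
#' dynamics: the network is continued from its post-training state with the
#' input cut entirely (\eqn{\alpha = 0}, no feedback), the trained readout is
#' applied for \code{horizon} steps, the first \code{sigma_discard} outputs
#' are dropped, and the index
#' \deqn{\sigma_{\alpha=0} = \left[\sigma(y^{out}) / \sigma(y^T)\right]^2}
#' is returned over the remaining \code{sigma_window} samples, normalized by
#' the teacher's standard deviation over the aligned window. A perfectly
#' quiescent output gives 0; an output fluctuating like the teacher gives
#' about 1.
#'
#' @param pred A [predict_closed_loop()] result (supplies the trained readout
#'   and post-training state).
#' @param weights,config The reservoir that produced \code{pred}.
#' @param teacher The teacher series used in training.
#' @param tc The [training_config()] used.
#' @return The suppression index (scalar \eqn{\ge 0}).
#' @export
sigma_alpha0 <- function(pred, weights, config = weights$config, teacher,
                         tc = training_config()) {
  stopifnot(inherits(pred, "prediction_result"))
  teacher <- as.numeric(teacher)
  f <- activation_fun(config)
  bias <- weights$w_off * config$offset_b
  x <- pred$final_state
  y_out <- numeric(tc$horizon)
  for (s in seq_len(tc$horizon)) {
    x <- as.numeric(config$mu * f(weights$W %*% x + bias))
    y_out[s] <- tanh(sum(pred$readout$w_out * x))
  }
  keep <- (tc$sigma_discard + 1):tc$horizon
  ref <- teacher[tc$n_train + keep]
  s_ref <- stats::sd(ref)
  if (!is.finite(s_ref) || s_ref == 0) {
    stop("teacher window has zero variance", call. = FALSE)
  }
  (stats::sd(y_out[keep]) / s_ref)^2
}
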