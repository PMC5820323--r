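#' Mackey-Glass generator configuration
#'
#' Parameters for the discrete Mackey-Glass (MG) map
#' \deqn{y_{n+1} = y_n + \delta \left( \frac{0.2\, y_\tau}{1 + y_\tau^{10}} - 0.1\, y_n \right),}
#' where \eqn{y_\tau} is the state \code{tau_m / stepsize} iterations in the
#' past. The map is iterated at step \code{stepsize} and every
#' \code{subsample}-th iterate is retained, so one retained sample spans
#' \code{stepsize * subsample} MG time units (1 at the defaults).
#'
#' @param tau_m Delay of the MG system in MG time units. Default 17, the
#'   classical chaotic regime.
#' @param stepsize Integration step of the discrete map. Default 1/10.
#' @param subsample Keep every \code{subsample}-th iterate. Default 10.
#' @param length Number of retained samples returned (after the transient).
#' @param history_value Constant value filling the initial delay buffer.
#'   Default 1.2.
#' @param transient Number of retained samples discarded before output.
#'   Default 1000.
#'
#' @return An object of class \code{mg_config}.
#' @export
#' @examples
#' cfg <- mg_config(length = 2035 + 35)
#' y <- generate_mg(cfg)
mg_config <- function(tau_m = 17, stepsize = 1 / 10, subsample = 10,
                      length = 5000, history_value = 1.2, transient = 1000) {
  stopifnot(tau_m > 0, stepsize > 0, stepsize < 1, subsample >= 1,
            length >= 1, transient >= 0, length > transient)
  buffer <- tau_m / stepsize
  if (abs(buffer - round(buffer)) > 1e-9) {
    stop("tau_m / stepsize must be a positive integer (delay-buffer length), got ",
         buffer, call. = FALSE)
  }
  structure(
    list(tau_m = tau_m, stepsize = stepsize, subsample = as.integer(subsample),
         length = as.integer(length), history_value = history_value,
         transient = as.integer(transient), buffer_len = as.integer(round(buffer))),
    class = "mg_config"
  )
}

#' Generate a Mackey-Glass time series
#'
#' Iterates the discrete MG map from a constant history, discards the
#' configured transient, and returns the retained samples uncentered.
#' The generator is fully deterministic: identical configurations give
#' bit-identical series.
#'
#' @param config An [mg_config()] object.
#' @return An object of class \code{mg_series}: a numeric vector of
#'   \code{config$length} samples with attributes \code{centered} (logical)
#'   and \code{increment_units} (MG time units per retained sample).
#' @export
generate_mg <- function(config = mg_config()) {
  stopifnot(inherits(config, "mg_config"))
  lag <- config$buffer_len
  n_keep <- config$length + config$transient
  n_iter <- n_keep * config$subsample
  # full iterate history: lag entries of constant pre-history, then n_iter new
  y <- numeric(lag + n_iter)
  y[seq_len(lag)] <- config$history_value
  d <- config$stepsize
  for (n in seq_len(n_iter)) {
    i <- lag + n
    y_tau <- y[i - lag]
    y[i] <- y[i - 1] + d * (0.2 * y_tau / (1 + y_tau^10) - 0.1 * y[i - 1])
    if (!is.finite(y[i])) {
      stop("MG iteration diverged (non-finite value) at iteration ", n,
           call. = FALSE)
    }
  }
  kept <- y[lag + seq(config$subsample, n_iter, by = config$subsample)]
  out <- kept[(config$transient + 1):n_keep]
  new_mg_series(out, centered = FALSE,
                increment_units = config$stepsize * config$subsample,
                config = config)
}

new_mg_series <- function(values, centered, increment_units, config = NULL) {
  structure(as.numeric(values), centered = centered,
            increment_units = increment_units, config = config,
            class = "mg_series")
}

#' Center a series on zero
#'
#' Subtracts the arithmetic mean, so the series oscillates around zero (as
#' required before it is fed to the tanh-limited readout). Idempotent.
#'
#' @param series An \code{mg_series} or plain numeric vector.
#' @return The centered series, same class as the input, with the
#'   \code{centered} attribute set.
#' @export
center_mg <- function(series) {
  if (length(series) == 0) stop("cannot center an empty series", call. = FALSE)
  if (inherits(series, "mg_series") && isTRUE(attr(series, "centered"))) {
    return(series)   # exact idempotence
  }
  vals <- as.numeric(series) - mean(as.numeric(series))
  if (inherits(series, "mg_series")) {
    new_mg_series(vals, centered = TRUE,
                  increment_units = attr(series, "increment_units"),
                  config = attr(series, "config"))
  } else {
    vals
  }
}

#' @export
print.mg_series <- function(x, ...) {
  cat(sprintf("<mg_series> %d samples, %s, %g MG time unit(s)/sample\n",
              length(x), if (isTRUE(attr(x, "centered"))) "centered" else "uncentered",
              attr(x, "increment_units")))
  print(utils::head(as.numeric(x), 6L))
  invisible(x)
}

#' @rdname center_mg
#' @param x An \code{mg_series}.
#' @export
is_centered <- function(x) isTRUE(attr(x, "centered"))

#' Write / read a Mackey-Glass series
#'
#' The series is stored as a single-column CSV next to a JSON sidecar holding
#' the generating configuration and the centering flag; [read_mg()] validates
#' the invariants (finite values; centered series have near-zero mean) on load.
#'
#' @param series An \code{mg_series}.
#' @param path CSV file path; the sidecar is \code{<path>.json}.
#' @return \code{write_mg()} returns \code{path} invisibly; \code{read_mg()}
#'   returns the \code{mg_series}.
#' @export
write_mg <- function(series, path) {
  stopifnot(inherits(series, "mg_series"))
  utils::write.csv(data.frame(value = as.numeric(series)), path, row.names = FALSE)
  cfg <- attr(series, "config")
  side <- list(
    centered = isTRUE(attr(series, "centered")),
    increment_units = attr(series, "increment_units"),
    config = if (!is.null(cfg)) unclass(cfg) else NULL
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mg
#' @export
read_mg <- function(path) {
  vals <- utils::read.csv(path)$value
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!all(is.finite(vals))) stop("stored series contains non-finite values", call. = FALSE)
  if (isTRUE(side$centered) && length(vals) > 1 &&
      abs(mean(vals)) > 1e-12 * max(stats::sd(vals), 1e-300)) {
    stop("series flagged centered but mean is nonzero", call. = FALSE)
  }
  cfg <- side$config
  if (!is.null(cfg)) cfg <- structure(cfg, class = "mg_config")
  new_mg_series(vals, centered = isTRUE(side$centered),
                increment_units = side$increment_units, config = cfg)
}
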