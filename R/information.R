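#' Histogram mutual information between two sequences
#'
#' Plug-in mutual information (in bits) from an equal-width 2-D histogram over
#' the observed ranges,
#' \deqn{MI = \sum_{x,y} P(x, y) \log_2 \frac{P(x, y)}{P(x) P(y)},}
#' with no bias correction. The estimator is symmetric in its arguments and
#' exact on discrete joint tables whose support aligns with the bins.
#'
#' @param a,b Numeric sequences of equal length.
#' @param bins Number of equal-width bins per axis (default 32).
#' @return Mutual information in bits (scalar, \eqn{\ge 0}). A constant
#'   sequence carries no information and yields 0.
#' @export
#' @examples
#' x <- rep(c(0, 1), 50)
#' mutual_information(x, x, bins = 2)   # 1 bit
#' mutual_information(x, rev(x), bins = 2)
mutual_information <- function(a, b, bins = 32) {
  if (length(a) != length(b)) {
    stop("sequences must have equal length (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  }
  stopifnot(bins >= 2, length(a) >= 1)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("sequences must be finite", call. = FALSE)
  }
  ra <- range(a); rb <- range(b)
  if (ra[1] == ra[2] || rb[1] == rb[2]) return(0)
  ia <- pmin(bins, floor((a - ra[1]) / (ra[2] - ra[1]) * bins) + 1L)
  ib <- pmin(bins, floor((b - rb[1]) / (rb[2] - rb[1]) * bins) + 1L)
  joint <- tabulate(ia + (ib - 1L) * bins, nbins = bins * bins) / length(a)
  pj <- matrix(joint, bins, bins)
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  outer_p <- outer(pa, pb)
  mi <- sum(pj[nz] * log2(pj[nz] / outer_p[nz]))
  max(mi, 0)
}

#' Mutual-information memory capacity of a driven trajectory
#'
#' Computes, for each node, the same-time mutual information \eqn{MI_i}
#' between the node's time series and the input that drove it, and aggregates
#' the node values into the memory capacity \eqn{C = \sum_i MI_i}. This MI sum
#' is the information-preservation index used to compare dynamical regimes of
#' the reservoir; it is distinct from the linear memory capacity commonly
#' quoted for echo state networks.
#'
#' @param traj A [state_trajectory] from a driven run (see [run_reservoir()]).
#' @param input The input samples aligned with the trajectory rows. Defaults
#'   to the input stored in the trajectory.
#' @param bins Histogram bins per axis (default 32).
#' @return An object of class \code{mi_estimate}: list with \code{per_node_mi}
#'   (bits), \code{capacity} (their sum), \code{bins}, \code{n_samples}.
#' @export
memory_capacity <- function(traj, input = NULL, bins = 32) {
  stopifnot(inherits(traj, "state_trajectory"))
  if (is.null(input)) input <- traj$input_used
  if (is.null(input)) {
    stop("no input supplied and the trajectory stores none", call. = FALSE)
  }
  input <- as.numeric(input)
  if (length(input) != nrow(traj$states)) {
    stop("input length (", length(input), ") does not match trajectory length (",
         nrow(traj$states), ")", call. = FALSE)
  }
  per_node <- vapply(seq_len(ncol(traj$states)), function(i) {
    mutual_information(traj$states[, i], input, bins = bins)
  }, numeric(1))
  structure(
    list(per_node_mi = per_node, capacity = sum(per_node),
         bins = as.integer(bins), n_samples = length(input)),
    class = "mi_estimate"
  )
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("<mi_estimate> C = %.3f bits over %d nodes (%d samples, %d bins)\n",
              x$capacity, length(x$per_node_mi), x$n_samples, x$bins))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mi_estimate <- function(x, ...) {
  tibble::tibble(node = seq_along(x$per_node_mi), mi = x$per_node_mi)
}

#' @exportS3Method generics::glance
glance.mi_estimate <- function(x, ...) {
  tibble::tibble(capacity = x$capacity, n_nodes = length(x$per_node_mi),
                 bins = x$bins, n_samples = x$n_samples)
}
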