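#' Configuration for a mu scan with realization averaging
#'
#' @param mu_grid Increasing vector of feedback gains to scan.
#' @param n_realizations Independent weight realizations per \eqn{\mu}
#'   (default 10; the full study profile uses 100).
#' @param base_seed Master seed; every per-cell seed derives from it.
#' @param metrics Character subset of
#'   \code{c("nmse", "sigma", "delta", "capacity", "lyapunov")}.
#' @param training A [training_config()].
#' @param reservoir A [reservoir_config()] template; its \code{mu} and
#'   \code{seed} are overridden per cell, its \code{alpha} is used for the
#'   driven phase.
#' @param mg An [mg_config()] for the teacher series (generated once per
#'   scan — the teacher is deterministic; only the weights vary across
#'   realizations).
#' @param lyap_nodes Number of nodes examined by the network Lyapunov
#'   estimate (default 10; the exponent is a max over nodes and node
#'   estimates agree closely, so a subset suffices at desk scale).
#' @param autonomous_steps Post-transient autonomous steps used for the
#'   autonomous synchronization error and regime label (default 500, after a
#'   500-step transient).
#' @param classify_regimes Run the autonomous network and label each cell's
#'   regime (default TRUE; turning it off skips the autonomous run when only
#'   driven metrics are wanted).
#' @return An object of class \code{scan_config}.
#' @export
scan_config <- function(mu_grid, n_realizations = 10, base_seed = 1L,
                        metrics = c("nmse", "sigma", "delta"),
                        training = training_config(),
                        reservoir = reservoir_config(alpha = 0.8),
                        mg = mg_config(length = training$n_train + training$horizon),
                        lyap_nodes = 10, autonomous_steps = 500,
                        classify_regimes = TRUE) {
  stopifnot(length(mu_grid) >= 1, !is.unsorted(mu_grid, strictly = TRUE),
            n_realizations >= 1)
  metrics <- match.arg(metrics,
                       c("nmse", "sigma", "delta", "capacity", "lyapunov"),
                       several.ok = TRUE)
  structure(
    list(mu_grid = mu_grid, n_realizations = as.integer(n_realizations),
         base_seed = as.integer(base_seed), metrics = metrics,
         training = training, reservoir = reservoir, mg = mg,
         lyap_nodes = as.integer(lyap_nodes),
         autonomous_steps = as.integer(autonomous_steps),
         classify_regimes = isTRUE(classify_regimes)),
    class = "scan_config"
  )
}

# Deterministic per-cell seed: refining the grid or adding realizations never
# reshuffles existing cells.
cell_seed <- function(base_seed, mu_index, realization) {
  as.integer((as.double(base_seed) * 48271 + mu_index * 75377 +
                realization * 104729) %% 2147483629)
}

#' Run a mu scan
#'
#' For every (\eqn{\mu}, realization) cell: builds a weight triple from a
#' seed derived deterministically from \code{base_seed}, teacher-forces the
#' driven network on the (single, shared) centered Mackey-Glass teacher,
#' trains the readout, and computes the requested complexity indices in the
#' driven and autonomous modes. Per-cell failures are recorded in the row
#' (\code{error} column), never fatal to the scan.
#'
#' @param cfg A [scan_config()].
#' @param progress Print one line per \eqn{\mu} to stderr (default FALSE).
#' @return An object of class \code{scan_result}: list with \code{cells}
#'   (tibble, one row per cell: mu, seed, nmse, sigma_alpha0,
#'   delta_mean_driven, delta_mean_autonomous, capacity, lambda_max, regime,
#'   diverged, error) and \code{summary} (per-mu mean and sd of each metric).
#' @export
run_scan <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "scan_config"))
  teacher <- center_mg(generate_mg(cfg$mg))
  tc <- cfg$training
  rows <- vector("list", length(cfg$mu_grid) * cfg$n_realizations)
  ri <- 0L
  for (k in seq_along(cfg$mu_grid)) {
    mu <- cfg$mu_grid[k]
    if (progress) message(sprintf("mu = %g", mu))
    for (r in seq_len(cfg$n_realizations)) {
      ri <- ri + 1L
      seed <- cell_seed(cfg$base_seed, k, r)
      rows[[ri]] <- scan_cell(mu, seed, teacher, cfg, tc)
    }
  }
  cells <- dplyr::bind_rows(rows)
  metric_cols <- intersect(
    c("nmse", "sigma_alpha0", "delta_mean_driven", "delta_mean_autonomous",
      "capacity", "lambda_max"), names(cells))
  summary <- cells |>
    dplyr::group_by(.data$mu) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(metric_cols),
      list(mean = ~mean(.x, na.rm = TRUE),
           sd = ~stats::sd(.x, na.rm = TRUE),
           se = ~stats::sd(.x, na.rm = TRUE) / sqrt(sum(is.finite(.x))))),
      n = dplyr::n(), .groups = "drop")
  structure(list(cells = cells, summary = summary, config = cfg),
            class = "scan_result")
}

scan_cell <- function(mu, seed, teacher, cfg, tc) {
  out <- tibble::tibble(mu = mu, seed = seed, nmse = NA_real_,
                        sigma_alpha0 = NA_real_,
                        delta_mean_driven = NA_real_,
                        delta_mean_autonomous = NA_real_,
                        capacity = NA_real_, lambda_max = NA_real_,
                        regime = NA_character_, diverged = NA,
                        error = NA_character_)
  tryCatch({
    rc <- cfg$reservoir
    rc$mu <- mu
    rc$seed <- seed
    w <- build_weights(rc)
    traj <- run_reservoir(w, rc, input = as.numeric(teacher),
                          n_steps = tc$n_train)
    post <- (tc$washout + 1):tc$n_train
    if (any(c("nmse", "sigma") %in% cfg$metrics)) {
      pred <- predict_closed_loop(w, rc, teacher, tc, traj = traj)
      out$nmse <- pred$nmse
      out$diverged <- pred$diverged
      if ("sigma" %in% cfg$metrics) {
        out$sigma_alpha0 <- sigma_alpha0(pred, w, rc, teacher, tc)
      }
    }
    if ("delta" %in% cfg$metrics && mu > 0) {
      out$delta_mean_driven <-
        sync_error(new_state_trajectory(traj$states[post, , drop = FALSE],
                                        mu, TRUE))$mean_delta
    }
    if ("capacity" %in% cfg$metrics) {
      sub <- new_state_trajectory(traj$states[post, , drop = FALSE], mu, TRUE,
                                  input_used = as.numeric(teacher)[post])
      out$capacity <- memory_capacity(sub)$capacity
    }
    # autonomous run: needed for the regime label and the autonomous
    # synchronization error
    if (cfg$classify_regimes || "delta" %in% cfg$metrics) {
      rc0 <- rc
      rc0$alpha <- 0
      n_auto <- cfg$autonomous_steps
      auto <- run_reservoir(w, rc0, n_steps = 500 + n_auto)
      auto_post <- new_state_trajectory(
        auto$states[(500 + 1):(500 + n_auto), , drop = FALSE], mu, FALSE)
      if ("delta" %in% cfg$metrics && mu > 0) {
        out$delta_mean_autonomous <- sync_error(auto_post)$mean_delta
      }
      if (cfg$classify_regimes) {
        node <- ((seed %% ncol(auto_post$states)) + 1L)
        cls <- classify_regime(auto_post$states[, node], mu = mu)
        out$regime <- cls$label
      }
    }
    if ("lyapunov" %in% cfg$metrics) {
      set.seed(seed + 1L)
      nodes <- sample.int(rc$n_nodes, min(cfg$lyap_nodes, rc$n_nodes))
      nl <- network_lyapunov(traj, delay = 12, dim = 4, nodes = nodes)
      out$lambda_max <- nl$lambda_max
    }
    out
  }, error = function(e) {
    out$error <- conditionMessage(e)
    out
  })
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %d mu values x %d realizations\n",
              length(x$config$mu_grid), x$config$n_realizations))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.scan_result <- function(x, ...) x$cells

#' @exportS3Method generics::glance
glance.scan_result <- function(x, ...) {
  tibble::tibble(n_mu = length(x$config$mu_grid),
                 n_realizations = x$config$n_realizations,
                 n_failed = sum(!is.na(x$cells$error)))
}

#' Plot scan summaries
#'
#' Mean of each computed metric against \eqn{\mu} with a standard-deviation
#' ribbon, one facet per metric (log scale for NMSE and the suppression
#' index).
#'
#' @param object A \code{scan_result}.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scan_result <- function(object, ...) {
  df <- object$summary |>
    tidyr::pivot_longer(-c("mu", "n"),
                        names_to = c("metric", "stat"),
                        names_pattern = "(.*)_(mean|sd|se)$") |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value") |>
    dplyr::filter(is.finite(.data$mean))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mu, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~.data$metric, scales = "free_y") +
    ggplot2::labs(x = expression(mu), y = "metric (mean ± sd)")
}

#' Write / read a scan result
#'
#' Cells go to a flat CSV; the summary and the scan configuration (grid,
#' realizations, seeds, metric list and the nested training / reservoir / MG
#' parameters) go to a JSON sidecar \code{<path>.json}, from which
#' [read_scan()] rebuilds the \code{scan_result}.
#'
#' @param result A \code{scan_result}.
#' @param path CSV file path for the per-cell table.
#' @return \code{write_scan()} returns \code{path} invisibly; \code{read_scan()}
#'   the reconstructed \code{scan_result}.
#' @export
write_scan <- function(result, path) {
  stopifnot(inherits(result, "scan_result"))
  utils::write.csv(result$cells, path, row.names = FALSE)
  cfg <- result$config
  side <- list(
    config = list(
      mu_grid = cfg$mu_grid, n_realizations = cfg$n_realizations,
      base_seed = cfg$base_seed, metrics = cfg$metrics,
      lyap_nodes = cfg$lyap_nodes, autonomous_steps = cfg$autonomous_steps,
      classify_regimes = cfg$classify_regimes,
      training = unclass(cfg$training),
      reservoir = unclass(cfg$reservoir),
      mg = unclass(cfg$mg)
    ),
    summary = result$summary
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  cells <- tibble::as_tibble(utils::read.csv(path))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sc <- side$config
  cfg <- scan_config(
    mu_grid = sc$mu_grid, n_realizations = sc$n_realizations,
    base_seed = sc$base_seed, metrics = sc$metrics,
    training = do.call(training_config,
                       sc$training[c("n_train", "washout", "horizon",
                                     "sigma_discard", "sigma_window")]),
    reservoir = do.call(reservoir_config,
                        sc$reservoir[c("n_nodes", "mu", "offset_b", "alpha",
                                       "connectivity", "activation", "seed")]),
    mg = do.call(mg_config,
                 sc$mg[c("tau_m", "stepsize", "subsample", "length",
                         "history_value", "transient")]),
    lyap_nodes = sc$lyap_nodes, autonomous_steps = sc$autonomous_steps,
    classify_regimes = sc$classify_regimes
  )
  structure(list(cells = cells, summary = tibble::as_tibble(side$summary),
                 config = cfg),
            class = "scan_result")
}

#' Detect non-chaotic mu windows in a scan result
#'
#' Groups consecutive grid points whose regime label is non-chaotic
#' (fixed point or periodic) into maximal closed intervals.
#'
#' @param result A \code{scan_result} whose cells carry regime labels, or a
#'   \code{bifurcation_diagram}.
#' @return A tibble with columns \code{mu_lo}, \code{mu_hi}.
#' @export
detect_windows <- function(result) {
  if (inherits(result, "bifurcation_diagram")) return(result$windows)
  stopifnot(inherits(result, "scan_result"))
  # majority regime per mu across realizations
  per_mu <- result$cells |>
    dplyr::filter(!is.na(.data$regime)) |>
    dplyr::group_by(.data$mu) |>
    dplyr::summarise(
      nonchaotic = mean(.data$regime %in% c("fixed_point", "periodic")) > 0.5,
      .groups = "drop") |>
    dplyr::arrange(.data$mu)
  nonchaotic_windows(per_mu$mu,
                     ifelse(per_mu$nonchaotic, "periodic", "chaotic"))
}
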