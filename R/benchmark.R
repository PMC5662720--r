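#' Run the simulation benchmark over a degradation grid
#'
#' Simulates random-walk tracks on an array, degrades each track's TOA matrix
#' at every requested combination of missed-detection probability `p_na` and
#' multipath probability `p_mp`, positions each degraded matrix with the
#' state-space model and/or the TDOA baseline, and evaluates both against the
#' simulated truth. This is the engine behind the published-style comparison
#' of the two estimators across degradation levels.
#'
#' Each (track, condition, rep, method) combination draws its RNG stream from
#' `seed` deterministically, so results are reproducible and independent of
#' the evaluation order.
#'
#' @param array Hydrophone array table.
#' @param config Base [sim_config()] for the clean simulation (its `p_na`,
#'   `p_mp` are ignored in favour of the grid).
#' @param p_na,p_mp Numeric vectors defining the degradation grid.
#' @param n_tracks Number of simulated tracks.
#' @param reps Degradation replicates per track and condition.
#' @param methods Character subset of `c("yaps", "tdoa")`.
#' @param seed Master seed.
#' @param se Compute standard errors in the state-space fits (slower).
#' @param keep_tracks Also return the per-track fitted/true tracks.
#' @param control A [yaps_control()] for the state-space fits.
#' @param tdoa_cfg A [tdoa_config()] for the baseline.
#' @return A list of class `toa_benchmark` whose element `metrics` is a tidy
#'   tibble: one row per track x condition x rep x method with the
#'   [evaluate_track()] summary columns, plus `mean_detect` (mean detecting
#'   hydrophones per ping). When `keep_tracks` is TRUE, `tracks` holds the
#'   per-fit position tables.
#' @export
run_benchmark <- function(array, config = sim_config(),
                          p_na = 0, p_mp = 0, n_tracks = 20, reps = 1,
                          methods = c("yaps", "tdoa"), seed = 1,
                          se = FALSE, keep_tracks = FALSE,
                          control = yaps_control(), tdoa_cfg = tdoa_config()) {
  array <- validate_array(array)
  methods <- match.arg(methods, several.ok = TRUE)
  grid <- tidyr::expand_grid(track = seq_len(n_tracks), p_na = p_na,
                             p_mp = p_mp, rep = seq_len(reps))
  sims <- purrr::map(seq_len(n_tracks), function(k)
    simulate_tag(array, config, seed = (seed * 1013L + k) %% .Machine$integer.max))
  rows <- vector("list", nrow(grid))
  tracks <- if (keep_tracks) vector("list", nrow(grid)) else NULL
  for (g in seq_len(nrow(grid))) {
    k <- grid$track[g]
    sim <- sims[[k]]
    dseed <- (seed * 7919L + k * 331L + grid$rep[g] * 17L +
                round(1e3 * grid$p_na[g]) * 101L +
                round(1e3 * grid$p_mp[g]) * 7L) %% .Machine$integer.max
    toa <- degrade_toa(sim$toa_clean, grid$p_na[g], grid$p_mp[g],
                       config$mp_max_m, config$v0, seed = dseed)
    out <- list()
    kept <- list()
    if ("yaps" %in% methods) {
      fit <- fit_yaps(toa, array, control = control, se = se)
      ev <- evaluate_track(fit, sim$truth, array)
      gm <- glance(ev)
      gm$n_positioned <- nrow(ev$per_position)
      gm$method <- "yaps"
      gm$converged <- fit$converged
      gm$D_xy_hat <- fit$params$estimate[fit$params$term == "D_xy"]
      gm$sigma_toa_hat <- fit$params$estimate[fit$params$term == "sigma_toa"]
      out$yaps <- gm
      if (keep_tracks) kept$yaps <- fit$track
    }
    if ("tdoa" %in% methods) {
      fit <- fit_tdoa(toa, array, tdoa_cfg)
      ev <- evaluate_track(fit, sim$truth, array)
      gm <- glance(ev)
      gm$n_positioned <- nrow(ev$per_position)
      gm$method <- "tdoa"
      gm$converged <- NA
      out$tdoa <- gm
      if (keep_tracks) kept$tdoa <- fit$track
    }
    res <- dplyr::bind_rows(out)
    res$track <- k
    res$p_na <- grid$p_na[g]
    res$p_mp <- grid$p_mp[g]
    res$rep <- grid$rep[g]
    res$mean_detect <- mean(detect_counts(toa))
    rows[[g]] <- res
    if (keep_tracks) tracks[[g]] <- c(kept, list(truth = sim$truth))
  }
  metrics <- dplyr::relocate(dplyr::bind_rows(rows),
                             "track", "p_na", "p_mp", "rep", "method")
  structure(list(metrics = metrics, tracks = tracks, array = array,
                 config = config, seed = seed),
            class = "toa_benchmark")
}

#' @export
print.toa_benchmark <- function(x, ...) {
  cat(sprintf("TOA positioning benchmark: %d fits over %d condition(s)\n",
              nrow(x$metrics),
              nrow(dplyr::distinct(x$metrics, .data$p_na, .data$p_mp))))
  print(summarise_benchmark(x))
  invisible(x)
}

#' Per-condition summary of a benchmark run
#'
#' Averages the per-track metrics within each (p_na, p_mp, method) cell.
#'
#' @param bench A `toa_benchmark` (or its `metrics` tibble).
#' @return Tibble with one row per cell: `mean_dev` and `rms_dev` pooled over
#'   every positioned transmission in the cell (weighted by per-fit position
#'   counts, so they equal the statistics over the pooled per-position
#'   deviations), plus the mean track-length error and mean efficiency.
#' @export
summarise_benchmark <- function(bench) {
  m <- if (inherits(bench, "toa_benchmark")) bench$metrics else bench
  dplyr::summarise(
    dplyr::group_by(m, .data$p_na, .data$p_mp, .data$method),
    mean_dev = sum(.data$mean_dev * .data$n_positioned) / sum(.data$n_positioned),
    rms_dev = sqrt(sum(.data$rms_dev^2 * .data$n_positioned) / sum(.data$n_positioned)),
    rel_len_err = mean(.data$rel_len_err),
    efficiency = mean(.data$efficiency),
    mean_detect = mean(.data$mean_detect),
    n = dplyr::n(), .groups = "drop")
}
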