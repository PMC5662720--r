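#' Settings for the TDOA multilateration baseline
#'
#' The classical per-ping solver assumes a fixed speed of sound `v` and
#' Gaussian noise on each pairwise time difference of arrival. The point
#' estimate is least squares over all unordered detecting pairs, so
#' `sigma_tdoa` does not affect it; it is retained for likelihood reporting.
#' The objective is seeded on a coarse grid over the array bounding box
#' expanded by `grid_margin` m at `grid_step` m spacing and refined from the
#' best `n_starts` nodes, which guards against the hyperbola twin-solution
#' ambiguity.
#'
#' @param v Fixed speed of sound (m/s).
#' @param sigma_tdoa Nominal TDOA noise sd (s); not used by the point estimate.
#' @param grid_step Seed-grid spacing (m).
#' @param grid_margin Expansion of the array bounding box for the seed grid (m).
#' @param n_starts Number of grid nodes refined by the local optimizer.
#' @param max_outlier_dist Distance to the nearest hydrophone beyond which a
#'   position is flagged as a gross outlier by [filter_outliers()] (m).
#' @return List of class `tdoa_config`.
#' @export
tdoa_config <- function(v = 1435, sigma_tdoa = 1e-4, grid_step = 5,
                        grid_margin = 50, n_starts = 3, max_outlier_dist = 500) {
  stopifnot(v > 0, grid_step > 0, grid_margin >= 0, n_starts >= 1,
            max_outlier_dist > 0)
  structure(list(v = v, sigma_tdoa = sigma_tdoa, grid_step = grid_step,
                 grid_margin = grid_margin, n_starts = n_starts,
                 max_outlier_dist = max_outlier_dist),
            class = "tdoa_config")
}

# Sum of squared pairwise-TDOA residuals at candidate position(s).
# With a_h = tau_h - d_h/v, the sum over unordered pairs of (a_n - a_m)^2
# equals k * sum(a^2) - sum(a)^2, which avoids forming the pairs explicitly.
tdoa_objective <- function(xy, tau, hx, hy, v) {
  xy <- matrix(xy, ncol = 2)
  d <- sqrt(outer(xy[, 1], hx, "-")^2 + outer(xy[, 2], hy, "-")^2)
  a <- matrix(tau, nrow(xy), length(tau), byrow = TRUE) - d / v
  k <- length(tau)
  k * rowSums(a^2) - rowSums(a)^2
}

#' Position a single ping by hyperbolic multilateration
#'
#' Minimizes the sum of squared differences between observed and predicted
#' pairwise TDOAs over all unordered pairs of detecting hydrophones. Returns
#' no position when fewer than three hydrophones detected the ping (the 2D
#' problem is then under-determined and such pings are discarded by this
#' approach). Near-collinear detecting geometries are solved but flagged
#' ambiguous, since the mirror solution attains a similar objective.
#'
#' @param tau_row Named numeric vector of arrival times (s), NA = missed;
#'   names must match the array ids (unnamed vectors are matched by position).
#' @param array Hydrophone array table.
#' @param cfg A [tdoa_config()].
#' @return One-row tibble: `x_est`, `y_est` (NA when unpositioned),
#'   `n_detections`, `rss` (s^2), `ambiguous`.
#' @export
solve_tdoa_ping <- function(tau_row, array, cfg = tdoa_config()) {
  array <- validate_array(array)
  if (!is.null(names(tau_row))) tau_row <- tau_row[array$hydro]
  det <- which(!is.na(tau_row))
  n_det <- length(det)
  if (n_det < 3)
    return(tibble::tibble(x_est = NA_real_, y_est = NA_real_,
                          n_detections = n_det, rss = NA_real_, ambiguous = NA))
  tau <- as.numeric(tau_row[det])
  hx <- array$x[det]; hy <- array$y[det]
  gx <- seq(min(array$x) - cfg$grid_margin, max(array$x) + cfg$grid_margin,
            by = cfg$grid_step)
  gy <- seq(min(array$y) - cfg$grid_margin, max(array$y) + cfg$grid_margin,
            by = cfg$grid_step)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  val <- tdoa_objective(grid, tau, hx, hy, cfg$v)
  seeds <- grid[order(val)[seq_len(min(cfg$n_starts, nrow(grid)))], , drop = FALSE]
  # refinement is confined to the seed-grid box: outside it the pairwise
  # objective flattens towards a far-field limit, and an inconsistent
  # (multipath-hit) row can otherwise drag the optimum arbitrarily far out
  lo <- c(min(gx), min(gy))
  hi <- c(max(gx), max(gy))
  best <- NULL
  for (s in seq_len(nrow(seeds))) {
    o <- optim(seeds[s, ], function(p) tdoa_objective(p, tau, hx, hy, cfg$v),
               method = "L-BFGS-B", lower = lo, upper = hi,
               control = list(factr = 10, maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # collinearity of the detecting hydrophones: max triangle area ~ 0
  area <- 0
  for (i in seq_len(n_det - 2))
    for (j in seq(i + 1, n_det - 1))
      for (k in seq(j + 1, n_det))
        area <- max(area, abs((hx[j] - hx[i]) * (hy[k] - hy[i]) -
                              (hx[k] - hx[i]) * (hy[j] - hy[i])) / 2)
  tibble::tibble(x_est = best$par[1], y_est = best$par[2],
                 n_detections = n_det, rss = best$value,
                 ambiguous = area < 1e-6)
}

#' Position every ping of a TOA matrix by TDOA multilateration
#'
#' Applies [solve_tdoa_ping()] independently to each transmission. Pings with
#' fewer than three detections get NA coordinates; they are counted in the
#' efficiency denominator, which is what makes this baseline lose positions
#' as detection probability drops.
#'
#' @param toa TOA tibble.
#' @param array Hydrophone array table.
#' @param cfg A [tdoa_config()].
#' @return An object of class `tdoa_fit`.
#' @examples
#' sim <- simulate_tag(benchmark_array(), sim_config(n_pings = 20), seed = 3)
#' fit <- fit_tdoa(sim$toa, sim$array)
#' glance(fit)
#' @export
fit_tdoa <- function(toa, array, cfg = tdoa_config()) {
  array <- validate_array(array)
  m <- as_toa_matrix(toa, array)
  rows <- purrr::map(seq_len(nrow(m)), function(i)
    solve_tdoa_ping(m[i, ], array, cfg))
  track <- dplyr::bind_cols(tibble::tibble(ping = sort(toa$ping)),
                            dplyr::bind_rows(rows))
  track$filtered <- FALSE
  structure(list(track = track, n_pings = nrow(m),
                 n_positioned = sum(!is.na(track$x_est)),
                 efficiency = mean(!is.na(track$x_est)),
                 array = array, cfg = cfg),
            class = "tdoa_fit")
}

#' Flag gross positional outliers
#'
#' Marks positions whose distance to the nearest hydrophone exceeds
#' `max_dist` (500 m in the standard post-processing rule) as filtered;
#' filtered positions are excluded from the accuracy metrics and from the
#' efficiency count.
#'
#' @param fit A `tdoa_fit`.
#' @param array Hydrophone array table (defaults to the one stored in `fit`).
#' @param max_dist Removal threshold (m).
#' @return The `tdoa_fit` with its `filtered` column updated.
#' @export
filter_outliers <- function(fit, array = fit$array, max_dist = 500) {
  stopifnot(inherits(fit, "tdoa_fit"), max_dist > 0)
  array <- validate_array(array)
  tr <- fit$track
  ok <- !is.na(tr$x_est)
  dmin <- rep(NA_real_, nrow(tr))
  if (any(ok)) {
    d <- sqrt(outer(tr$x_est[ok], array$x, "-")^2 +
              outer(tr$y_est[ok], array$y, "-")^2)
    dmin[ok] <- apply(d, 1, min)
  }
  fit$track$filtered <- !is.na(dmin) & dmin > max_dist
  fit$n_positioned <- sum(ok & !fit$track$filtered)
  fit$efficiency <- fit$n_positioned / fit$n_pings
  fit
}

#' @export
print.tdoa_fit <- function(x, ...) {
  cat(sprintf("TDOA multilateration fit: %d/%d pings positioned (efficiency %.2f)\n",
              x$n_positioned, x$n_pings, x$efficiency))
  invisible(x)
}

#' Tidy a TDOA fit
#'
#' @param x A `tdoa_fit`.
#' @param ... Unused.
#' @return Tibble with one row per transmission: `ping`, `x_est`, `y_est`,
#'   `n_detections`, `rss`, `ambiguous`, `filtered`.
#' @export
tidy.tdoa_fit <- function(x, ...) x$track

#' One-row TDOA summary
#'
#' @param x A `tdoa_fit`.
#' @param ... Unused.
#' @return One-row tibble with ping counts and positioning efficiency.
#' @export
glance.tdoa_fit <- function(x, ...) {
  tibble::tibble(n_pings = x$n_pings, n_positioned = x$n_positioned,
                 efficiency = x$efficiency,
                 n_filtered = sum(x$track$filtered))
}

#' Plot a TDOA track over the hydrophone array
#'
#' @param object A `tdoa_fit`.
#' @param truth Optional tibble with true `x`, `y` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tdoa_fit <- function(object, truth = NULL, ...) {
  tr <- dplyr::filter(object$track, !is.na(.data$x_est), !.data$filtered)
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$x_est, y = .data$y_est)) +
    ggplot2::geom_path(colour = "darkorange") +
    ggplot2::geom_point(data = object$array, ggplot2::aes(x = .data$x, y = .data$y),
                        shape = 17, size = 3, colour = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", title = "TDOA multilateration track")
  if (!is.null(truth))
    p <- p + ggplot2::geom_path(data = truth, ggplot2::aes(x = .data$x, y = .data$y),
                                colour = "grey50", linetype = 2)
  p
}
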