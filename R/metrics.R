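#' Mean deviation between estimated and true positions
#'
#' The arithmetic mean of the Euclidean distances between matched estimated
#' and true positions. Rows are matched 1:1 by order (use ping-aligned
#' tables); rows where the estimate is missing (unpositioned pings) are
#' dropped before averaging.
#'
#' @param est Data frame of estimated positions; columns `x_est`/`y_est`
#'   (or `x`/`y`).
#' @param truth Data frame of true positions, columns `x`, `y`, same rows.
#' @return Mean deviation (m).
#' @export
mean_deviation <- function(est, truth) {
  mean(position_deviations(est, truth))
}

position_deviations <- function(est, truth) {
  ex <- est[[if ("x_est" %in% names(est)) "x_est" else "x"]]
  ey <- est[[if ("y_est" %in% names(est)) "y_est" else "y"]]
  if (length(ex) != nrow(truth)) abort("est and truth must have matching rows")
  ok <- !is.na(ex) & !is.na(ey)
  if (!any(ok)) abort("no matched positions to compare")
  sqrt((ex[ok] - truth$x[ok])^2 + (ey[ok] - truth$y[ok])^2)
}

track_length <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) abort("need at least two positions to measure track length")
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Relative error in estimated track length
#'
#' Track length is the summed length of consecutive straight segments; the
#' error is (length(estimated) - length(true)) / length(true) * 100, so
#' positive values are over-estimation. For estimators that skip pings, only
#' positioned points are joined, in ping order, bridging gaps with straight
#' segments — the mechanism behind length under-estimation when many pings
#' are lost.
#'
#' @param est Data frame of estimated positions (`x_est`/`y_est` or `x`/`y`),
#'   NA rows skipped.
#' @param truth Data frame of true positions, columns `x`, `y`.
#' @return Signed percentage.
#' @export
relative_track_length_error <- function(est, truth) {
  ex <- est[[if ("x_est" %in% names(est)) "x_est" else "x"]]
  ey <- est[[if ("y_est" %in% names(est)) "y_est" else "y"]]
  lt <- track_length(truth$x, truth$y)
  if (lt <= 0) abort("true track has zero length")
  (track_length(ex, ey) - lt) / lt * 100
}

#' Pair estimated positions with the temporally closest truth
#'
#' For evaluation against an independently logged reference track (e.g. a
#' GPS trace at a different rate): each estimated position is paired with the
#' single truth record minimizing the absolute time difference; ties go to
#' the earlier truth point.
#'
#' @param est Data frame with a time column `t` (or `t_est`), time-sorted.
#' @param truth Data frame with columns `t`, `x`, `y`, time-sorted.
#' @return `est` with appended columns `x_true`, `y_true`, `t_true`, `dt`
#'   (the signed time offset est - truth).
#' @export
match_nearest_in_time <- function(est, truth) {
  if (nrow(truth) == 0) abort("truth is empty")
  te <- est[[if ("t_est" %in% names(est)) "t_est" else "t"]]
  idx <- vapply(te, function(ti) {
    d <- abs(truth$t - ti)
    which(d == min(d))[1]  # ties -> earlier truth point
  }, integer(1))
  dplyr::bind_cols(tibble::as_tibble(est),
                   tibble::tibble(t_true = truth$t[idx],
                                  x_true = truth$x[idx],
                                  y_true = truth$y[idx],
                                  dt = te - truth$t[idx]))
}

#' Evaluate an estimated track against the truth
#'
#' Computes the benchmark performance metrics: positioning efficiency
#' (positions produced / transmissions), mean and root-mean-square deviation,
#' the signed relative track-length error, the fraction of positions within
#' 0.5 m and 1 m of truth, and per-position records carrying the deviation
#' and the distance from the true position to the array centre.
#'
#' @param est Estimated track (`x_est`/`y_est` or `x`/`y`), ping-aligned with
#'   `truth`; NA rows count as unpositioned. A `yaps_fit` or `tdoa_fit` may
#'   be passed directly (filtered TDOA positions are treated as unpositioned).
#' @param truth True track, columns `x`, `y` (one row per transmission).
#' @param array Optional hydrophone array table for the distance-to-centre
#'   column.
#' @param n_transmissions Efficiency denominator; defaults to `nrow(truth)`.
#' @return Object of class `track_metrics`; see [glance.track_metrics()].
#' @examples
#' truth <- tibble::tibble(x = c(0, 3, 6), y = c(0, 4, 8))
#' est <- tibble::tibble(x_est = c(0, 3, 9), y_est = c(0, 8, 12))
#' glance(evaluate_track(est, truth))
#' @export
evaluate_track <- function(est, truth, array = NULL, n_transmissions = NULL) {
  if (inherits(est, "yaps_fit")) est <- est$track
  if (inherits(est, "tdoa_fit")) {
    tr <- est$track
    tr$x_est[tr$filtered] <- NA_real_
    tr$y_est[tr$filtered] <- NA_real_
    est <- tr
  }
  if (is.null(n_transmissions)) n_transmissions <- nrow(truth)
  ex <- est[[if ("x_est" %in% names(est)) "x_est" else "x"]]
  ey <- est[[if ("y_est" %in% names(est)) "y_est" else "y"]]
  ok <- !is.na(ex) & !is.na(ey)
  dev <- sqrt((ex[ok] - truth$x[ok])^2 + (ey[ok] - truth$y[ok])^2)
  centre_dist <- rep(NA_real_, sum(ok))
  if (!is.null(array)) {
    ctr <- array_centre(array)
    centre_dist <- sqrt((truth$x[ok] - ctr["x"])^2 + (truth$y[ok] - ctr["y"])^2)
  }
  per_position <- tibble::tibble(ping = which(ok), deviation = dev,
                                 centre_dist = centre_dist)
  structure(list(
    efficiency = sum(ok) / n_transmissions,
    mean_dev = mean(dev),
    rms_dev = sqrt(mean(dev^2)),
    rel_len_err = relative_track_length_error(est, truth),
    frac_within = c(`0.5` = mean(dev <= 0.5), `1` = mean(dev <= 1)),
    per_position = per_position,
    n_transmissions = n_transmissions),
    class = "track_metrics")
}

#' @export
print.track_metrics <- function(x, ...) {
  cat(sprintf(paste0("Track metrics: efficiency %.3f, mean dev %.3f m, ",
                     "RMS %.3f m, track-length error %+.1f%%\n"),
              x$efficiency, x$mean_dev, x$rms_dev, x$rel_len_err))
  invisible(x)
}

#' Per-position deviations of an evaluated track
#'
#' @param x A `track_metrics`.
#' @param ... Unused.
#' @return Tibble with `ping`, `deviation` (m) and `centre_dist` (m, distance
#'   from the true position to the array centre; NA when no array was given).
#' @export
tidy.track_metrics <- function(x, ...) x$per_position

#' One-row metric summary
#'
#' @param x A `track_metrics`.
#' @param ... Unused.
#' @return One-row tibble: `efficiency`, `mean_dev`, `rms_dev`,
#'   `rel_len_err`, `frac_within_0.5`, `frac_within_1`.
#' @export
glance.track_metrics <- function(x, ...) {
  tibble::tibble(efficiency = x$efficiency, mean_dev = x$mean_dev,
                 rms_dev = x$rms_dev, rel_len_err = x$rel_len_err,
                 frac_within_0.5 = unname(x$frac_within["0.5"]),
                 frac_within_1 = unname(x$frac_within["1"]))
}

#' Deviation versus distance to the array centre
#'
#' @param object A `track_metrics` with an array-based `centre_dist`.
#' @param ... Unused.
#' @return A ggplot object (log1p-style scaled y axis).
#' @export
autoplot.track_metrics <- function(object, ...) {
  ggplot2::ggplot(object$per_position,
                  ggplot2::aes(x = .data$centre_dist, y = .data$deviation)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = "distance to array centre (m)", y = "deviation (m)")
}
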