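#' Simulation settings for the benchmark generator
#'
#' Bundles every knob of the forward simulator. The defaults are the benchmark
#' conditions: a 250-ping track with movement diffusivity `D_xy` = 1 m^2/s,
#' sound-speed diffusivity `D_v` = 0.01 m^2/s^3 around 1435 m/s, a stable
#' ~2 s burst interval drifting as a random walk with sd `sigma_bi`, and
#' Gaussian TOA measurement noise of sd `toa_noise_sd` seconds. Degradation is
#' controlled by `p_na` (per-entry missed-detection probability), `p_mp`
#' (per-entry multipath probability) and `mp_max_m` (multipath offsets drawn
#' uniformly within +/- this many meters of equivalent range).
#'
#' `toa_noise_sd` represents receiver timing error; its default (3e-4 s,
#' about 0.43 m of range at 1435 m/s) was calibrated once so that the
#' TDOA baseline attains its published clean-data accuracy on the benchmark
#' array (see the methods vignette).
#'
#' @param n_pings Number of transmissions.
#' @param bi_mean Mean burst interval (s).
#' @param sigma_bi Random-walk sd of the burst interval (s).
#' @param D_xy Movement diffusivity (m^2/s).
#' @param D_v Sound-speed diffusivity (m^2/s^3).
#' @param v0 Initial speed of sound (m/s).
#' @param toa_noise_sd Gaussian TOA measurement noise sd (s).
#' @param p_na Probability an arrival is missed, per TOA entry.
#' @param p_mp Probability an arrival is multipath-offset, per TOA entry.
#' @param mp_max_m Maximum magnitude of the multipath offset (m equivalent).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pings = 250, bi_mean = 2.0, sigma_bi = 1e-3,
                       D_xy = 1.0, D_v = 0.01, v0 = 1435,
                       toa_noise_sd = 3e-4,
                       p_na = 0, p_mp = 0, mp_max_m = 100) {
  cfg <- list(n_pings = as.integer(n_pings), bi_mean = bi_mean, sigma_bi = sigma_bi,
              D_xy = D_xy, D_v = D_v, v0 = v0, toa_noise_sd = toa_noise_sd,
              p_na = p_na, p_mp = p_mp, mp_max_m = mp_max_m)
  stopifnot(cfg$n_pings >= 2, bi_mean > 0, sigma_bi >= 0, D_xy >= 0, D_v >= 0,
            v0 > 0, toa_noise_sd >= 0, mp_max_m >= 0)
  if (p_na < 0 || p_na > 1 || p_mp < 0 || p_mp > 1)
    abort("p_na and p_mp must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' Simulate transmission times with a random-walk burst interval
#'
#' The interval between consecutive transmissions performs a Gaussian random
#' walk: the first interval equals `bi_mean` and each subsequent interval adds
#' N(0, `sigma_bi`^2). Equivalently the transmission times satisfy
#' t(i) | t(i-1), t(i-2) ~ N(2 t(i-1) - t(i-2), sigma_bi^2). An interval that
#' would come out non-positive (possible only for very large `sigma_bi`) is
#' resampled with a warning so that times stay strictly increasing.
#'
#' @param n Number of transmissions (>= 2).
#' @param bi_mean Mean burst interval (s).
#' @param sigma_bi Interval random-walk sd (s).
#' @param seed Optional RNG seed.
#' @return Numeric vector of `n` strictly increasing times starting at 0.
#' @examples
#' simulate_ping_times(4, 2, 0)  # 0 2 4 6
#' @export
simulate_ping_times <- function(n, bi_mean, sigma_bi, seed = NULL) {
  stopifnot(n >= 2, bi_mean > 0, sigma_bi >= 0)
  if (!is.null(seed)) set.seed(seed)
  intervals <- numeric(n - 1)
  intervals[1] <- bi_mean
  for (i in seq_len(n - 1)[-1]) {
    step <- intervals[i - 1] + rnorm(1, 0, sigma_bi)
    tries <- 0L
    while (step <= 0) {
      tries <- tries + 1L
      if (tries > 1000L) abort("burst-interval walk cannot stay positive; sigma_bi too large")
      step <- intervals[i - 1] + rnorm(1, 0, sigma_bi)
    }
    if (tries > 0L) warn("resampled a non-positive burst interval")
    intervals[i] <- step
  }
  c(0, cumsum(intervals))
}

#' Simulate a random-walk track
#'
#' Each coordinate performs an independent Gaussian random walk whose
#' displacement variance grows linearly with the time increment:
#' increments ~ N(0, 2 * D_xy * dt), the standard diffusion scaling.
#'
#' @param times Strictly increasing transmission times (s).
#' @param D_xy Diffusivity (m^2/s).
#' @param start Numeric length-2 start position (m).
#' @param seed Optional RNG seed.
#' @return Tibble with columns `t`, `x`, `y`.
#' @export
simulate_track <- function(times, D_xy, start = c(50, 50), seed = NULL) {
  stopifnot(length(times) >= 1, all(diff(times) > 0), D_xy >= 0, length(start) == 2)
  if (!is.null(seed)) set.seed(seed)
  n <- length(times)
  sds <- sqrt(2 * D_xy * diff(times))
  x <- start[1] + cumsum(c(0, rnorm(n - 1, 0, sds)))
  y <- start[2] + cumsum(c(0, rnorm(n - 1, 0, sds)))
  tibble::tibble(t = times, x = x, y = y)
}

#' Simulate the speed-of-sound random walk
#'
#' Speed of sound varies slowly with temperature and density; it is modelled
#' as one value per transmission following a random walk with increments
#' N(0, 2 * D_v * dt). Increments that would drive the speed non-positive are
#' resampled with a warning.
#'
#' @param times Strictly increasing transmission times (s).
#' @param v0 Initial speed of sound (m/s).
#' @param D_v Diffusivity of the speed process (m^2/s^3).
#' @param seed Optional RNG seed.
#' @return Numeric vector of speeds, one per transmission.
#' @export
simulate_sound_speed <- function(times, v0 = 1435, D_v = 0.01, seed = NULL) {
  stopifnot(v0 > 0, D_v >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- length(times)
  v <- numeric(n)
  v[1] <- v0
  sds <- sqrt(2 * D_v * diff(times))
  for (i in seq_len(n)[-1]) {
    step <- rnorm(1, 0, sds[i - 1])
    tries <- 0L
    while (v[i - 1] + step <= 0) {
      tries <- tries + 1L
      if (tries > 1000L) abort("sound-speed walk cannot stay positive")
      step <- rnorm(1, 0, sds[i - 1])
    }
    if (tries > 0L) warn("resampled a non-positive sound-speed step")
    v[i] <- v[i - 1] + step
  }
  v
}

#' Build a TOA matrix from a true track
#'
#' For every transmission and hydrophone the arrival time is the transmission
#' time plus the Euclidean travel distance divided by the speed of sound at
#' that transmission, plus Gaussian measurement noise.
#'
#' @param track Tibble with columns `t`, `x`, `y`, `v` (the true track).
#' @param array Hydrophone array table.
#' @param toa_noise_sd Measurement noise sd (s).
#' @param seed Optional RNG seed.
#' @return TOA tibble (`ping` plus one column per hydrophone), all entries present.
#' @export
build_toa <- function(track, array, toa_noise_sd = 0, seed = NULL) {
  array <- validate_array(array)
  stopifnot(all(c("t", "x", "y", "v") %in% names(track)), toa_noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(track)
  dist <- outer(track$x, array$x, "-")^2 + outer(track$y, array$y, "-")^2
  tau <- track$t + sqrt(dist) / track$v
  tau <- tau + matrix(rnorm(n * nrow(array), 0, toa_noise_sd), n)
  toa_tibble(tau, array$hydro)
}

#' Degrade a TOA matrix with missed detections and multipath
#'
#' Each entry is independently dropped (set to `NA`) with probability `p_na`;
#' each surviving entry is independently offset with probability `p_mp` by a
#' time drawn uniformly from +/- `mp_max_m` meters of equivalent range at
#' sound speed `v` (the published benchmark uses 100 m at 1435 m/s).
#' Missingness is applied before multipath; with independent draws the order
#' does not change the law, but fixing it makes runs reproducible.
#'
#' @param toa TOA tibble.
#' @param p_na Missed-detection probability per entry.
#' @param p_mp Multipath probability per entry.
#' @param mp_max_m Maximum offset magnitude (m).
#' @param v Sound speed used to convert the offset to seconds (m/s).
#' @param seed Optional RNG seed.
#' @return Degraded TOA tibble of the same shape.
#' @export
degrade_toa <- function(toa, p_na = 0, p_mp = 0, mp_max_m = 100, v = 1435,
                        seed = NULL) {
  if (p_na < 0 || p_na > 1 || p_mp < 0 || p_mp > 1)
    abort("p_na and p_mp must lie in [0, 1]")
  stopifnot(mp_max_m >= 0, v > 0)
  if (!is.null(seed)) set.seed(seed)
  m <- as_toa_matrix(toa)
  if (p_na > 0)
    m[runif(length(m)) < p_na] <- NA_real_
  if (p_mp > 0) {
    hit <- !is.na(m) & runif(length(m)) < p_mp
    m[hit] <- m[hit] + runif(sum(hit), -mp_max_m, mp_max_m) / v
  }
  out <- toa_tibble(m, setdiff(names(toa), "ping"))
  out$ping <- sort(toa$ping)
  out
}

#' Restrict a TOA matrix to a subset of hydrophones
#'
#' Mimics deploying a sparser array: keeps only the requested hydrophone
#' columns. Rows (pings) are always retained, even when no detection remains,
#' because the state-space positioner still estimates those transmissions.
#'
#' @param toa TOA tibble.
#' @param array Hydrophone array table matching `toa`.
#' @param keep Character vector of hydrophone ids to retain.
#' @return List with elements `toa` and `array`, both restricted to `keep`.
#' @export
subsample_hydrophones <- function(toa, array, keep) {
  array <- validate_array(array)
  if (length(keep) < 1) abort("`keep` must name at least one hydrophone")
  unknown <- setdiff(keep, array$hydro)
  if (length(unknown))
    abort(paste0("unknown hydrophone id(s): ", paste(unknown, collapse = ", ")))
  m <- as_toa_matrix(toa, array)
  sel <- array$hydro %in% keep
  list(toa = dplyr::bind_cols(tibble::tibble(ping = sort(toa$ping)),
                              tibble::as_tibble(as.data.frame(m[, sel, drop = FALSE]))),
       array = array[sel, , drop = FALSE])
}

#' Simulate one tagged track and its TOA matrix
#'
#' Runs the full forward model: burst-interval transmission times, random-walk
#' track started uniformly inside the 100 x 100 m quadrant (unless `start` is
#' given), sound-speed walk, noisy TOA matrix, then the configured
#' missed-detection/multipath degradation.
#'
#' @param array Hydrophone array table.
#' @param config A [sim_config()].
#' @param seed Optional RNG seed (one seed drives the whole simulation).
#' @param start Optional length-2 start position (m).
#' @return List of class `toa_sim`: `truth` (tibble `ping`, `t`, `x`, `y`, `v`),
#'   `toa` (degraded TOA tibble), `toa_clean` (before degradation), `array`,
#'   `config`.
#' @examples
#' sim <- simulate_tag(benchmark_array(), sim_config(n_pings = 25), seed = 1)
#' sim$truth
#' @export
simulate_tag <- function(array, config = sim_config(), seed = NULL, start = NULL) {
  array <- validate_array(array)
  if (!inherits(config, "sim_config")) abort("`config` must come from sim_config()")
  if (!is.null(seed)) set.seed(seed)
  times <- simulate_ping_times(config$n_pings, config$bi_mean, config$sigma_bi)
  if (is.null(start)) start <- runif(2, 0, 100)
  track <- simulate_track(times, config$D_xy, start)
  track$v <- simulate_sound_speed(times, config$v0, config$D_v)
  toa_clean <- build_toa(track, array, config$toa_noise_sd)
  toa <- degrade_toa(toa_clean, config$p_na, config$p_mp, config$mp_max_m, config$v0)
  structure(list(truth = dplyr::bind_cols(tibble::tibble(ping = seq_along(times)), track),
                 toa = toa, toa_clean = toa_clean, array = array, config = config),
            class = "toa_sim")
}

#' @export
print.toa_sim <- function(x, ...) {
  cat("Simulated acoustic tag track\n")
  cat(sprintf("  %d pings on %d hydrophones; mean detections/ping %.2f\n",
              nrow(x$truth), nrow(x$array), mean(detect_counts(x$toa))))
  invisible(x)
}
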