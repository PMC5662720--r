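#' Predicted times of arrival for a set of latent states
#'
#' The deterministic part of the observation model: the arrival of ping i at
#' hydrophone H is predicted as the transmission time plus the Euclidean
#' distance from the transmitter to the hydrophone divided by the speed of
#' sound at that transmission.
#'
#' @param latents Tibble (or list) with per-ping vectors `t`, `x`, `y`, `v`.
#' @param array Hydrophone array table.
#' @return Matrix of predicted arrival times, pings by hydrophones.
#' @examples
#' arr <- hydrophone_array(0, 0)
#' predict_toa(list(t = 10, x = 50, y = 50, v = 1435), arr)
#' @export
predict_toa <- function(latents, array) {
  array <- validate_array(array)
  stopifnot(all(c("t", "x", "y", "v") %in% names(latents)))
  if (any(latents$v <= 0)) abort("speed of sound must be positive")
  d <- sqrt(outer(latents$x, array$x, "-")^2 + outer(latents$y, array$y, "-")^2)
  m <- latents$t + d / latents$v
  colnames(m) <- array$hydro
  m
}

#' Log-density of the robust TOA residual mixture
#'
#' TOA residuals are modelled as a two-component mixture: with probability
#' `p_mix` a Gaussian with mean 0 and sd `sigma_toa` (receiver timing noise),
#' otherwise a scaled t-distribution with 3 degrees of freedom and scale
#' `scale_t`, whose heavy tails absorb multipath-delayed arrivals. Both
#' components are centred at zero. Computed in log space for stability.
#'
#' @param e Residual(s), seconds.
#' @param sigma_toa Gaussian sd (s), > 0.
#' @param p_mix Gaussian mixture weight in (0, 1]; 1 gives a pure Gaussian.
#' @param scale_t Scale of the t component (s), > 0.
#' @return Log-density, same length as `e`.
#' @export
mixture_logpdf <- function(e, sigma_toa, p_mix, scale_t) {
  stopifnot(sigma_toa > 0, scale_t > 0, p_mix > 0, p_mix <= 1)
  lg <- log(p_mix) + dnorm(e, 0, sigma_toa, log = TRUE)
  if (p_mix == 1) return(lg)
  lt <- log(1 - p_mix) + dt(e / scale_t, df = 3, log = TRUE) - log(scale_t)
  pmax(lg, lt) + log1p(exp(-abs(lg - lt)))
}

#' Joint negative log-density of the TOA state-space model
#'
#' Reference R implementation of the model's joint density: the sum of
#' (a) burst-interval random-walk terms for the transmission times (from the
#' third ping), (b) position random-walk terms, (c) sound-speed random-walk
#' terms (both from the second ping, with variance 2*D*dt and dt taken from
#' the latent transmission times), and (d) the robust mixture log-density of
#' every non-missing TOA residual. Missing entries contribute nothing. The
#' first states of each walk are diffuse. This function mirrors the compiled
#' objective used by [fit_yaps()] and serves as its readable cross-check.
#'
#' @param latents Tibble/list with per-ping `t`, `x`, `y`, `v`.
#' @param params Named list with `sigma_bi`, `D_xy`, `D_v`, `sigma_toa`,
#'   `p_mix`, `scale_t` (natural scale).
#' @param toa TOA tibble.
#' @param array Hydrophone array table.
#' @return The joint negative log-likelihood (scalar).
#' @export
joint_nll <- function(latents, params, toa, array) {
  array <- validate_array(array)
  m <- as_toa_matrix(toa, array)
  n <- nrow(m)
  stopifnot(length(latents$t) == n)
  tt <- latents$t; x <- latents$x; y <- latents$y; v <- latents$v
  dt_ <- diff(tt)
  if (any(dt_ <= 0)) abort("latent transmission times must be increasing")
  nll <- 0
  if (n >= 3)
    nll <- nll - sum(dnorm(diff(tt)[-1], diff(tt)[-(n - 1)], params$sigma_bi, log = TRUE))
  sd_xy <- sqrt(2 * params$D_xy * dt_)
  sd_v <- sqrt(2 * params$D_v * dt_)
  nll <- nll - sum(dnorm(diff(x), 0, sd_xy, log = TRUE)) -
    sum(dnorm(diff(y), 0, sd_xy, log = TRUE)) -
    sum(dnorm(diff(v), 0, sd_v, log = TRUE))
  resid <- m - predict_toa(latents, array)
  obs <- !is.na(resid)
  bad <- -sum(mixture_logpdf(resid[obs], params$sigma_toa, params$p_mix, params$scale_t))
  if (!is.finite(bad)) abort("non-finite observation term in joint_nll (mixture log-density)")
  nll <- nll + bad
  if (!is.finite(nll)) abort("non-finite process term in joint_nll (random-walk increments)")
  nll
}

#' Initial latent states from a TOA matrix
#'
#' Plumbing for the optimizer: positions start at the mean coordinates of the
#' detecting hydrophones (interpolated across pings with no detections),
#' transmission times at the earliest arrival minus the nominal travel time
#' from the initial position to that hydrophone at speed `v0` (interpolated
#' and forced strictly increasing across gaps), and sound speed constant at
#' `v0`.
#'
#' @param toa TOA tibble.
#' @param array Hydrophone array table.
#' @param v0 Nominal speed of sound (m/s).
#' @return Tibble with per-ping `t`, `x`, `y`, `v` (never NA).
#' @export
init_latents <- function(toa, array, v0 = 1435) {
  array <- validate_array(array)
  m <- as_toa_matrix(toa, array)
  n <- nrow(m)
  det <- rowSums(!is.na(m))
  if (all(det == 0)) abort("TOA matrix contains no detections")
  if (sum(det > 0) < 2) abort("need at least two pings with detections")
  wt <- !is.na(m)
  x0 <- ifelse(det > 0, (wt %*% array$x) / pmax(det, 1), NA_real_)
  y0 <- ifelse(det > 0, (wt %*% array$y) / pmax(det, 1), NA_real_)
  idx <- seq_len(n)
  x0 <- approx(idx[det > 0], x0[det > 0], idx, rule = 2)$y
  y0 <- approx(idx[det > 0], y0[det > 0], idx, rule = 2)$y
  first <- apply(m, 1, function(r) if (all(is.na(r))) NA_integer_ else which.min(r))
  t0 <- rep(NA_real_, n)
  for (i in idx[det > 0]) {
    h <- first[i]
    t0[i] <- m[i, h] - sqrt((array$x[h] - x0[i])^2 + (array$y[h] - y0[i])^2) / v0
  }
  t0 <- approx(idx[det > 0], t0[det > 0], idx, rule = 2)$y
  # enforce strict monotonicity (ties can arise from interpolation at the ends)
  eps <- 1e-4
  for (i in idx[-1]) if (t0[i] <= t0[i - 1]) t0[i] <- t0[i - 1] + eps
  tibble::tibble(t = t0, x = as.numeric(x0), y = as.numeric(y0), v = rep(v0, n))
}

#' Control settings for the state-space fit
#'
#' Starting values, parameter bounds (on the transformed scale: log for
#' positive parameters, logit for the mixture weight) and optimizer
#' tolerances. Defaults follow common practice for this model class: start
#' the movement and sound-speed diffusivities at their typical magnitudes and
#' the mixture weight at 0.9; bound the logit weight at +/-12 so the pure
#' Gaussian limit stays numerically well defined.
#'
#' @param sigma_bi,D_xy,D_v,sigma_toa,scale_t,p_mix Starting values
#'   (natural scale).
#' @param lower,upper Named numeric vectors of transformed-scale bounds;
#'   entries `log_sigma_bi`, `log_D_xy`, `log_D_v`, `log_sigma_toa`,
#'   `log_scale_t`, `logit_p_mix`.
#' @param rel_tol Outer optimizer relative tolerance on the objective.
#' @param max_iter Outer optimizer iteration cap.
#' @return List of class `yaps_control`.
#' @export
yaps_control <- function(sigma_bi = 1e-3, D_xy = 1, D_v = 0.01,
                         sigma_toa = 1e-4, scale_t = 1e-3, p_mix = 0.9,
                         lower = c(log_sigma_bi = log(1e-9), log_D_xy = log(1e-6),
                                   log_D_v = log(1e-9), log_sigma_toa = log(1e-7),
                                   log_scale_t = log(1e-7), logit_p_mix = -12),
                         upper = c(log_sigma_bi = log(10), log_D_xy = log(1e3),
                                   log_D_v = log(10), log_sigma_toa = log(1),
                                   log_scale_t = log(1), logit_p_mix = 12),
                         rel_tol = 1e-8, max_iter = 1000) {
  structure(list(start = list(sigma_bi = sigma_bi, D_xy = D_xy, D_v = D_v,
                              sigma_toa = sigma_toa, scale_t = scale_t, p_mix = p_mix),
                 lower = lower, upper = upper,
                 rel_tol = rel_tol, max_iter = max_iter),
            class = "yaps_control")
}

param_order <- c("log_sigma_bi", "log_D_xy", "log_D_v",
                 "log_sigma_toa", "log_scale_t", "logit_p_mix")

# Stronger starting latents for the optimizer: multilaterate every ping with
# >= 3 detections (discarding seeds landing > `max_seed_dist` from the nearest
# hydrophone, as a multipath-corrupted triple can send the solver far away),
# interpolate positions across the remaining pings, and take per-ping
# transmission times as the median over detecting hydrophones of arrival
# minus nominal travel time. Falls back to init_latents() when multilateration
# yields fewer than two usable seeds.
seed_latents <- function(toa, array, v0 = 1435, max_seed_dist = 500) {
  m <- as_toa_matrix(toa, array)
  n <- nrow(m)
  idx <- seq_len(n)
  det <- rowSums(!is.na(m))
  xs <- rep(NA_real_, n)
  ys <- rep(NA_real_, n)
  cfg <- tdoa_config(v = v0)
  for (i in idx[det >= 3]) {
    s <- solve_tdoa_ping(m[i, ], array, cfg)
    dmin <- min(sqrt((s$x_est - array$x)^2 + (s$y_est - array$y)^2))
    if (is.finite(dmin) && dmin <= max_seed_dist) {
      xs[i] <- s$x_est
      ys[i] <- s$y_est
    }
  }
  if (sum(!is.na(xs)) < 2) return(init_latents(toa, array, v0))
  xs <- approx(idx[!is.na(xs)], xs[!is.na(xs)], idx, rule = 2)$y
  ys <- approx(idx[!is.na(ys)], ys[!is.na(ys)], idx, rule = 2)$y
  tt <- rep(NA_real_, n)
  for (i in idx[det > 0]) {
    h <- which(!is.na(m[i, ]))
    tt[i] <- stats::median(m[i, h] -
                             sqrt((array$x[h] - xs[i])^2 + (array$y[h] - ys[i])^2) / v0)
  }
  tt <- approx(idx[det > 0], tt[det > 0], idx, rule = 2)$y
  for (i in idx[-1]) if (tt[i] <= tt[i - 1]) tt[i] <- tt[i - 1] + 1e-4
  tibble::tibble(t = tt, x = xs, y = ys, v = rep(v0, n))
}

# One pass of the sparse inner Newton with all six parameters map-fixed:
# pulls the latent states to the joint mode under an inflated, almost purely
# Gaussian observation scale. Annealing that scale downwards walks the
# latents into the basin of the final mode before the mixture tails flatten
# the surface.
anneal_latents <- function(toa, array, start, init, sigmas = c(1e-2, 1e-3)) {
  m <- as_toa_matrix(toa, array)
  data <- list(model_code = 0L, toa = m, hxy = cbind(array$x, array$y))
  fix_all <- list(log_sigma_bi = factor(NA), log_D_xy = factor(NA),
                  log_D_v = factor(NA), log_sigma_toa = factor(NA),
                  log_scale_t = factor(NA), logit_p_mix = factor(NA))
  lat <- init
  for (sig in sigmas) {
    st <- start
    st$sigma_toa <- sig
    st$p_mix <- 0.999
    pars <- as.list(transform_params(st))
    pars$top <- lat$t; pars$x <- lat$x; pars$y <- lat$y; pars$v <- lat$v
    objw <- TMB::MakeADFun(data, pars, random = c("top", "x", "y", "v"),
                           map = fix_all, DLL = "toatrack", silent = TRUE)
    val <- suppressWarnings(objw$fn())
    p <- objw$env$last.par.best
    nm <- names(p)
    cand <- tibble::tibble(t = unname(p[nm == "top"]), x = unname(p[nm == "x"]),
                           y = unname(p[nm == "y"]), v = unname(p[nm == "v"]))
    if (all(is.finite(cand$t)) && !is.unsorted(cand$t, strictly = TRUE))
      lat <- cand
  }
  lat
}

transform_params <- function(start) {
  c(log_sigma_bi = log(start$sigma_bi), log_D_xy = log(start$D_xy),
    log_D_v = log(start$D_v), log_sigma_toa = log(start$sigma_toa),
    log_scale_t = log(start$scale_t),
    logit_p_mix = stats::qlogis(start$p_mix))
}

# Joint-MAP fallback: block-coordinate ascent on the penalized likelihood.
# Alternates a 6-parameter nlminb step (latents map-fixed) with a sparse
# Newton latent step (parameters map-fixed) until the parameter step is
# stationary. Avoids the severe conditioning gap (1/sigma_toa^2 curvature in
# the time latents vs O(1) in the diffusivities) that stalls a monolithic
# joint quasi-Newton pass.
map_fit <- function(toa, array, init, control, max_sweeps = 20) {
  m <- as_toa_matrix(toa, array)
  n <- nrow(m)
  data <- list(model_code = 0L, toa = m, hxy = cbind(array$x, array$y))
  fix_lat <- list(top = factor(rep(NA, n)), x = factor(rep(NA, n)),
                  y = factor(rep(NA, n)), v = factor(rep(NA, n)))
  fix_par <- list(log_sigma_bi = factor(NA), log_D_xy = factor(NA),
                  log_D_v = factor(NA), log_sigma_toa = factor(NA),
                  log_scale_t = factor(NA), logit_p_mix = factor(NA))
  lat <- init
  tr <- transform_params(control$start)
  pars_at <- function(tr, lat) {
    p <- as.list(tr)
    p$top <- lat$t; p$x <- lat$x; p$y <- lat$y; p$v <- lat$v
    p
  }
  conv <- FALSE
  for (it in seq_len(max_sweeps)) {
    objp <- TMB::MakeADFun(data, pars_at(tr, lat), map = fix_lat,
                           DLL = "toatrack", silent = TRUE)
    op <- nlminb(objp$par, objp$fn, objp$gr,
                 lower = control$lower[param_order],
                 upper = control$upper[param_order],
                 control = list(rel.tol = control$rel_tol, iter.max = 200))
    delta <- max(abs(op$par - tr[param_order]))
    tr[param_order] <- op$par
    objl <- TMB::MakeADFun(data, pars_at(tr, lat), map = fix_par,
                           random = c("top", "x", "y", "v"),
                           DLL = "toatrack", silent = TRUE)
    invisible(suppressWarnings(objl$fn()))
    p <- objl$env$last.par.best
    nm <- names(p)
    lat <- tibble::tibble(t = unname(p[nm == "top"]), x = unname(p[nm == "x"]),
                          y = unname(p[nm == "y"]), v = unname(p[nm == "v"]))
    if (delta < 1e-6) {
      conv <- TRUE
      break
    }
  }
  objf <- TMB::MakeADFun(data, pars_at(tr, lat), DLL = "toatrack", silent = TRUE)
  list(opt = list(objective = as.numeric(objf$fn(objf$par)),
                  convergence = if (conv) 0L else 1L,
                  message = if (conv) "block-coordinate sweeps stationary"
                            else "sweep limit reached"),
       par_full = objf$par)
}

make_yaps_obj <- function(toa, array, init, start, random = TRUE) {
  m <- as_toa_matrix(toa, array)
  data <- list(model_code = 0L, toa = m,
               hxy = cbind(array$x, array$y))
  pars <- as.list(transform_params(start))
  pars$top <- init$t; pars$x <- init$x; pars$y <- init$y; pars$v <- init$v
  TMB::MakeADFun(data, pars,
                 random = if (random) c("top", "x", "y", "v") else NULL,
                 DLL = "toatrack", silent = TRUE)
}

#' Fit the TOA state-space positioning model
#'
#' Estimates the whole track, the transmission times and the sound-speed
#' series jointly from a TOA matrix by maximum likelihood. In `"laplace"`
#' mode (the standard analysis for this model class) the per-ping latent
#' states are integrated out with the Laplace approximation — the inner
#' Newton step exploits the banded latent Hessian, since each ping's states
#' couple only to their neighbours — and the six model parameters are
#' optimized with [nlminb()]. `"map"` mode instead maximizes the joint
#' penalized likelihood over latents and parameters together; it is a
#' robustness fallback and skips the integration.
#'
#' A position is produced for every transmission, including pings detected by
#' fewer than three (or zero) hydrophones: the movement model bridges them.
#'
#' @param toa TOA tibble (`ping` plus one column per hydrophone; NA = missed).
#' @param array Hydrophone array table.
#' @param control A [yaps_control()].
#' @param mode `"laplace"` (default) or `"map"`.
#' @param v0 Nominal speed of sound used for initialization (m/s).
#' @param se Compute standard errors (parameter SEs from the Fisher
#'   information, latent SEs from the posterior curvature)? Skipping them
#'   saves roughly half the run time.
#' @return An object of class `yaps_fit`; see [tidy.yaps_fit()] and
#'   [glance.yaps_fit()] for tidy access.
#' @examples
#' sim <- simulate_tag(benchmark_array(), sim_config(n_pings = 30), seed = 7)
#' fit <- fit_yaps(sim$toa, sim$array, se = FALSE)
#' glance(fit)
#' @export
fit_yaps <- function(toa, array, control = yaps_control(),
                     mode = c("laplace", "map"), v0 = 1435, se = TRUE) {
  mode <- match.arg(mode)
  array <- validate_array(array)
  m <- as_toa_matrix(toa, array)
  if (nrow(m) < 2) abort("need at least two pings")
  init <- seed_latents(toa, array, v0)
  init <- anneal_latents(toa, array, control$start, init)
  laplace <- mode == "laplace"
  npar <- length(param_order)
  if (laplace) {
    obj <- make_yaps_obj(toa, array, init, control$start, random = TRUE)
    opt <- tryCatch(
      suppressWarnings(
        nlminb(obj$par, obj$fn, obj$gr,
               lower = control$lower[param_order],
               upper = control$upper[param_order],
               control = list(rel.tol = control$rel_tol,
                              iter.max = control$max_iter,
                              eval.max = 2L * control$max_iter))),
      error = function(e) list(par = obj$par, objective = NA_real_,
                               convergence = 1L,
                               message = paste0("optimizer error: ",
                                                conditionMessage(e))))
    par_full <- obj$env$last.par.best
  } else {
    res <- map_fit(toa, array, init, control)
    opt <- res$opt
    par_full <- res$par_full
  }
  est_tr <- par_full[seq_len(npar)]
  params <- tibble::tibble(
    term = c("sigma_bi", "D_xy", "D_v", "sigma_toa", "scale_t", "p_mix"),
    estimate = c(exp(est_tr[1:5]), stats::plogis(est_tr[6])),
    std_error = NA_real_)
  lat_names <- names(par_full)
  track <- tibble::tibble(
    ping = seq_len(nrow(m)),
    t_est = unname(par_full[lat_names == "top"]),
    t_se = NA_real_,
    x_est = unname(par_full[lat_names == "x"]),
    x_se = NA_real_,
    y_est = unname(par_full[lat_names == "y"]),
    y_se = NA_real_,
    v_est = unname(par_full[lat_names == "v"]),
    v_se = NA_real_,
    n_detections = as.integer(rowSums(!is.na(m))))
  if (se && laplace) {
    sdr <- tryCatch(TMB::sdreport(obj, getReportCovariance = FALSE),
                    error = function(e) NULL)
  }
  if (se && laplace && !is.null(sdr)) {
    sr <- summary(sdr, "report")
    params$estimate <- unname(sr[params$term, "Estimate"])
    params$std_error <- unname(sr[params$term, "Std. Error"])
    rnd <- summary(sdr, "random")
    rn <- rownames(rnd)
    track$t_se <- unname(rnd[rn == "top", "Std. Error"])
    track$x_se <- unname(rnd[rn == "x", "Std. Error"])
    track$y_se <- unname(rnd[rn == "y", "Std. Error"])
    track$v_se <- unname(rnd[rn == "v", "Std. Error"])
  }
  structure(list(track = track, params = params, nll = opt$objective,
                 converged = opt$convergence == 0, message = opt$message,
                 mode = mode, n_pings = nrow(m), n_obs = sum(!is.na(m)),
                 array = array),
            class = "yaps_fit")
}

#' @export
print.yaps_fit <- function(x, ...) {
  cat(sprintf("TOA state-space fit (%s): %d pings, %d arrivals, nll = %.3f%s\n",
              x$mode, x$n_pings, x$n_obs, x$nll,
              if (x$converged) "" else "  [NOT converged]"))
  print(x$params)
  invisible(x)
}

#' Tidy a fitted track
#'
#' @param x A `yaps_fit`.
#' @param ... Unused.
#' @return Tibble with one row per transmission: estimated time, position and
#'   sound speed with standard errors, and the number of detecting hydrophones.
#' @export
tidy.yaps_fit <- function(x, ...) x$track

#' One-row model summary
#'
#' @param x A `yaps_fit`.
#' @param ... Unused.
#' @return One-row tibble with the six parameter estimates, the marginal
#'   negative log-likelihood, and convergence information.
#' @export
glance.yaps_fit <- function(x, ...) {
  est <- setNames(as.list(x$params$estimate), x$params$term)
  dplyr::bind_cols(tibble::as_tibble(est),
                   tibble::tibble(nll = x$nll, converged = x$converged,
                                  n_pings = x$n_pings, n_obs = x$n_obs,
                                  mode = x$mode))
}

#' Plot an estimated track over the hydrophone array
#'
#' @param object A `yaps_fit`.
#' @param truth Optional tibble with true `x`, `y` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.yaps_fit <- function(object, truth = NULL, ...) {
  p <- ggplot2::ggplot(object$track, ggplot2::aes(x = .data$x_est, y = .data$y_est)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::geom_point(data = object$array, ggplot2::aes(x = .data$x, y = .data$y),
                        shape = 17, size = 3, colour = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", title = "Estimated track")
  if (!is.null(truth))
    p <- p + ggplot2::geom_path(data = truth, ggplot2::aes(x = .data$x, y = .data$y),
                                colour = "grey50", linetype = 2)
  p
}
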