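test_that("predicted arrival times follow distance over sound speed", {
  arr <- hydrophone_array(0, 0)
  # transmitter on top of the hydrophone: mu = t
  expect_equal(unname(predict_toa(list(t = 3, x = 0, y = 0, v = 1435), arr)[1, 1]), 3)
  # (50,50) -> (0,0) at v = 1435, t = 10
  mu <- unname(predict_toa(list(t = 10, x = 50, y = 50, v = 1435), arr)[1, 1])
  expect_equal(mu, 10 + sqrt(5000) / 1435, tolerance = 1e-12)
  # doubling v halves the travel-time term exactly
  mu2 <- unname(predict_toa(list(t = 10, x = 50, y = 50, v = 2870), arr)[1, 1])
  expect_equal(mu2 - 10, (mu - 10) / 2, tolerance = 1e-12)
  expect_error(predict_toa(list(t = 0, x = 0, y = 0, v = -1), arr), "positive")
})

test_that("the residual mixture density is correct and integrates to 1", {
  # pure Gaussian at 0: log(1/sqrt(2*pi))
  expect_equal(mixture_logpdf(0, 1, 1, 1), log(1 / sqrt(2 * pi)), tolerance = 1e-9)
  # quadrature: density integrates to 1 for several parameter sets
  for (prm in list(c(1e-4, 0.9, 1e-3), c(1, 0.5, 2), c(0.01, 0.99, 0.5))) {
    total <- integrate(function(e) exp(mixture_logpdf(e, prm[1], prm[2], prm[3])),
                       -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  # heavy tail: at 10 sigma the mixture dominates the pure Gaussian
  s <- 1e-4
  expect_gt(mixture_logpdf(10 * s, s, 0.9, s), dnorm(10 * s, 0, s, log = TRUE))
  # matches the closed form at a generic point
  e <- 2.5e-4
  byhand <- log(0.9 * dnorm(e, 0, s) + 0.1 * dt(e / 1e-3, 3) / 1e-3)
  expect_equal(mixture_logpdf(e, s, 0.9, 1e-3), byhand, tolerance = 1e-12)
})

test_that("joint_nll assembles the process and observation terms", {
  arr <- hydrophone_array(0, 0)
  prm <- default_params(p_mix = 1)
  lat <- list(t = c(0, 2), x = c(30, 30), y = c(40, 40), v = c(1435, 1435))
  toa <- toatrack:::toa_tibble(matrix(c(0, 2) + 50 / 1435, 2, 1), "h1")
  # two pings, one hydrophone, zero residuals: only normalizing constants
  expected <- -(2 * dnorm(0, 0, sqrt(2 * prm$D_xy * 2), log = TRUE) +
                  dnorm(0, 0, sqrt(2 * prm$D_v * 2), log = TRUE) +
                  2 * dnorm(0, 0, prm$sigma_toa, log = TRUE))
  expect_equal(joint_nll(lat, prm, toa, arr), expected, tolerance = 1e-10)
  # a missing entry contributes nothing
  toa_na <- toa
  toa_na$h1[2] <- NA
  expected_na <- expected + dnorm(0, 0, prm$sigma_toa, log = TRUE)
  expect_equal(joint_nll(lat, prm, toa_na, arr), expected_na, tolerance = 1e-10)
  # perturbing one observed tau by delta adds delta^2 / (2 sigma^2)
  delta <- 3e-4
  toa_d <- toa
  toa_d$h1[1] <- toa_d$h1[1] + delta
  expect_equal(joint_nll(lat, prm, toa_d, arr) - joint_nll(lat, prm, toa, arr),
               delta^2 / (2 * prm$sigma_toa^2), tolerance = 1e-8)
})

test_that("the compiled objective agrees with the reference joint density", {
  sim <- small_sim(n_pings = 12, seed = 31)
  prm <- default_params(sigma_toa = 3e-4)
  init <- init_latents(sim$toa, sim$array)
  obj <- toatrack:::make_yaps_obj(sim$toa, sim$array, init, prm, random = FALSE)
  expect_equal(as.numeric(obj$fn(obj$par)),
               joint_nll(init, prm, sim$toa, sim$array), tolerance = 1e-6)
  # and with missing entries
  toa_na <- sim$toa
  toa_na$h2[3:5] <- NA
  init2 <- init_latents(toa_na, sim$array)
  obj2 <- toatrack:::make_yaps_obj(toa_na, sim$array, init2, prm, random = FALSE)
  expect_equal(as.numeric(obj2$fn(obj2$par)),
               joint_nll(init2, prm, toa_na, sim$array), tolerance = 1e-6)
})

test_that("the autodiff gradient matches central finite differences", {
  skip_if_not_installed("numDeriv")
  sim <- small_sim(n_pings = 6, seed = 32)
  init <- init_latents(sim$toa, sim$array)
  obj <- toatrack:::make_yaps_obj(sim$toa, sim$array, init,
                                  default_params(sigma_toa = 3e-4), random = FALSE)
  g_ad <- as.numeric(obj$gr(obj$par))
  # small relative FD steps: curvature in the time latents is ~ 1/sigma_toa^2
  g_fd <- numDeriv::grad(function(p) as.numeric(obj$fn(p)), obj$par,
                         method.args = list(d = 1e-7, r = 6))
  expect_equal(g_ad, g_fd, tolerance = 1e-6)
})

test_that("Laplace equals the exact marginal for a linear-Gaussian walk", {
  set.seed(33)
  n <- 40
  rw_sd <- 0.7; obs_sd <- 0.3; prior_sd <- 2
  state <- cumsum(c(rnorm(1, 0, prior_sd), rnorm(n - 1, 0, rw_sd)))
  y <- state + rnorm(n, 0, obs_sd)
  obj <- TMB::MakeADFun(
    data = list(model_code = 1L, y_obs = y, obs_sd = obs_sd, rw_sd = rw_sd,
                prior_sd = prior_sd),
    parameters = list(state = rep(0, n)),
    random = "state", DLL = "toatrack", silent = TRUE)
  laplace_nll <- as.numeric(obj$fn())
  # closed form: y ~ N(0, S), S_ij = prior_sd^2 + rw_sd^2 (min(i,j)-1) + obs_sd^2 I
  S <- prior_sd^2 + rw_sd^2 * (outer(1:n, 1:n, pmin) - 1) + diag(obs_sd^2, n)
  ch <- chol(S)
  exact_nll <- 0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
                        sum(backsolve(ch, y, transpose = TRUE)^2))
  expect_equal(laplace_nll, exact_nll, tolerance = 1e-8)
})

test_that("initial latent states are usable on degraded matrices", {
  sim <- small_sim(n_pings = 40, seed = 34)
  # single hydrophone detecting everything: positions start on that hydrophone
  one <- subsample_hydrophones(sim$toa, sim$array, "h2")
  ini <- init_latents(one$toa, one$array)
  expect_true(all(ini$x == one$array$x[1] & ini$y == one$array$y[1]))
  # noise-free full matrix: initial t within the maximum travel time of truth
  sim0 <- small_sim(n_pings = 40, toa_noise_sd = 0, seed = 35)
  ini0 <- init_latents(sim0$toa, sim0$array)
  max_tt <- max(sqrt(200^2 + 200^2)) / 1400  # generous travel-time bound
  expect_lt(max(abs(ini0$t - sim0$truth$t)), max_tt)
  # heavy missingness: no NaN, strictly increasing times
  deg <- degrade_toa(sim$toa, 0.8, 0, seed = 36)
  inid <- init_latents(deg, sim$array)
  expect_true(all(is.finite(unlist(inid))))
  expect_true(!is.unsorted(inid$t, strictly = TRUE))
  expect_error(init_latents(degrade_toa(sim$toa, 1, 0, seed = 1), sim$array),
               "detection")
})

test_that("a noise-free fully detected track is recovered almost exactly", {
  sim <- simulate_tag(bench_array, sim_config(n_pings = 100, toa_noise_sd = 0),
                      seed = 37)
  fit <- fit_yaps(sim$toa, sim$array, se = FALSE)
  rms <- sqrt(mean((fit$track$x_est - sim$truth$x)^2 +
                     (fit$track$y_est - sim$truth$y)^2))
  expect_lt(rms, 0.01)
})

test_that("one position is estimated per transmission regardless of detections", {
  sim <- small_sim(n_pings = 60, seed = 38)
  for (p_na in c(0, 0.5, 0.8)) {
    toa <- degrade_toa(sim$toa_clean, p_na, 0, seed = 39 + round(10 * p_na))
    fit <- fit_yaps(toa, sim$array, se = FALSE)
    expect_equal(nrow(fit$track), nrow(sim$truth))
    expect_true(all(is.finite(fit$track$x_est)))
    expect_equal(fit$track$n_detections, detect_counts(toa))
  }
})

test_that("laplace and joint-MAP modes agree on a small clean instance", {
  sim <- small_sim(n_pings = 25, seed = 40)
  f1 <- fit_yaps(sim$toa, sim$array, mode = "laplace", se = FALSE)
  f2 <- fit_yaps(sim$toa, sim$array, mode = "map", se = FALSE)
  expect_true(f2$converged)
  # positions agree well within the movement scale (~2 m per step); the
  # variance parameters legitimately differ because MAP maximizes the
  # penalized likelihood without the integration penalty
  rms_gap <- sqrt(mean((f1$track$x_est - f2$track$x_est)^2 +
                         (f1$track$y_est - f2$track$y_est)^2))
  expect_lt(rms_gap, 1.0)
  dev_map <- sqrt(mean((f2$track$x_est - sim$truth$x)^2 +
                         (f2$track$y_est - sim$truth$y)^2))
  expect_lt(dev_map, 1.5)
})

test_that("standard errors are returned and positive under the Laplace fit", {
  sim <- small_sim(n_pings = 25, seed = 41)
  fit <- fit_yaps(sim$toa, sim$array, se = TRUE)
  expect_true(all(fit$track$x_se > 0))
  expect_true(all(fit$track$t_se > 0))
  expect_true(all(fit$params$std_error[fit$params$term %in%
                                         c("sigma_toa", "D_xy")] > 0))
  td <- tidy(fit)
  expect_named(td, c("ping", "t_est", "t_se", "x_est", "x_se", "y_est", "y_se",
                     "v_est", "v_se", "n_detections"))
  expect_s3_class(glance(fit), "tbl_df")
})
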