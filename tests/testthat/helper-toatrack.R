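# Shared fixtures: everything is generated in code at test time.

bench_array <- benchmark_array()

# A small clean simulation used by many tests (30 pings keeps fits fast).
small_sim <- function(n_pings = 30, toa_noise_sd = 3e-4, seed = 101, ...) {
  simulate_tag(bench_array, sim_config(n_pings = n_pings,
                                       toa_noise_sd = toa_noise_sd, ...),
               seed = seed)
}

# Natural-scale parameter list at the estimator's default starting values.
default_params <- function(...) {
  utils::modifyList(list(sigma_bi = 1e-3, D_xy = 1, D_v = 0.01,
                         sigma_toa = 1e-4, p_mix = 0.9, scale_t = 1e-3),
                    list(...))
}

# Rigid motions of an array/track pair, for equivariance tests.
rotate90 <- function(df, xcol = "x", ycol = "y") {
  out <- df
  out[[xcol]] <- -df[[ycol]]
  out[[ycol]] <- df[[xcol]]
  out
}
translate <- function(df, dx, dy, xcol = "x", ycol = "y") {
  out <- df
  out[[xcol]] <- df[[xcol]] + dx
  out[[ycol]] <- df[[ycol]] + dy
  out
}
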