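// Joint negative log-density of the TOA state-space positioning model.
//
// Latent processes (one value per transmission i):
//   burst interval: t(i)-t(i-1) | past ~ N(t(i-1)-t(i-2), sigma_bi^2)   [i >= 3]
//   position:       x(i) | x(i-1) ~ N(x(i-1), 2*D_xy*dt), same for y   [i >= 2]
//   sound speed:    v(i) | v(i-1) ~ N(v(i-1), 2*D_v*dt)                [i >= 2]
// with dt = t(i)-t(i-1) taken from the latent transmission times; the first
// state of each process is diffuse (no prior contribution).
//
// Observation: for every non-missing arrival tau(i,h),
//   resid = tau(i,h) - [ t(i) + dist(i,h)/v(i) ]
// distributed as a mixture p_mix*N(0,sigma_toa^2) + (1-p_mix)*t3(scale_t),
// the scaled t with 3 df supplying the heavy tail that absorbs multipath.
//
// model_code 1 is a linear-Gaussian random-walk reduction (direct noisy
// observation of a scalar RW) used to validate the Laplace machinery against
// the closed-form marginal likelihood.

#define TMB_LIB_INIT R_init_toatrack
#include <TMB.hpp>

template <class Type>
bool isNA(Type x) {
  return R_IsNA(asDouble(x));
}

// log density of the standard t with 3 df: 2/(pi*sqrt(3)) * (1+x^2/3)^-2
template <class Type>
Type log_dt3(Type x) {
  return log(Type(2.0)) - log(Type(M_PI) * sqrt(Type(3.0))) -
         Type(2.0) * log(Type(1.0) + x * x / Type(3.0));
}

template <class Type>
Type objective_function<Type>::operator()() {
  DATA_INTEGER(model_code);

  if (model_code == 1) {
    DATA_VECTOR(y_obs);
    DATA_SCALAR(obs_sd);
    DATA_SCALAR(rw_sd);
    DATA_SCALAR(prior_sd);
    PARAMETER_VECTOR(state);
    Type nll = 0.0;
    nll -= dnorm(state(0), Type(0.0), prior_sd, true);
    for (int i = 1; i < state.size(); ++i)
      nll -= dnorm(state(i), state(i - 1), rw_sd, true);
    for (int i = 0; i < y_obs.size(); ++i)
      nll -= dnorm(y_obs(i), state(i), obs_sd, true);
    return nll;
  }

  DATA_MATRIX(toa);   // n_pings x n_hydro, NA = not detected
  DATA_MATRIX(hxy);   // n_hydro x 2 hydrophone coordinates (m)

  PARAMETER(log_sigma_bi);
  PARAMETER(log_D_xy);
  PARAMETER(log_D_v);
  PARAMETER(log_sigma_toa);
  PARAMETER(log_scale_t);
  PARAMETER(logit_p_mix);

  PARAMETER_VECTOR(top);  // transmission times (s)
  PARAMETER_VECTOR(x);    // easting (m)
  PARAMETER_VECTOR(y);    // northing (m)
  PARAMETER_VECTOR(v);    // speed of sound (m/s)

  Type sigma_bi  = exp(log_sigma_bi);
  Type D_xy      = exp(log_D_xy);
  Type D_v       = exp(log_D_v);
  Type sigma_toa = exp(log_sigma_toa);
  Type scale_t   = exp(log_scale_t);
  Type p_mix     = invlogit(logit_p_mix);

  int n  = toa.rows();
  int nh = toa.cols();
  Type nll = 0.0;
  Type log_p   = log(p_mix);
  Type log_1mp = log(Type(1.0) - p_mix);

  // burst-interval random walk on transmission times
  for (int i = 2; i < n; ++i)
    nll -= dnorm(top(i) - top(i - 1), top(i - 1) - top(i - 2), sigma_bi, true);

  // position and sound-speed random walks; dt floored to keep sd positive
  // should the inner optimizer momentarily disorder the transmission times
  for (int i = 1; i < n; ++i) {
    Type dt = top(i) - top(i - 1);
    dt = CppAD::CondExpGt(dt, Type(1e-6), dt, Type(1e-6));
    Type sd_xy = sqrt(Type(2.0) * D_xy * dt);
    Type sd_v  = sqrt(Type(2.0) * D_v * dt);
    nll -= dnorm(x(i), x(i - 1), sd_xy, true);
    nll -= dnorm(y(i), y(i - 1), sd_xy, true);
    nll -= dnorm(v(i), v(i - 1), sd_v, true);
  }

  // robust mixture likelihood of the observed arrival times
  for (int i = 0; i < n; ++i) {
    for (int h = 0; h < nh; ++h) {
      if (isNA(toa(i, h))) continue;
      Type dx = hxy(h, 0) - x(i);
      Type dy = hxy(h, 1) - y(i);
      Type dist = sqrt(dx * dx + dy * dy + Type(1e-12));
      Type mu = top(i) + dist / v(i);
      Type e = toa(i, h) - mu;
      Type lg = log_p + dnorm(e, Type(0.0), sigma_toa, true);
      Type lt = log_1mp + log_dt3(e / scale_t) - log_scale_t;
      nll -= logspace_add(lg, lt);
    }
  }

  ADREPORT(sigma_bi);
  ADREPORT(D_xy);
  ADREPORT(D_v);
  ADREPORT(sigma_toa);
  ADREPORT(scale_t);
  ADREPORT(p_mix);

  return nll;
}
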