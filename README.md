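# toatrack

Track estimation for acoustic telemetry, directly from time-of-arrival data.

Aquatic animals are tracked by tagging them with acoustic transmitters and
surrounding the study site with synchronized hydrophones. The classical
pipeline positions each ping independently by hyperbolic multilateration on
time *differences* of arrival (TDOA), discards every ping heard by fewer
than three receivers, and filters the resulting cloud of positions
afterwards. `toatrack` is for telemetry researchers who want the model-based
alternative (the YAPS approach): one joint state-space model, fitted by
maximum likelihood to the raw time-of-arrival (TOA) matrix, which estimates
the whole track at once, yields a position for *every* transmission, and is
robust to multipath arrivals.

## The model

Latent states per ping `i`: transmission time `t(i)`, position
`x(i), y(i)`, speed of sound `v(i)`. Three coupled Gaussian random walks
form the process model,

    t(i) - t(i-1) | .  ~  N( t(i-1) - t(i-2), sigma_bi^2 )        (burst interval)
    x(i) | x(i-1)      ~  N( x(i-1), 2 * D_xy * dt )              (movement, same for y)
    v(i) | v(i-1)      ~  N( v(i-1), 2 * D_v  * dt )              (sound speed)

with `dt = t(i) - t(i-1)`, and the observation model predicts the arrival at
hydrophone `H` as `mu(H,i) = t(i) + dist(H,i) / v(i)`. Residuals
`tau(i,H) - mu(H,i)` follow a robust mixture
`p * N(0, sigma_toa^2) + (1-p) * t3(e/s)/s` — Gaussian receiver noise plus a
zero-centred scaled t with 3 df whose heavy tail absorbs multipath. The
latent states are integrated out by the Laplace approximation (sparse inner
Newton, via a compiled TMB template) and the six parameters
(`sigma_bi`, `D_xy`, `D_v`, `sigma_toa`, `s`, `p`) are estimated by maximum
likelihood. A classical per-ping TDOA least-squares solver, a forward
simulator of the benchmark (random-walk tracks, missed detections, bounded
multipath offsets) and the standard accuracy metrics are included.

## Worked example

Simulate a 100-ping track on the benchmark array (five hydrophones on the
corners and centre of a 100 x 100 m quadrant), drop 30% of detections, then
fit both estimators:

```r
library(toatrack)

array <- benchmark_array()
sim <- simulate_tag(array, sim_config(n_pings = 100, p_na = 0.3), seed = 1)
sim
#> Simulated acoustic tag track
#>   100 pings on 5 hydrophones; mean detections/ping 3.27

fit <- fit_yaps(sim$toa, array)
fit
#> TOA state-space fit (laplace): 100 pings, 327 arrivals, nll = -1717.869
#> # A tibble: 6 × 3
#>   term      estimate std_error
#> 1 sigma_bi  0.000865 0.0000881
#> 2 D_xy      1.01     0.120
#> 3 D_v       0.0385   0.129
#> 4 sigma_toa 0.000302 0.0000262
#> 5 scale_t   0.000325 0.00685
#> 6 p_mix     1.000    0.000379
```

The movement diffusivity (true value 1) and the TOA noise sd (true value
3e-4 s) are recovered; with no simulated multipath the mixture weight heads
to its Gaussian limit. `tidy(fit)` gives the per-ping track with standard
errors; every transmission is positioned, including the ~9% heard by fewer
than three hydrophones:

```r
glance(evaluate_track(fit, sim$truth, array))
#>   efficiency mean_dev rms_dev rel_len_err frac_within_0.5 frac_within_1
#> 1          1    0.756    1.01       -8.50            0.43          0.71

td <- fit_tdoa(sim$toa, array)
td
#> TDOA multilateration fit: 80/100 pings positioned (efficiency 0.80)
glance(evaluate_track(td, sim$truth, array))
#>   efficiency mean_dev rms_dev rel_len_err frac_within_0.5 frac_within_1
#> 1        0.8     3.69    14.7        189.           0.438         0.662
```

Same data, same truth: the state-space fit positions all 100 pings with
0.76 m mean error, while per-ping multilateration loses a fifth of the
transmissions and averages 3.7 m, inflating the apparent track length by
189%. `autoplot(fit, truth = sim$truth)` overlays the estimated and true
tracks on the array; `run_benchmark()` sweeps whole grids of degradation
conditions and returns a tidy metrics table.

A thin command-line wrapper with `simulate`, `degrade`, `fit-yaps`,
`fit-tdoa`, `evaluate` and `benchmark` subcommands is installed at
`system.file("cli", "toatrack", package = "toatrack")`.

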