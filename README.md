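# raffsim

Rotating-frame relaxometry with RAFFn pulse trains: pulse construction,
two-pool Bloch–McConnell simulation, steady-state relaxation fitting,
pixel-wise mapping, and myocardial-infarct contrast analysis.

## What this is for

Relaxation Along a Fictitious Field (RAFFn) is a rotating-frame MRI
preparation: a train of amplitude- and frequency-modulated rotary-echo
packets is applied before the readout, and the signal measured at a set of
train lengths decays toward a driven steady state. Fitting the decay of the
two acquisitions started from +z and from inverted magnetization with

    SI±Z(t) = SI0,±Z · e^(−R·t) − S_SS · (1 − e^(−R·t)),   SS = S_SS / SI0

gives the relaxation rate constant R (s⁻¹) and steady-state fraction SS per
pixel. Stretching the rotary-echo packet by a factor TL (element duration
TL·π/(√2·ω₁ᵐᵃˣ); 2.25 ms packets at the nominal 625 Hz, TL = 1) retunes the
preparation's sensitivity. Infarct contrast is summarised as the relative
relaxation time difference, RRTD = (T_MI − T_remote)/T_remote · 100%.

The package is aimed at quantitative-MRI researchers who want to simulate,
fit and benchmark these preparations without scanner data: it builds the
pulses (stretched RAFF2, RAFF1–5, CW spin-lock, adiabatic HS1/HS4/AHP, hard
pulses), propagates a water/solute two-pool exchange system with dipolar
relaxation through arbitrary shaped trains, fits decay curves and maps, and
generates a seeded synthetic short-axis cardiac phantom (MI / remote /
healthy regions) to exercise the whole chain.

## Worked example

Build the nominal RAFF2 packet, simulate dual-polarity decay curves for the
healthy-myocardium two-pool system, and fit the steady-state model:

```r
library(raffsim)

pk <- make_raff2_packet(625, TL = 1.0)
pk
#> <p_packet> RAFF2 TL1.0: 128 samples, packet 2.263 ms (element 0.566 ms), peak 625 Hz, alpha2 45.0 deg

sys <- two_pool_system("Fn1", "healthy")
dc  <- simulate_decay_curves(sys, pk, max_packets = 64, n_timepoints = 33)
fit <- fit_ss_model(dc)
glance(fit)
#> # A tibble: 1 × 4
#>       R SS_fraction residual_norm converged
#>   <dbl>       <dbl>         <dbl> <lgl>
#> 1 0.546      -0.668      0.000365 TRUE
```

The fitted R ≈ 0.546 s⁻¹ sits just under the dipolar rates of the model
(R1 ≈ R2 ≈ 0.548 s⁻¹ at τ_c = 10 ps — with near-equal R1/R2 the decay is
essentially isotropic), and the steady-state fraction |SS| ≈ 0.67 is the
driven plateau left by the rotary echo's residual per-packet rotation; it
falls monotonically as the packet is stretched (≈ 0.87 at TL 0.6, ≈ 0.02 at
TL 2.0 — see `simulate_relaxation_table()`).

Phantom → maps → contrast, with 1% noise:

```r
tt   <- seq(0, 0.07232, length.out = 9)
spec <- phantom_spec(grid = c(96, 96), noise_sigma = 0.01, seed = 42,
                     region_params = default_region_params(mi_ratio = 1.182))
ser  <- synthesize_series(spec, tt, polarity = "both")
mp   <- fit_map(ser$plus, tt, model = "ss_model",
                mask = ser$mask$MI | ser$mask$remote,
                paired_stack = ser$minus, method_label = "RAFF2 TL0.6")
contrast_report(list(`RAFF2 TL0.6` = mp), ser$mask)
#> # A tibble: 1 × 8
#>   method        t_mi    sd_mi  n_mi t_remote sd_remote n_remote rrtd_percent
#>   <chr>        <dbl>    <dbl> <int>    <dbl>     <dbl>    <int>        <dbl>
#> 1 RAFF2 TL0.6 0.0532 0.000574   924   0.0450  0.000472      924         18.3
```

The MI-region relaxation time (53.2 ms) exceeds the remote time (45.0 ms)
by 18.3% — recovering, under noise, the 18.2% effect size the phantom was
built with (`mi_ratio = 1.182`).

The pipeline stages are also scriptable from YAML configs
(`run_config()` / `inst/exec/raffsim`): `simulate-table`, `export-shapes`,
`make-phantom`, `fit-maps`, `contrast-report`, each writing a deterministic
provenance sidecar.

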