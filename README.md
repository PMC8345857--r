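# tauspread

Pathological tau — the misfolded, aggregating protein behind Alzheimer's
disease and other tauopathies — spreads between connected neurons along
axons, and different tau conformers show different preferences for
spreading in the anterograde (soma → axon terminal) versus retrograde
direction. `tauspread` implements a mechanistic model of how such
directional bias can emerge from axonal transport alone: soluble tau
enhances the processivity of the anterograde motor kinesin, while
insoluble tau obstructs it, and the balance of those two feedbacks — not
any built-in asymmetry — decides where tau ends up.

The package is aimed at computational neuroscientists and modelers of
protein-spread dynamics who want a reproducible, testable implementation
of concentration-feedback transport in a closed two-neuron system.

## The model in brief

Two species are tracked on a 1-D axis through five compartments
(presynaptic somatodendritic compartment, axon initial segment, axon,
synaptic cleft, postsynaptic somatodendritic compartment): soluble tau
*n*(*x*, *t*) and insoluble tau *m*(*x*, *t*), in µM. Soluble tau diffuses
everywhere (the axon initial segment and cleft act as diffusion barriers,
scale λ ≪ 1) and is actively transported inside the axon with effective
velocity

    v(n, m) = v_a (1 + δn)(1 − εm) − v_r

so the net axonal flux is `j = f(−D_n ∂n/∂x) + (1 − f) v n`, with
diffusing fraction *f*. The species interconvert via fragmentation (βm)
and aggregation (γn(n + m)); total mass is conserved exactly. The
somatodendritic deposition bias

    B(t) = [(n̄_post + m̄_post) − (n̄_pre + m̄_pre)] / [n̄_post + m̄_post + n̄_pre + m̄_pre]

summarises the outcome: +1 purely anterograde, −1 purely retrograde. In
the (δ, ε) plane the boundary between anterograde- and retrograde-biased
steady states is a straight line (the zero-bias manifold) whose slope
dδ/dε ≈ 2.8 at the calibrated baseline, doubling when γ doubles and
halving when γ halves (β acts oppositely).

The numerics are a conservative finite-volume discretization (harmonic-
mean interface diffusivities, upwinded advection, compartment boundaries
resolved on cell faces) integrated by a stiff implicit multistep solver
with a banded Jacobian; the right-hand side is compiled. See the methods
vignette (`vignettes/tau-transport-model.Rmd`) for the full account.

## Worked example

```r
library(tauspread)

mod <- tau_model(tau_preset("anterograde"))   # δ = 1, ε = 0.01
mod$params
#> Tau transport model parameters
#>   D_n = 12 um^2/s, f = 0.92 (effective axonal D = 11.04 um^2/s)
#>   v_a = 0.7 um/s, v_r = 0.7 um/s
#>   beta = 5.048e-07 1/s, gamma = 1e-05 1/(uM s)
#>   delta = 1 1/uM, epsilon = 0.01 1/uM
#>   lambda (AIS/SC barrier) = 0.01

ss <- run_to_steady_state(mod)    # uniform 0.2 µM axonal soluble tau at t = 0
ss$converged
#> [1] TRUE
sd_bias(ss$state, mod)
#> [1] 0.3236
```

The bias time series shows the three phases of the dynamics — an early
soluble-tau wave into the postsynaptic compartment, conversion to
insoluble tau over days, and slow re-equilibration to a stable
anterograde-biased steady state after months:

```r
bias_timeseries(ss$trajectory)[c(15, 25, 35, 41), c("time_s", "sd_post_n_uM", "sd_post_m_uM", "bias")]
#>          time_s sd_post_n_uM sd_post_m_uM   bias
#> 15 2.154435e+03       0.0086       0.0000 0.7699
#> 25 1.343399e+05       0.1534       0.0293 0.3904
#> 35 8.376776e+06       0.0400       0.1525 0.3492
#> 41 1.000000e+08       0.0401       0.1542 0.3236
```

So at *t* = 2154 s only soluble tau has reached the somatodendritic
compartments (0.0086 µM postsynaptically) and the bias transient peaks
near 0.77; by *t* = 10⁸ s insoluble tau dominates (0.154 µM vs 0.040 µM)
and the bias settles at +0.32 — a strong anterograde deposition bias.
Swapping the preset for `"retrograde"` (δ = 0.01, ε = 1) gives
B = −0.63; `"unbiased"` (δ = 1, ε = 0.35) gives B ≈ 0.

The manifold analysis chains a steady-state sweep, per-row cubic root
extraction and a line fit:

```r
man <- manifold_analysis(tau_model(tau_params()))   # 96 steady-state runs
coef(man)
#>     slope intercept
#>    2.8512   -0.0075
```

A thin CLI wrapping these functions (subcommands `run`, `steady`,
`converge`, `sweep`, `manifold`, `calibrate`, `fit`) is installed at
`inst/cli/tauspread.R`.

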