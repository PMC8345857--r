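---
title: "Modeling directional bias in tau spread from axonal transport feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling directional bias in tau spread from axonal transport feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauspread)
```

## The model

`tauspread` simulates two species of pathological tau on a single spatial
axis running through two neurons: soluble tau $n(x,t)$ (misfolded monomers
and small oligomers, mobile) and insoluble tau $m(x,t)$ (filaments and
tangles, immobile), both in µM. The domain is divided into five segments in
fixed order — presynaptic somatodendritic compartment (SD), axon initial
segment (AIS), axon proper, synaptic cleft (SC), postsynaptic SD — and the
processes acting on each species are switched per compartment:

| Compartment | Active transport | Diffusion | Interconversion |
|---|---|---|---|
| SD (both) | no | yes | yes |
| AIS | no | slow ($\lambda D_n$) | yes |
| Axon | yes | yes ($f D_n$) | yes |
| SC | no | slow ($\lambda D_n$) | no |

Soluble tau moves by diffusion and, inside the axon only, by motor-driven
active transport. The tug-of-war between kinesin (anterograde) and dynein
(retrograde) is summarised by an effective velocity with concentration
feedback,

$$v(n, m) = v_a\,(1 + \delta n)(1 - \epsilon m) - v_r,$$

where soluble tau enhances kinesin processivity through $\delta$ and
insoluble tau obstructs it through $\epsilon$, while the retrograde motor
is unaffected. The expression is evaluated literally: when
$\epsilon m > 1$ the velocity becomes strongly negative, which is the
mechanism behind retrograde-dominated regimes, so no clamping is applied.
The net axonal flux of $n$ splits into a diffusing fraction $f$ and a
transported fraction $1 - f$:

$$j_{net} = f\,(-D_n n_x) + (1 - f)\, v(n,m)\, n.$$

The species interconvert through fragmentation (unimolecular,
$m \to n$ at rate $\beta m$) and aggregation (bimolecular, $n \to m$ at
rate $\gamma n (n + m)$), i.e. a net soluble production
$\Gamma(n,m) = \beta m - \gamma n(n+m)$. There is no recruitment of
healthy tau, no clearance and no leakage: with zero-flux ends the total
mass $\int (n + m)\,dx$ is exactly conserved, which doubles as a global
correctness check on the numerics.

In the somatodendritic compartments the governing equation keeps diffusion
(at the unscaled effective diffusivity $D_n$, as the compartment hosts no
motor transport and hence no diffusing-fraction split; the alternative
$f D_n$ reading is available via `scale_sd_diffusion = TRUE`) plus
interconversion. The AIS and SC are AIS-like diffusion barriers with
effective diffusivity $\lambda D_n$, $\lambda \ll 1$; the SC additionally
has no interconversion, so insoluble tau can never appear there.

## Parameters

| Symbol | Meaning | Unit | Default | Origin |
|---|---|---|---|---|
| $D_n$ | theoretical diffusivity of $n$ | µm²/s | 12 | measured (cultured neurons) |
| $f$ | diffusing fraction of $n$ | — | 0.92 | measured |
| $v_a, v_r$ | native anterograde/retrograde velocity | µm/s | 0.7 | measured |
| $\beta$ | fragmentation rate | 1/s | 5.048e-7 | calibrated (below) |
| $\gamma$ | aggregation rate | 1/(µM·s) | 1e-5 | calibrated (below) |
| $\delta$ | kinesin enhancement by $n$ | 1/µM | regime-specific | swept in [0, 1] |
| $\epsilon$ | kinesin inhibition by $m$ | 1/µM | regime-specific | swept in [0, 1] |
| $\lambda$ | barrier diffusivity scale | — | 0.01 | chosen $\ll 1$ |

$\delta$ and $\epsilon$ carry units of 1/µM so that $\delta n$ and
$\epsilon m$ are dimensionless; the conventional sweep range $[0, 1]$ is
interpreted in these units. Note $D_n f = 11\ \mu m^2/s$, the effective
axonal diffusivity as measured.

Geometry defaults are 200 µm somatodendritic segments, a 40 µm AIS, a
20 µm cleft segment (treated as a one-dimensional barrier, not a physical
~20 nm gap) and a 1000 µm axon. The axon length deserves comment, since it
is a free choice: the steady-state deposition bias is produced by the
exponential concentration gradient that transport feedback builds along
the axon, so the bias strength grows with axonal path length. At 500 µm
the anterograde regime saturates near $B \approx 0.13$; at 1000 µm — still
a short axon by cortical standards — the three canonical regimes reproduce
the expected strong biases ($+0.32$, $-0.63$, $\approx 0$). We therefore
adopt 1000 µm as the default and keep it configurable.

### The three canonical regimes

`tau_preset()` encodes the three transport-feedback regimes:
`"anterograde"` ($\delta = 1, \epsilon = 0.01$), `"retrograde"`
($\delta = 0.01, \epsilon = 1$) and `"unbiased"`
($\delta = 1, \epsilon = 0.35$). Their qualitative behaviour — strong
postsynaptic deposition, strong presynaptic deposition, and balanced
deposition emerging from an initial anterograde transient — is recovered
by the somatodendritic bias statistic

$$B(t) = \frac{(\bar n_{post} + \bar m_{post}) - (\bar n_{pre} + \bar m_{pre})}
              {\bar n_{post} + \bar m_{post} + \bar n_{pre} + \bar m_{pre}},$$

computed over compartment-mean concentrations. When there is no
somatodendritic tau at all (e.g. at $t = 0$ under the axonal initial
condition) the bias is reported as missing, never as 0.

### Calibrating the interconversion rates

$\beta$ and $\gamma$ cannot be pinned from transport measurements. The
package fixes them by requiring the feedback pair
$(\delta, \epsilon) = (1, 0.35)$ to be net-unbiased at steady state.
Within the plausible range $[10^{-8}, 10^{-5}]$ for both rates, the
steady-state bias is monotone increasing in $\beta$ at fixed $\gamma$
(faster fragmentation shifts the standing $m/n$ ratio down, weakening the
$\epsilon$ channel), so for each $\gamma$ on a small log grid
`calibrate_interconversion()` scans $\beta$ downward for a sign change and
bisects inside it. Candidates must satisfy two qualitative timescale
constraints drawn from the phenomenology the model is meant to reproduce:
insoluble tau overtakes soluble tau only after more than a day of model
time, and the run must genuinely reach steady state. Among anchored
candidates the one that equilibrates earliest is preferred — the reading
of "biologically plausible rates" under which distributions stabilise
within months rather than years. With the default geometry this selects
$\gamma = 10^{-5}$ 1/(µM·s) and $\beta \approx 5.05 \times 10^{-7}$ 1/s
(standing $m/n \approx 2.7$, insoluble dominance after ≈3 days, steady
state after ≈1.4 years of model time at the anchor).

## Discretization and integration

The equations are discretized by a vertex-centred finite-volume scheme on
an inhomogeneous mesh: node spacing at most `fine_h` (default 1 µm) within
`refine_width` (10 µm) of every internal compartment boundary and at most
`coarse_h` (5 µm) elsewhere. Nodes are placed `fine_h/2` on either side of
each boundary so that every boundary coincides exactly with a cell face;
no cell straddles two compartments and the discontinuous masks are
resolved crisply. Three numerical choices matter:

* **Face-held coefficients.** Transport masks and effective diffusivities
  live on faces, not nodes, so interface fluxes are single-valued and mass
  conservation is exact by construction (the interior fluxes telescope and
  interconversion cancels between the species). Faces between cells of
  different compartments use the harmonic mean of the adjacent effective
  diffusivities, the standard conservative treatment of a discontinuous
  coefficient.
* **Upwind advection.** The active term uses first-order upwinding with
  the direction set by the sign of the face-averaged velocity. This is a
  deliberate deviation from centred treatments: it is positivity-
  preserving and robustly stable at the modest cell Péclet numbers here,
  at the cost of $O(h)$ accuracy in the advective term. A grid-refinement
  test (halving both spacings) verifies the steady bias moves by under 2%
  in all three regimes.
* **No clamping inside the solver.** Tiny negative concentrations from
  floating-point error are truncated to zero only in reported outputs
  (`state_at()`, CSV writers, plots), never in the solver state.

Time integration is method-of-lines with `deSolve::lsode` (implicit
multistep, variable order and step). The state is interleaved
$(n_1, m_1, n_2, m_2, \dots)$ so the Jacobian is banded with half-
bandwidth 3, which the integrator generates internally. The right-hand
side used by the solver is compiled (Rcpp); a pure-R reference
implementation (`time_derivative()`) is exported, and the test suite
asserts their equivalence together with an independent dense-loop
evaluation of the discretization. Default tolerances are
`rel_tol = 1e-8`, `abs_tol = 1e-12`; a total-mass drift above $10^{-6}$
relative at any output time is a hard error, not a warning.

Steady state is declared through the normalized change rate between
successive stored outputs,

$$\frac{\lVert n_k - n_{k-1}\rVert_1 + \lVert m_k - m_{k-1}\rVert_1}
       {\lVert n_k\rVert_1 + \lVert m_k\rVert_1}\,/\,\Delta t < 10^{-9}\ \mathrm{s}^{-1},$$

with cell-width-weighted L1 norms. The rate depends on the output cadence
(log-spaced, 40 points by default), so the trajectory always carries its
output grid. The default horizon is $10^8$ s: the slowest relaxation mode
is fragmentation-limited ($\sim 1/\beta \approx 2\times 10^6$ s, with
prefactors pushing full convergence towards $10^{7.5}$ s), and the
threshold of $10^{-9}$ s⁻¹ is only reliably crossed beyond $10^7$ s. The
stiff integrator covers the longer horizon at negligible extra cost, and
unconverged runs are flagged explicitly, never silently.

## Initial conditions and the random-profile generator

Three initializations are provided: the canonical uniform axonal profile
(0.2 µM soluble tau in the axon proper, nothing elsewhere, no aggregates),
somatodendritic insoluble seeding (a constant dose in one SD compartment,
mass-matched to the axonal profile by default), and mass-matched random
profiles. The random generator draws Uniform(0, 1) anchors for each
species at each SD midpoint and at ten equally spaced axonal points,
interpolates linearly across the full domain (constant beyond the
outermost anchors), zeroes insoluble tau in the cleft, and rescales both
profiles by one common factor to the target mass. The common factor
preserves the drawn soluble/insoluble proportions; per-species
normalization is available as an option. Two reading choices were open
here and are resolved as: anchors sit at SD midpoints (the simplest
placement consistent with one value per compartment and interpolation
across the whole domain), and the axonal anchor span is the axon proper,
excluding the AIS.

These profiles probe robustness of the steady state, not realism: real
initiation is a slow recruitment process from healthy tau that this closed
model deliberately excludes. Convergence of random ensembles therefore
demonstrates uniqueness of the attractor under these parameters, and
nothing about how real pathology is seeded.

## The zero-bias manifold

`bias_grid()` runs every $(\delta, \epsilon)$ pair of a rectangular grid
to steady state from the axonal initial condition; `zero_bias_roots()`
fits a cubic polynomial of bias against $\epsilon$ per $\delta$ row and
extracts the real root in $[0, 1]$; `fit_manifold()` fits the line
$\delta = a\,\epsilon + b$ through the roots. Conventions: the slope is
reported as $d\delta/d\epsilon$ (the convention under which the baseline
slope, the unbiased anchor at $\delta = 1$, and the direction of the
rate-perturbation effects are mutually consistent); when the cubic has
several admissible roots the one inside the grid's empirical sign-change
bracket is preferred; rows whose bias never changes sign on the grid are
omitted with a warning rather than extrapolated. The default desk-scale
sweep is 8 $\delta$ values in $(0, 1]$ by 12 $\epsilon$ values in
$[0, 0.6]$ (96 steady-state runs, about 15–20 s compiled), which brackets
every root of the baseline manifold; under halved aggregation or doubled
fragmentation the two steepest rows exit the $\epsilon$ window and are
dropped, leaving six roots for the fit.

At the calibrated baseline the sweep yields a slope of ≈2.85 with
intercept ≈0. Doubling $\gamma$ doubles the slope (≈5.6), halving it
halves it (≈1.44); $\beta$ acts oppositely. The mechanism is the standing
$m/n$ ratio: interconversion equilibrium gives $m/n \approx \gamma\,
(n+m)/\beta$, and the velocity balance $\delta n \approx \epsilon m$ then
makes the zero-bias ratio $\delta/\epsilon$ proportional to $\gamma/\beta$.
The diffusing fraction $f$ rescales the gradient that feedback can build
(bias magnitude off the manifold) but not the velocity balance itself, so
the root positions stay put — both effects are asserted in the test suite.

## The bias-curve fitting harness

`fit_bias_parameters()` matches simulated $B(t)$ to observed
`(time, bias)` pairs by randomized search over $\beta, \gamma$
(log-uniform), $\delta, \epsilon, f$ (uniform) within their plausible
ranges, with one local refinement stage around the incumbent and optional
user-supplied warm starts. Observed-bias inputs must already be on the
$[-1, 1]$ scale of $B$; mapping external network-bias parameterizations
onto that scale is the caller's responsibility. The fit is deliberately
reported with a non-uniqueness caveat: the manifold structure means
families of parameter combinations produce nearly identical bias curves,
so individual fitted values should not be over-interpreted.

## Problem sizes used in the tests

The packaged checks run at desk scale: the default mesh (≈360 nodes for
the default geometry, ≈260 for the 500 µm-axon test geometry), 96-point
sweeps for the baseline manifold, 32-point reduced sweeps for the
rate-perturbation ratios, ensembles of 10 random initializations per
regime for the robustness checks, and 10-observation synthetic bias
curves for the fitting harness. These sizes were chosen so the full suite
exercises every claim in minutes; all of them are arguments, not
constants, and scale up directly.

## Known limitations

* One spatial dimension: somatodendritic geometry is collapsed, so only
  compartment means are meaningful there; missorting within dendrites is
  out of scope.
* The AIS and SC barriers share a single static $\lambda$; real barriers
  are differentially and dynamically permeable.
* Mass conservation is an idealization over month-long horizons: there is
  no recruitment, clearance, or leakage to neighbouring cells.
* First-order upwinding trades advective accuracy for positivity; the
  grid-convergence test bounds the induced bias error at the defaults.
* Motor kinetics are time-averaged into effective velocities; explicit
  start-stop dynamics live below the model's timescale resolution.
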