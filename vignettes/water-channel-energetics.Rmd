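---
title: "Osmotic shrinkage kinetics and the energetics of water-channel permeation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Osmotic shrinkage kinetics and the energetics of water-channel permeation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaflux)
```

## The measurement and the model

Facilitated water transport through single-file channels such as
aquaporins is usually quantified by subjecting large unilamellar vesicles
(LUVs, ~100 nm diameter) to a hyperosmotic jump in a stopped-flow
instrument and following the 90° scattered light intensity as the vesicles
shrink. `aquaflux` implements the quantitative chain from those traces to
the activation thermodynamics of the channel.

The physical core is the osmotic shrinkage equation. With surface area
$S$, water permeability $P_f$, molar water volume $V_w$ and internal
osmolyte conservation $c_{in}(t) = c_{in,0} V_0 / V(t)$,

$$\frac{dV}{dt} = S P_f V_w \left(\frac{c_{in,0} V_0}{V} - c_{out}\right).$$

This ODE has a closed-form solution in the principal branch of the Lambert
W function (`volume_analytic()`); an adaptive ODE integration
(`volume_numeric()`, via **deSolve**) is kept as an independent
cross-check and the two agree to better than $10^{-6}$ relative error over
the whole experimentally relevant parameter range (tested over random
sweeps of $P_f \in [1, 500]$ µm/s, $r_0 \in [40, 80]$ nm and gradients up
to 0.5 osmol/L). Scattered intensity is taken as affine in vesicle volume;
after normalization $I_{norm}(t) = 1 - b\,V(t)$ with a single free
coefficient $b$ per trace (the raw offset is absorbed by the
normalization).

A reconstituted sample is never homogeneous: a fraction $X$ of vesicles
carries no protein, and the protein-carrying vesicles hold a
Poisson-distributed number of channel protomers. The mean signal is a
mixture of shrinkage curves, and the membrane permeability decomposes as
$P_f = P_{f,m} + P_{f,c}$ with $P_{f,c} = n\,p_f / (\pi d^2)$ for $n$
pores of unitary permeability $p_f$ in a vesicle of diameter $d$.

## The three fitting routines

1. **Exponential** (`fit_exponential()`): a double-exponential
   approximation $I(t) = I_0 - a e^{-t/\tau_{empty}} - b e^{-t/\tau_{prot}}$
   with $P_f = \frac{r_0}{3 V_w \tau}\frac{c_{in,0}+c_{out}}{2 c_{out}^2}$.
   Fast and traditional, but biased: the kinetics are not exponential, and
   the bias grows with the osmotic gradient (quantified in the test
   suite).
2. **Per-trace analytical** (`fit_analytical_single()`): nonlinear least
   squares of the two-population Lambert-W model over $(P_{f,c}, X, b)$,
   with $P_{f,m}$ fixed from a protein-free control.
3. **Global activation-energy fit** (`fit_global_ea()`): all traces of one
   suspension measured at several temperatures are fitted simultaneously.
   Because it is the same suspension, $X$ is shared, and the channel
   permeability is constrained to the Arrhenius law
   $P_f(T) = A e^{-E_a/RT} + P_{f,m}(T)$, making $E_a$ itself a fit
   parameter. Only the intensity coefficient $b_k$ is free per
   temperature.

Numerically, all three routines exploit that the linear parameters
(amplitudes, $b_k$) enter the residual linearly: they are profiled out in
closed form and the Levenberg-Marquardt search (**minpack.lm**) runs only
over the few nonlinear parameters. For the global fit that search space is
$(E_a, \ln P_{f,ref}, X)$, with the Arrhenius amplitude parameterized at
the median temperature for conditioning; bounds are $X \in [0,1]$,
$E_a \in [0, 50]$ kcal/mol, permeabilities positive. Starts are
deterministic and data-driven (per-trace analytical fits followed by an
Arrhenius regression), with four additional perturbed starts as a
safeguard against local minima. Standard errors come from the
Jacobian-based covariance at the optimum; results at parameter boundaries
or without channel/membrane contrast carry explicit flags instead of
failing silently.

The fit window starts after a configurable instrument dead time (default
1 ms) and residuals are unweighted, since stopped-flow noise on the
normalized intensity is close to homoscedastic; both choices are exposed
as arguments.

## The synthetic generator and what it does (not) emulate

`population_model()` + `simulate_ensemble()` generate seeded synthetic
ensembles with matched protein-free controls. Defaults are the AQP1-like
study conditions used throughout: $d = 100$ nm extruded vesicles,
$c_{in,0} = 0.21$ osmol/L with a 0.15 osmol/L sucrose jump (the buffer
recipe converted at NaCl ×2), $P_{f,m} = 6$ µm/s with $E_{a,m} = 11.6$
kcal/mol for the lipid background, $p_f = 3.2\cdot10^{-13}$ cm³/s at
278 K with $E_{a,c} = 3.75$ kcal/mol for the channel, $N_{mean} = 20$
protomers per proteoliposome, $X = 0.4$, temperatures
277–301 K, additive Gaussian intensity noise of sd 0.01. The Poisson
channel-count mixture is evaluated with exact mass bins up to the
$1-10^{-6}$ quantile; a `"fixed"` dispersion mode provides the
zero-variance two-population limit in which the fitting model is exactly
correct. The sampling grid mimics a dual time base (0.5 ms spacing over
the first tenth of the trace, 5 ms thereafter) so that both the fast
channel relaxation (~10 ms) and the slow membrane relaxation (~0.3 s) are
resolved, as stopped-flow electronics do in practice. Optionally a
lognormal vesicle-radius spread (CV ~10%) approximates the residual
polydispersity of extrusion through a 7-node quantile mixture.

Not emulated: mixing artifacts and instrument dead-time distortions,
photomultiplier shot noise, vesicle aggregation or lysis, and scattering
physics beyond the linear intensity-volume assumption. Passing tests on
these synthetic data therefore demonstrate correctness of the estimators
under the stated statistical model, not robustness to instrument-specific
artifacts.

## Error studies

Four Monte-Carlo studies mirror the main error sources in
activation-energy estimation:

* `gaussian_pf_study()`: Gaussian scatter on per-temperature $P_f$
  propagated through the Arrhenius regression; reports mean and SEM vs
  the number of averaged measurements (non-positive draws are redrawn and
  counted).
* `temperature_range_study()`: the $1/T$ leverage effect - the Ea spread
  scales as $R\sigma/\sqrt{\sum(1/T_i - \overline{1/T})^2}$, so wide
  temperature ranges dominate any increase in point count. Ranges share
  common random numbers so comparisons are paired.
* `temperature_bias_study()`: imperfect insulation is modeled as a
  temperature error ramping linearly from 0 at the coldest set point to
  $\Delta\Delta t$ at the hottest, with the *true* cuvette temperature
  exceeding the recorded one. Data generated at the true temperatures and
  regressed against recorded ones then overestimate $E_a$, monotonically
  in $\Delta\Delta t$ and - in the noiseless limit - independently of the
  true $E_a$ (the bias is a pure ratio of $1/T$ spreads). The opposite
  sign convention would underestimate instead; the convention is a
  documented modeling choice.
* `reconstitution_study()`: the full pipeline over grids of $N_{mean}$,
  $X$ and $p_f$, comparing the three routines on identical data. The
  global fit is consistently the most precise, the exponential
  approximation the least; a slow channel ($p_f = 2\cdot10^{-14}$ cm³/s)
  degrades all routines by shrinking the contrast between $P_{f,c}$ and
  $P_{f,m}$.

Default replicate counts (e.g. 10,000 for the Gaussian study) match the
scale of the original analyses; the test suite runs reduced replicates
(1,500-4,000, and 12 ensembles per cell for the pipeline-level study),
which are the sizes at which the asserted properties are stable under the
fixed seeds.

## Transition-state decomposition

With an accurate $E_a$ and unitary permeability $p_f$, transition-state
theory links the barrier components:

$$p_f = \kappa\,\nu_0 v_w\, e^{1 + \Delta S^\ddagger/R} e^{-E_a/RT},
\qquad \nu_0 = k_B T / h,\; v_w = V_W/N_A,$$

where the transmission coefficient $\kappa \in (0,1]$ corrects the
classical attempt frequency for barrier recrossing. `entropy_from_pf()`
inverts this for $\Delta S^\ddagger$; `enthalpy_of_activation()` gives
$\Delta H^\ddagger = E_a - RT$ (activation volume term fixed at 0, the
standard solution-reaction approximation, though kept in the data model);
`gibbs_decomposition()` completes
$\Delta G^\ddagger = \Delta H^\ddagger - T\Delta S^\ddagger$. The
alternative route through the linearized Eyring regression of
$\ln(p_f/T)$ on $1/T$ (`eyring_linear_fit()`) is algebraically consistent
with the prefactor route after the $E_a = \Delta H^\ddagger + RT$
conversion, and the tests verify both routes against each other.

```{r}
tst_decompose(pf = cm3_s_to_m3_s(3.2e-13), Ea = kcal_to_J(3.75),
              kappa = 0.48, temperature = 278, T_eval = 298,
              rel_dpf = 0.05, dEa = kcal_to_J(0.16), dkappa = 0.04)
```

Numerical choices worth knowing:

* $\nu_0$ and $v_w$ are evaluated at the temperature of the supplied
  $p_f$ (278 K for the AQP1 reference value); the pre-exponential is
  treated as temperature-independent across the 24 K window.
  `entropy_temperature_sensitivity()` quantifies the residual drift from
  the neglected $\ln T$ dependence (~0.6 J/(mol·K) across the window,
  well inside the propagated uncertainty).
* $V_w = 18.0$ cm³/mol is a documented, configurable constant;
  1 kcal = 4184 J exactly; CODATA constants in `aquaflux_constants`.
* `entropy_error()` implements the stated quadrature propagation
  $\delta(\Delta S^\ddagger) = R\sqrt{(\delta p_f/p_f)^2 +
  (\delta E_a/RT)^2 + (\delta\kappa/\kappa)^2}$ literally. Note that a
  $\delta E_a$ of 0.16 kcal/mol alone contributes ~2.25 J/(mol·K) through
  this formula - more than typical totals quoted for such analyses - so
  the relative weighting of the three inputs matters and the function
  deliberately takes them explicitly rather than assuming defaults.
* The inferred $\Delta S^\ddagger$ is hypersensitive to $E_a$ *through
  the pre-exponential*: when $p_f$ is reconstructed from a fitted
  Arrhenius amplitude, $\delta(\Delta S^\ddagger) \approx \delta E_a / T$,
  i.e. a 1% $E_a$ error already moves the entropy by ~0.6 J/(mol·K).
  This is the quantitative reason the global fit's precision matters.

## Transmission coefficient from trajectories

The MD post-processing layer operates on 1-D position-vs-time series
along the pore axis (plain text tables; running or parsing actual MD is
out of scope). `count_permeations()` and `count_halfway()` implement an
explicit entry/exit state machine: a traversal is an entry across one
boundary followed by an exit across the opposite one without an
intervening return; a half-way event is an entry that reaches the
dividing surface $z_{div}$ before exiting either side. Ambiguities are
resolved explicitly: trajectories that begin inside the pore are credited
with nothing (unknown origin); a single sampling step that jumps clear
across the pore counts as one traversal; reaching exactly $z_{div}$
counts for entries from the low side. The implementation collapses each
trajectory to its sequence of region changes and walks those events once;
an independent per-sample replay oracle in the test suite must agree
exactly on thousands of random walks.

`transmission_coefficient()` reports
$\kappa = N_{through} / N_{halfway}$, which is $\le 1$ by construction
(completion requires reaching $z_{div}$) and matches the meaning of
$\kappa$ as a recrossing correction. The literal inverse ratio is
available via `strict_ratio = TRUE` for comparability with analyses that
quote it the other way around; the orientation is stated on the result.
Spread is estimated over trajectory subsets (quarters or halves).
`free_energy_profile()` performs Boltzmann inversion
$\Delta G(z) = -RT\ln d(z)$ of the normalized position distribution in
0.05 nm bins, reporting empty bins as `NA` rather than infinities; the
profile is defined up to the normalization constant.

`generate_walk_trajectories()` supplies the synthetic stand-in for MD
output: overdamped Langevin walkers in a configurable 1-D potential, with
reflecting reservoir walls one nm beyond each pore boundary keeping the
particle number constant (the synthetic analogue of bulk water). Drift
with zero noise gives ballistic traversals and exactly $\kappa = 1$;
equilibrium occupancies match Boltzmann weights; $\kappa$ of flat-potential
walkers is stable under dividing-surface shifts of ±0.2 nm.

```{r}
geom <- pore_geometry()        # [-1.4, 1.7] nm, z_div = 0
tr <- generate_walk_trajectories(NULL, geom, n_particles = 200,
                                 n_steps = 2000, step_sd = 0.1, seed = 1)
transmission_coefficient(tr, geom)
```

For free diffusion the recrossing probability is high, so $\kappa$ is
small; values like 0.5 for a real channel indicate that half of the
molecules reaching the barrier top complete the transition.

## End-to-end pipeline

`run_pipeline()` chains everything: simulate (or load) an ensemble, fit
the controls, run the global fit, convert the fitted ensemble
pre-exponential to single-channel units via the explicit
$\pi d^2 / N_{mean}$ scaling, and decompose the barrier with a supplied
$\kappa$. Outputs embed the seed and a hash of the resolved
configuration; identical configurations and seeds give byte-identical
results.

```{r, eval = FALSE}
res <- run_pipeline(list(noise_sd = 0.005), output_dir = "run1", seed = 1)
res$summary
```

## Design notes and limitations

* **Units.** SI internally (m, s, J, osmol/m³); conventional units
  (µm/s, cm³/s, kcal/mol) at the interfaces, with explicit converters.
  This removes the most common class of silent errors in this analysis.
* **Osmolarities** are treated as ideal; buffer recipes must be converted
  by the caller (helpers document the NaCl ×2 convention).
* **Identifiability.** When $P_{f,c}$ is not well separated from
  $P_{f,m}$ (slow channels, poor reconstitution, high background), all
  routines degrade; fits flag low contrast and boundary-pinned $X$
  rather than failing. Improving reconstitution density or lowering the
  membrane background are the experimental remedies.
* **The two-population fitting model is an approximation** to the Poisson
  mixture it is fitted to; the residual misspecification is part of what
  the reconstitution study quantifies.
* **Interfaces.** The package is driven from R: the exported functions,
  the trace-CSV/manifest dialect (`read_trace_csv()`,
  `read_ensemble()`), the trajectory tables and `run_pipeline()`
  constitute the tool surface; there is no separate shell executable.
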