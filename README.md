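# aquaflux

Stopped-flow osmotic shrinkage kinetics and the activation thermodynamics
of water channels, for biophysicists characterizing aquaporins, artificial
water channels and other single-file pores reconstituted into large
unilamellar vesicles.

When vesicles are subjected to a hyperosmotic jump, their volume follows

$$\frac{dV}{dt} = S P_f V_w \left(\frac{c_{in,0} V_0}{V(t)} - c_{out}\right),$$

whose closed-form solution in the Lambert W function underlies all fits in
the package. The membrane permeability of a channel-doped vesicle splits
into a lipid background and a channel term,
$P_f = P_{f,m} + n\,p_f/(\pi d^2)$, and the temperature dependence of the
channel term gives the Arrhenius activation energy $E_a$. The package's
central estimator is a **global activation-energy fit**: all traces of one
vesicle suspension measured at several temperatures are fitted
simultaneously with a shared empty-vesicle fraction $X$ and the channel
permeability constrained to $P_f(T) = A e^{-E_a/RT} + P_{f,m}(T)$, so
$E_a$ is estimated directly from the raw traces rather than from a
two-stage Arrhenius regression. From $(p_f, E_a)$ and a transmission
coefficient $\kappa$ the transition-state layer extracts the barrier
components

$$\Delta H^\ddagger = E_a - RT, \qquad
p_f = \kappa \nu_0 v_w\, e^{1+\Delta S^\ddagger/R} e^{-E_a/RT}, \qquad
\Delta G^\ddagger = \Delta H^\ddagger - T \Delta S^\ddagger .$$

Also included: a seeded synthetic stopped-flow generator (Poisson channel
counts, empty-vesicle fraction, Arrhenius-consistent permeabilities,
additive noise), Monte-Carlo studies of $E_a$ error sources (permeability
scatter, temperature range and bias, reconstitution heterogeneity), and
transmission-coefficient estimation from 1-D permeation trajectories
($\kappa = N_{through}/N_{halfway}$ with an explicit, tested entry/exit
state machine) plus Boltzmann inversion of the water free-energy profile.

## Worked example

Simulate an AQP1-like temperature series and recover its activation
energy with the global fit:

```r
library(aquaflux)

model <- population_model(N_mean = 20, X = 0.4)   # AQP1-like defaults
proto <- measurement_protocol(noise_sd = 0.005)   # 277-301 K, 5 temps
ens   <- simulate_ensemble(model, proto, seed = 42)

fit <- fit_global_ea(ens)     # controls fitted internally for Pf_m(T)
summary(fit)
#> Ea = 3.587 +- 0.098 kcal/mol;  X = 0.401 +- 0.00088
#>  temperature_K Pf_c_um_s Pf_m_um_s            b
#>            277  194.6511  5.554957 1.910226e+21
#>            283  223.4924  8.707106 1.910999e+21
#>            289  255.1391 13.401519 1.910946e+21
#>            295  289.7022 20.163005 1.909511e+21
#>            301  327.2856 29.867884 1.908753e+21
```

The true generator values are $E_a = 3.75$ kcal/mol and $X = 0.4$: one
noisy five-temperature series recovers them within roughly two standard
errors, with the per-temperature channel permeabilities ($P_{f,c}$, µm/s)
lying exactly on the fitted Arrhenius curve and the lipid background
$P_{f,m}$ rising much more steeply with temperature (its activation
energy, 11.6 kcal/mol, is ~3x that of the channel).

Decompose the barrier with the reference single-channel permeability and
a transmission coefficient of 0.48:

```r
tst_decompose(pf = cm3_s_to_m3_s(3.2e-13), Ea = kcal_to_J(3.75),
              kappa = 0.48, temperature = 278, T_eval = 298,
              rel_dpf = 0.05, dEa = kcal_to_J(0.16), dkappa = 0.04)
#> Transition-state decomposition of the permeation barrier
#>   inputs: pf = 3.2e-13 cm3/s at 278 K, Ea = 3.75 kcal/mol, kappa = 0.48
#>   dH = 3.158 kcal/mol (at 298 K)
#>   dS = 1.900 +- 2.54 J/(mol K)
#>   T dS = 0.135 kcal/mol, dG = 3.023 kcal/mol at 298 K
```

The enthalpic barrier (3.16 kcal/mol) dominates the free-energy barrier
(3.02 kcal/mol at 298 K); the entropic term is small and *positive*
(~1.9 J/(mol·K), contributing -0.14 kcal/mol at 298 K), meaning the
transition state is slightly less ordered than bulk water. The quoted
uncertainty follows the explicit quadrature propagation of the three
input errors.

`run_pipeline()` chains simulation, control fits, the global fit and the
TST decomposition into one seeded, hash-stamped run; see the vignette
(`vignettes/water-channel-energetics.Rmd`) for the model details, the
numerical choices, and what the synthetic data do and do not emulate.

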