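---
title: "Allosteric thermodynamic modelling of heat-activated channel gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allosteric thermodynamic modelling of heat-activated channel gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermogate)
```

`thermogate` models the equilibrium gating of a heat-activated cation
channel (the TRPV1 phenomenology: activation by heat and capsaicin,
inhibition by external Na⁺) and implements the analysis chain that converts
macroscopic current–temperature recordings into absolute
open-probability–temperature (P~o~–T) relations. This vignette is the
package's account of the science: the models and their assumptions, the
tunable parameters, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was open.

## The gating model

The core model ("model i") couples four equilibria multiplicatively,
MWC-style:

1. **Pore opening**, equilibrium constant $L$, *temperature-independent*.
   This assumption exists to reproduce the observed plateaus in P~o~–T
   relations, where P~o~ stalls well below 1 over a 10 K stretch.
2. **A two-step temperature sensor**: sequential transitions with van 't
   Hoff constants $J_1(T)$ and $J_2(T)$,
   $J(T) = \exp(-(\Delta H^0 - T\Delta S^0)/RT)$, enthalpies in kcal/mol and
   $R = 1.9872\times10^{-3}$ kcal mol⁻¹ K⁻¹. The sequential arrangement
   (state weight $J_1 J_2$ for the fully activated sensor) keeps the state
   count down and removes one free coupling parameter; a parallel
   arrangement fits equally well and is deliberately not provided.
3. **External Na⁺ binding**, association constant $K_1'$ (per molar), with a
   Hill-style cooperative binding term $(K_1'[\mathrm{Na}])^{1.5}$. The 1.5
   exponent is an empirical stand-in for weak inter-subunit cooperativity —
   a full tetrameric treatment would quadruple the state space for no gain
   in identifiability — and is exposed as the `coop` argument. Na⁺ binding
   multiplies the weights of opening by $F$, of sensor step 1 by $G$, and of
   step 2 by $H$; inhibition corresponds to $F, G, H < 1$.
4. Optionally, **capsaicin binding** ($K_2'$, same cooperative exponent)
   with generic coupling factors `c_L`, `c_J1`, `c_J2`, `c_Na`. The factors
   are named generically because no canonical naming exists for them; their
   defaults are neutral (1).

Coupling factors multiply the statistical weight of the conformation an
arrow points to: $D$ applies to the open pore once the sensor has left its
resting state, $D\,E$ when fully activated. P~o~ is the ratio of open-state
weights to the full partition function. Two derived checks are wired into
the test suite: the closed-form evaluation must agree with brute-force state
enumeration to $10^{-12}$, and with every coupling factor at 1 the model
must collapse to $P_o = L/(1+L)$ regardless of temperature and ligands.

Two alternates are provided for model comparison. **Model ii** gives the
Na⁺-bound branch its own temperature-dependent opening ($J_3$) — the
mechanistically heavier reading in which Na⁺ changes what the opening
transition is, rather than only its weight. **Model iii** is the
single-sensor reduction; it reproduces model i exactly when the second
sensor step is folded out ($J_2 \to 0$, $E = H = 1$), which the suite
asserts.

### Heat capacity

The alternative sensor parameterization
$J(T) = \exp(\Delta S^0(T_0)/R - (\Delta C_p/R)(1 - T_0/T + \ln(T_0/T)))$
attributes temperature sensitivity to a heat-capacity change. Within the
experimentally accessible window the two parameterizations are not
distinguishable: once their $J(T)$ values are matched over the window, the
P~o~–T curves agree to the same precision as the match. The suite tests this
conditionally — in a tight-match regime the curves agree to $10^{-6}$, and
at moderate $\Delta C_p$ the P~o~ discrepancy is bounded by the $\ln J$
mismatch itself. The claim is about parameterization equivalence on a
window, not about distinguishability in principle.

### The illustrative parameter set

No canonical fitted parameter values are available for the full model, so
the package ships an *illustrative* preset
(`inst/extdata/model_i_illustrative.json`, loaded by
`model_preset_illustrative()`), chosen once to reproduce the qualitative
phenomenology and then frozen:

- sensor enthalpies 40 and 100 kcal/mol with midpoints 270 K and 315 K
  (well-separated: a flat intermediate plateau in 0 Na⁺);
- $L = 0.005$, $D = 50$, $E = 600$: plateau P~o~ ≈ 0.2 in 0 Na⁺, near-full
  activation at high temperature;
- $K_1' = 500$ M⁻¹ (half-inhibition near 2 mM at zero voltage, consistent
  with the reported extrapolated affinity), $F = 0.1$, $G = 0.01$,
  $H = 0.5$: 130 mM Na⁺ lowers the plateau to ≈ 0.05 and shifts the low-
  temperature rise upward so the plateau all but disappears;
- $K_2' = 2\times10^7$ M⁻¹ with `c_L` = 5000: saturating capsaicin (10 µM)
  drives P~o~ ≈ 0.99 and makes the P~o~–T relation nearly flat, which is
  what justifies using saturating-agonist recordings to estimate the
  conduction temperature-dependence.

These values are not experimentally constrained fits and are documented as
such in the JSON itself.

## From currents to open probabilities

A macroscopic current is $I(T) = N\, i(T)\, P_o(T)$ plus leak. The
open-channel current follows an Arrhenius law
$i(T) = i_0 e^{-\Delta H^{\neq}/RT}$ with $\Delta H^{\neq} = 9$ kcal/mol as
the canonical default, estimated from saturating-agonist recordings where
$P_o$ is flat. `it_to_pot()` divides the conduction dependence out;
`scale_pot()` anchors the result on an absolute scale using the relative
current magnitude at the reference temperature against a reference condition
of known P~o~ (saturating capsaicin, P~o~ ≈ 0.9 at +90 mV and room
temperature; chained references are supported with provenance). Scaling that
would push any P~o~ above 1 is an error, not a clip — it indicates a wrong
reference.

Steepness is quantified by fitting
$I(T) = \exp(-(\Delta H_{app} - T\Delta S_{app})/RT)$. On normalized data
the $(\Delta H, \Delta S)$ pair is degenerate with an overall amplitude, so
the fit is performed as ordinary least squares of $\ln I$ on $1/T$ and
$\Delta H_{app}$ (slope) is the quantity to interpret;
$Q_{10} \approx e^{\Delta H_{app}/20}$. A caveat the test suite makes
explicit: apparent enthalpies are *lower bounds* on the generating sensor
enthalpies. If a rising phase starts from a plateau at fraction $r$ of its
saturation level, the maximal log-slope is attenuated by
$(1-\sqrt r)/(1+\sqrt r)$; recovery within 15% requires deep plateaus
(strong coupling), and the additivity test uses such a regime.

Averaging across cells uses fixed-width temperature binning (default 1 K,
`T_bin`) in place of manual matching of similar temperatures; bins with
fewer than two members are dropped. When no sample falls exactly at the
reference temperature, the nearest sample within 1 K is used and recorded.
Leak subtraction is off by default (leak is treated as negligible relative
to the currents of interest); a constant-leak correction is available in the
generator for sensitivity checks.

## Noise analysis

The hybrid non-stationary/stationary method estimates the per-time-point
current variance from scaled successive differences of ordered sweeps,
$y_j = (x_j - x_{j+1})/2$ and $\sigma_I^2 = \tfrac{2}{N-2}\sum(y_j - \bar
y)^2$ — slow common drift (rundown) cancels to first order, which is the
reason to prefer it over the naive ensemble variance for channels that run
down. The variance–mean relation $\sigma^2 = I\,i - I^2/N$ is linear in
$(i, 1/N)$ and fitted by unweighted linear least squares; the weighting of
time points is not prescribed anywhere, and unweighted is the choice made
here. A single stationary condition spans too narrow a mean-current range to
identify $i$ and $N$ jointly (the fit refuses when max/min < 1.2), so data
from a low- and a high-P~o~ condition are pooled under the assumption of
shared $i$ and $N$; a constrained mode fixes $i$ from an external estimate.
Absolute open probability is $P_o = I_{mean,ss}/(iN)$.

Two documented failure modes are reproduced as tests: low-pass filtering of
the sweeps reduces the apparent single-channel current (direction asserted,
not magnitude), and with 20% linear rundown the successive-difference
estimator's P~o~ bias stays within 3× its drift-free value while the naive
variance fails outright. Edge samples (5% per side by default) are trimmed
to discard capacitive transients before leak/baseline subtraction.

## Dose–response, voltage, and the GHK relation

Na⁺ inhibition is fitted with the Hill equation in the inhibition
convention: the zero-ligand response is $I_{max}$ (removing Na⁺ activates
the channel), $I([X]) = I_{min} + (I_{max} -
I_{min})/(1 + ([X]/K_{1/2})^s)$. Fits use Levenberg–Marquardt least squares
with $K_{1/2}$ and $s$ on the log scale to enforce positivity; a brute-force
grid search serves as the oracle in tests. The voltage dependence of
affinity follows $K_{1/2}(V) = K_{1/2}(0)\,e^{-z\delta V/k_BT}$, fitted by
log-linear regression.

Theoretical current–voltage relations combine a Boltzmann open-probability
factor with the constant-field (GHK) flux. The flux is evaluated in the
numerically stable form $P\,F[z_1 C_{in}\, g(u_1) - f z_2 C_{out}\,
g(-u_2)]$ with $g(u) = u/(1-e^{-u})$ and $u_k = z_k FV/RT$; the permeability
ratio $f$ multiplies the external-ion (inward) summand only, matching the
printed layout of the source equation. The removable singularity at $V = 0$
is patched by the second-order expansion $g(u) \approx 1 + u/2 + u^2/12$ for
$|u| < 10^{-4}$; continuity across 0 is verified against the analytic limit.
Voltages are mV at every interface and volts internally.

## Inactivation

Irreversible loss of channels during slow heating is overlaid on the
equilibrium curve as $P_{o,inact}(t, T) = P_o(T)\,e^{-k(T)t}$ with
$k(T) = A(1-F_{Na})^2 e^{-(\Delta H^{\neq} - T\Delta S^{\neq})/RT}$
(canonical constants $A = 200$, $\Delta H^{\neq} = 45$ kcal/mol,
$\Delta S^{\neq} = 0.133$ kcal mol⁻¹ K⁻¹). $F_{Na}$, the equilibrium
fraction of Na⁺-bound states from the gating model, implements the
observation that external Na⁺ protects against inactivation. Ramp time
comes from the empirical sigmoid
$t = -0.83258 \ln(T_{max}/(T - 0.1) - 1) + 3.3181$ with $T_{max} = 333$ K.
Two parses of that flattened expression are possible; the one adopted sends
$T \to T_{max}$ as $t \to \infty$, which is the stated behaviour of the
ramp. Time units are the ramp-clock units implied by the transform — only
relative times matter to the survival factor, and the `time_scale` argument
expresses ramp speed (a fast jump is `time_scale` → 0, recovering the
equilibrium curve).

The survival factor is applied pointwise in $(t(T), T)$, exactly as the
empirical recipe prescribes, *not* as a path integral over the ramp
history; a cumulative-hazard variant $\exp(-\int k\,dt)$ is available as an
explicitly non-canonical option (`cumulative = TRUE`) for comparison. The
overlay reproduces the characteristic ramp/jump divergence: ramp and jump
curves agree below ~25 °C in 0 Na⁺ and separate sharply above.

## The synthetic-data generator

`sim_config()` + `gen_*()` emulate the statistical structure the analysis
assumes: Arrhenius single-channel conduction, binomial (or two-state Markov
with exponential autocorrelation) channel-number fluctuations, Gaussian
instrument noise, constant leak, lognormal cell-to-cell expression scatter,
per-sweep multiplicative rundown, and either linear or sigmoid-clock
temperature ramps. Everything is seeded and bit-reproducible; the seed is
surfaced in output metadata.

What it does *not* emulate — and therefore what passing tests do not show
about real recordings: kinetic (non-equilibrium) gating during fast
temperature changes, voltage-dependent gating (all simulations are at a
fixed test potential), series-resistance and filtering artifacts beyond the
boxcar filter used in one directional test, temperature-measurement error,
and any structural correlate of the transitions.

## Numerical and design choices

- Positivity of equilibrium constants is enforced at construction;
  nonlinear fits carry positive parameters on the log scale. Automated
  bounded least squares replaces the visual/manual parameter adjustment
  that is common practice for these models.
- `0^1.5 = 0`: zero ligand concentrations are exact zeros in the binding
  terms, so zero-ligand states carry weight exactly 0.
- The pipeline computes condition-to-reference current ratios *within* each
  simulated cell (paired measurement), so expression scatter cancels; each
  cell's relation is normalized at the reference temperature before
  averaging.
- Problem sizes used by the test suite and the acceptance script are desk
  scale, chosen to make sampling error a small fraction of every asserted
  tolerance: e.g. 50-sweep ensembles of 400 channels for noise-analysis
  recovery, 1000 random parameter draws for the enumeration oracle, and
  500-point ramps for enthalpy-recovery fits.
- Temperatures are kelvin internally everywhere; interfaces accept Celsius
  where stated (`unit = "C"`, CSV dialects).

## Known limitations

- The allosteric models are equilibrium models; inactivation is an overlay,
  not a state-model extension, and recovery from inactivation is out of
  scope.
- Apparent enthalpies from log-slope fits systematically underestimate
  transition enthalpies unless plateaus are deep (see above).
- The illustrative preset is qualitative; none of its couplings should be
  quoted as measured quantities.
- No voltage-dependent transitions in the gating models: the analysis is
  valid at strongly depolarized potentials where activation curves
  saturate.
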