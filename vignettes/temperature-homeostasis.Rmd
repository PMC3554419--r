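---
title: "Temperature scaling and metabolite homeostasis in anaerobic yeast glycolysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature scaling and metabolite homeostasis in anaerobic yeast glycolysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotherm)
```

## The question the model answers

Microorganisms cannot regulate their own temperature. When the temperature of
an anaerobic, glucose-fermenting yeast culture changes, every glycolytic
enzyme loses or gains catalytic capacity. The question is whether the
capacities of the different enzymes respond to temperature with the *same*
normalized function or with *different* ones — and how one could tell from
metabolite measurements alone, without trusting in-vitro kinetics.

The argument rests on a steady-state observation. Write each reaction rate as

\[ v_j = e_j\,k_{cat,j}\; f_j(K_S, K_P, K_E, S, P, E)\,\Big(1 - \frac{\Gamma_j}{K_{eq,j}}\Big), \]

where only the capacity \(e_j k_{cat,j}\) is assumed temperature dependent,
with a normalized scale \(R_j(T)\) such that
\(k_{cat,j}(T) = k_{cat,j}(T_0)\,R_j(T)\). At steady state the balances are
\(N v = 0\). If every enzyme shares one scale, \(R_j \equiv R\), then \(R\)
factors out of \(N v\): the steady-state *concentrations* solve the same
equations at every temperature, and all *fluxes* simply scale by \(R(T)\).
Two consequences are directly observable:

* under glucose excess (batch), intracellular metabolite levels are
  independent of the growth temperature while the flux scales with \(R(T)\);
* under glucose limitation (chemostat), metabolite levels are a function of
  the extracellular glucose concentration only, so points gathered under any
  temperature regime collapse onto one curve per metabolite.

A single enzyme with a deviating temperature function breaks the collapse —
but only for metabolites *upstream* of that enzyme, which is what makes the
deviation localizable.

## The packaged kinetic model

The full Teusink-style glycolysis model is not reprinted here; the package
ships a reduced backbone (`models/reduced_glycolysis.yaml`) that preserves
every structural feature the argument uses: a facilitated-diffusion glucose
carrier (GLT), an irreversible entry kinase (HXK), a near-equilibrium
isomerase (PGI), an irreversible committed step (PFK), a reversible
1-to-2 cleavage with the pooled triose phosphates (FBA, \(K_{eq}\) in mM
convention), a lumped lower-glycolysis step (TDHL: TDH·PGK·PGM·ENO), pyruvate
kinase (PYK), a lumped decarboxylation/reduction sink to ethanol and CO2
(PDC), and a small glycerol branch (GLYCB). Cofactors (ATP/ADP, NAD/NADH) are
treated as buffered and omitted. Users with a full SBML model can import its
structure (`load_model(..., format = "sbml")`); kinetic laws are never
guessed, and such a model refuses to simulate until laws are supplied.

Two modelling choices deserve explanation because the design was genuinely
open:

**Competitive product inhibition on the irreversible steps.** In a chain of
purely irreversible Michaelis–Menten reactions, a metabolite is determined
solely by its consumer's saturation, so a capacity perturbation cannot
propagate upstream past the first irreversible step. Full glycolysis models
transmit that information through reversible mass-action terms and allosteric
couplings. The reduced model restores the coupling in the simplest
thermodynamically sensible way: PFK is competitively inhibited by its product
FBP, TDHL by PEP, and PYK by pyruvate (the `effector_constants` of the rate
law; the general rate form explicitly allows effector terms). Without this,
the documented upstream-deviation pattern is unreachable in a reduced model.
HXK deliberately carries *no* product inhibition: its substrate (intracellular
glucose) is not a measured metabolite, and leaving the step uncoupled keeps
the transport flux insensitive to downstream perturbations, which is what
keeps downstream pools clean in the perturbed scenarios.

**Capacity calibration.** The capacities (mM/min at 30 °C) are calibrated to
the cultivation constraints of the emulated experiments rather than to any published parameter
set: an anaerobic glucose-limited chemostat at dilution rate
\(D = 0.03\,h^{-1}\) and 25 g/L feed glucose must be feasible at every
temperature in 12–30 °C (the attainable growth rate at 12 °C is only one
sixth of that at 30 °C, so the feasibility margin at 12 °C dictates the
transport capacity), the glucose-excess batch at 30 °C must have a unique
stable steady state with single-digit-mM pools, and the glucose-excess
"plateau" must be flat enough that pools sampled between 80 % and 30 % of the
initial glucose differ by well under 2 % (this sets the low transport
\(K_m\): the carrier operates far into saturation over the sampled window).

## Temperature machinery

* **Ratkowsky scaling.** \(V_{max,j}(T) = b_j (T - T_{min})^2\) below the
  optimum; normalized, \(R(T) = ((T - T_{min})/(T_0 - T_{min}))^2\) with
  \(T_0 = 30\) °C. The packaged \(T_{min} = -0.42\) °C is calibrated so that
  \(R(30)/R(12) = 6.0\), the observed batch flux ratio between those
  temperatures; the original Ratkowsky coefficients are not printed in the
  source material, so the calibration is recorded in the configuration and
  overridable. Per-reaction coefficients follow the reference flux share,
  \(b_j = b_{Glc}\, v_j(30°C)/v_{consumption}(30°C)\) (`compute_b()`).
* **"Two times less sensitive".** The phrase fixes no unique transformation
  of \(R(T)\). The package halves the Ratkowsky *exponent* (2 → 1), which
  halves \(d\ln R/dT\) at every temperature and keeps \(R(T_0) = 1\).
  Alternatives (rescaled \(T_{min}\), halved \(\Delta R\)) would also be
  expressible via `apply_sensitivity()` but are not defaults.
* **Equilibrium constants.** Van't Hoff propagation
  \(\ln(K_{eq,2}/K_{eq,1}) = \Delta H^0_r/R\,(1/T_1 - 1/T_2)\) is available
  (`keq_at_temperature()`, anchored on the packaged 12/30 °C pairs), but OFF
  by default: the recomputed fold changes between 12 and 30 °C are all below
  two-fold, a minor effect against the six-fold capacity change. The printed
  fold-change column of the anchor table mixes direction conventions; the
  packaged table stores the direction per reaction explicitly.
* **Profiles.** Constant (batch), linear down-and-back shift at 0.2 °C/min
  (18 °C per leg, 1.5 h, 3 h total), and the circadian sinoid
  \(21 + 9\sin(\pi/12\,t + 1.57)\) (24-h period, 12–30 °C range). The phase
  constant 1.57 is taken literally as printed, not as \(\pi/2\); the
  difference is under 0.003 °C.

## Reactor embedding

Extracellular amounts follow
\(dN_i/dt = q_i N_X + F_{in} C_{i,in} - F_{out} C_{i,out}\), with ethanol
additionally losing \(k_{evap} N_{EtOH}\) (default 0.008 h\(^{-1}\), a
configuration value — the source defers the constant to earlier work — and
disabled for carbon audits). Intracellular rates convert to biomass-specific
rates through the cytosol volume (2 mL/gDW default), and growth is coupled as
\(\mu = Y_{xs}\, q_s\) with \(Y_{xs} = 0.09\) g/g. Because growth withdraws
carbon, an anabolic drain at G6P — sized from \(Y_{xs}\) and the biomass
composition CH\(_{1.8}\)O\(_{0.5}\)N\(_{0.2}\) (24.6 g/C-mol) — is part of
the reactor derivative and of every algebraic steady state
(`reactor_sink()`); with it the closed-batch carbon balance closes
identically up to integration error. Growth dilution of intracellular pools
(\(\mu c\), at most 0.03 h\(^{-1}\) against pool turnovers of minutes) is
neglected. CO2 is vented: it carries no dissolved balance, only a cumulative
off-gas integral, whose rate is the measured proxy for glycolytic flux.

Chemostat runs are initialized at the algebraic steady state of the constant
starting temperature: at \(\mu = D\) the biomass-specific uptake is pinned at
\(q_s = D/Y_{xs}\), so the residual glucose is found by a one-dimensional
root search over the clamped substrate and biomass follows from the glucose
balance. This replaces integrating five residence times and is exact. Batch
runs start at the feed glucose with pools equilibrated to glucose excess
(cells adapted by previous cycles) and stop at a 0.02 mM glucose floor, where
the depleted system becomes needlessly stiff. Sequential-batch cultivation is
emulated as one batch per temperature sampled at three exponential-phase
points (glucose at 80/55/30 % of the charge) — the adaptation cycles of the
real protocol have no counterpart in a model without acclimation state.

## The collapse statistic and localization

Measurements are analysed in two strata. In the glucose-*limited* stratum a
pooled monotone (isotonic) reference curve \(\hat g\) of level versus
\(\log_{10}\) glucose is fitted over all regimes — mirroring how the
experiments overlay all regimes on one axis pair — and each regime is scored
by its median relative residual; a regime is deviant when its score exceeds
\(\theta\). Residual temperature dependence is tested by the rank correlation
of residuals with temperature, with a permutation p-value (1000 label
permutations, seeded; rank-based to avoid assuming a functional form). In the
glucose-*excess* stratum the reference relation degenerates to a point, so
the score is the largest deviation of the per-temperature median from the
30 °C level. The default \(\theta = 0.15\), raised to twice the replicate CV
when that is larger, encodes that measurement error — not the model — limits
discrimination. Localization applies the boundary rule to the excess-stratum
flags ordered along the pathway: all-deviant upstream of one reaction,
all-clean downstream, names that reaction; an all-clean or inconsistent
pattern names none.

## The synthetic-measurement generator

`synthesize_measurements()` emulates the *structure* of the experimental data:
duplicate samples at the scheduled times, two independent cultures (re-
simulations with initial biomass jittered by ±5 %), multiplicative lognormal
noise with mean exactly 1, replicate means with standard errors, and glucose
censored at half the limit of quantification (0.01 mM) below it. The default
CV of 0.10 is an artifact decision chosen to be comparable to the visible
error bars of the source figures — true replicate CVs are not printed
anywhere. What the generator does **not** emulate: instrument-level effects
(ion suppression, calibration drift), quenching and extraction artefacts,
biological adaptation between sequential batches, and any hierarchical
(enzyme-level) regulation. Passing tests therefore show that the *analysis
pipeline* discriminates the two hypotheses at the assumed noise level, not
that real measurements would.

## Numerical choices

* Steady states: damped Newton in log-concentration space (iterates stay
  positive) with numerical Jacobian, absolute tolerance \(10^{-9}\) mM/min on
  \(\max|Nv|\); on failure, stiff ODE relaxation to a plateau followed by a
  Newton polish, with the successful path reported. All-zero capacities
  return the trivial zero-flux state with a warning rather than an error.
* Dynamics: `deSolve::lsoda`, rtol \(10^{-8}\), atol \(10^{-10}\) mM.
  Negative states are never clamped inside rate evaluation; reversible rates
  are written in the expanded `forward - reverse` form so that zero substrate
  gives a finite back-rate instead of an indeterminate mass-action ratio.
* Problem sizes in the tests and scripts — 50-seed recovery loops, 500 null
  tables for the permutation-size check, 600-point batch grids, two circadian
  cycles of adaptation before two sampled cycles — are the package's choices
  balancing statistical resolution against determinism of the suite.

## Known limitations

The reduced model's absolute concentrations and yields are calibrated, not
fitted; only the structural claims (homeostasis under shared scaling,
upstream-limited deviation, collapse across regimes) are quantitative
targets. Cofactor dynamics, storage metabolism, the allosteric PFK of full
models, succinate, and gas-phase dynamics are out of scope. The localization
rule assumes a single perturbed enzyme on a linear backbone; simultaneous
perturbations of several enzymes are not supported (and destabilize this
class of models). Temperatures above the 30 °C reference are outside the
sub-optimal Ratkowsky branch and are rejected only by the
\(T \ge T_{min}\) guard, so users should stay within 12–30 °C.
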