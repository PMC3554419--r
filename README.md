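# glycotherm

Kinetic modelling of how anaerobic *Saccharomyces cerevisiae* glycolysis
responds to temperature dynamics, for systems biologists and fermentation
scientists who want to test **whether all enzymes of a pathway share one
catalytic-capacity–temperature relationship** using only metabolite and
residual-substrate measurements — no in-vitro kinetics.

## The model in brief

Each reaction rate has the form

    v_j = e_j · k_cat,j · f_j(K_S, K_P, K_E, S, P, E) · (1 − Γ_j / K_eq,j)

with only the capacity `e·k_cat` temperature dependent, scaled by a
normalized Ratkowsky function

    R(T) = ((T − T_min) / (T_0 − T_min))²,   T_0 = 30 °C,  T_min = −0.42 °C,

so that `R(30)/R(12) ≈ 6`, the observed batch flux ratio. At steady state
`N·v = 0`; if every enzyme shares `R(T)`, the scale factors out: metabolite
concentrations are a temperature-independent function of extracellular
glucose and all fluxes scale by `R(T)` (homeostasis). One enzyme with a
deviating temperature sensitivity breaks this — but only for metabolites
upstream of itself, which makes the deviant enzyme localizable.

The package provides:

* a reduced 9-reaction glycolysis network (`reduced_glycolysis()`, YAML
  model file in `inst/models/`), plus structural SBML import;
* Ratkowsky scaling, per-enzyme sensitivity perturbations, Van't Hoff
  propagation of equilibrium constants anchored on 12/30 °C pairs;
* bioreactor mass balances (batch and chemostat at D = 0.03 h⁻¹, 25 g/L
  glucose feed, biomass growth, ethanol evaporation, CO₂ off-gas);
* three temperature regimes — sequential batches at
  12/18/24/30 °C, 3-h linear shifts at 0.2 °C/min, circadian sinoid
  `21 + 9·sin(π/12·t + 1.57)`;
* the collapse statistic (isotonic metabolite-vs-glucose reference curve,
  per-regime deviation scores, permutation test for residual temperature
  dependence) and the pathway-ordered localization rule;
* a synthetic-measurement generator (duplicate samples, independent
  cultures, lognormal noise, glucose LOQ censoring).

## Worked example

Perturb the lumped lower-glycolysis step (TDHL) to be twice less
temperature-sensitive, simulate glucose-excess batches at 12–30 °C, add 10 %
measurement noise, and ask the analysis which enzyme deviates:

```r
library(glycotherm)
model <- reduced_glycolysis()

# capacity scale shared by all enzymes, normalized to 30 degC
rk <- ratkowsky_params()
round(ratkowsky_scale(rk, c(12, 18, 24, 30)), 3)
#> [1] 0.167 0.367 0.644 1.000

# chemostat operating point at the reference cultivation conditions
cfg <- reactor_config("chemostat", dilution_rate = 0.03)
cs <- chemostat_steady_state(model, cfg, T = 30)
round(c(residual_glucose_mM = cs$glucose_mM,
        biomass_gdw_l = cs$biomass_gdw_l, mu = cs$mu), 4)
#> residual_glucose_mM       biomass_gdw_l                  mu
#>              0.0114              2.2498              0.0300

# round-1 scenario: TDHL twice less temperature-sensitive, batch regime
sbr <- run_scenario(model, scenario_spec("SBR", "single_enzyme_different",
                                         sensitivity = sensitivity_spec("TDHL", 2)))
tab <- synthesize_measurements(list(sbr), noise_model(cv = 0.10, seed = 1))
report <- analyze_collapse(tab, pathway = model, replicate_cv = 0.10, n_perm = 0)
round(setNames(report$scores$excess_dev, report$scores$metabolite), 3)
#>   F6P   FBP   G6P   PEP   PYR  TRIO
#> 0.527 0.719 0.557 0.098 0.082 0.691
report$localization$candidate
#> [1] "TDHL"
```

Reading the numbers: the capacity scale drops six-fold from 30 to 12 °C; the
chemostat at dilution rate 0.03 h⁻¹ leaves ~0.011 mM residual glucose and
grows at exactly `mu = D`. Under the perturbation, the glucose-excess levels
of G6P, F6P, FBP and the triose pool deviate by 53–72 % from their 30 °C
reference across the batch temperatures, while PEP and pyruvate — downstream
of TDHL — stay within noise. The boundary rule therefore names TDHL.

## Analysis workflow

The `analysis/` scripts run the full in-silico program and write tidy
tables under `results/`:

1. `01_temperature_model.R` — Ratkowsky scale tables, Van't Hoff enthalpies
   and recomputed Keq fold changes;
2. `02_steady_states.R` — homeostasis under uniform scaling, chemostat
   operating points over 12–30 °C;
3. `03_scenarios.R` — both simulation rounds over batch / linear-shift /
   circadian regimes (the combined normalized table `figure2_table.csv`),
   plus the numerical flux-temperature sensitivity check;
4. `04_collapse.R` — noisy synthetic measurements, collapse scores,
   localization, and recovery rates over 50 noise seeds.

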