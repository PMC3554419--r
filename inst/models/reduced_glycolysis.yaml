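# Reduced anaerobic yeast glycolysis backbone.
# Concentrations in mM (intracellular per cytosol volume), capacities in
# mM/min at the 30 degC reference. Cofactors (ATP/ADP, NAD/NADH) are treated
# as buffered and omitted; lower glycolysis TDH..ENO is lumped into TDHL and
# pyruvate decarboxylase + alcohol dehydrogenase into PDC. The irreversible
# backbone steps carry competitive product inhibition (effector_constants) so
# that a downstream capacity perturbation propagates upstream, as it does
# through the reversible/allosteric couplings of full glycolysis models.
# Capacities are calibrated so that an anaerobic glucose-limited chemostat at
# dilution rate 0.03 1/h is feasible over 12-30 degC and the glucose-excess
# batch has a unique stable steady state at 30 degC.
name: reduced_glycolysis
species:
- id: GLCo
  compartment: extracellular
- id: GLCi
  compartment: intracellular
- id: G6P
  compartment: intracellular
- id: F6P
  compartment: intracellular
- id: FBP
  compartment: intracellular
- id: TRIO
  compartment: intracellular
- id: PEP
  compartment: intracellular
- id: PYR
  compartment: intracellular
- id: ETOH
  compartment: extracellular
- id: GLYC
  compartment: extracellular
- id: CO2
  compartment: extracellular
reactions:
- id: GLT
  pathway_index: 1
  stoichiometry: {GLCo: -1.0, GLCi: 1.0}
  rate_law:
    kind: facilitated_diffusion
    vmax_ref: 130.0
    km_substrates: {GLCo: 0.05}
    km_products: {GLCi: 0.05}
- id: HXK
  pathway_index: 2
  stoichiometry: {GLCi: -1.0, G6P: 1.0}
  rate_law:
    kind: irreversible_mm
    vmax_ref: 350.0
    km_substrates: {GLCi: 0.08}
- id: PGI
  pathway_index: 3
  stoichiometry: {G6P: -1.0, F6P: 1.0}
  rate_law:
    kind: reversible_mm
    vmax_ref: 2000.0
    km_substrates: {G6P: 1.4}
    km_products: {F6P: 0.3}
    keq_ref: 0.29
- id: PFK
  pathway_index: 4
  stoichiometry: {F6P: -1.0, FBP: 1.0}
  rate_law:
    kind: irreversible_mm
    vmax_ref: 300.0
    km_substrates: {F6P: 0.1}
    effector_constants: {FBP: 0.3}
- id: FBA
  pathway_index: 5
  stoichiometry: {FBP: -1.0, TRIO: 2.0}
  rate_law:
    kind: reversible_mm
    vmax_ref: 300.0
    km_substrates: {FBP: 0.3}
    km_products: {TRIO: 1.0}
    keq_ref: 1.4
- id: TDHL
  pathway_index: 6
  stoichiometry: {TRIO: -1.0, PEP: 1.0}
  rate_law:
    kind: irreversible_mm
    vmax_ref: 600.0
    km_substrates: {TRIO: 0.4}
    effector_constants: {PEP: 0.2}
- id: PYK
  pathway_index: 7
  stoichiometry: {PEP: -1.0, PYR: 1.0}
  rate_law:
    kind: irreversible_mm
    vmax_ref: 600.0
    km_substrates: {PEP: 0.2}
    effector_constants: {PYR: 0.55}
- id: PDC
  pathway_index: 8
  stoichiometry: {PYR: -1.0, ETOH: 1.0, CO2: 1.0}
  rate_law:
    kind: irreversible_mm
    vmax_ref: 600.0
    km_substrates: {PYR: 2.0}
- id: GLYCB
  pathway_index: 9
  branch: true
  stoichiometry: {TRIO: -1.0, GLYC: 1.0}
  rate_law:
    kind: irreversible_mm
    vmax_ref: 5.0
    km_substrates: {TRIO: 10.0}
clamped: [GLCo, ETOH, GLYC, CO2]
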