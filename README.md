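# saxsolv

Structural–thermodynamic modelling of protein small-angle X-ray
scattering (SAXS) in water–cosolvent binary solvents.

## What it does, and for whom

For structural biologists and biophysicists studying how small
stabilizers (sugars, osmolytes, modified sugars) shift protein
oligomeric and unfolding equilibria, `saxsolv` turns a *batch* of
absolute-scale SAXS curves — recorded across protein concentration,
temperature and cosolvent concentration — into elementary
thermodynamic parameters, instead of fitting each curve in isolation.

The forward model for each curve is

    dΣ/dΩ(q) = n · P(q) · S_M(q)

* `n = c·N_A/M1` — nominal monomer number density, thermally corrected
  through the mean molar volume;
* `P(q) = Σ_j x_j α_j P_j(q)` — effective form factor of the state
  mixture. State populations `x_j` and first-shell water occupancies
  `φ_j` solve a coupled mass-action + Schellman-exchange system: the
  transition constants in water, `K_W1j` (with Debye–Hückel
  electrostatics and self-consistent counterion screening), are dressed
  by the solvent composition into effective constants
  `K_1j = K_W1j φ_1^{m_1} X_Wb^{m_j/α_j − m_1} / φ_j^{m_j/α_j}`, where
  the `m_j` are hydration-shell site counts. Preferential solvation
  (`K_exj`) sets `φ_j` and thereby the local-domain scattering length
  density of the two hydration shells;
* `S_M(q) = 1 + β(q)[S(q) − 1]` — measured structure factor: an
  effective one-component hard-sphere-double-Yukawa (DLVO repulsion +
  generic attraction of contact depth `J` and range `d`) treated with
  Percus–Yevick + random-phase approximation, coupled through
  `β(q) = |P⁽¹⁾(q)|²/P(q)`.

A batch is fitted by minimising `H = χ² + γL`: the average reduced
chi-square plus a neighbour-ratio regularization of the per-curve
`(J, d)`. Every elementary energy follows
`ΔG(T) = ΔG° + (ΔCp − ΔS°)(T − T°) − ΔCp·T·ln(T/T°)`.

Because the original experimental curves are not distributable, the
package ships a first-class synthetic-data generator and a seeded
parameter-recovery harness; state populations can also be mapped over
temperature × cosolvent concentration as a phase diagram
(`phaseDiagram()`).

## Worked example

Simulate the canonical 12-curve monomer–dimer batch (2 and 10 g/L ×
25/45/60 °C × 0/0.15 M cosolvent, 2 % noise) and re-fit the generating
thermodynamics from scratch:

```r
library(saxsolv)
scen <- defaultRecoveryScenario(seed = 1)
rec  <- recoveryExperiment(scen, seed = 1,
                           control = list(popSize = 16, maxGen = 25))
round(cbind(truth = rec$truth, estimate = rec$estimate,
            bias = rec$bias, se = rec$se), 4)
```

which prints (about two minutes on one CPU):

```
                 truth estimate    bias     se
transition.2.dG0 -11.0 -10.9983  0.0017 0.0243
transition.2.dS0 300.0 301.3999  1.3999 2.6852
exchange.1.dG0     1.5   1.4489 -0.0511 0.0269
exchange.2.dG0    -2.0  -2.1284 -0.1284 0.0704
```

Reading: the monomer→dimer reference free energy (kJ/mol) and entropy
(J/mol/K) and the two water–cosolvent exchange free energies (kJ/mol)
are recovered within small fractions of their values; `rec$chi2AtTruth`
(1.061 here, 1200 points) sits at the noise floor of 1, and the fitted
`χ²` (1.057) is at least as good — the estimator is consistent and the
noise model self-consistent.

Single pieces are exposed directly, e.g.

```r
phiFromExchange(2, 0.2)                    # 0.8889: shell water occupancy
pyStructureFactor(1e-9, R = 17, eta = 0.1) # 0.4556: PY compressibility limit
releasedWaters(c(404, 404), 753) / 2       # 27.5 waters per monomer on dimerisation
```

A thin CLI (`inst/scripts/saxsolv`) wraps the same functions:
`saxsolv hydrate --pdb file.pdb`, `saxsolv simulate --config default
--out dir`, `saxsolv fit --manifest m.tsv --config c.yaml`,
`saxsolv phasediagram --config c.yaml --c0 2`.

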