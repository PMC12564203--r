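---
title: "Kinetic modelling of PI3K/AKT-PI cycle crosstalk and GSK3β-targeted interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of PI3K/AKT-PI cycle crosstalk and GSK3β-targeted interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aktpi)
```

## The model

Insulin signalling through PI3K/AKT is the canonical route by which a cell
turns an extracellular insulin pulse into inactivation of glycogen synthase
kinase 3β (GSK3β): insulin binds its receptor, the activated receptor
recruits and phosphorylates IRS, phospho-IRS recruits PI3K, PI3K converts
PIP2 to PIP3, PIP3 activates AKT, and phospho-AKT (pAKT) phosphorylates
GSK3β into its inactive form pGSK3β. Because GSK3β overactivity is a shared
feature of bipolar disorder and type-2 diabetes, and because the
phosphatidylinositol (PI) second-messenger cycle both consumes and
regenerates PIP2, `aktpi` implements the two pathways as a single coupled
reaction network: the **crosstalk model** (28 reactions over 27 named
species) and, for comparison, a **PI3K/AKT-only reduction** that omits the
PI cycle, GPCR and PKC branches.

Every reaction follows one of three rate laws:

* irreversible mass action, $v = k_f \prod_i [X_i]^{\alpha_i}$;
* reversible mass action, $v = k_f \prod_i [X_i]^{\alpha_i} -
  k_b \prod_j [Y_j]^{\gamma_j}$;
* single-substrate Michaelis–Menten, $v = V_{max} S / (K_m + S)$, used
  once, for receptor internalization.

Concentrations are in nM and time in seconds; first-order constants are
s⁻¹, second-order constants nM⁻¹s⁻¹. The state derivative is assembled as
$\dot{x} = N\,v(x)$ with $N$ the net stoichiometry matrix. Degradation
steps ("Null" products in the source table) simply remove mass.

Two conventions ship for the enzymatic steps, because the tabulated
notation does not distinguish them:

* `catalyst_mode = "literal"` (default): every listed reactant is
  consumed, exactly as mass action reads.
* `catalyst_mode = "catalytic"`: the six mechanistically enzymatic
  reactants (PTP1B, the IRS–PI3K complex, PTEN, pAKT in the GSK3β
  phosphorylation step, active G protein, DAG in PKC activation) are
  regenerated on the product side, i.e. have net stoichiometry zero.

The literal reading is the default because it reproduces a characteristic
signature of the reference exposure tables: under direct GSK3β–inhibitor
binding, pAKT exposure *rises* while the AKT pool is untouched, which can
only happen if pAKT is consumed by the GSK3β phosphorylation step (binding
sequesters GSK3β, so less pAKT is spent). All scenario orderings checked by
the tests hold in either mode.

One species identification is worth noting: the tabulated GSK3β
phosphorylation step names a doubly-phosphorylated "ppAKT" that nothing
else produces; it is treated as an alias of pAKT (a distinct species would
be permanently zero and the cascade would dead-end). Likewise the PI→PIP
step is printed as reversible but with no reverse constant; it is encoded
with $k_b = 0$ and the reversibility flag retained.

## Interventions

Lithium's three proposed mechanisms, and the curcumin alternative, are
declarative transforms of `(network, init)`:

| scenario | effect |
|---|---|
| `control` | identity |
| `akt_modulation` | initial AKT × 1.30 |
| `pip2_modulation` | initial PIP2 × 0.63 |
| `gsk3b_binding` | lithium 1000 nM, Ki 1000 nM, reversible GSK3β binding |
| `total_effects` | all three combined |
| `curcumin` | curcumin 1000 nM, Ki 66.3 nM |

The binding reaction is ordinary reversible mass action,
GSK3β + inhibitor ⇌ complex. Equilibrium data constrain only the ratio
$K_i = k_{off}/k_{on}$, so kinetics are fixed by a reference dissociation
rate `koff_ref` (default 0.1 s⁻¹, giving an equilibration time of seconds,
far inside the default horizon); a sensitivity test over
`koff_ref ∈ {0.01, 0.1, 1}` bounds the induced spread in the pGSK3β
exposure ratio at under 15%, dominated by the slow-equilibration
transient at 0.01 s⁻¹. For curcumin only an IC50 is available; for a
competitive inhibitor in the low-substrate regime IC50 ≈ Ki, so Ki is
taken equal to 66.3 nM. The inhibitor is depletable — consumed into the
complex — which at dose ≫ target pool is indistinguishable from a clamped
inhibitor. PIP2 scaling applies to the initial value only; the PI-cycle
resynthesis reactions are untouched.

In the excess-inhibitor regime the bound fraction at equilibrium is
`dose/(dose + Ki)`: 0.500 for lithium (1000/1000 nM) and 0.938 for
curcumin (1000/66.3 nM) — the algebraic form of curcumin's stronger
binding, which the ODE route reproduces to within 0.5%.

## Outcome metrics

The primary outcome is **exposure**, the concentration–time integral in
nM·s over the horizon, computed by the composite trapezoid rule on the
stored output grid (not solver-internal quadrature) so that any saved
trajectory CSV yields identical numbers. The headline statistic is the
**phospho-percentage**, `100 × exposure(p-form) / exposure(base form)` —
the phosphorylated form relative to the *unphosphorylated* form, not to
the total pool. This convention was fixed by verifying it against every
self-consistent percentage/exposure triple of the reference comparison
tables (13 of 14 reproduce to two decimals; the remaining cell is
internally inconsistent with its own printed exposures and is excluded).
`scenario_report()` emits the standard comparison layout: one column per
scenario; rows for the inhibitor complex (when present), AKT, pAKT, pAKT%,
GSK3β, pGSK3β, pGSK3β%. Cells print rounded half-up to two decimals;
full precision is retained in the object and its CSV export.
`relative_activity()` (free target over the initial total pool) is
provided for activity-style readouts.

## Numerical choices

* Integration uses the adaptive, stiff-capable `lsoda` solver; if its
  stiff/nonstiff switching heuristic stalls (it occasionally does in the
  strongly stiff growth phase discussed below), the run is retried once
  with the pure-BDF stiff integrator at the same tolerances. Both
  attempts are deterministic; two identical calls produce bit-identical
  trajectories.
* Default tolerances are `rel_tol = 1e-8`, `abs_tol = 1e-10` nM — tight
  because exposure integrals amplify drift; halving them moves reported
  exposures by well under 0.1%. Internally the solver is run at
  `abs_tol/100` so that the trajectory contract (no concentration below
  `-abs_tol`) holds with margin; the bound is asserted, not clipped, so a
  genuinely misbehaving integration fails loudly rather than being
  masked.
* The default horizon is 600 s with a 0.1 s output grid, covering the
  crosstalk model's late transient structure with room to spare; both are
  ordinary settings knobs. Ensemble and scenario-comparison runs in the
  tests and the acceptance script use a 0.5 s grid — exposure ratios are
  insensitive to the reporting grid (a 10× refinement moves exposures by
  under 0.1%) and the coarser grid keeps the suite quick.
* Insulin is delivered as an initial bolus; the reaction table has no
  zeroth-order source, so there is no sustained input term.

## The synthetic baseline, and what the tests do and do not show

The published initial concentrations for this network live in
supplementary material that the package does not reproduce; the main-text
constraint is only that baseline protein concentrations span
0.0009–300 nM. `default_initial_conditions()` therefore ships an explicit
synthetic guess with the right *structure*: substrate pools (IR, IRS,
AKT, GSK3β, PIP2, PI, G, PKC and the phosphatases) at 10–300 nM, a
100 nM insulin bolus, and every complex, intermediate and phospho-form at
zero pre-stimulus. The values are frozen in a version-pinned CSV
(`inst/extdata/synthetic_baseline_initial_conditions.csv`) and are
deliberately labelled synthetic.

Consequences, stated plainly:

* **Absolute exposures are not comparable** to the reference tables —
  those require the original initial concentrations and horizon. The
  package does not fit initial conditions to reproduce them, by design.
  When users supply their own table (`load_initial_conditions()` accepts
  the alias spellings) and horizon, `scenario_report()` produces the same
  layout for side-by-side comparison.
* **Orderings are the tested claims**: direct GSK3β binding raises
  pGSK3β% above control, curcumin out-binds lithium at equal dose, and
  these hold on the default baseline and on ≥ 90% of a 50-member
  ensemble whose nonzero initial values and rate constants carry
  independent lognormal noise at 20% coefficient of variation (lognormal
  for positivity; unit-mean multipliers; explicit seeds, never global
  RNG state).

One structural property of the published reaction set deserves emphasis:
PIP2 hydrolysis produces *both* IP3 and DAG, and both are independently
recycled back to PIP2 (IP3 via inositol → PI → PIP; DAG directly). Each
pass through the cycle therefore multiplies PI-cycle mass by more than
one, and the PI-cycle pools grow exponentially (slow doubling, rate
≈ 0.05 s⁻¹ on the default baseline). This is a faithful rendering of the
tabulated reactions, not an implementation artifact: the model is usable
for finite-horizon exposure comparison, but its PI-cycle species have no
steady state, which is a known limitation of the reaction set and one
reason absolute PI-cycle exposures should not be over-interpreted. The
AKT/GSK3β readouts that the reports are built from remain bounded over
the default horizon.

## Problem sizes used by the tests

The test suite and acceptance script run the full crosstalk model at a
600 s horizon (0.5 s reporting grid) for scenario comparisons, 300 s for
tolerance/grid-stability checks, the 50-member cv = 0.2 ensemble for the
robustness fraction, and small hand-written networks (≤ 3 reactions)
for the closed-form and RK4-oracle checks, where the oracle is a
self-contained fixed-step stepper with hand-coded derivatives.
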