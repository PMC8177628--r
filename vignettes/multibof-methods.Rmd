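---
title: "Multi-biomass flux balance analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-biomass flux balance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multibof)
```

## The model and its assumptions

Constraint-based analysis treats metabolism as a flux vector $v$ over the
stoichiometric matrix $S$ at steady state, $S v = 0$, with bounds
$v^{lb} \le v \le v^{ub}$, and predicts phenotype by maximising flux
through a biomass objective function (BOF)

$$\alpha_1 BC_1 + \dots + \alpha_m BC_m \rightarrow
  \alpha_{m+1} BC_{m+1} + \dots + \alpha_n BC_n ,$$

whose consumed-side coefficients $\alpha_i$ (mmol gCDW⁻¹) are scaled so
that one unit of flux drains exactly 1 g of precursors per gram cell dry
weight — the flux is then the specific growth rate in h⁻¹. `multibof`
starts from two observations: (i) the coefficients $\alpha_i$ depend on
the nutrient environment, and (ii) similar environments produce similar
compositions. Three methods operationalise this:

* **BTW** attaches every available composition as its own irreversible
  pseudo-reaction and puts coefficient 1 on each in the FBA objective.
  The LP then picks the growth-maximal mixture. Two consequences are
  used as test invariants: with a single BOF the method *is* FBA, and
  the BTW optimum dominates every single-BOF optimum (any single-BOF
  solution is feasible for the BTW program).
* **HIP** assumes a locally affine map from the $n$-dimensional uptake
  space to each coefficient: $\alpha_i(u) = a_i + b_i^\top u$. With
  exactly $n+1$ affinely independent measurements the plane is solved
  exactly; with more, each coefficient gets a least-squares plane
  (`fit_mode` is chosen by this rule, never silently). Affine maps
  extrapolate below zero past the line from a positive coefficient to a
  zero; a negative $\alpha_i$ would mean growth-coupled *infusion* of a
  precursor, so raw negatives are replaced by `clamp_fraction` (default
  0.01) times the reference composition's coefficient — essential
  compounds stay present in trace amounts, compounds absent from the
  reference stay absent.
* **HIP-I** iterates HIP to self-consistency. The starting point $u$ is
  a vector of *upper bounds* on the mapped uptakes (fixing uptakes would
  contradict the idea that the optimum may not use them). $B_0 =
  \mathrm{hip}(u)$ is maximised under bounds $u$; the optimal uptake
  magnitudes $v_1$ re-query the map, and so on until
  $\lVert v_k - v_{k-1}\rVert_\infty \le \varepsilon$ (the first test is
  against $u$ itself, so a fixed point terminates at iteration 0 and
  equals HIP) or $k_{max}$ is exhausted, which is reported as
  `converged = FALSE`, never as an error.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| solver tolerance | 1e-9 | – | feasibility/optimality tolerance of the LP backend; loose tolerances produce spurious acetate/RQ differences between methods |
| `eps` (HIP-I) | 1e-3 | mmol gCDW⁻¹ h⁻¹ | convergence threshold on the uptake vector, ∞-norm over the map's dimensions only |
| `k_max` | 100 | iterations | HIP-I budget; toy trajectories converge in ≤ 5 |
| `clamp_fraction` | 0.01 | – | fraction of the reference coefficient substituted for negative extrapolations |
| `unconstrained_value` | 1000 | mmol gCDW⁻¹ h⁻¹ | magnitude to which non-limiting medium uptakes are opened |
| relative-acetate `cap` | 10 | – | ratio cap in `relative_grid`, guarding against division by near-zero reference secretion |
| essentiality threshold | 0.01 | – | grRatio below which a knockout is called essential (growth reduced ≥ 99%) |

"Fixing at the optimum" in the lexicographic stages uses equality bounds
widened by a relative slack of 1e-9 so that solver round-off in the first
stage cannot render the second infeasible.

## Environment semantics

An `environment_point` names exchange reactions and nonnegative uptake
magnitudes. In `fixed` mode the exchange flux is pinned to −u (phase
planes of growth/acetate/RQ); in `upper_bound` mode the flux is bounded
to [−u, 0] (required by HIP-I, where the solution may sit strictly inside
the bound). All *other* exchanges that admit uptake in the input model —
its distributed medium — are opened to the unconstrained value; secretion
bounds are never touched. Uptake is a negative exchange flux throughout;
user-facing values are positive magnitudes.

## The three-level respiratory quotient

RQ compares CO₂ secretion to O₂ uptake. A plain FBA optimum leaves both
fluxes badly underdetermined (alternate optima), so RQ is computed on a
three-level solution: maximise growth; fix it and maximise acetate
secretion; fix both and minimise total absolute flux on the irreversible
split of the network (parsimonious FBA). Zero O₂ uptake at that final
solution raises a dedicated `multibof_undefined_rq` condition — distinct
from infeasibility, because "the model grows fermentatively" and "the
model cannot grow" are different findings.

## What the toy generator emulates — and what it does not

`make_toy_model()` builds a ~20-reaction aerobic heterotroph: glucose,
ammonium, O₂, CO₂, acetate and alanine exchanges; full oxidation
(glc + 6 O₂ → 6 CO₂ + 26 ATP) against an overflow branch
(glc → 2 ac + 2 CO₂ + 2 ATP); protein/carbohydrate/lipid synthesis gated
by GPRs including one isoenzyme pair; and two unit-mass biomass
compositions differing in group make-up (A protein-rich ≈ the
nutrient-rich composition, B carbohydrate-rich ≈ nitrogen limitation).
Two ingredients were added deliberately:

* **ATPM**, a non-growth ATP demand. Without an ATP sink, excess carbon
  under forced uptakes cannot be catabolised and fixed-mode environments
  become infeasible for trivial reasons. Every genome-scale model carries
  the same reaction (maintenance).
* **Alanine overflow** (0.5 glc + nh4 → ala, secreted). Genome-scale
  models dispose of excess nitrogen through carbon-bearing byproducts;
  the carbon price matters, because it makes taking *unneeded* nitrogen
  strictly suboptimal. That is what gives HIP-I a well-defined,
  solver-independent uptake read-out on the toy: the raw FBA vertex
  leaves nitrogen uptake strictly below a wasteful bound.

The toy reproduces the qualitative phenomenology the methods were built
for — overflow metabolism (RQ > 1 under O₂ caps), BTW dominance,
nitrogen-wasting HIP-I trajectories contracting onto the stable boundary
— but not genome-scale properties: no redox/proton bookkeeping, no
elemental balancing of the biosynthesis lumps, a handful of genes, and
growth rates (~1–3 h⁻¹ at generous uptakes) chosen for LP legibility
rather than physiology. A green toy test therefore establishes the
*algorithmic* contracts (interpolation identities, fixed-point behaviour,
lexicographic ordering, binning semantics), not numerical agreement with
any real organism. The generator is bitwise deterministic in
`(spec, seed)`; the seed only drives the optional lognormal jitter on
BOF coefficients (`jitter = 0` by default, so the default toy is a fixed,
stated world).

## Artificial composition pipeline

`build_artificial_bofs()` reproduces the standard construction of a
three-environment composition set from a model's two source biomass
reactions: arithmetic mean per compound over the union (a compound
missing from one source counts as zero, hence is halved), removal of
explicitly dropped compounds, normalisation to 1 g/gCDW (this is the
unlimited-environment composition), then per-group scaling for the
nitrogen- and carbon-limited columns of the scaling table, each
re-normalised. `default_scaling_table()` carries the nine canonical
groups (DNA, RNA, Protein, Lipid, Carbohydrates, Energy, Co-factors,
Ions, Others) with nitrogen limitation shrinking protein (×0.2) and
inflating storage (lipid ×20, carbohydrate ×15), carbon limitation doing
the reverse, and the three environment coordinates (18, 8.5), (13.5,
1.5), (1.5, 0.68) mmol gCDW⁻¹ h⁻¹ attached per column.

Mass normalisation sums over **consumed** entries only, including
energy-currency compounds — the literal reading of the 1 g convention.
Users wanting macromolecule-only normalisation can pass an explicit
hydrolysis set via `exclude_compounds`; the default stays literal.
Produced-side coefficients are scaled by the same factor during
normalisation so the pseudo-reaction stays internally balanced.

## Numerical choices and degenerate inputs

* The LP backend is a dense two-phase bounded-variable simplex written
  for this package (the deployment environment offers no R LP library).
  Dantzig pricing switches to Bland's rule after 500 iterations, so the
  heavily degenerate flux cones cannot cycle. It is validated against an
  independent exhaustive basic-solution enumeration oracle in the test
  suite.
* Alternate optima: `solve_fba` returns whatever vertex the simplex
  reports. Operations that need determinism must use the lexicographic
  entry points (`max_secretion_at_optimal_growth`, `pfba_minimize`).
  HIP-I deliberately uses the raw vertex for its uptake read-out; a
  `deterministic_uptake` flag substitutes a growth-then-minimal-uptake
  lexicographic read-out and is off by default.
* `hip_bof` re-normalises after clamping (clamping perturbs the mass);
  at measurement points no clamp fires and the map reproduces the
  measured coefficients to 1e-9, so normalisation is a no-op there.
* Exactly-boundary growth ratios follow the printed interval semantics:
  grRatio = 0.01 is *not* essential; experimental score −3 is
  intermediate; ratios marginally above 1 from solver noise are clipped
  to 1 before binning. Infeasible mutant LPs score grRatio 0, the
  standard deletion-screen convention.
* 0/0 ratios in `relative_grid` become 1; a positive phenotype over a
  zero reference becomes the `undefined_positive` sentinel (rendered
  white in the field's heat maps) rather than Inf; only the acetate
  ratio is capped (default 10).

## Known limitations

* The simplex is dense and intended for toy-to-medium models; a
  genome-scale model (thousands of reactions) wants a sparse
  revised-simplex or an external solver behind the same `lp_solve`
  contract.
* HIP is strictly affine; step-wise or saturating composition responses
  are out of scope by design, as are many-to-one environment↔composition
  maps.
* The knockout screen deletes single genes only and evaluates GPRs
  boolean-exactly; no enzyme abundance or regulation.
* SBML support covers the L3-FBC subset the field's models actually use
  (species, compartments, parameters-as-bounds, gene-product
  associations, flux objectives); exotic constructs (initial assignments,
  rules) are ignored.
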