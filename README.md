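# multibof

Flux balance analysis (FBA) with environment-dependent biomass objective
functions, in R.

## The problem

A genome-scale metabolic model predicts phenotypes by maximising flux
through a biomass objective function (BOF) — a pseudo-reaction draining
precursors (protein, RNA, lipid, carbohydrate, ATP, ...) in the
proportions that make up 1 g of cell dry weight, so that its flux is the
specific growth rate in h⁻¹. In reality that composition is not fixed: a
nitrogen-starved cell carries less protein and more storage carbohydrate
than the same cell in rich medium. When several biomass compositions have
been measured under different nutrient conditions, the modeller needs a
principled way to use all of them. `multibof` implements three such
methods on top of the standard FBA linear program

```
max  Σ_j c_j v_j      s.t.   Σ_j s_ij v_j = 0  ∀i,    v_j^lb ≤ v_j ≤ v_j^ub,
```

* **BTW** (Biomass Tradeoff Weighting): every available BOF is attached as
  its own irreversible pseudo-reaction and all of them get objective
  coefficient c_j = 1; the LP distributes flux among them. With one BOF it
  reduces to ordinary FBA, and its optimum always dominates every
  single-BOF optimum.
* **HIP** (plane interpolation): each biomass coefficient αᵢ is an affine
  function of the nutrient-uptake coordinates (glucose, ammonium, ...),
  fit through the measured (environment, composition) points — exactly
  through n+1 points in n dimensions, least squares with more. Negative
  extrapolations are clamped to 1% of a reference coefficient and the
  result is re-normalised so the consumed mass is 1 g/gCDW.
* **HIP-I**: the fixed-point iteration of HIP. Starting from upper bounds
  u on the mapped uptakes, the FBA optimum's uptake vector re-queries the
  map for a new composition until |v_k − v_{k−1}|∞ ≤ ε (default 10⁻³,
  at most k_max = 100 iterations).

Around these sit the supporting machinery: SBML L3-FBC/COBRA-JSON model
I/O, BOF construction (merging, group scaling, unit-mass normalisation),
lexicographic acetate maximisation, parsimonious FBA, the respiratory
quotient RQ = v(CO₂)/v(O₂), 2-D phenotype phase planes, single-gene
knockout screens with growth-ratio binning, and an angle-based similarity
score against experimental essentiality data. An internal dense simplex
solver makes the package self-contained (no external LP dependency).

## Worked example

Everything below runs on the built-in deterministic toy model — a small
aerobic heterotroph with glucose/ammonium/O₂ uptake, respiration vs
acetate overflow, and two biomass compositions (A protein-rich, B
carbohydrate-rich):

```r
library(multibof)
m    <- make_toy_model()
bofs <- toy_compositions(m)
base <- m
base$reactions[c("BIOMASS_A", "BIOMASS_B")] <- NULL
base$objective <- numeric()

env <- environment_point(c(EX_glc_e = 6, EX_nh4_e = 4),
                         mode = "upper_bound")

# single-BOF FBA vs BTW
solve_fba(apply_environment(attach_bof(base, bofs$A, "BOF"), env), c(BOF = 1))
solve_btw(build_btw(base, bofs), env)

# HIP: fit the affine map through three measured compositions
ms <- measurement_set(list(
  bof_measurement(c(EX_glc_e = 18,   EX_nh4_e = 8.5),  bofs$A),
  bof_measurement(c(EX_glc_e = 13.5, EX_nh4_e = 1.5),  bofs$B),
  bof_measurement(c(EX_glc_e = 1.5,  EX_nh4_e = 0.68),
                  mean_bofs(bofs$A, bofs$B))),
  c("EX_glc_e", "EX_nh4_e"))
map <- fit_affine_map(ms, reference = bofs$A)
hip_solve(base, map, env)

# HIP-I from a nitrogen-wasting start
hip_i_solve(base, map,
            environment_point(c(EX_glc_e = 4, EX_nh4_e = 20),
                              mode = "upper_bound"))

# similarity of a model tally against an experimental tally
similarity_angle(c(237, 8, 1054), c(226, 60, 1013))
```

Output (abridged):

```
single-BOF growth: A 1.3177, B 2.0794 h-1
BTW growth 2.4949, split A 0.9767 / B 1.5182
HIP growth at (6, 4): 1.4950 h-1
<hip_i_result> converged after 5 iteration(s); growth 2.6278859
     EX_glc_e EX_nh4_e
[1,]        4  13.5655
...
[6,]        4  12.8397
similarity angle: 0.0504 rad
```

Reading this: under joint C/N limitation the BTW optimum (2.49 h⁻¹)
strictly exceeds both single-BOF optima because the two compositions
spend carbon and nitrogen in different ratios, so a mixture exhausts both
budgets. HIP instead *commits* to the interpolated composition for
(6, 4), which grows slower — the same ordering the methods show on the
genome scale. The HIP-I trajectory starts at a wasteful nitrogen bound of
20 and contracts monotonically onto the self-consistent uptake 12.84; the
angle 0.0504 rad is the worked similarity example between a computational
(essential, intermediate, no-effect) = (237, 8, 1054) tally and the
experimental minimal-medium tally (226, 60, 1013).

Phase planes and knockout screens follow the same pattern:

```r
grid <- scan_phase_plane(base, map, seq(0, 18, 2), seq(0, 8.5, 1),
                         mode = "upper_bound")         # HIP per cell
ko   <- single_gene_deletion(base, bofs$A, env)        # grRatio per gene
bin_ratios(ko); three_group_vector(ko)
```

A command-line wrapper is installed at `inst/cli/multibof`
(`Rscript multibof <subcommand> --config cfg.json ...`, subcommands
`make-toy`, `build-bofs`, `fba`, `btw`, `hip`, `hip-i`, `rq`,
`phase-plane`, `knockout`, `similarity`).

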