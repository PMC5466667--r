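---
title: "Methods: a semi-empirical protocell model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a semi-empirical protocell model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protocell)
```

# The model

## Proto-metabolic networks

Two minimal reaction networks stand in for a primitive metabolism.
Both feed on energy-rich nutrients (A, B, C, D) taken up passively
from a non-limiting environment, and both are built from
cross-catalytic condensation cycles whose catalysts are themselves
network products — the self-production motif of metabolism–repair
organisation.

* **PM1** (heterotrophic): `R1: A + B -> AB + w` (catalysed by ACD)
  and `R2: A + C + D -> ACD + 2w` (catalysed by AB), with decays
  `AB -> 2w` and `ACD -> acd`.
* **PM2** (autotrophic): ACD is assembled in two steps through the
  intermediate AC (`A + C -> AC` under ACD catalysis,
  `AC + D -> ACD` under AB catalysis), with an additional decay
  `AC -> 2w`.

Every condensation releases one permeable leaving group `w` per bond
formed. The decay end-product `acd` is completely impermeable and
osmotically trapped: it is the volume-growth driver. All kinetics are
irreversible mass action; a catalyst enters its rate law linearly and
appears on neither side of the reaction.

The precise stoichiometry of such minimal proto-metabolisms is a
modelling choice, not a measured fact; the topology above follows the
metabolism-repair lineage of these networks, and the data model
(`species_spec()`, `reaction_spec()`, `network_model()`) is fully
declarative so an alternative scheme can be swapped in without code
changes. Rate-constant defaults are package-owned
(`pm_default_rates()`); they were chosen so the encapsulated networks
reach non-trivial steady states on an hours-to-days timescale at the
default environment (20 mol/m³ per nutrient, 100 mol/m³ total outer
osmolarity — the assay buffer).

A moiety matrix (one primitive moiety per nutrient letter) provides
the conservation oracle: condensations conserve every moiety exactly
(`w` carries none — the leaving-group reading), decays are the only
dissipative steps, and `closed_variant()` reroutes them
(AB → A + B, AC → A + C) to build a fully conservative network for
the conservation tests.

## Compartment physics

The membrane is a topologically closed bilayer holding `N_l`
primitive lipids (head area `alpha_l` = 0.2 nm²) and `N_L`
synthesised lipids (`alpha_L` = 0.6 nm²; 0.4 nm² describes the
mono-acyl derivative instead), two leaflets sharing the lipids:
`S_mu = (N_l a_l + N_L a_L) / 2`, bilayer thickness 3 nm.

Water relaxes osmotic differences much faster than any chemistry
here, so volume is an algebraic projection, not a dynamical variable:
after every reaction, transport or membrane event,
`V_in = sum(N_i) / (N_A * C_out)` over the osmotically active aqueous
species (all of them; membrane lipids excluded). The **reduced
surface** `Phi = S / (36 pi V^2)^(1/3)` tracks morphology:

* `Phi = 1` — sphere;
* `Phi >= 2^(1/3)` — enough surface for two equal spheres of half
  the volume: the protocell **divides** (threshold configurable;
  2^(1/3) is the natural geometric choice);
* `Phi <= 1 - epsilon` (default `epsilon = 0.1`) — osmotic tension
  beyond tolerance: the protocell **bursts** and the lineage ends.
  Only the geometric division threshold has a canonical value; both
  thresholds are parameters of `event_rule()` / `default_physics()`.

Division splits membrane lipids evenly per species (odd remainder to
a random daughter) and partitions every aqueous count binomially with
p = 1/2 in the stochastic engine; the deterministic engine halves all
extensive state (partition noise is the stochastic engine's job).

## Composition-dependent permeability

Solute permeability is class-based: `impermeable` (acd),
`constant` (w), or `composition_dependent` (nutrients and the lipid
precursor), the latter scaling the base permeability by an
**exact-matching polynomial** f(chi) through calibration control
points — interpolation, not regression, evaluated in barycentric
Lagrange form. The default control points {(0, 1), (0.375, 10),
(1, 2)} are a stand-in with the empirically motivated shape (an
interior maximum: heterogeneous membranes leak fastest); the assay
pipeline (`exp_assay()`) produces drop-in replacements from data.

## Lipid synthesis and membrane exchange

The extension `add_lipid_synthesis()` adds a diffusible precursor P
and the bulk reaction `RS: P -> L` catalysed by AB. Aqueous L is
osmotically active until inserted. Four membrane channels couple the
bilayer to its environment (propensities per hour):

1. l uptake: `k_in * S_mu * c_l,env * N_A`;
2. l release: `k_out * N_l`;
3. L insertion: `k_in * S_mu * [L]_aq * N_A`;
4. displacement: `k_d * N_L` — one membrane L leaves to the bath and
   one l enters, atomically, conserving the total lipid count.

`k_d` deliberately touches neither the RS rate law nor the net
surface budget; it only tunes the stationary composition
`chi_L` downward, monotonically. The default `k_out` is chosen to
balance channel 1 against channel 2 for a pure-l membrane of any
size, so primitive-lipid exchange alone causes no net drift.

# Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `C_out` | 100 | mol/m³ | outer osmolarity (assay buffer) |
| `r0` | 200 | nm | initial vesicle radius |
| `alpha_l`, `alpha_L` | 0.2, 0.6 | nm² | lipid head areas |
| `lambda` | 3 | nm | bilayer thickness |
| base nutrient permeability | 2e-12 | m/s | at chi = 0; scaled by f(chi) |
| `base_P_w` | 1e-10 | m/s | waste export (constant class) |
| `k_syn` | 0.1 | (mol/m³)⁻¹h⁻¹ | lipid synthesis rate constant |
| `base_P_P` | 1e-11 | m/s | precursor permeability |
| `k_in` | 1e-9 | m/s | lipid association |
| `c_l_env` | 1e-4 | mol/m³ | free primitive-lipid monomer outside |
| `k_d` | 0 | h⁻¹ | displacement (the selection dial) |
| `phi_divide`, `epsilon_burst` | 2^(1/3), 0.1 | — | event thresholds |

Why these growth defaults: in the exponential reproduction regime the
volume growth rate is set by the trapped end-product's equilibrium
share (g = d2·[ACD]/c_acd, where c_acd is the osmolarity left over
after the buffered and self-maintaining species take theirs), and the
surface growth rate by the synthesis flux per membrane lipid. Their
ratio fixes a stationary cell size (≈150 nm here) and a stationary
division time (≈10 h at k_d = 0); `base_P_w` is set high enough that
the permeable waste stays at quasi-steady state instead of inflating
the volume into an osmotic runaway. These values were frozen once the
regime existed and are not tuned per experiment.

# Numerical choices

* **Deterministic engine**: Dormand–Prince RK45, adaptive PI step
  control, relative tolerance 1e-8 and absolute tolerance 1e-3
  molecule counts; Phi-threshold crossings located by bisection on
  the step; the FSAL derivative is invalidated and recomputed after
  each event. Dense output by cubic Hermite interpolation in delta
  form (exact for constant solutions).
* **Steady states**: long relaxation then damped Newton on the
  dynamic species (pure accumulators — acd, the inert osmolyte —
  grow forever in a fixed compartment and are excluded). Newton can
  polish onto an *unstable* root when a trajectory lingers near the
  dead state; the leading Jacobian eigenvalue is therefore checked
  and the search re-relaxed from a perturbed root if positive. Two
  steady states are the same attractor when metabolite concentrations
  agree within 1e-2 relative (coarse grids; avoids numerical
  splitting).
* **Stochastic engine**: exact direct-method SSA over reactions
  (propensity `k N_cat prod falling(N_i, s_i) / (V N_A)^(order-1)`),
  per-species influx/efflux, and the four lipid channels; volume and
  geometry are re-projected after every firing (all propensities
  depend on V, so no dependency-graph shortcut applies). All
  randomness flows through R's RNG: one seed gives a bit-identical
  event sequence.
* **Initialisation**: growth runs start from the encapsulated
  network's fixed-compartment steady state
  (`equilibrium_concentrations()`), not from an arbitrary seed — a
  cold metabolic start inflates the volume before lipid synthesis
  ramps up and bursts the vesicle, a transient artefact rather than
  the regime under study. Compositions that exceed the osmotic budget
  are scaled into it. The inert osmolyte X absorbs the initial slack
  so the starting sphere is exactly isotonic.
* **Desk-scale stochastic runs**: the original stochastic horizon
  (thousands of days) is out of scope by design. The SSA is
  cross-validated against the ODE in a fixed 75 nm compartment
  (~1e5 molecules, 20 seeds, 3-SE band), and growth/division SSA runs
  start from the deterministic stationary state (~4e5 molecules);
  starting a *small sphere* instead is not equivalent — the
  stationary size is an attractor of the parameter set, and a 60 nm
  sphere cannot grow its surface fast enough and bursts.

# What the synthetic data emulate — and what they do not

`gen_release_trace()` produces F(t) = 1 − exp(−kt) plus additive
Gaussian noise clipped to [0, 1] (clipping introduces a small bias at
the extremes), emulating a perfect-sink dye-release assay on
monodisperse 200 nm vesicles. `gen_composition_series()` draws the
per-composition rates from an exact polynomial with an interior
maximum. Real traces additionally carry photobleaching, background
leakage, vesicle polydispersity and calibration error — none are
modelled, so a green recovery test establishes correctness of the
fitting pipeline, not robustness to those artefacts. The F∞-free
variant of the exponential fit engages only when a trace has
genuinely plateaued below 0.9 (a flat tail), not merely slowed.

# Design choices where the design was open

* **Branch seeding for bistability**: two branches, near-dead
  (1e-4 mol/m³) and elevated (20 mol/m³) metabolite seeds. The
  attractor count is 0 (dead only), 1, or 2.
* **k_d semantics**: an atomic L→l swap at rate `k_d N_L`, conserving
  lipid count and leaving both the synthesis rate law and the surface
  budget untouched.
* **Decay products**: AB and AC decay to the permeable w; ACD decays
  to the impermeable acd, providing the trapped end-product the
  growth mechanism requires.
* **Environment**: an infinite buffer; released w and l vanish into
  the bath; aqueous L inserts only into its own membrane.
* **Time unit**: hours internally; day-scale quantities are reported
  in days by the CLI and experiment tables.

# Known limitations

* Reconstructed network topology and package-owned rate constants:
  quantitative values (division times, steady-state concentrations)
  characterise *this* parameterisation, not a literature-calibrated
  one.
* No membrane mechanics (bending, tension, leaflet asymmetry), no
  reversible kinetics, no explicit water transport, no interacting
  populations competing for finite resources.
* The deterministic engine treats division as exact halving;
  fluctuation-driven phenomena (partition noise accumulation,
  extinction) live exclusively in the SSA.
* The uniform-permeability and selection sweeps are descriptive
  (mean ± SD over a 10-generation stationary window); no hypothesis
  testing is layered on top.
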