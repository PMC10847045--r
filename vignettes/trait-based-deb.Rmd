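---
title: "From genomes to phenotypes: the trait-based DEB model in rhizodeb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From genomes to phenotypes: the trait-based DEB model in rhizodeb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizodeb)
```

`rhizodeb` predicts growth phenotypes of soil bacteria on root-exudate
metabolites from genome-derived traits alone. This vignette explains the
model, the provenance and meaning of every tunable constant, the numerical
choices, and what the synthetic test fixtures do and do not establish about
real data.

## The dynamic energy budget core

Each organism is a single-reserve, single-structure DEB consumer. Reserve
`E` and structure `V` (both mol C per litre of medium) share one biomass
elemental composition. The state equations, per consumer:

* Reserve gains assimilated carbon from uptake (`y_ED` C-mol reserve per
  mol substrate taken up) and loses the mobilization flux
  `k_E m_E - m_E r` (per C-mol structure), where `m_E = E/V`.
* Mobilized reserve is partitioned with maintenance (`k_M`, h^-1 per C-mol
  structure) taking priority over growth and constitutive extracellular
  enzyme production (a fraction `zeta_X` of the growth flux). The specific
  structural growth rate follows as
  `r = (k_E m_E - k_M) / (m_E + y_EV (1 + zeta_X))`.
* Growth converts reserve to structure with yield `y_VE`; the complement
  `(y_EV - 1)` per unit structure is respired, as are maintenance and the
  assimilation overhead `(a - y_ED)` per mol substrate (`a` = carbon atoms
  per molecule).
* When reserve cannot cover maintenance (`r < 0`), the deficit is paid from
  structure with an overhead multiplier (default 1.2): starving cells
  shrink faster than their maintenance demand alone would suggest. The
  multiplier is a config entry (`integrator$starvation_overhead`); its
  value is a convention, not a measurement.
* Reserve and structure turn over at a density-dependent rate
  `gamma = gamma0 * B_tot / B_ref` (defaults 0.1 h^-1 at a reference
  biomass of 0.01 mol C/l); losses accumulate as necromass, not CO2. The
  functional form is the simplest density-proportional closure; both
  constants are config entries and should be treated as uncertain.

Carbon is conserved exactly: substrates + reserve + structure + enzyme +
CO2 + necromass is constant along every trajectory, and every simulation
asserts closure to better than 1e-6 relative (observed: ~1e-14).

### Reported phenotypes

* **Realized growth rate** is measured the way a growth curve would measure
  it: the instantaneous log-slope of *total* biomass `E + V`, summarized
  (median by default; mean/max via `reporting$r_metric`) over the time
  points above a floor of 1e-4 h^-1. The structural rate `r` of the growth
  equation transiently exceeds `r_max` while an inoculum rich in reserve
  (90% by protocol) converts reserve to structure; total biomass does not
  grow during that conversion, so the biomass-based metric is free of the
  inoculum artefact. Its maximum at saturating substrate equals the
  genome-inferred `r_max` — that identity is the defining contract of the
  porter-density closure and is verified in the acceptance suite for every
  fixture isolate to within 2% (observed: ~0.01%).
* **Biomass production (BP)** is the cumulative *gross* synthesis flux of
  reserve and structure (assimilation plus structural synthesis), with
  turnover losses staying inside BP and flowing to necromass. This keeps
  `CUE = BP/(BP + BR)` in [0, 1] even for cultures that end up starving.
  A net mode (`reporting$bp_mode = "net"`: net biomass increment plus
  necromass) is provided for sensitivity analyses. Production-respiration
  *scaling* is assessed on rates (cumulative value over run duration),
  because cumulative batch totals are anticomplementary — production plus
  respiration is bounded by the carbon consumed — and the power-law
  signature lives in the rates.
* **Latency** is the time of peak CO2 production rate ("peak growth
  mineralization") on the output grid.

## Trait translation

### Cell allometry (`allometry` config group)

Cell volume `V_c = 0.25 (G / 1 Mbp)` um^3 anchors a 4-Mbp genome at 1 um^3;
dry mass `M_dry = 435 fg x V_c^0.86` and protein volume
`V_P = 0.21 V_c^0.80` (sublinear) follow published allometric regressions
of cellular biomolecule composition on volume; 47% of dry mass is carbon,
giving `lambda_B` cells per mol biomass C. All coefficients are config
entries: they are literature-scale defaults, not fitted values, and any
user with measured cell sizes should override them.

### Translation economics (`ribosome`, `translation` groups)

`k_E = r_max V_P / V_R` with `V_R` the minimum ribosomal volume able to
replicate all proteins and ribosomes within a division cycle at `r_max`
while replacing degraded copies (degradation rates `eta`, `phi`, default
0.02 h^-1). The bound is implemented exactly as

`V_R = l_P v_P N_P (phi/r + 1) / (v_R (r_R/r - l_R (eta/r + 1)))`

with `l_P = 975` bp (325 codons), `l_R = 4566` bp, `r_R = 226800` bp/h
(63 nt/s). Written this way the expression needs a dimensionless ribosome
volume scaling constant `v_R`; the default 0.0143 is the average
protein-to-ribosome volume ratio (6e-8 / 4.2e-6 um^3), calibrated so the
expression numerically equals the direct count-based calculation
`v_ribosome x N_ribosomes`. With these defaults a cell growing at
0.35 h^-1 carries ~5,600 ribosomes occupying ~11% of protein volume —
within the range of direct measurements — and `k_E/r_max` spans ~2-100
from fast to slow growers. The equality case of the bound is used when
deriving `k_E` (the minimum feasible ribosome investment); growth rates at
which the bound diverges raise an infeasibility error.

Translational yield `y_VE` maps rRNA operon count piecewise-linearly in
log copies from 0.8 (one operon) to 0.3 (fifteen operons). The linear-in-log
form is a modelling choice — the genomic signal is ordinal more than
metric — and the bounds are config entries.

### Substrate chemistry and thermodynamics (`chemistry`, `thermo` groups)

NOSC uses the standard charge-corrected definition
`4 - (4a + b - 3c - 2d - z)/a`. Catabolic energy assumes full aerobic
oxidation: `(4 - NOSC) a` electrons at -119.5 kJ per mol electrons
(config), reproducing about -2.87 MJ/mol for glucose. Diffusivity uses a
Wilke-Chang molar-volume correlation with molar volume estimated from
molar mass at 1 g/cm^3 solute density; for a 180 g/mol sugar this gives
7.5e-10 m^2/s against a measured ~6.7e-10.

The assimilation yield couples catabolism and anabolism:
`y_ED = 1/(Y_cat + lambda Y_an)` with both stoichiometric coefficients
equal to `1/a` mol substrate per C-mol (the catabolic turn oxidizes, the
anabolic turn conserves, one carbon), and
`lambda = (dG_an + dG_diss)/(-dG_cat)` per C-mol. `dG_an` is a
building-block conversion constant (default 100 kJ/C-mol, overridable per
substrate via a `dG_block` column) plus the synthesis cost of the
transporter complement (`e_porter x` binding sites per C-mol, a weak but
monotone feedback); `dG_diss = dG_syn/nu` (defaults 700/5 = 140 kJ/C-mol)
is the constant dissipation of biomass-component synthesis. These
constants sit at bioenergetics-literature scale but are the least
constrained part of the model; every one is config- or column-overridable.
Under the defaults sugars assimilate at ~0.67 C-mol/C-mol and amino acids
lower, which propagates into the class ordering of CUE.

### Uptake kinetics (`kinetics` group)

The forward binding rate is the diffusion-limited encounter rate per site,
`k+ = 4 pi D r_p` with porter radius `r_p = 1 nm`; the intrinsic affinity
is `K0 = k2/(k+ N_A)` with `k2 = 180 s^-1` the maximum per-site processing
rate. The affinity inflation term depends only on binding sites *per cell*
(`B_T/n = rho x 4 r_c^2 / r_p^2`), so `K = K0 (1 + 4 rho r_c / r_p)` is
constant in biomass — the distinction between updating the affinity
dynamically during growth or freezing it at inoculation is mathematically
empty under area-fraction-based site counts, which is why no such switch
exists. Specific affinity `Vmax/K` saturates in `rho`: beyond a few
permille of surface coverage additional binding sites buy almost no
low-concentration advantage, and the `Vmax`-`K` frontier is (weakly)
concave — the geometry behind uptake-strategy diversity.

### Porter-density closure (`closure` group)

The closure finds the total porter area fraction `rho*` such that, at
saturating substrate, the steady-state reserve density supports
`r = r_max`. With uptake proportional to total biomass C (binding sites
are biomass-specific), the reserve density obeys
`dm_E/dt = s (1 + m_E) - k_E m_E` with supply `s = y_ED(rho) Vmax(rho)`,
so `m_E* = s/(k_E - s)` and the reserve-capacity identity
`k_E = p_Am/m_E*` holds at the solution by construction. Demand requires
`m_E_req = (r_max y_EV (1 + zeta_X) + k_M)/(k_E - r_max)`; the solve is a
bracketed 1-D root-find in `rho` (relative tolerance 1e-8) with an inner
fixed point for the porter-cost feedback on `y_ED` (convergent in one step
for the linear default cost; iterated defensively, capped at 50). The
supply is strictly increasing in `rho`, so the root is unique; absence of
a sign change up to the packing limit (default 0.25) raises an
infeasible-phenotype error with diagnostics.

The density is solved once per isolate on a glucose reference substrate
and then distributed across substrates as
`rho_i = rho* z_rho[class(i)] / n_class(i)` — the reading most consistent
with scaling solved estimates by normalized gene frequencies. A
`rho_mode = "per_substrate"` sensitivity mode re-solves the density on
every substrate before class weighting. Under fixture defaults the solved
totals span ~0.002-0.25% of the cell surface and per-substrate densities
~1e-4-1e-2%, with affinities in the 0.01-0.1 uM range.

## Simulation protocols

`deb_protocol()` defaults encode the standard batch study: 125 mg C/l of a
single metabolite, an inoculum of 10^3 cells per gram of soil mapped 1 g ~
1 ml to the litre of medium (the mapping is config-exposed; the
literature convention is not explicit), split 90% reserve / 10% structure,
integrated 500 h or until substrate exhaustion (threshold 1e-12 mol C/l,
detected by a root function). Mixed-medium runs split the same total
carbon evenly over all metabolites, run 1,500 h or until the first
depletion, and ledger per-substrate consumption for preference and niche
breadth analyses; each isolate is grown alone by default, with a
`community = TRUE` mode for joint competition.

Integration uses `deSolve::lsodar` (adaptive, stiff-capable, with root
termination) at `rtol = 1e-8`, `atol = 1e-14`; halving the tolerances
changes cumulative BP, BR and CUE by less than 1e-4 relative (tested).
Derivatives clamp pools at zero so the solver cannot be driven negative by
round-off; non-finite states abort with the last state attached. The ODEs
are deterministic — seeds only enter fixture generation.

## The synthetic fixtures

`fixture_isolates()` and `fixture_substrates()` emulate the *structure* of
a rhizosphere isolate collection: genome sizes 2-10 Mbp, 1-15 rRNA
operons, minimum generation times log-linear in operon count (1.5-160 h,
i.e. maximum rates ~0.005-0.45 h^-1) with lognormal scatter, Dirichlet
transporter frequencies over the six substrate classes, and glycoside
hydrolase frequencies; positive root responders are biased toward
organic-acid/auxin transporters, fewer operons and fewer hydrolases,
negative responders the reverse. Substrates come from per-class template
sets of real metabolite formulas, so NOSC and molecular size have
realistic class structure (random stoichiometry easily produces
thermodynamically absurd molecules).

What passing tests on these fixtures establishes: internal consistency of
the trait translation, exact agreement of the flux network with the
governing equations, carbon conservation, recovery of `r_max` by the
closure, and correct statistical recovery of planted effects. What they do
*not* establish: agreement with any real isolate collection. In
particular, the fixtures deliberately do not reproduce the empirical
covariance among traits of real rhizosphere panels, so population-level
distributional features that depend on that covariance — e.g. a formally
bimodal realized-growth-rate distribution — emerge only weakly here (both
growth regimes are occupied, but a two-component mixture is not favoured
by BIC); `classify_regimes(method = "mixture")` remains available and is
validated on synthetic bimodal data. Real trait tables are supplied
through `read_isolates()`/`read_substrates()` in the same schema.

## Problem sizes

The shipped test suite parameterizes populations of up to 40 isolates and
simulates a 16-isolate x 6-substrate batch grid plus smaller mixed runs
(~40 s total); the reproduction script runs 16 isolates x 12 substrates
(192 batch + 16 mixed simulations, ~1 min). Both scale linearly in the
number of isolate-substrate pairs; a 39 x 82 study is a few thousand ODE
runs, well within a single CPU-hour.

## Known limitations

* All thermodynamic constants are class-level defaults, not per-metabolite
  measurements; absolute CUE values inherit that uncertainty even though
  the class *ordering* (sugars above amino acids) is robust.
* Extracellular enzymes are a pure carbon cost: all modelled substrates
  are monomers, so enzyme products are not returned to the medium.
* No soil matrix: mineral sorption, diffusion fields around particles and
  spatial competition are outside the model's scope, as are non-O2
  electron acceptors, pH speciation and nutrient (N/P) co-limitation.
* The rrn-to-yield map and the ribosome-economy constants are calibrated
  to scale, not fitted; users with ribosome profiling or growth-law data
  should tighten them via `deb_config()`.
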