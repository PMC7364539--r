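---
title: "Methods: constraint-based analysis of a versatile methanotroph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based analysis of a versatile methanotroph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellaflux)
```

## The model class and its assumptions

cellaflux analyses genome-scale metabolic reconstructions by flux balance
analysis (FBA).  A model is a stoichiometric matrix $S$ (balanced
metabolites $\times$ reactions) with flux bounds $lb \le v \le ub$; the
steady-state assumption $S\,v = 0$ and a linear objective (usually the
biomass pseudo-reaction, whose flux is the specific growth rate $\mu$ in
h$^{-1}$) define a linear program.  All fluxes are in
mmol h$^{-1}$ g-DW$^{-1}$.

Conventions, chosen to match common practice in the constraint-based
community:

* **Exchanges are export-positive.** An exchange reaction touches a single
  balanced metabolite; positive flux secretes it, uptake is a negative
  flux, so a medium granting an uptake rate $u$ sets the exchange lower
  bound to $-u$.  Minimising an uptake therefore means maximising the
  (negative) exchange flux.
* **Boundary species carry no balance row.** Species flagged with the SBML
  `boundaryCondition` (common in SEED-era files) are treated as open ends
  and dropped from $S$.
* **Free mineral set.** `apply_medium()` first closes every uptake except a
  documented default free set (O$_2$, water, protons, phosphate,
  ammonium/nitrate, sulfate, trace ions — the composition of a nitrate
  mineral salts medium), then opens the requested carbon sources.  Export
  bounds are never touched, so CO$_2$ and by-product secretion stay open.
  The set is an argument of `apply_medium()` because deposited models
  differ in how they name these exchanges.
* **Deletions act through GPRs.** A gene-protein-reaction rule is a boolean
  expression (`and` = complex subunits, `or` = isozymes); a deletion sets
  the deleted genes to false and closes the bounds of reactions whose rule
  evaluates false.  Unknown gene ids in a deletion request warn rather
  than fail, so strain panels do not abort on annotation mismatches.

## Simulation protocols

* `solve_fba()` — plain FBA with optional fixed rates (e.g. $\mu$ pinned to
  a measured value).
* `parsimonious_refine()` — FBA optima are usually degenerate.  To report
  a unique representative flux distribution the objective is fixed at its
  optimum and total absolute flux $\sum_j |v_j|$ is minimised
  (split-variable LP).  Published flux maps rarely state their degeneracy
  resolution; this parsimonious rule is ours, documented, and the refined
  objective is checked to move by less than $10^{-6}$.
* `min_uptake_at_growth()` — the yield-optimisation protocol used for
  enzyme-demand predictions: fix $\mu$ (and any measured secretion rates),
  minimise substrate uptake, refine parsimoniously.
* `max_growth_at_uptake()` — maximal theoretical yield: bound the uptake,
  set maintenance to zero, maximise biomass; yield
  $= \mu / u \times 1000$ g-DW mol$^{-1}$.
* `fit_atp_maintenance()` — non-growth-associated maintenance (NGAM) is a
  lower-bounded ATP hydrolysis flux $m$.  Predicted yield is non-increasing
  and piecewise-linear in $m$ (shrinking feasible region), so the $m$
  reproducing a measured yield is found by bisection on
  $[0, m_{\max}]$, where $m_{\max}$ is the maximal feasible hydrolysis
  flux at that uptake; convergence tolerance $10^{-3}$ g-DW mol$^{-1}$,
  60-iteration cap.
* `check_energy_cycles()` — curation QC: with every exchange closed the
  maximal ATP hydrolysis flux must be zero (tolerance $10^{-6}$);
  otherwise the parsimoniously minimal active set is reported, which is
  the loop to fix (usually a wrongly reversible reaction).

### The LP core

All protocols sit on one dense bounded-variable two-phase simplex
(`R/lp.R`).  The problems are small (tens to a few hundred variables), so
the basis system is re-factorised at every iteration — slower
asymptotically but free of accumulated inverse drift.  Reduced-cost and
pivot tolerance is $10^{-9}$; mass balance of every reported optimum is
asserted at $10^{-6}$; Dantzig pricing switches to Bland's rule after a
burn-in proportional to problem size to exclude cycling; infinite bounds
are clamped to $\pm 10^6$ and an optimum touching the clamp reports
`unbounded`.  The test suite cross-checks optima against exhaustive vertex
enumeration on all toy models small enough to enumerate.

## The curated mini-model

`make_minicella_model()` builds a 88-reaction, hand-verifiable model of
Methylocella central carbon metabolism.  It encodes the pathway logic that
drives the organism's substrate phenotypes:

* sMMO (NADH- and O$_2$-consuming) for methane; PQQ-linked methanol and
  methylamine oxidation feeding formaldehyde and methylene-THF;
* the serine cycle with malyl-CoA cleavage, whose glyoxylate deficit is
  covered **anaplerotically by isocitrate lyase** — this is what makes ICL
  essential on C1 substrates while malate synthase is dispensable there;
* the glyoxylate shunt (ICL + MS), required for net C2 assimilation from
  ethanol/acetate, with no ethylmalonyl-CoA alternative;
* two parallel propane routes: PrMO $\to$ 1-propanol $\to$ propanal $\to$
  propionyl-CoA $\to$ methylmalonyl-CoA $\to$ succinyl-CoA, and sMMO
  $\to$ 2-propanol $\to$ acetone $\to$ acetol $\to$ 2-oxopropanal $\to$
  lactate $\to$ pyruvate.

Design choices that were genuinely open:

* **Lumped biomass.** The biomass reaction drains acetyl-CoA,
  oxaloacetate, PEP, NADPH and ATP in fixed proportions rather than a full
  macromolecular composition.  This keeps every growth/no-growth argument
  checkable by hand; the fixture's quantitative yields are therefore its
  own and are *not* expected to match measured yields of the organism.
* **Monooxygenase product-ratio coupling.** Which fraction of propane is
  oxidised to 1- versus 2-propanol is set by enzyme kinetics, not by
  optimality, so a pure FBA model would route everything through the
  cheaper branch.  The observed partition (roughly 3 parts 2-propanol to
  2 parts 1-propanol in propane-grown cultures) is enforced with a
  balanced coupling pseudo-metabolite linking the two monooxygenation
  fluxes.  This is what makes the acetol-oxidation deletion strain grow on
  propane with a genuinely lower yield: three fifths of the oxidised
  propane is forced into a branch it can only excrete.
* **Lumped respiration.** P/O ratios are 2 for NADH, 1 for cytochrome-c
  level electrons (PQQ dehydrogenases) and 1 for FADH$_2$.  The proton
  stoichiometry of PQQ alcohol oxidation is not quantified in the
  literature for this organism; a single lumped cytochrome branch is our
  documented stand-in.
* **Dead-end substrates.** Glyoxylate, oxalate, glycine and urea have
  exchanges and transporters, but no route can net-produce acetyl-CoA from
  them, so growth fails structurally (urease and oxalate decarboxylation
  provide nitrogen/energy only).  Glyoxylate still rescues the ICL
  deletion on C1 media because the serine cycle can consume it directly —
  reproducing the characteristic rescue-without-growth pattern.

## Synthetic data generators

All randomness flows through explicit seeds via an isolated RNG wrapper;
the global random state is saved and restored around every draw.

* `make_toy_pathway_model()` emulates nothing biological: it is scaffolding
  with an exactly known optimum (designed yield), optional ATP-generating
  side routes for maintenance algebra, parallel routes for degeneracy
  tests and an optional deliberately infeasible ATP loop for the QC check.
* `simulate_proteome()` emulates the structure of a label-free proteomics
  campaign over growth conditions: a few planted enzymes whose abundance
  is an affine function of their predicted flux plus Gaussian noise
  (stated as a fraction of each gene's dynamic range), a background of
  flux-independent proteins, of which only a minority map to metabolic
  reactions — mirroring real experiments where most detected proteins are
  not metabolic enzymes.  It does **not** emulate peptide-level missingness,
  shared peptides, or correlated (batch) noise.
* `simulate_growth_series()` emulates serum-vial yield measurements:
  exponential biomass, substrate decreasing by biomass/yield, Gaussian OD
  noise, and an optional nutrient-limitation plateau during which growth
  stops but maintenance consumption continues (which is why including the
  plateau biases the slope low).  Gas-liquid transfer kinetics are not
  modelled.

Because the generators are idealisations, green tests demonstrate the
correctness of the algorithms under the stated assumptions, not
performance on real proteomes or growth curves.

## Statistical components

* Pearson $r$ with the classical two-sided $t$ test on $n-2$ degrees of
  freedom; with the three conditions of a typical substrate-shift design
  this is one degree of freedom (a standard Cauchy).
* Benjamini–Hochberg step-up over all *testable* enzymes; proteins that
  are unmappable, incomplete or flux/abundance-invariant are excluded and
  reported with a reason, never silently given $p = 1$.
* Flux-to-enzyme aggregation is the sum of absolute fluxes over the
  gene's reactions (scale-consistent, symmetric for reversible
  reactions); `aggregate = "max"` is available.  Abundances are used raw;
  per-condition total-intensity normalisation is opt-in.
* The yield estimator is ordinary least squares of produced biomass (g)
  on consumed substrate (mol) with a free intercept (the intercept
  absorbs OD baseline offsets); the linear-phase window is user-chosen,
  with a maximal-$R^2$ prefix heuristic available but off by default.

### A power limitation worth knowing

With three conditions the correlation test has one degree of freedom, and
the $p$-value decays extremely slowly in $|r|$: $r = 0.9995$ still gives
$p \approx 0.02$, and since $q \ge p$ under any multiplicity correction,
an FDR threshold of 0.05 is reachable only by correlations that are
perfect to about $10^{-5}$.  Our simulations quantify this: at noise equal
to 10% of the dynamic range, planted enzymes reach $|r| \approx
0.99{-}0.999$ yet mean recovery at $q < 0.05$ is only about 0.2 (the
false-discovery proportion stays controlled).  In practice this means a
three-condition screen can only crown all-or-nothing expression patterns
— enzymes expressed in exactly the conditions where their reaction
carries flux, which correlate perfectly — and that is precisely the
character of the significant hits reported for this organism.  More
conditions, not better statistics, is the fix.

## Network topology

Metabolite connectivity $k$ counts the reactions a species takes part in;
currency metabolites (ATP and redox cofactors top the list) are
deliberately included, and compartment-duplicated species count
separately by default (both exposed as arguments).  The scale-free slope
is unweighted OLS of $\log_{10} n(k)$ on $\log_{10} k$ over non-empty
bins — no logarithmic binning — so the value depends on the fit range and
is reported with it.  Venn overlaps between reconstructions match by
identifier only; structural matching is out of scope.

## Problem sizes used by the test suite

Unit and property tests run on the mini-model (88 reactions) and on toy
chains of up to 7 reactions (the enumeration oracle grows combinatorially,
so only models of that size are enumerated).  Simulation-based checks use
1000 uniform-null replicates for FDR control, 100 seeded proteome
simulations, and 300–400 growth-curve replicates — sizes at which
Monte-Carlo standard errors are far below the margins being asserted.  The
full deposited genome-scale reconstruction (1436 reactions) is exercised
by `scripts/full_model_integration.R`, which requires the downloaded
model file and is therefore not part of the default suite.

## Known limitations

* No flux variability analysis; alternate optima are summarised by a
  single parsimonious representative.
* No MILP methods (essentiality via binary variables, strain design) and
  no quadratic objectives.
* Element/charge balancing is stored but not enforced; the QC notion of
  consistency here is energetic (no ATP from nothing), not elemental.
* The mini-model's biomass lump makes its absolute yields and growth
  rates illustrative only.
* Thermodynamics enters only through irreversibility assignments.
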