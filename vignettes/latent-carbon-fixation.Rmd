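---
title: "Finding latent carbon-fixation cycles in a heterotrophic metabolic network"
author: "latentpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding latent carbon-fixation cycles in a heterotrophic metabolic network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentpath)
```

## The question

Heterotrophs such as *E. coli* carry no carbon-fixation pathway, yet their
central metabolism contains every enzyme class that natural carbon-fixation
cycles are built from.  This package asks, computationally: can a subset of
the native reactions be wired into a cycle that converts CO2 and cellular
cofactors into pyruvate?  The flagship answer is the GED cycle - reductive
carboxylation of ribulose 5-phosphate (Ru5P) by 6-phosphogluconate
dehydrogenase (Gnd), cleavage of 6-phosphogluconate by the Entner-Doudoroff
enzymes into pyruvate and glyceraldehyde 3-phosphate (GAP), gluconeogenic
return of pyruvate to GAP, and pentose-phosphate-pathway regeneration of
Ru5P.

Five analysis stages are implemented end to end: network preprocessing,
thermodynamics-constrained pathway enumeration, Max-min Driving Force (MDF)
evaluation with Pareto ranking, flux-balance-analysis (FBA) yield
comparison of pathway variants, and positional ^13^C labeling prediction,
plus the Michaelis-Menten utilities used for enzyme characterization.
Everything runs on a bundled ~45-reaction central-metabolism fixture, so no
genome-scale download is needed.

## Preprocessing and the search space

Pathway search operates on the strictly cytoplasmic network:
`pruneForSearch()` removes exchanges, transports, and any reaction touching
a non-cytosolic species (compartment read from the BiGG-style `_c` suffix).
`addCurrencyExchanges()` then appends reversible *pseudo-reactions* that
regenerate ATP (from ADP + Pi and from AMP + 2 Pi), NADH and NADPH, and
exchange protons, water, oxygen and ammonia freely - the assumption being
that the host supplies energy, redox power and inorganic ions.  CO2 is
deliberately **not** given a free exchange: it is the counted substrate.
Pseudo-reactions are flagged and never appear in reaction counts, driving
force constraints, or reported supports.  On the fixture, the default
currency specification creates seven pseudo-reactions (ammonia is omitted
because the fixture has no nitrogen chemistry; it is added automatically
for models that declare it).

All reactions are treated as reversible during search regardless of their
annotated bounds - reversibility is decided by thermodynamics, not by the
model's directionality conventions.  Source bounds are kept and used only
by the FBA stage.

## Thermodynamics

Reaction energies are transformed standard Gibbs energies dG'0 (pH 7.5,
ionic strength 0.25 M convention), vendored with the fixture.  They are
*synthetic estimates*: a per-metabolite formation-energy table was fitted
by weighted least squares to literature-convention reaction values and the
reaction energies recomputed from it, which makes the table Hess-consistent
(no artificial free-energy cycles).  Two values are pinned exactly: the
pentose isomerase equilibrium (Keq = 0.458, i.e. +1.94 kJ/mol) and the Gnd
reaction (+10.89 kJ/mol), chosen so that at 1 mM reactants and dissolved
CO2 at the Henry-law level of 200 mbar the oxidative decarboxylation sits
at about -1.5 kJ/mol - effectively reversible, which is the thermodynamic
heart of the analysis:

```{r}
net <- buildCoreModel()
transformDg(net, "GND")   # kJ/mol, oxidative direction
```

Temperature is fixed at 298.15 K (the convention of the vendored
energies), water and protons are excluded from concentration terms, and
dissolved CO2 is pinned at `0.0338 M/bar * 0.2 bar = 6.76 mM`; O2 defaults
to 1 mM.  `co2PressureToConc()` and friends expose the Henry-law
arithmetic; the measured Gnd KM(CO2) of 0.9 mM corresponds to roughly 3%
headspace CO2 at ambient pressure.

The **Max-min Driving Force** of a pathway is the largest B such that
metabolite concentrations c within a physiological range (default 1 uM -
10 mM) make every reaction's driving force -dG' = -(dG'0 + RT sum_j S_j ln
c_j) at least B.  `computeMdf()` solves this linear program and reports the
optimal log-concentrations, per-reaction dG' and the bottleneck reactions.
Cofactor pairs float freely within the bounds; no concentration ratios are
fixed.  When several concentration optima exist, any optimal vertex may be
reported - only B and the per-reaction energies are contract-stable.

## Pathway enumeration

`enumeratePathways()` solves a mixed-integer linear program.  Each
reversible reaction is split into forward and backward arcs with binary
activity indicators z (at most one direction active) and fluxes 0 <= v <=
V z (V = 1000).  Constraints: steady state on every species except the
queried net conversion (3 CO2 consumed, 1 pyruvate produced; currency
species are balanced by the pseudo-reactions); and for every active arc a
driving-force constraint linked by big-M (M = 2000 kJ/mol, safely above
any attainable |dG'|) with B >= 1e-6, so only thermodynamically feasible
pathways are admitted.  The objective maximizes `B/RT - w * (number of
reactions)` with weight w = 1 by default; the fixture's Pareto front is
unchanged for w in {0.5, 1, 2}.

The solution space is iterated with *integer cuts*: after each solution,
the constraint `sum of the support's indicators <= |support| - 1` excludes
that directed support and all of its supersets.  Because a non-minimal
support can still be found before one of its subsets, the result is
post-filtered to minimal supports.  Minimality has a useful consequence:
the flux sign pattern of a minimal support is unique (if two steady-state
solutions disagreed in a flux's sign, a convex combination would zero that
flux, contradicting minimality), so directed supports are well defined.
Each accepted solution is re-certified with the exact MDF linear program,
and fluxes are reported scaled to one mole of product.

On the fixture the top-ranked solution is the GED cycle: 16 reactions,
MDF approximately 7.9 kJ/mol, and the enumeration's later solutions are
its more complicated variants (e.g. reverse pyruvate kinase in place of
PEP synthetase, at lower MDF).  `paretoFront()` keeps the pathways not
dominated in (higher MDF, fewer reactions); on the fixture that is the GED
cycle alone, with or without the oxygen-sensitive formate lyase present.

Two independent back ends solve the linear programs: HiGHS (through a
`python`/scipy subprocess; the only MILP-capable solver in the stack) and
the package's own two-phase dense simplex with Bland's rule.  The
brute-force oracle `bruteForceEnumerate()` - exhaustive subset search with
per-subset feasibility LPs and MDF evaluation, used on networks of up to
12 reactions - runs entirely on the pure-R simplex, so implementation and
oracle never share a solver.

## ATP accounting

`atpCost()` maps adenylates to phosphoanhydride-bond equivalents (ATP = 2,
ADP = 1, AMP = 0): an ATP-to-ADP conversion costs one equivalent, an
ATP-to-AMP conversion - PEP synthetase - costs two, and substrate-level
phosphorylation is credited.  Per mole of pyruvate the GED cycle spends 6
equivalents (twice through PEP synthetase at 2 plus phosphoglycerate
kinase at 1), the RuBP (Calvin-Benson) cycle 7 (five phosphoglycerate
kinase, three phosphoribulokinase, minus one pyruvate kinase credit).

## FBA yields of non-growing cells

The FBA stage reproduces the production-oriented comparison:
`applyCurations()` applies the standard genome-scale curation set (single
proton-translocating transhydrogenase, irreversible homoserine
dehydrogenase, removal of disputable or unrealistic reactions, blocked
threonine cleavage, oxygen-sensitivity flags on the formate lyases; each
class is skipped with a warning on models that lack the ids, so the
fixture passes through mostly untouched).  `makeVariant()` builds the
comparison strains: shunt variants block PFK, PFK_3, F6PA, G6PDH2r and FBP
(a synonym table maps G6PDH2r to the fixture's ZWF), GED variants make Gnd
reversible, RuBP variants add phosphoribulokinase and Rubisco.

`maxProductYield()` maximizes product secretion at a fixed substrate
uptake (xylose 10.8, glucose 13.1 mmol/gDW/h - measured anaerobic
fermentation rates), a fixed ATP maintenance flux of 6.86 mmol/gDW/h, free
bidirectional CO2 exchange, and all other uptakes closed; an auxiliary
electron donor can be enabled as an irreversible hydrogen dehydrogenase
with unconstrained H2 uptake.  Yields are reported per mole substrate,
absolute and relative to the canonical (WT) route.  On the fixture,
anaerobic glucose fermentation is homolactate at exactly 2 mol/mol; the
GED shunt matches or beats the RuBP shunt for every product, strictly for
ATP-limited ones, because it gains one substrate-level ATP through the GAP
branch that the Rubisco route lacks.  Numeric bar heights of the published
full-model figure are *not* reproduction targets; only orderings and the
in-text claims are tested.

## Labeling predictions

The ^13^C simulator is positional and exact: carbons are numbered from the
carboxyl/aldehyde end, and the atom maps (pentose to Ru5P; CO2 entering as
the new C1 of 6-phosphogluconate with Ru5P shifting to C2-C6; aldol
cleavage sending C1-C3 to pyruvate and C4-C6 to GAP) are hard-coded tables
transcribed from the pathway chemistry - see `atomMapTable()`.  Pyruvate
is a 50:50 mixture of the Eda product and GAP-derived pyruvate (one of
each per shunt turn; "about half" is modelled as exactly half).  Serine
and glycine inherit GAP; alanine samples the pool; valine condenses two
independent pool draws and loses one carboxyl as CO2; histidine combines
the five R5P carbons with serine's beta-carbon (the purine detour of its
sixth carbon is not modelled).  All fractions are dyadic rationals, so the
printed predictions (half-labeled alanine and valine under ^13^CO2; the
1:1:1:1 valine ladder and M+1 histidine under 1-^13^C-xylose + ^13^CO2)
are met exactly.  Natural ^13^C abundance (~1.1%) is off by default.
Because pool draws are independent and identically distributed, *which* of
the two pyruvates loses its carboxyl does not change the distribution; what
the 1:1:1:1 pattern does require is that the lost carbon be a carboxyl -
losing a non-carboxyl carbon instead would collapse the ladder to
1:0:2:0:1, a contrast the test suite checks explicitly.

```{r}
aminoAcidIsotopologues(tracerSpec("xylose", 1, co2Labeled = TRUE))$VAL
```

## Kinetics

`mmRate()`/`fitMm()` implement the Michaelis-Menten model with unweighted
Levenberg-Marquardt least squares (a 1/v^2 weighting option exists),
deterministic initialization (kcat from the rate maximum, KM from the
half-maximal point) and standard errors from the parameter covariance.
`synthMmData()` emulates the assay design: 15 points log-spaced over
[KM/10, 10 KM] with 5% multiplicative noise; recovery at that design is
unbiased to within a few percent (checked over 200 replicates).  Published
kinetic constants are used only as simulation ground truth, never as
reproduction targets.  `ru5pEquilibrium()` reproduces the assay-design
calculation for the isomerase-coupled reductive assay: a 16 mM
ribose-5-phosphate stock equilibrates to `16 * 0.458 / 1.458 = 5.03` mM
Ru5P.  The pool-partition reading of that calculation is deliberate; the
alternative (Ru5P = Keq times the *initial* R5P, without conservation) is
rejected because it ignores mass balance.

## The fixture and what passing tests mean

`buildCoreModel()` is the single source of the fixture (the files under
`inst/extdata/` are its serialization): ~45 reactions spanning
glycolysis/gluconeogenesis, ED, both pentose-phosphate branches, xylose
uptake, fermentation sinks and energy/redox bookkeeping, with full-molecule
carbon counts (CoA and nicotinamide carbons included) so elemental carbon
balance closes exactly.  Optional blocks add PRK/Rubisco and a compact
TCA/anaplerosis arm.  `randomNetwork()` generates small carbon-balanced
networks (coefficients -2..2, dG'0 uniform in +/-40 kJ/mol, no currency
species) for the enumeration oracle; `synthMmData()` seeds all noise
explicitly, and no generator touches the global RNG state.

The fixture emulates the *structure* of central metabolism, not the scale
of a genome-scale reconstruction: passing tests demonstrate that the
algorithms are correct and that the GED cycle's identification follows
from the stated thermodynamics on this network.  They do not by themselves
establish the full-model results (the two-pathway Pareto front including
the reverse glycine cleavage route), which require the genome-scale
reconstruction; that check ships as an opt-in integration test.

## Numerical choices and limitations

* LP/MILP tolerances: feasibility 1e-6; supports decoded at flux > 1e-6;
  positive-MDF threshold 1e-6 kJ/mol.  Problem sizes: the fixture MILP has
  ~70 arcs; enumeration to 6 solutions takes a few seconds.
* Enumeration order is solver-dependent; determinism is guaranteed at the
  set level (tests compare sorted supports), and the first solution is the
  objective optimum.
* Pruning is by metabolite compartment; a periplasmic reaction acting only
  on cytosolic species would survive, which may differ from other
  implementations of "strictly cytoplasmic".
* Reaction count, not enzyme count: isozymes and multi-reaction enzymes
  are not collapsed.
* The MDF concentration bounds (1 uM - 10 mM, cofactors free) are the
  package's defaults, surfaced in `concentrationBounds()`; published
  supplementary constraint sets may differ, which is why the GED cycle's
  MDF is asserted as a bound (> 3 kJ/mol), not an equality.
* The byproduct structure of the full 15-product panel depends on the
  genome-scale model and is out of scope on the fixture.
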