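---
title: "Methods: constraint-based analysis of fungal EPS metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based analysis of fungal EPS metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epsflux)
```

## The model and its assumptions

`epsflux` works with stoichiometric (constraint-based) models of
metabolism. A model is a set of metabolites, a set of reactions with
bounded fluxes, and a boolean gene-protein-reaction (GPR) rule per
reaction. The central assumption is steady state: internal metabolite
concentrations do not change, so every feasible flux vector $v$ satisfies
$S v = 0$ with $S$ the stoichiometric matrix (rows metabolites, columns
reactions), together with box bounds $lb \le v \le ub$ in mmol/gDW/h.
Exchange pseudo-reactions connect the network to the environment; by
convention uptake is a negative exchange flux, so a medium is just a set
of lower bounds: an uptake limit $u$ on an exchange sets its lower bound
to $-u$, and every unlisted exchange is closed for uptake.

Flux balance analysis (FBA) maximizes one reaction's flux - here either
the biomass pseudo-reaction (its flux is the specific growth rate, 1/h)
or the extracellular polysaccharide (EPS) sink - over that polytope. FBA
says nothing about regulation or kinetics: a `"+"` growth phenotype means
the network *can* sustain flux to biomass, not that the organism will.
The two sole-source phenotype disagreements retained in the packaged
validation tables (citrate as a carbon source, urea as a nitrogen source)
are of exactly this kind: the stoichiometry admits growth that the
organism does not realize, plausibly for transport or regulatory reasons
a stoichiometric model cannot see.

## The solver stack

FBA and the flux-minimization step are linear programs. The package
solves them with an internal bounded-variable two-phase simplex using
Bland's smallest-index rule, which cannot cycle on degenerate networks;
the basis is refactorized at every iteration, a deliberate
robustness-over-speed trade that is immaterial at the network sizes the
package targets (up to a few hundred reactions). Feasibility of the
phase-1 artificials is accepted below $10^{-7}$ relative; downstream
checks treat $|S v| \le 10^{-6}$ as steady state and fluxes below
$10^{-6}$ as zero. The gap between the solver tolerance and these
verification thresholds is what lets a "zero growth" essentiality call be
distinguished from numerical dust.

Because FBA optima are typically non-unique (parallel isozyme routes,
futile cycles), every analysis that consumes the whole flux vector uses
`parsimonious_reference()`: a second LP that, holding the objective at at
least 99.99% of its optimum, minimizes total absolute flux via the usual
positive/negative split. On tree-like networks this reproduces the unique
optimum up to the retained fraction; on degenerate networks it suppresses
futile cycles and arbitrary path splits, giving a reproducible wild-type
reference.

MOMA (minimization of metabolic adjustment) predicts the flux state of a
perturbed network as the Euclidean projection of the wild-type reference
onto the perturbed polytope, $\min \sum_i (v_i - v^{ref}_i)^2$. This is a
strictly convex quadratic program with a unique solution; it is handed to
`quadprog::solve.QP` after dropping linearly dependent steady-state rows
by rank-revealing QR.

## Screens built on the solvers

**Essentiality.** `single_gene_deletion()` re-evaluates every GPR under a
single-gene knockout (AND = complex, all subunits required; OR =
isozymes, any one suffices), closes the reactions whose rule turns false,
and re-solves FBA. A gene is essential when the objective falls below
$10^{-6}$ - the numeric floor chosen for the qualitative criterion that
deletion abolishes growth. For product essentiality,
`essential_for_product()` first floors the biomass flux at a fraction of
its wild-type optimum (default 0.5, exposed as an argument) so that "EPS
synthesis in growing cells" is what is screened; published essentiality
counts for product objectives are conditional on this choice, which the
sources leave unstated, and 0.5 was fixed here before any comparison as a
mid-range coupling.

**Phenotypes.** `sole_source_call()` replaces the medium's designated
carbon (or nitrogen) source with the tested substrate at the same molar
cap - calls are threshold-based, so the cap choice does not affect them -
keeping the other role's default source in place. Substrates without an
exchange reaction are reported `"untestable"`, distinct from `"-"`.

**Supplementation.** `supplementation_scan()` opens one amino-acid
exchange at 0.01 mmol/gDW/h (the conventional trace-supplement rate, also
used by the fermentation medium preset) and records rate changes for both
the biomass and the EPS objective against the same baseline. Since a
supplement only relaxes one bound, LP monotonicity makes every percent
increase non-negative; this is asserted in the test suite. The EPS
objective is maximized uncoupled from growth by default because the two
quantities are reported separately; a `biomass_fraction` argument
provides the coupled variant, and neither mode is claimed to be "the"
published configuration.

**Overexpression screen.** `screen_targets()` implements the five-step
amplification screen: (i) impose a minimum EPS flux, set to a fraction
$\varphi$ (default 0.1) of the EPS FBA maximum under the medium - the
sources state that a production flux was imposed but not its level, so
$\varphi$ is a parameter and the screen's contract is the ranking, not
absolute fluxes; (ii) compute the parsimonious wild-type reference on the
fermentation medium with the biomass objective; (iii) force each
non-zero-flux internal reaction to carry at least `fold` (default 2)
times its reference flux, preserving direction; (iv) re-predict the flux
state by MOMA; (v) score each target by
$f_{PH} = f_{biomass} \times f_{EPS}$, the product of the biomass and EPS
fold changes, selecting targets with higher EPS flux and $f_{PH} > 1$.
Ranking is by $f_{PH}$ rounded to 8 decimals, ties broken by reaction id,
so repeated runs are byte-identical and quadratic-program round-off
cannot reorder genuine ties.

## Objective construction

`build_biomass_reaction()` converts macromolecular mass fractions
(g/gDW) into molar drains through a registry of molar masses
(coefficient = 1000 x fraction / molar mass, mmol/gDW), plus a
growth-associated ATP hydrolysis term. The default composition
(`default_biomass_composition()`: protein 0.42, glucan 0.28, lipid 0.08,
RNA 0.06, chitin 0.05, DNA 0.01, small molecules 0.10; GAM 40 mmol
ATP/gDW) is a documented placeholder for an EPS-producing basidiomycete -
measured compositions live in supplementary data that the package cannot
ship - and is meant to be replaced by user data; mass closure
(coefficients x molar masses summing back to 1 g/gDW) is enforced by
construction and by test.

`build_eps_reaction()` turns monosaccharide mole percentages into a sink
draining the activated nucleotide-sugar donors (glucose from UDP-glucose,
galactose from UDP-galactose, mannose from GDP-mannose, fucose from
GDP-fucose, xylose from UDP-xylose, arabinose from UDP-arabinose,
rhamnose from dTDP-rhamnose), normalized to 1 mmol total monosaccharide,
releasing the corresponding NDP carriers. The default profile
(`default_eps_composition()`: glucose 60, galactose 15, mannose 10,
xylose 6, arabinose 5, fucose 2, rhamnose 2 mole%) encodes the
qualitative consensus for these polymers - glucose dominant, fucose and
rhamnose minor - again as replaceable data, not code. Polymerization
energetics (ATP per glycosidic bond) are off by default since no
stoichiometry for the polymerization stage is established.

## What the toy generator emulates - and what it does not

`generate_toy_model()` emits a compartment-free core carbon network:
carbon-source exchanges, kinase/catabolic steps into hexose phosphate, a
lumped glycolysis module yielding 2 ATP and 2 pyruvate per hexose
phosphate, amino-acid synthesis, and a biomass sink with seeded rational
coefficients. With `include_eps_pathway` it adds the nucleotide-sugar
branch - phosphoglucomutase and UTP-glucose pyrophosphorylase into
UDP-glucose, 4-epimerization to UDP-galactose, dehydrogenation and
decarboxylation to UDP-xylose and on to UDP-arabinose, the
mannose-6-P/mannose-1-P arm to GDP-mannose and GDP-fucose (a two-gene
AND complex), and the dTDP-glucose/dTDP-rhamnose arm (a second complex) -
feeding an EPS sink built by `build_eps_reaction()` from the default
composition. NTP carriers are recycled through lumped
nucleoside-diphosphate kinase steps so the branch is stoichiometrically
closed.

All yields are small rationals, so the optima have closed forms: with
biomass drawing $a$ amino-acid units, $b$ hexose-phosphate units and $c$
ATP ($a, b, c \in \{1, 2\}$ drawn by seed), maximal growth on glucose
uptake $L$ is $\mu^* = L/(2b + a + c)$, and - because every donor costs
exactly one hexose phosphate plus one NTP - the maximal EPS rate is
$L/3$ regardless of the biomass coefficients. These closed forms, derived
from the topology and not from any LP code, are embedded as ground truth
and re-checked against FBA at generation time. Planted essential sets are
known by construction: the three core catabolic genes plus the optional
precursor-chain genes for growth; additionally every single-gene,
non-isozyme step of the EPS branch for the product objective. The
fermentation medium's 0.01 mmol/gDW/h amino-acid feed keeps a trickle of
growth alive when amino-acid synthesis is deleted, so that gene drops out
of the fermentation essential set - reproducing, at desk scale, the
direction that richer media shrink essentiality.

The generator's defaults (glucose cap 10 mmol/gDW/h, amino-acid cap 0.01,
three carbon sources, one isozyme pair, two planted chain genes) were
fixed once as representative desk-scale conditions. What the toys do
*not* emulate: genome-scale size and redundancy, compartments and
transport mechanics, cofactor/redox bookkeeping beyond ATP, and any
regulatory layer. Passing the planted-truth suite therefore demonstrates
correctness of the algorithms, not predictive accuracy on real
genome-scale reconstructions.

`inject_gap()` plants a curation-style dead end by removing all consumers
of one seeded-chosen internal metabolite, with a candidate filter that
guarantees exactly one new dead end and preserved growth; the bare
8-reaction core has no such candidate and raises an explicit
"no candidate" error.

## Numerical and design choices

* Reversibility is encoded purely by `lower_bound < 0`; there is no
  separate flag to fall out of sync.
* Balance checking exempts exchanges, the biomass and EPS sinks and
  `DM_`/`SK_` ids (intentionally unbalanced pseudo-reactions); reactions
  whose metabolites lack formulas are `"unverifiable"`, never
  `"imbalanced"` - absent annotation is not evidence of error. Gap
  *detection* is in scope; automated gap *filling* is not, matching
  curation practice where fills are manual decisions.
* The GPR grammar is case-insensitive `and`/`or` with parentheses, AND
  binding tighter than OR; it matches SBML-FBC text renderings and is
  property-tested against exhaustive truth tables.
* SBML Level 3 + FBC v2 serialization is implemented directly on `xml2`
  (species, flux-bound parameters, gene-product association trees, an
  active objective, subsystem labels in notes); identifiers are encoded
  to SIds by prefixing and `__<code>__` escapes, the reversible
  convention of COBRA-style tools. The write/read round trip is the
  identity on every field the model carries, verified both internally
  and against an external FBA implementation in the test suite.
* Unbounded objectives are treated as model QC failures (a missing cap),
  never clamped silently; infeasibility always surfaces as a status.
* Report rounding: percentages to one decimal, counts exact; raw values
  are retained in the JSON serialization, and key order is fixed so
  identical inputs give byte-identical reports.
* The analysis surface is the package's exported functions plus the
  reproduction script under `scripts/`; no shell entry point is shipped,
  since the intended users drive these analyses from R.

## Problem sizes used in the shipped checks

The test suite and the reproduction script run entirely on generated
toys: 8-14 reaction cores where exhaustive vertex enumeration is the
oracle, and ~40-reaction EPS-bearing models for the screens - sizes
chosen so each property is checked against an independent brute-force
or closed-form computation. Genome-scale reproduction targets (model
member counts, subsystem shares, absolute essentiality counts) require
the original supplementary reconstruction file, which is not
redistributed here; with that file adapted through `read_model_table()`'s
column mapping, the same pipeline applies unchanged.

## Known limitations

Single deletions only (no double-knockout epistasis); quadratic MOMA only
(a linear-MOMA variant is a documented extension point); no flux
variability analysis, sampling, or thermodynamic constraints; no
regulatory constraints - all consistent with the scope of a
stoichiometric reconstruction analysis. The dense simplex is not meant
for models beyond a few thousand reactions; swapping in an external LP
backend behind `solve_lp()` would be the natural upgrade path.
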