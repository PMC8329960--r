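---
title: "Trilevel oncogene inference on metabolic networks: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trilevel oncogene inference on metabolic networks: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoflux)
```

## The question the package answers

Cancer cells reprogram metabolism. Given two context-specific genome-scale
metabolic models — one reconstructed from healthy tissue expression, one from
tumor expression — which single enzyme-encoding gene dysregulation, applied
to the *normal* model, moves its flux pattern closest to the *cancer*
pattern? A gene whose up-, down-regulation or knockout reproduces the
cancer-versus-normal fold-change pattern well is a candidate oncogene, even
when its own differential expression is modest.

The search is a trilevel optimization. The outer level chooses the gene
targets, the dysregulation mode, and a regulated strength $\delta \in (0,1]$.
The middle level simulates the mutant by flux balance analysis (FBA): maximize
the cellular objective $w_{ATP} v_{ATP} + w_{bio} v_{bio}$ over steady-state
fluxes $N(v_f - v_b) = 0$ within (mutated) bounds, with reversible reactions
split into non-negative forward/backward pairs. The innermost level resolves
the degeneracy of the FBA optimum by the *uniform flux distribution* (UFD):
among near-optimal solutions, the unique flux vector minimizing
$\sum_k v_{f,k}^2 + v_{b,k}^2$. Without this selection step, fold changes of
individual fluxes would be artifacts of whichever vertex the LP solver
happened to return.

## From fluxes to scores

Two observable families are compared between mutant and normal states:

* **Metabolite-flow rates** $r_m$ (flux-sums): the total synthesis rate of
  each base metabolite, pooled over its compartment instances — per
  instance, $\sum_{N_{ij}>0} N_{ij} v_{f,j} - \sum_{N_{ij}<0} N_{ij} v_{b,j}$.
* **Per-direction fluxes** $v_{f}$ and $v_b$ of every reaction.

Both are summarized as floored log2 fold changes,
$\mathrm{LFC} = \log_2(\max(x_{MU},\tau)/\max(x_{BL},\tau))$ with
$\tau = 10^{-6}$ flux units by default. The floor keeps every fold change
finite and total; its side effect is that genuinely-zero-to-zero components
report exactly 0, which is the intended "unchanged" reading.

The *template* is the same quantity computed between the cancer and normal
models (no dysregulation), with per-component fuzzy bounds spread by a
factor of 4: $[\mathrm{LFC}/4,\, 4\,\mathrm{LFC}]$ for increases and
mirrored for decreases. A mutant is scored two ways:

* **Similarity ratio** (qualitative): a per-component indicator is $+1$ when
  mutant and template both rise beyond $\log_2(1+\varepsilon)$, $-1$ when
  both fall below $\log_2(1-\varepsilon)$, else 0. Printed as a sum of
  indicators over components, matched decreases would *lower* a maximized
  ratio, which cannot produce the fraction-like values near 0.8–0.9 that
  concordant mutants should earn; the package therefore defaults to the
  `match_fraction` convention — a component counts when it matches in either
  direction or is unchanged on both sides — and keeps the literal signed
  mean behind `sr_convention = "literal"`.
* **Fuzzy-equal membership** (quantitative): a triangular membership
  function per component, 1 at the template fold change, falling linearly
  to 0 at the fuzzy bounds. A template component with zero fold change has
  degenerate bounds; it grades 1 exactly when the mutant is itself within
  the no-change tolerance, preserving "unchanged stays unchanged" where the
  triangle would divide by zero.

$\eta_S$ averages the two similarity ratios, $\eta_E$ averages the
membership grades, and the fitness combines a weighted-sum and a worst-case
decision: $\eta_D = [(\eta_S + \eta_E)/2 + \min(\eta_S, \eta_E)]/2$. By
default $\eta_E$ pools metabolite-flow and flux grades into one list;
`eta_e_pooling = "split"` averages the families separately first, since a
single reported $\eta_E$ per gene is compatible with either reading.

## Gene-to-bound translation

GPR rules are parsed to disjunctive normal form; each distinct AND-clause
becomes an integer pseudo-enzyme code, deduplicated across reactions. A
reaction is *isozyme-backed* with respect to a gene when its rule carries at
least one pseudo-enzyme not containing that gene. The isozyme set is
computed per gene (not per code): the operational question is whether the
network can still catalyze the reaction when this particular gene is
impaired, which is a property of the gene–reaction pair.

A dysregulation of strength $\delta$ rewrites bounds by interpolating
between the basal flux (the normal state's FBA+UFD solution, the unique
minimum-norm representative) and the bound extreme: upregulation forces
$v_f \ge (1-\delta)v_f^{basal} + \delta v_f^{UB}$, downregulation caps
$v_f \le (1-\delta)v_f^{basal} + \delta v_f^{LB}$, knockout pins both
directions at zero. Down and knockout leave isozyme-backed reactions
untouched; upregulation carries no exemption (over-expressing one isozyme
raises capacity regardless of the others); reaction-level targets bypass
the GPR table entirely. A gene maps to *all* reactions whose rule mentions
it. A reaction reached by two targets with opposing modes is an error; the
same mode from two genes applies the later target's strength.

## The outer search

Per-gene screening is one-dimensional in $\delta$ for each mode, so the
package enumerates modes exactly and optimizes $\delta$ by a coarse grid
(16 points, denser near 0 to catch low-strength optima) followed by
golden-section refinement around the grid optimum — deterministic and
cheaper than a population method in one dimension. Knockout needs no
strength. Infeasible mutants score 0 rather than raising, so screening
loops are total; combinations whose targets collide on a reaction with
opposing modes score 0 for the same reason.

Multi-gene search (K genes jointly) uses a hybrid differential evolution
over a mixed encoding: gene and mode indices are rounded from continuous
coordinates, strengths stay continuous. DE/rand/1/bin with crossover rate
0.8 and a per-generation mutation scale drawn from (0.1, 1.0), greedy
selection (hence a monotone best-so-far trajectory), a *migration* operator
that re-seeds the population around the incumbent when normalized diversity
drops below 0.05, and an *acceleration* operator that locally refines the
incumbent's strengths by a shrinking line search each generation. Default
population is 10 times the encoding dimension. These hyperparameters are
this package's declared choices for the hybrid-DE family; evaluations are
cached by (targets, modes, strength quantized to $10^{-3}$), below which
the inner quadratic program's numerical noise dominates anyway. For
$K = 1$ the encoding degenerates and the call delegates to the per-gene
screen.

## Interval (variability) analysis

FBA-based scores inherit the arbitrariness of alternate optima, and cancer
cells need not grow at the maximum rate. Metabolite-flow variability
analysis (MFVA) bounds each flux-sum over all steady-state flux vectors
retaining at least a fraction $\zeta$ of the objective, for $\zeta$ on a
grid (default $0.1, 0.2, \ldots, 1.0$). Each (metabolite, $\zeta$, sense)
bound is one LP on the linear production form of the flow rate; because the
feasible set only grows as $\zeta$ falls, a grid is exact for these linear
functionals and makes the LP count explicit, whereas treating $\zeta$ as a
continuous decision variable would add nothing. The minimum-norm (UFD)
layer is not imposed during bound computation: the extrema of a linear
functional over the FBA polytope do not depend on which interior point the
UFD would select, and the relaxation of the objective constraint is shared
with the UFD ($10^{-6}$ relative) precisely so the reported point always
lies inside its own interval.

Flow intervals map through the floored log2 fold change endpoint-wise
(log2 is increasing; no outward rounding beyond float arithmetic) and then
through the exact image of the triangular membership function: the maximum
grade is 1 when the interval straddles the template value, otherwise the
larger endpoint grade; the minimum is the smaller endpoint grade. Averaging
lower and upper grades componentwise gives the interval decision grade
$[\eta_{E,\min}, \eta_{E,\max}]$, which by construction contains the point
$\eta_E$. Stacking each mutant's flow intervals as a (lower, upper) column
pair, with the cancer model's own column appended, yields the flux-sum
bound matrix consumed by downstream multivariate analysis (the factor
analysis itself is out of scope here).

## The synthetic fixture: what it emulates, what it does not

`generate_toy_pair()` builds the smallest network exercising every code
path: a capacity-limited uptake, an AND-regulated entry step, an
isozyme-regulated ATP-producing branch in parallel with a plain branch (so
the minimum-norm program faces a genuine degeneracy), a reversible
two-compartment transport (so compartment pooling matters), a distal
synthesis step as the canonical planted target, a nested OR/AND side
branch, and separate ATP-maintenance and biomass drains for the two-term
objective (weights 0.5/0.5 by default — the weighting is a modeling choice
the package exposes rather than fixes). The "cancer" partner is the normal
model with the planted dysregulation's mutated bounds applied directly, so
ground truth is exact by construction rather than re-extracted; planted
targets are restricted to irreversible reactions so the mutated split box
collapses losslessly to net bounds. The default planted condition is a 50%
upregulation of the distal synthesis gene; the step's capacity equals the
uptake capacity so that the planted mutant remains feasible with slack
across the strength range. Generation is deterministic per seed, to the
byte, in the emitted SBML.

What passing on this fixture demonstrates: correctness of the bound
algebra, the inner LP/QP layers, compartment pooling, the scoring
machinery, and recoverability of a planted signal against decoys. What it
does not demonstrate: behavior on genome-scale models (thousands of
metabolites, dense GPR isozymy, thermodynamically infeasible loops, which
here inflate flux-sum upper bounds at permissive $\zeta$ since no loopless
constraint is imposed), nor anything about real expression-derived model
extraction, which this package deliberately consumes as finished SBML
inputs.

## Numerical choices

* **LP layer**: `boot::simplex` behind an internal wrapper that QR-reduces
  the (routinely rank-deficient) stoichiometric equality rows to a row
  basis, shifts variables so lower bounds become zero, and adds upper
  bounds as inequality rows. The wrapper is property-tested against a
  brute-force vertex-enumeration oracle.
* **QP layer**: `quadprog::solve.QP` (dual active-set); when only internal
  reactions enter the UFD norm, the remaining variables carry a $10^{-8}$
  ridge to keep the Hessian positive definite.
* **Objective relaxation**: the UFD and MFVA constrain
  $obj \ge \zeta\,obj^* - 10^{-6}\max(|obj^*|, 1)$; without the slack the
  quadratic program sits exactly on the LP optimum's face and the
  active-set method reports spurious inconsistency.
* **Tie-breaks**: rankings order by fitness, then membership grade, then
  lexicographic gene id; degenerate template components use the no-change
  band; bound mutation clamps basal fluxes into their original box before
  interpolating to absorb solver-level rounding.
* **Problem sizes**: the shipped tests and examples run networks of 6–11
  metabolites and about a dozen reactions, strength grids of 16–21 points,
  DE populations of a few dozen over tens of generations — sizes chosen so
  each claim is verifiable against exhaustive enumeration.

## Known limitations

* No loopless/thermodynamic constraints: internal cycles can inflate
  flux-sum upper bounds in MFVA at permissive growth fractions.
* The component universe for cross-model comparison is the intersection of
  base metabolites and of reactions present in both models; components
  exclusive to one model are excluded and counted in the template's
  coverage report, so every score discloses the universe it was computed
  over.
* Flux fold changes cover both directions of every shared reaction by
  default (`flux_directions = "active"` restricts to basally active ones);
  a direction blocked in both models contributes an exact zero.
* Transcript-level GPR (gene–transcript–protein–reaction) and enzyme
  kinetics are out of scope; rules are boolean.
* The per-gene screen is deterministic; the RNG seed only matters for the
  multi-gene differential evolution.
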