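---
title: "Constraint-based evaluation of metabolic models with fbakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based evaluation of metabolic models with fbakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbakit)
```

## The modelling framework

fbakit evaluates stoichiometrically constrained genome-scale metabolic
models (GEMs) of the kind distributed for budding yeast. A GEM is a set
of species (metabolites), a set of reactions with flux bounds and
gene-protein-reaction (GPR) rules, and a biomass objective. Flux balance
analysis (FBA) treats the cell at steady state: with stoichiometric
matrix $S$ (rows: internal metabolites, columns: reactions) and flux
vector $v$, it solves the linear program

$$\max_v \; v_{\text{biomass}} \quad \text{s.t.} \quad S v = 0, \quad
lb \le v \le ub .$$

The biomass flux is the proxy for growth rate. Everything else the
package does — deletion screens, auxotrophy classification, epistasis,
blocked-reaction detection — is a family of perturbed or repeated FBA
problems.

### Encoding conventions

The package follows the conventions of the yeast consensus models:

* Exchange reactions are written "reactant ->", with a boundary
  placeholder species (suffix `_b`) as formal product. Placeholders
  never enter $S$, so an exchange column carries a single $-1$ on its
  internal species: **positive flux exports, negative flux imports**.
  (The era's documentation also describes these columns as $+1$ entries,
  which is inconsistent with the stated sign semantics; the package
  encodes $-1$ so that the sign semantics — positive = produced — hold,
  which is what every downstream computation relies on.)
* Biomass is itself a species, produced by a pseudoreaction and drained
  by the biomass exchange, which serves as the objective.
* "isa" reactions (SBO term 395, "encapsulating process") map specific
  compounds into generic class species ("octanoate isa fatty acid") and
  must be irreversible, so generic species act only as sinks; a
  reversible isa reaction would interconvert chemically distinct
  compounds. `validate_conventions()` reports violations.
* Hypothetical constructs — biomass and lipid pseudoreactions,
  transport without a known transporter, exchanges — carry SBO term 397
  ("omitted process").

`read_sbml()`/`write_sbml()` handle both the COBRA-era SBML Level 2
dialect (kinetic-law bound parameters, `GENE_ASSOCIATION` notes) and
Level 3 `fbc` (structured gene-product associations); when both rule
encodings are present the structured one wins, because the notes field
is free text. Infinite bounds are kept explicit as $\pm\infty$
throughout — the solver handles them natively, so no large-number
substitute (the historical `1000` convention) is ever introduced, and
unboundedness is reported as such instead of masquerading as a large
finite optimum.

## The linear-programming core

No LP library is assumed: `lp_solve()` is a dense two-phase primal
simplex with bounded variables, written for the problem sizes this
package meets (tens to a few hundred reactions). Design points that
matter for reproducibility:

* **Tolerances.** Feasibility/optimality tolerance $10^{-9}$ (absolute)
  at the solver; package-level contract checks use $10^{-6}$.
* **Determinism.** Entering variables are chosen by Dantzig's rule with
  smallest-index tie-breaks, switching to Bland's rule after $3(n+m)$
  iterations so degenerate problems terminate; for a fixed problem the
  pivot sequence, and hence the returned vertex, is deterministic.
* **Rank deficiency.** Mass-balance matrices carry redundant rows
  (conserved moieties); phase-1 artificials that stay basic at zero are
  frozen rather than treated as errors.
* **"No growth" vs infeasible.** A model that admits $v = 0$ but cannot
  produce biomass is reported `optimal` with objective 0, so screens can
  compare against a threshold; `infeasible` is reserved for genuinely
  empty feasible sets (e.g. a forced flux that deletions cut off).

The test suite cross-checks the simplex against an independent
brute-force oracle that enumerates all basic solutions of small random
networks (up to 12 reactions, all bounds finite) — two implementations
sharing no code, required to agree on 100 seeded fixtures.

### Geometric FBA

FBA optima are routinely degenerate: alternate optimal flux
distributions form a face of the polytope. For any quantity defined
"relative to wild-type flux" a canonical representative is needed.
`geometric_fba()` fixes the objective at its optimum, then iterates:
flux variability analysis (FVA) delimits the current optimal box; the
summed absolute deviation ($L_1$; the norm is a package choice, the
procedure's description leaves it implicit) from the box midpoints is
minimized; the minimal total deviation is frozen as a constraint; and
the process repeats until the box's maximal width falls below $10^{-6}$
(cap: 50 iterations; convergence is typically 1–3). Every step's
feasible set is defined by problem data only, so the result is invariant
under reaction reordering and solver restarts — verified to $10^{-5}$ in
the tests. An unbounded optimal face is an error instructing bound
tightening, not a silent clamp.

## Perturbations

* **Media** (`medium_spec()`, `apply_medium()`): listed exchange bounds
  are replaced; every unlisted exchange is closed to uptake but left
  open to export. A "supplemented" medium (`open_medium()`) opens every
  exchange to uptake at a configurable magnitude — the package's
  operationalization of the loosely specified "supplemented/maximal"
  media used in auxotrophy work. Opening the biomass exchange to uptake
  is harmless: imported biomass cannot raise the export flux being
  maximized.
* **Deletions** (`apply_deletions()`): a reaction is disabled (bounds
  (0,0)) exactly when its GPR rule evaluates false under the deletion
  set; AND joins complex subunits, OR joins isoenzymes, and reactions
  without gene association are untouchable.
* **Anaerobic transform** (`anaerobic_transform()`): closes oxygen
  uptake, opens the supplement exchanges (sterols and phosphatidate in
  yeast), disables the aerobic lipid pseudoreaction and enables the
  anaerobic variant — switching the biomass definition, since the
  aerobic lipid recipe requires oxygen-dependent sterol synthesis.
* **Flux restriction** (`restrict_gene_flux()`): each reaction carrying
  the gene has its bounds intersected with $[-f|v^*|, +f|v^*|]$, where
  $v^*$ is the geometric-FBA reference flux. The default is symmetric
  about zero because the underlying protocol says only that flux is
  "limited by a fixed amount"; a sign-preserving mode
  ($[0, f v^*]$ or $[f v^*, 0]$) is available behind a flag. At $f = 0$
  the restriction equals deletion; at $f = 1$ it never relaxes an
  existing bound.

The viability threshold is relative: a perturbed model is viable when
its objective exceeds $10^{-6}$ times the wild-type objective
(configurable; the source protocols state no threshold, and any
reasonable value classifies identically on the fixtures because
perturbed optima are either 0 or a sizable fraction of wild type).

## Essentiality and auxotrophy metrics

`single_deletion_screen()` + `score_essentiality()` follow the
convention in which **positive = predicted growth**. With curated lists
of essential and auxotroph-inducing genes as the condition (both count
as condition-negative, i.e. expected not to grow on minimal medium):

| | gene unlisted (inessential) | gene listed |
|---|---|---|
| predicted growth | TP | FP |
| predicted no growth | FN | TN |

Derived metrics are sensitivity $tp/(tp+fn)$, specificity
$tn/(tn+fp)$, positive/negative predictive values, and
`combined_accuracy` = sensitivity × specificity. The last is reported in
parts of the literature under the name "geometric mean" although the
printed values follow the plain product of the two (rounded)
percentages; the package implements and documents the product.

`auxotrophy_screen()` runs each deletion on a minimal and a supplemented
medium and classifies into three mutually exclusive categories:
`auxotroph_confirmed` (no growth minimal, growth supplemented — the
expected auxotroph signature), `viable_in_minimal`, and
`inviable_in_supplemented` (the model wrongly predicts the deletion
cannot be rescued by any supplementation).

## Epistasis

Genetic interactions are quantified with the nonscaled multiplicative
definition $\epsilon = W_{xy} - W_x W_y$, where fitness $W$ is maximal
biomass production relative to wild type. Perturbation is fractional
flux restriction (above) rather than outright deletion, so essential
and inessential genes are both informative. `pairwise_screen()`
computes the geometric-FBA reference once, then $W$ for every gene and
$W_{xy}$ for every unordered pair; a reaction annotated to both genes
of a pair is capped once — bounds are set, not compounded, so the joint
restriction is well defined and symmetric, and symmetry
$\epsilon(x,y) = \epsilon(y,x)$ is re-verified explicitly in the tests.

Because $\epsilon$ is compared against exact zero only up to numerics,
an interaction is counted when $|\epsilon| > 10^{-4}$; the count is
re-reported at a tenth and ten times that cutoff
(`counts_by_tolerance`) so its sensitivity to the choice is visible.
`restriction_profile()` repeats the screen over a grid of restriction
levels — default 0 % to 90 % of wild-type flux in 10 % steps, reading
the protocol's abbreviated "(0%, 10%, 90%)" as that full grid — and
tabulates counts per level. Long screens are chunked through a
deterministic, resumable checkpoint file.

Two instructive regimes on the built-in fixtures: serial genes on a
sole pathway at half restriction give $W_x = W_y = W_{xy} = 0.5$, hence
$\epsilon = +0.25$ (alleviating: the second restriction is invisible
behind the first); a redundant-branch gene paired with an unrelated
sole-pathway gene gives $\epsilon = 0$; and the two members of a
redundant isoenzyme pair give $\epsilon = -0.5$ (aggravating: each is
harmless alone, jointly they halve capacity).

## Reconstruction derivation and blocked reactions

`derive_reconstruction()` separates the evidence-only network
reconstruction (GENRE) from the model (GEM): reactions annotated SBO
395 or 397 are removed, all remaining bounds are stripped (direction
constraints are modelling assumptions), and orphaned species — boundary
placeholders, biomass, any metabolite left without a reaction — are
pruned. The gene set is recomputed from the surviving rules rather than
assumed unchanged. The operation is idempotent, and a model with no SBO
annotation at all is rejected: deriving from it would silently return
the input, which is almost certainly a mistake.

`blocked_reactions()` flags reactions whose FVA range is exactly (0, 0)
with the objective unconstrained. The default exchange regime opens
every exchange in both directions, so the blocked set reflects
structural gaps in the network rather than medium choices (the regime
is recorded on the result and a medium may be supplied instead).
Opening exchanges can only shrink the blocked set; the tests check this
monotonicity.

## The synthetic fixtures: what they do and do not show

The package ships three generators used throughout its tests and its
acceptance script:

* `chain_model(L, u)` — a linear pathway whose optimum ($= u$), deletion
  responses (all essential) and restriction responses (fitness $= f$)
  are known in closed form.
* `branched_model()` — isoenzyme redundancy (OR), an enzyme complex and
  cofactor loop (AND + regeneration), oxygen-dependent sterol synthesis
  with an importable rescue (the auxotroph motif), two lipid
  pseudoreactions with an aerobic/anaerobic biomass switch, and "isa"
  class mappings, each annotated with the SBO terms the derivation
  relies on. Aerobic optimum 5, anaerobic (transformed) 10, all
  verifiable by hand.
* `random_feasible_model(seed)` — a seeded random flow network built
  around an explicitly constructed feasible flux, so the optimum is
  provably positive and small enough (≤ 12 reactions, finite bounds)
  for brute-force vertex enumeration to serve as an oracle.

These fixtures emulate the *mechanisms* a genome-scale model exercises —
degenerate optima, GPR logic, media dependence, pseudoreaction
annotation — at sizes where every expected value is computable
independently. They do not emulate the statistics of real networks:
thousands of reactions, conserved-moiety rank deficiency at scale,
extensive pleiotropy, or the biological gene lists. Passing tests
therefore demonstrate correctness of the algorithms, not predictive
accuracy on an organism; the latter requires the distributed model
files, which the evaluation pipeline accepts unchanged (see the test
suite's final acceptance block) but which are not shipped here.

Problem sizes were chosen so the full suite runs in well under a minute
of LP time: 100 random fixtures for the solver-versus-oracle law, and a
30-gene multi-module network (435 pairs) for the desk-scale epistasis
screen with checkpointing. A genome-scale pairwise screen (~420 000
LPs for 918 genes) is a long-running batch job; the chunked checkpoint
mechanism exists for exactly that use.

## Known limitations

* The simplex is dense; models beyond a few thousand reactions would
  want a sparse factorizing solver.
* Geometric FBA accumulates one constraint block per iteration; on
  models with very wide optimal faces memory grows with iteration count
  (in practice convergence takes a handful of iterations).
* No regulatory constraints, kinetic rate laws, thermodynamic
  (loopless) analysis beyond the directionality bounds, or
  temperature-dependent phenotypes — all outside the constraint-based
  evaluation scope.
* The SBML writer emits the Level 2 COBRA dialect only (the reader
  accepts Level 3 `fbc` as well); annotation coverage is limited to SBO
  terms, ChEBI and PubMed MIRIAM URIs.
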