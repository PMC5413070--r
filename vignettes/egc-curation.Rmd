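---
title: "Detecting and removing energy-generating cycles in metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and removing energy-generating cycles in metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Flux-balance analysis (FBA) treats a metabolic network as a linear program:
steady-state fluxes $v$ satisfy $S v = 0$ for the stoichiometric matrix $S$,
each flux is boxed by bounds $v^{\min} \le v \le v^{\max}$, and an objective
such as the biomass reaction is maximized.  FBA carries no thermodynamics, so
a reconstruction can contain **energy-generating cycles (EGCs)**: sets of
internal reactions that, with every exchange closed, still charge an energy
currency — regenerating ATP from ADP, NADH from NAD⁺, or pumping protons
across a membrane — out of nothing.  A classic example is a pair of
transporters that move the same metabolite with different proton
stoichiometries; running one against the other builds a gradient for free.
EGCs are distinct from futile cycles, which *consume* energy and are
thermodynamically unremarkable: an EGC is a futile cycle run backwards.
Models with EGCs overestimate biomass yields (energy is free) and mislead any
downstream analysis that touches energy metabolism.

`egctools` implements two operations around this failure mode:

1. **Detection** — a per-currency linear program that certifies whether any
   cycle can charge that currency.
2. **Correction** — a globally minimal set of *unidirectional reaction
   deactivations* that eliminates every cycle while preserving biomass
   production, found by a bi-level program reformulated to a single
   mixed-integer level.

```{r, eval = FALSE}
library(egctools)
m   <- load_model("model.xml", namespace = "bigg")
m   <- normalize_model(m)
md  <- attach_dissipation(m)
rep <- detect_egc(md)
sol <- solve_correction(build_bilevel(md, split_reversibles(md)))
```

## Detection

### Energy-dissipation reactions

For each of fifteen energy currencies — ATP, CTP, GTP, UTP, ITP, NADH, NADPH,
FADH₂, FMNH₂, ubiquinol-8, menaquinol-8, 2-demethylmenaquinol-8, acetyl-CoA,
L-glutamate, and the transmembrane proton gradient — an irreversible
**energy-dissipation reaction** is attached, e.g.

```
atp + h2o  ->  adp + pi + h          (ATP)
nadh       ->  nad + h               (NADH)
h[periplasm] -> h[cytosol]           (proton gradient)
```

The redox templates deliberately omit the electron acceptor: with an acceptor
present, internal cofactor regeneration could re-capture the electrons and
the reaction would carry flux even in a healthy model.  The price is that
these reactions are not electron-balanced — they exist only as measuring
devices and are exempted from the balance screen.  The catalog shipped in
`inst/extdata/dissipation_catalog.tsv` is this package's own curation: it
takes the ATP and NADH forms above as canonical and extends the same
hydrolysis/deprotonation pattern to the remaining currencies; it is fully
user-replaceable.  One curation choice worth flagging: currency lists in the
field sometimes name ubiquinol-8 twice; this catalog carries menaquinol-8 as
a distinct entry, consistent with the menaquinone-driven example cycle among
the fixtures.

Templates are written over namespace-neutral species keys and resolved
against the model through a synonym table covering BiGG, ModelSEED and
MetaNetX identifiers, with compartment-suffix matching and a preference for
the cytosol.  The **integration** of a template is the fraction of its
metabolites present in the model; a template with integration below 1
references a species the model lacks, can never carry flux, and is reported
as "not integrated" rather than attached.

### The detection program

For each attached dissipation reaction $d$:

$$\max v_d \quad \text{s.t.} \quad S v = 0,\qquad v_i = 0 \;\; \forall i \in E,$$

where $E$ is the set of exchange reactions, and every network reaction other
than the dissipation reactions is clamped to $[-1,1]$ (reversible) or
$[0,1]$ (irreversible), intersected with its own bounds.  Zero flux is always
feasible, so $v_d^{\*} \ge 0$; any $v_d^{\*} > 0$ certifies at least one
cycle charging currency $d$.  Because cycles run at their flux ceilings, with
unit clamps $v_d^{\*}$ is additionally a lower bound on the number of
*non-overlapping* cycles for that currency (`count_lower_bound()`).  One
caveat, surfaced by the transporter-triangle fixture: a cycle whose
stoichiometry yields fractional energy per turn (four translocated protons
per ATP gives $v_{ATP}^{\*} = 0.25$) produces a bound below one even though a
cycle exists; the value is reported as-is, never floored, and `has_egc` uses
the positivity test, not the magnitude.

An aggregate pre-screen maximizing $\sum_d v_d$ is solved alongside the
per-currency programs and stored on the report; it is cheaper for batch
triage while the per-currency optima remain the primary output.

Before detection, `normalize_model()` (i) rewrites every exchange into the
secretion convention (negative flux = uptake), a pure sign relabelling that
provably leaves the flux polytope unchanged, and (ii) relaxes the lower bound
of the ATP maintenance reaction to zero, so no obligatory ATP regeneration is
demanded while all uptakes are closed.  Both actions are recorded in a change
log.

## Correction

### The bi-level view

Let $\delta^{RF}_y, \delta^{RB}_y \in \{0,1\}$ indicate removal of the
forward or backward direction of reaction $y$ (reversible reactions are two
independent unidirectional candidates; exchanges and dissipation reactions
are never candidates).  The search contrasts two cases sharing the binaries:

* **growth case**: $S v^g = 0$, bounds gated as
  $v^{\min}_y (1-\delta^{RB}_y) \le v^g_y \le v^{\max}_y (1-\delta^{RF}_y)$
  with all exchanges opened to a rich medium, and biomass
  $v^g_{Bio} \ge T_g$;
* **non-growth case**: $S v^{ng} = 0$ with all exchanges closed and the
  detection clamps, in which the *maximal* summed dissipation flux
  $\max c^\top v^{ng}$ must equal zero ($c$ selects the dissipation
  reactions).

The outer objective minimizes $\sum_y w_y (\delta^{RF}_y + \delta^{RB}_y)$.
Uniform weights $w_y = 1$ treat every removal as equally likely; the weight
table accepts per-direction values for curators who prefer to spare, say,
irreversible reactions or thermodynamically well-supported ones.  (The
printed form of the inner condition in the source literature reads as a
minimization; the accompanying text demands the *maximal* dissipation flux be
zero, which is the condition implemented — a zero minimum is trivially
attained at $v^{ng}=0$ and would constrain nothing.)

### Single-level reformulation

The inner maximization is an LP, so it is replaced by its dual.  Requiring a
dual-feasible point with dual objective $\le 0$ pins the inner maximum at
zero by weak duality (zero is attained at $v^{ng} = 0$).  The dual objective
is

$$\sum_y \alpha_y\, u_y (1-\delta^{RF}_y) \;+\; \sum_y \beta_y\, (-l_y)(1-\delta^{RB}_y),$$

with $\alpha, \beta \ge 0$ the bound duals and $u_y \ge 0$, $l_y \le 0$ the
clamped non-growth bounds.  Every term is a product of nonnegative factors,
so "dual objective $\le 0$" is equivalent to every term vanishing — and the
usual big-M product linearization collapses to plain gating constraints:
$\alpha_y \le M\,\delta^{RF}_y$ where a forward candidate exists,
$\alpha_y = 0$ on non-candidates with $u_y > 0$, and symmetrically for
$\beta$.  The dual-feasibility rows
$S^\top \mu + \alpha - \beta = c$ (metabolite potentials $\mu$ free within
$[-M, M]$) complete the certificate: for an EGC-free assignment they are
exactly a discrete "no downhill cycle" potential argument.  $M = 1000$ by
default, scaled to the unit clamps that keep duals small.

Big-M truncation is the classic failure mode of such reformulations, so no
solution is ever trusted from the MILP alone: `solve_correction()` re-solves
all fifteen detection LPs and the rich-medium growth LP on the constrained
model and reports `certified_egc_free` and `growth_ok` from those plain LPs.
The test suite additionally enumerates *every* binary assignment on each
fixture and verifies that the single-level program is feasible exactly when
the two underlying LPs say so.

Removals are applied by constraining the affected bound to zero — never by
deleting the reaction — so a curator can re-enable a direction in
environments where it is thermodynamically plausible.

### Protocol details

* **Growth threshold** $T_g$: the published method leaves the value open;
  the default is 1% of the unmodified model's rich-medium biomass optimum
  (configurable, relative or absolute).  A threshold above the attainable
  optimum is rejected before solving.
* **Two-pass search** (`run_two_pass()`): the cheapest fix frequently removes
  the ATP synthase, which also abolishes respiratory ATP production.  Pass
  two repeats the search with synthase id/name patterns protected; both
  results are reported side by side.
* **Alternatives** (`enumerate_alternatives()`): equally minimal removal sets
  are enumerated by pinning the objective and adding no-good cuts, giving
  curators a choice among mathematically equivalent fixes.
* **Determinism**: ties between equal-weight optima are broken by a tiny
  index-ordered perturbation ($10^{-6}$ per candidate rank), so repeated runs
  return identical sets.
* **Non-growth flux variables**: the growth case carries the dissipation
  reactions with open bounds (they cannot help biomass); the non-growth
  primal variables are retained in the program for transparency even though
  the dual certificate alone is binding.

## Solvers

No linear- or integer-programming library is part of this package's
dependency footprint; the optimisations run on a self-contained dense
two-phase simplex (`lp_solve()`) with Bland's-rule anti-cycling, and a
depth-first branch-and-bound (`milp_solve()`) that explores the zero branch
first (removal sets are small).  This is adequate because every program in
the intended workflow is small: toy fixtures, reduced models, and removal
programs with tens of binaries.  The solvers are validated in the test suite
against `boot::simplex` on random programs and against exhaustive
enumeration of binary assignments.  For genome-scale correction work an
industrial MILP solver would be preferable; the program object produced by
`build_bilevel()` exposes its full constraint system (`A`, `dir`, `rhs`,
bounds, integer indices) precisely so it can be handed to one.

## What the synthetic models emulate — and what they do not

`make_fixture()` reconstructs the published worked cycle motifs as minimal
models: the symporter/uniporter proton pump, the malate–sodium–proton
triangle driving a synthase (0.25 ATP per turn), the tartrate antiporter
chain, the menaquinone loop closed by a four-enzyme chain, the paired
adenylyltransferases charging a spare GTP, plus cycle-free and two-pathway
controls and a sodium-synthase trap for the two-pass protocol.  Two
liberties are documented rather than hidden: fixture stoichiometries include
explicit proton bookkeeping so that cycles balance at steady state (the
published figures omit protons), and the menaquinone loop is qualitative —
its ground truth comes from enumeration on the fixture itself, not from the
source organism's reconstruction.  `make_random_egc_model()` composes a
viable linear backbone with planted cofactor-mismatch or transporter-mismatch
motifs and tree-shaped filler that provably cannot close cycles.

What passing tests on these models shows: the detection LP agrees with
exhaustive cycle enumeration, the MILP finds provably minimal cuts, and the
certificates hold.  What it does not show: behaviour on genome-scale
networks with thousands of reactions, mass/charge-imbalanced stoichiometry
(the balance screen flags but does not repair — imbalanced reactions can
fake or mask cycles and should be fixed upstream), multi-compartment
eukaryotic transport complexes, or identifier quirks of real database
exports beyond the synonym table's coverage.

## Numerical choices

| Quantity | Default | Why |
|---|---|---|
| flux clamp | 1 | unit clamps make $v_d^*$ a cycle-count bound |
| zero tolerance | $10^{-6}$ | LP noise is ~$10^{-9}$; optima in between are flagged "numerically zero", not silently dropped |
| rich medium | exchange bounds $\pm 1000$ | the de-facto "unbounded" convention in published models; the uptake magnitude is configurable |
| viability threshold | $10^{-6}$ | any genuinely positive optimum passes; zero-growth models are excluded from correction |
| balance tolerance | $10^{-6}$ per element | published models carry floating-point coefficients |
| big-M | 1000 | bounds duals under unit clamps; guarded by the post-hoc certificate |
| simplex pivot tolerance | $10^{-9}$ | dense tableau at toy-model scale |

Test-suite problem sizes: fixtures of 6–13 reactions, fifty seeded random
models of 20–60 reactions, and full $2^{\le 9}$ binary enumerations per
fixture — sizes chosen so that every optimisation result in the suite is
paired with an exhaustive or independent check.

## Known limitations

* Removal is the only repair: reaction additions that might restore growth
  after aggressive cuts are out of scope (they risk inventing capabilities
  and need manual review), so models whose every cycle-breaking cut also
  kills biomass are reported `no_removal_correction`.
* Thermodynamically constrained FBA variants (TMFA-style concentration
  bounds, loopless formulations) are not implemented; correcting the model
  itself keeps downstream FBA tooling unchanged.
* Mass/charge imbalance is flagged (`check_balance()`), never repaired.
* The synonym and synthase-pattern tables are curated defaults; unusual
  identifier schemes require user-supplied tables.
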