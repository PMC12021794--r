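---
title: "Refining Boolean models with partial most-permissive dynamics"
author: "mrbm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining Boolean models with partial most-permissive dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrbm)
```

## The problem

Logical models describe a regulatory network as `n` components, each with a
Boolean activity level and a logical rule giving its target level as a
function of the state `x in {0,1}^n`.  Under the *asynchronous* updating
scheme one component at a time moves one step toward its target, producing a
non-deterministic state transition graph (STG) whose terminal strongly
connected components are the attractors — fixed points when they are single
states.  In differentiation models, fixed points are typically identified
with cell fates, and whether a fate is reachable from a given transient
state is a central prediction.

Boolean abstraction is coarse: a regulator is either fully absent or fully
present, and all regulations exerted by one regulator engage and release
together.  A *multivalued* model, where some components have levels
`0 ... m`, can separate such effects by letting different regulations engage
at different activity thresholds.  The practical question this package
addresses is: **given a Boolean model whose asynchronous dynamics misses a
fixed-point reachability, which (few) components should be multivalued, and
with which thresholds, so that the reachability reappears?**

## Updating schemes

Three schemes on a Boolean model `f` are implemented.

* **Asynchronous** (`buildSTG(model, "asynchronous")`): from `x`, one
  component `j` with `x_j != f_j(x)` moves one step toward `f_j(x)`.

* **Most permissive** (`"mp"`): every component ranges over `{0, 1, i, d}`,
  where `i` ("increasing") and `d` ("decreasing") are transient levels a
  component passes through on its way up or down.  A component at a
  transient level may be *read* by any rule as either 0 or 1: writing
  `gammaStates(x)` for the Boolean states obtained by freeing every
  transient coordinate, component `j` may start increasing (`0`/`d` to `i`)
  when `f_j(x') = 1` for some reading `x'`, start decreasing (`1`/`i` to
  `d`) when `f_j(x') = 0` for some reading, and commit `i -> 1` or `d -> 0`
  at any time.  This scheme over-approximates every consistent refinement
  of the Boolean abstraction: whatever a finer quantitative or multivalued
  realization could do, the most-permissive STG contains a corresponding
  trajectory.

* **Partial most permissive** (`"partial"`, with a component set J): the
  members of J follow the most-permissive rules; every other component
  stays Boolean and jumps `0 <-> 1` directly when some reading licenses the
  jump.  `J = {}` is exactly the asynchronous scheme and `J = all` exactly
  the most-permissive scheme, state by state.

Three structural facts make the partial scheme useful as a *localization*
device, and are enforced as tested invariants of the package:

1. fixed points are the same under every scheme;
2. trajectories are monotone in J: every Boolean-to-Boolean reachability of
   the `J1` system holds in the `J2` system whenever `J1` is a subset of
   `J2` (in particular asynchronous trajectories persist in every partial
   system, and all partial trajectories persist most-permissively);
3. the `J`-partial dynamics contains every corner-to-corner trajectory of
   every multivalued refinement whose multivalued set is J (completeness).

Because basins grow monotonically with J, comparing basin sizes across
schemes — always counted over Boolean states only, as a percentage of
`2^n`, so the numbers are comparable — reveals *where* reachability is
lost: if a property holds most-permissively but not asynchronously, some
minimal J already recovers it partially.

## Multivalued refinements by per-clause thresholds

A multivalued model `h` on `X = prod {0..m_j}` *refines* `f` when every
unit move of `h` is licensed by the Boolean model under the reading map
`alphaStates()`: a coordinate at level 0 reads as 0, at `m_j` as 1, and
interior levels read as either value.  Concretely, `h_j(x) > x_j` requires
some reading `x'` with `x'_j = 0` and `f_j(x') = 1`, and symmetrically for
decreases.  `isRefinement()` checks this exhaustively and returns a
witnessing `(state, component)` on failure.

The package constructs refinements from a Boolean base by thresholding:
each occurrence of a multivalued regulator `g` in a clause of a target's
canonical DNF gets a threshold `s in {0 .. m_g - 1}`; a plain literal
becomes "level of `g` at least `s + 1`", a negated one "level of `g` at
most `s`".  The *tendency* `H_k(x)` of target `k` is `+1` where the
rewritten rule holds, `-1` elsewhere, and the update steps one level in
that direction, clamping at `0` and `m_k`.  At corner states the
thresholded literals collapse to the Boolean ones, so corner fixed points
correspond one-to-one with the fixed points of the base — `cornerToBoolean()`
and `booleanToCorner()` implement the bijection.

Two structural rules are enforced at construction time; both stem from the
fact that the tendency is forced to be `+1` or `-1` everywhere (the model
may never "pause" a component at an interior level):

* **No self-regulated multivalued components.**  If `j` occurs in its own
  rule, there are interior levels where the only clause driving `H_j = +1`
  contains the positive self-literal; a licensing reading would need
  `x'_j = 0` while the clause needs `x'_j = 1`, so no valid refinement with
  forced tendencies exists.  (Self-*inhibited* components are excluded from
  the search anyway, because multivaluing them changes the attractor
  structure; the constructive exclusion here extends to self-activation.)

* **Consistent thresholds on dual regulations.**  When a regulator acts on
  one target with both polarities (a dual edge), a positive-occurrence
  threshold above a negative-occurrence threshold leaves a *dead zone*: an
  interior level at which no thresholded clause is active although every
  Boolean reading satisfies the target's rule, so the forced `-1` tendency
  cannot be licensed.  Requiring every positive-occurrence threshold to be
  at most every negative-occurrence threshold per (regulator, target)
  removes the dead zone, and then validity is provable: for a decrease,
  pick in each inactive clause a thresholded-false literal and read its
  regulator accordingly (`0` for a positive literal at level `<= s`, `1`
  for a negated literal at level `>= s + 1`); the consistency rule
  guarantees these per-regulator choices never conflict, and the resulting
  reading falsifies the whole rule.  For an increase the single active
  clause fixes a conflict-free reading directly.  `buildRefinement()`
  rejects gapped dual assignments and `enumerateThresholdAssignments()`
  omits them; every refinement the package constructs passes
  `isRefinement()` by design, and the test suite asserts this on seeded
  random models.

## The minimal-set search

`mrbmSearch()` operationalizes the localization idea:

1. **Preconditions** (`checkPreconditions()`): at least two fixed points
   and no cyclic attractor in the asynchronous STG.  Cyclic attractors are
   scheme-dependent, so basin comparison across schemes is not meaningful
   for them; the search refuses to run (unless forced).
2. The property must hold under the full most-permissive dynamics —
   otherwise no refinement can restore it, and the search stops with an
   error saying so.
3. Sizes `l = 0, 1, 2, ...` are tried in order over the *admissible*
   components (neither outputs nor self-inhibited,
   `admissibleComponents()`), enumerating all subsets of each size
   lexicographically and testing the property in each partial system.  The
   search stops at the first size with satisfying sets and returns **all**
   of them, plus a complete audit log (`searchLog()`) from which minimality
   can be re-checked.

Properties are reachability of a target fixed point from an initial state
(`reachProperty()`, `reachSetProperty()`) or basin-size equality with the
most-permissive reference (`basinEqualProperty()`), both with a JSON
serialization for scripting.

`exhaustiveParameterization()` then turns a satisfying J into concrete
refinements, favouring parsimony: first every member of J at `m = 2`
(three levels), then — only if no assignment works — one component at a
time raised to `m = 3`, enumerating all consistent threshold assignments
at each stage and keeping those whose asynchronous dynamics satisfies the
property.  An exhausted schedule returns an empty result rather than an
error: persistent failure usually indicates the base model itself is
incomplete.

## Worked example

The built-in three-component model (`toyModel()`) has rules

```{r rules}
toy <- toyModel()
for (g in componentNames(toy)) cat(g, ",", ruleString(toy, g), "\n")
```

with fixed points `011` and `101` and no cyclic attractor.  The basin
sizes under the five schemes of interest:

```{r basins}
schemes <- list(asyn = buildSTG(toy, "asynchronous"),
                mp = buildSTG(toy, "mp"),
                g1 = buildSTG(toy, "partial", mpComponents = "g1"),
                g2 = buildSTG(toy, "partial", mpComponents = "g2"),
                g3 = buildSTG(toy, "partial", mpComponents = "g3"))
sapply(schemes, function(ts)
  c(`101` = basinSizePercent(basin(ts, "101")),
    `011` = basinSizePercent(basin(ts, "011"))))
```

The basin of `101` is insensitive to the scheme (87.5%), while the basin
of `011` grows from 50% (asynchronous) to 75% (most permissive): the
asynchronous dynamics loses reachabilities of `011`, among them the
trajectory from `010`.  The basin-equality search returns a unique
minimal singleton:

```{r search}
mrbmSearch(toy, basinEqualProperty("011"))
```

Annotating the shortest `{g1}`-partial trajectory from `010` to `011`
shows *why* g1 must be multivalued — g3 switches on while g1 is still
rising (reading it as present), then g2 switches on while g1 is at the
same transient level (reading it as absent):

```{r path}
annotatePath(schemes$g1, "010", "011")
```

The ad-hoc reading of this path: the activation g1 -> g3 must engage at a
lower activity than the inhibition g1 -| g2 releases.  With three levels
on g1 that means activation threshold `s = 0` (active from level 1) and
inhibition threshold `s = 1` (inhibiting only at level 2):

```{r refinement}
ref <- buildRefinement(toy, "g1", maxLevels = 2, thresholds = c(1, 0))
ref
isRefinement(ref, toy)
refinementFixedPoints(ref)
evaluateRefinementProperty(ref, reachProperty("010", "011"))
basinSizePercent(basin(buildSTG(ref), booleanToCorner(ref, "011")))
```

The refinement's corner fixed points `011` and `201` map to the base fixed
points, the lost trajectory is restored, and the basin of `011` reaches
the most-permissive 75%.  `exhaustiveParameterization(toy, "g1",
reachProperty("010", "011"))` finds the same assignment among the
satisfying ones at the first (three-level) stage.

### The partial scheme is an envelope, not a prediction

The partial dynamics deliberately over-approximates refinements: along a
single trajectory a transient J-component may be read as absent by one
rule and *later as present by another, including readings that disable a
rule*.  A threshold refinement has no such freedom — an interior level
satisfies positive and negative occurrences according to its fixed
thresholds.  The model above separates the two notions cleanly: with
`J = {g2}` the partial system does reach `011` from `010` (basin 62.5%),

```{r envelope}
isReachable(schemes$g2, "010", "011")
basinSizePercent(basin(schemes$g2, "011"))
```

yet *no* three-level threshold refinement of g2 reproduces this — both
assignments stay at the asynchronous 50% with `010 -> 011` unreachable
(this is asserted in the test suite).  Consequently, reachability searches
(`reachProperty`) can return partial sets whose exhaustive
parameterization then fails; the basin-equality property is the more
selective criterion here, and indeed returns `{g1}` uniquely while the
plain reachability search returns both `{g1}` and `{g2}`.  Users should
treat a satisfying J as a candidate to be confirmed by
`exhaustiveParameterization()`, not as a guarantee.

## The random-model generator

`randomModel(generatorConfig(...))` samples rules directly in DNF — one or
two clauses of up to three literals, negations with probability 0.3 by
default — which matches the clause structure the threshold machinery
operates on and keeps regulatory densities in the range typical of
published small logical models.  Seeding makes every model reproducible,
`forbidSelfInhibition` (default) re-samples rules inducing negative or
dual self-edges so that generated models have admissible components, and
`requireFixedPointsOnly` rejection-samples models until the asynchronous
attractors are all fixed points, emulating the precondition of the search.

The generator emulates *structure*, not biology: it produces no input
stimuli held constant, no layered signalling topology, and no bias toward
canalizing rules.  Passing property suites on generated models therefore
demonstrates the scheme identities (fixed-point invariance, trajectory
monotonicity, degeneration at `J = {}` and `J = all`, refinement validity
and completeness) on a broad sample of small dense networks — it does not
by itself validate predictions on any particular biological model.  The
test suites run these invariants on fifty seeded models of dimensions 3-6,
with exhaustive state-space enumeration throughout; those sizes keep every
closure computation exact while exercising all code paths.

## Numerical and design choices

* **State strings** order coordinates by declaration order; alphabets are
  `{0,1}`, `{0,1,i,d}` (transient levels), or digits `0..m` (multivalued,
  `m <= 9`).  All state sets and successor lists are radix-sorted, so
  every operation — including BFS tie-breaking in `annotatePath()` — is
  deterministic and locale-independent.
* **Canonical DNF**: negation-normal form, distribution, removal of
  contradictory clauses, absorption, literals sorted per clause, clauses
  sorted by their literal strings.  Clause indices in threshold files
  refer to this order, making it part of the file contract.
* **Explicit graphs** with a default cap of `2^22` states; exceeding the
  cap raises a distinct capacity error (never silent truncation).  Full
  most-permissive systems have `4^n` states, so models beyond roughly
  `n = 11` need a root-restricted construction.
* **Basins** may overlap (the dynamics is non-deterministic); no
  partition is imposed.  Reported percentages refer to Boolean states
  (corner states for multivalued systems) and are printed to one decimal.
* Strongly connected components and reachability closures are delegated
  to igraph; the test suite re-derives them with independent brute-force
  oracles (Floyd-Warshall closure, direct rule evaluation via R's parser)
  on small instances.

## Limitations

* Only fixed-point properties are supported.  Cyclic attractors are
  scheme-dependent, so cross-scheme basin comparison is undefined for
  them; models with cyclic asynchronous attractors are rejected by the
  search preconditions.
* Tendencies are forced to `+1`/`-1`, which excludes refinements that hold
  a component at an interior level; this is what makes self-regulated
  multivalued components impossible (see above) and is the price of a
  purely threshold-parameterized construction.
* The partial scheme is an upper envelope of threshold refinements
  (strictly, on some models — see the worked example); minimal sets from
  reachability searches require confirmation by parameterization.
* Everything is explicit-state; symbolic or polynomial-time reachability
  for the most-permissive scheme is out of scope, which bounds practical
  full-space analyses to around twenty components asynchronously and
  eleven most-permissively.
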