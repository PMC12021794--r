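# mrbm — multivalued refinement of Boolean models

Boolean models of regulatory networks update each component toward the
value of a logical rule; under the asynchronous scheme (one component
moves one step at a time) the attractors of the state transition graph are
read as cell fates, and reachability of a fixed point from a transient
state is a model prediction.  The two-level abstraction is coarse, though:
every regulation exerted by a component engages and releases at the same
instant.  Some fate decisions hinge on a regulator acting on one target at
a lower activity than on another — a distinction only a *multivalued*
model (levels `0 … m`) can express — and the corresponding trajectories
are simply absent from the asynchronous Boolean dynamics.

`mrbm` is for modellers who have such a Boolean model and a missing
fixed-point reachability, and want to know **which few components to
multivalue, and with which regulation thresholds, so that the property
reappears** in the asynchronous dynamics of the refined model.

The method rests on three updating schemes for the same model
`f : {0,1}^n → {0,1}^n`:

* **asynchronous** — component `j` steps toward `f_j(x)`;
* **most permissive (m.p.)** — components range over `{0, 1, i, d}`, the
  transient levels `i`/`d` marking progress upward or downward; a
  transient regulator may be read as either 0 or 1 (the readings
  `γ(x)`), which makes the m.p. state transition graph an upper envelope
  of every consistent refinement of `f`;
* **partial J-m.p.** — only the components of a set `J` use the
  four-level rules, all others stay Boolean; `J = ∅` is the asynchronous
  and `J = {1..n}` the m.p. scheme, and trajectories are monotone in `J`.

If a property `P` (reachability `x ⇝ ω`, or basin-size equality
`#B_J(ω) = #B_mp(ω)`, with basins always counted over Boolean states)
holds most-permissively but not asynchronously, the search enumerates
admissible component sets `J` of growing size until `P` holds in the
partial J-m.p. dynamics, returning *all* minimal sets with a full audit
log.  A satisfying `J` is then turned into a multivalued refinement: each
occurrence of a multivalued regulator in a clause of a target's DNF gets
a threshold `s` (regulation exerted at levels `s+1 … m`; for a negated
literal, absence holds at levels `0 … s`), the tendency of a target being
`+1` where the rewritten rule holds and `−1` elsewhere.  Every refinement
built this way provably satisfies the refinement condition
(`h_j(x) > x_j ⇒ ∃x′∈α(x): f_j(x′) = 1, x′_j = 0`, and dually), and its
corner fixed points biject with the fixed points of `f`.

## Worked example

```r
library(mrbm)
toy <- toyModel()                      # built-in 3-component network
fixedPoints(toy)
#> [1] "011" "101"

asyn <- buildSTG(toy, "asynchronous")  # 8 states
mp   <- buildSTG(toy, "mp")            # 64 states over {0,1,i,d}^3
basinSizePercent(basin(asyn, "011"))
#> [1] 50
basinSizePercent(basin(mp, "011"))
#> [1] 75
```

The basin of `011` loses a third of its most-permissive size under the
asynchronous scheme — among the lost trajectories, `010 ⇝ 011`.  The
search for a minimal set restoring the basin size:

```r
mrbmSearch(toy, basinEqualProperty("011"))
#> SearchResult: minimal size 1, 1 satisfying set(s)
#>   {g1}
#>   property: basin of {011} as large as under the most permissive scheme; 4 candidate sets tested
```

Why g1?  The annotated shortest partial-m.p. trajectory shows g3 reading
the rising g1 as *present* one step before g2 reads it as *absent*:

```r
g1 <- buildSTG(toy, "partial", mpComponents = "g1")
annotatePath(g1, "010", "011")
#>   from  to component change
#> 1  010 000        g2   1->0
#> 2  000 i00        g1   0->i
#> 3  i00 i01        g3   0->1
#> 4  i01 i11        g2   0->1
#> 5  i11 d11        g1   i->d
#> 6  d11 011        g1   d->0
```

So the activation g1 → g3 must engage at a lower g1 activity than the
inhibition g1 ⊣ g2 releases: with three levels on g1, activation
threshold 1 (`s = 0`) and inhibition threshold 2 (`s = 1`):

```r
ref <- buildRefinement(toy, "g1", maxLevels = 2,
                       thresholds = data.frame(
                         regulator = c("g1", "g1"), target = c("g3", "g2"),
                         clause = c(1L, 1L), s = c(0L, 1L)))
isRefinement(ref, toy)
#> [1] TRUE
refinementFixedPoints(ref)              # corners 011 and 201 <-> 011, 101
#> [1] "011" "201"
evaluateRefinementProperty(ref, reachProperty("010", "011"))
#> [1] TRUE
basinSizePercent(basin(buildSTG(ref), "011"))
#> [1] 75
```

The refinement's asynchronous dynamics recovers both the trajectory and
the full most-permissive basin size.
`exhaustiveParameterization(toy, "g1", reachProperty("010", "011"))`
finds the same assignment automatically.

A command-line front end over the same functions ships in
`inst/scripts/mrbm` (subcommands `fixedpoints`, `stg`, `basins`, `reach`,
`search`, `refine`, `parameterize`, `verify`; exit code 1 signals a
violated property, 2 a usage/parse error, 3 a state-cap overflow).

See the vignette (`vignettes/refining-boolean-models.Rmd`) for the model
assumptions, the threshold-consistency rules, and the limits of the
partial scheme as an envelope of refinement behaviour.

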