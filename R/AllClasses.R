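#' @import methods
NULL

#' Boolean model of a regulatory network
#'
#' An ordered set of components together with one logical regulatory function
#' per component.  Component order is the declaration order of the source
#' file and fixes the coordinate index of every state vector, so `"010"`
#' always reads component levels left to right in declaration order.
#'
#' Rules are stored both as parsed expression trees and as a canonical
#' disjunctive normal form (DNF).  Clauses of the DNF are sorted by their
#' literal strings, and threshold assignments of multivalued refinements are
#' keyed by clause index, so the clause order is part of the file contract.
#'
#' @slot components Character vector of component names, in declaration order.
#' @slot rules Named list of parsed expression trees, one per component.
#' @slot dnf Named list; for each component, the canonical clause list.  Each
#'   clause is a named integer vector mapping a regulator to 1 (plain
#'   literal) or 0 (negated literal).
#'
#' @seealso [parseBooleanModel()], [deriveRegulatoryGraph()], [fixedPoints()]
#' @export
setClass("BooleanModel",
  representation(components = "character", rules = "list", dnf = "list"))

setValidity("BooleanModel", function(object) {
  msgs <- character(0)
  comps <- object@components
  if (length(comps) == 0L) msgs <- c(msgs, "model has no components")
  if (anyDuplicated(comps)) msgs <- c(msgs, "duplicate component names")
  if (!identical(sort(names(object@rules)), sort(comps))) {
    msgs <- c(msgs, "rules must be named after the components")
  }
  if (!identical(sort(names(object@dnf)), sort(comps))) {
    msgs <- c(msgs, "dnf must be named after the components")
  }
  for (nm in names(object@rules)) {
    sup <- .exprSupport(object@rules[[nm]])
    bad <- setdiff(sup, comps)
    if (length(bad) > 0L) {
      msgs <- c(msgs, sprintf("rule for '%s' references undeclared component(s): %s",
                              nm, paste(bad, collapse = ", ")))
    }
  }
  if (length(msgs) > 0L) msgs else TRUE
})

#' Multivalued refinement of a Boolean model
#'
#' A multivalued model obtained from a Boolean base model by granting the
#' components of a set J more than two activity levels and attaching a
#' regulation threshold to every clause in which a multivalued regulator
#' occurs.  A threshold `s` on a plain literal means the regulation is
#' exerted at levels `s+1, ..., m`; on a negated literal it means the
#' absence condition holds at levels `0, ..., s`.
#'
#' @slot base The [BooleanModel-class] being refined.
#' @slot mpComponents Character vector: the multivalued component set J.
#' @slot maxLevels Named integer vector of maximum activity levels, one per
#'   component (1 for components outside J).
#' @slot thresholds A `data.frame` with columns `regulator`, `target`,
#'   `clause` (1-based index into the target's canonical DNF) and `s`
#'   (integer in `0 ... maxLevels[regulator] - 1`), one row per occurrence of
#'   a multivalued regulator in a clause.
#'
#' @seealso [buildRefinement()], [isRefinement()], [refinementSuccessors()]
#' @export
setClass("MultivaluedRefinement",
  representation(base = "BooleanModel", mpComponents = "character",
                 maxLevels = "integer", thresholds = "data.frame"))

setValidity("MultivaluedRefinement", function(object) {
  msgs <- character(0)
  comps <- object@base@components
  if (!all(object@mpComponents %in% comps)) {
    msgs <- c(msgs, "mpComponents must be declared components of the base model")
  }
  if (!identical(sort(names(object@maxLevels)), sort(comps))) {
    msgs <- c(msgs, "maxLevels must be named after the base components")
  }
  if (any(object@maxLevels < 1L)) msgs <- c(msgs, "maxLevels must be >= 1")
  if (any(object@maxLevels > 9L)) msgs <- c(msgs, "maxLevels above 9 are not supported")
  out <- setdiff(comps, object@mpComponents)
  if (any(object@maxLevels[out] != 1L)) {
    msgs <- c(msgs, "components outside the multivalued set must have maxLevel 1")
  }
  th <- object@thresholds
  need <- c("regulator", "target", "clause", "s")
  if (!all(need %in% names(th))) {
    msgs <- c(msgs, "thresholds must have columns regulator, target, clause, s")
  } else if (nrow(th) > 0L) {
    if (!all(th$regulator %in% object@mpComponents)) {
      msgs <- c(msgs, "threshold regulators must belong to the multivalued set")
    }
    mreg <- object@maxLevels[th$regulator]
    bad <- th$s < 0L | th$s > mreg - 1L
    if (any(bad)) {
      i <- which(bad)[1L]
      msgs <- c(msgs, sprintf(
        "threshold s=%d for (%s -> %s, clause %d) outside 0..%d",
        th$s[i], th$regulator[i], th$target[i], th$clause[i], mreg[i] - 1L))
    }
  }
  if (length(msgs) > 0L) msgs else TRUE
})

#' Explicit state transition graph of a logical model
#'
#' States are compact strings over the per-component alphabets: `0`/`1` for
#' Boolean coordinates, additionally `i` (increasing) and `d` (decreasing)
#' for coordinates updated most-permissively, and digits `0 ... m` for
#' multivalued coordinates.  A state is *Boolean* when it contains no `i` or
#' `d`; in a multivalued system the *corner* states (every coordinate at 0 or
#' at its maximum) play the same role.
#'
#' @slot scheme One of `"asynchronous"`, `"mp"`, `"partial"`,
#'   `"multivalued"`, `"boolean-projection"`.
#' @slot components Character vector of component names (fixes coordinates).
#' @slot mpComponents Components updated most-permissively (`"partial"`), all
#'   components (`"mp"`), or the multivalued set (`"multivalued"`).
#' @slot maxLevels Named integer vector of maximum levels (multivalued
#'   systems only; empty otherwise).
#' @slot states Character vector of all states of the system.
#' @slot from,to Parallel character vectors: the transition relation.
#' @slot root Optional initial state; when present the system contains
#'   exactly the states reachable from it.
#'
#' @seealso [buildSTG()], [attractors()], [basin()], [isReachable()]
#' @export
setClass("TransitionSystem",
  representation(scheme = "character", components = "character",
                 mpComponents = "character", maxLevels = "integer",
                 states = "character", from = "character", to = "character",
                 root = "character"))

setValidity("TransitionSystem", function(object) {
  msgs <- character(0)
  if (length(object@scheme) != 1L ||
      !object@scheme %in% c("asynchronous", "mp", "partial", "multivalued",
                            "boolean-projection")) {
    msgs <- c(msgs, "unknown scheme")
  }
  if (length(object@from) != length(object@to)) {
    msgs <- c(msgs, "from and to must have equal length")
  }
  if (length(object@from) > 0L &&
      (!all(object@from %in% object@states) || !all(object@to %in% object@states))) {
    msgs <- c(msgs, "every transition endpoint must be a state of the system")
  }
  if (length(object@root) > 1L) msgs <- c(msgs, "root must be a single state")
  if (length(object@root) == 1L && !object@root %in% object@states) {
    msgs <- c(msgs, "root must be a state of the system")
  }
  if (length(msgs) > 0L) msgs else TRUE
})

#' Attractor of a transition system
#'
#' A terminal strongly connected component: a set of states that is strongly
#' connected and has no transition leaving it.  Size-1 attractors are fixed
#' points, larger ones are cyclic attractors.
#'
#' @slot states Character vector of member states.
#' @slot kind `"fixed_point"` or `"cyclic"`.
#' @export
setClass("Attractor", representation(states = "character", kind = "character"))

setValidity("Attractor", function(object) {
  if (length(object@states) == 0L) return("attractor must be nonempty")
  ok <- if (length(object@states) == 1L) "fixed_point" else "cyclic"
  if (!identical(object@kind, ok)) return("kind inconsistent with size")
  TRUE
})

#' Basin of attraction
#'
#' The set of states from which an attractor is reachable.  The reported
#' size is the number of Boolean states of the basin (corner states mapped
#' to Boolean states for multivalued systems), as a percentage of the
#' Boolean state space, so that basins are comparable across updating
#' schemes with different state spaces.
#'
#' @slot attractor The [Attractor-class] the basin belongs to.
#' @slot members Character vector: all states from which the attractor is
#'   reachable (including non-Boolean ones).
#' @slot booleanMembers Boolean states of the basin (corners mapped back to
#'   Boolean states in multivalued systems).
#' @slot sizePercent `100 * |booleanMembers| / 2^n`.
#' @export
setClass("Basin",
  representation(attractor = "Attractor", members = "character",
                 booleanMembers = "character", sizePercent = "numeric"))

#' Result of a minimal multivalued-set search
#'
#' @slot propertyDescription One-line description of the tested property.
#' @slot size Minimal satisfying set size found, or `NA` when the search was
#'   exhausted.
#' @slot sets List of character vectors: all satisfying sets of the minimal
#'   size (each a subset of the admissible components).
#' @slot log A `data.frame` with one row per candidate set tested: columns
#'   `size`, `set` (comma-joined), `satisfied`.
#' @seealso [mrbmSearch()]
#' @export
setClass("SearchResult",
  representation(propertyDescription = "character", size = "integer",
                 sets = "list", log = "data.frame"))
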