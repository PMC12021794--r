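# Transition relations: asynchronous, most permissive (m.p.), partial
# J-m.p., and multivalued asynchronous; plus explicit state transition
# graph construction.

.capacityStop <- function(msg) {
  stop(structure(class = c("mrbm_capacity_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.substChar <- function(chars, j, v) {
  chars[j] <- v
  paste(chars, collapse = "")
}

# Core engine shared by the three Boolean-model schemes.  `jmask` flags the
# most-permissively updated coordinates.  For each component the rule's
# possible readings over the gamma completions decide which moves fire:
# m.p. coordinates step through the transient levels i/d, the others jump
# between the Boolean levels directly.
.partialSucc <- function(tt, pow2, chars, jmask) {
  idx <- .gammaIndices(chars, pow2)
  out <- character(0)
  for (j in seq_along(chars)) {
    col <- tt[idx, j]
    canOn <- any(col == 1L)
    canOff <- any(col == 0L)
    xj <- chars[j]
    if (jmask[j]) {
      if ((xj == "0" || xj == "d") && canOn) out <- c(out, .substChar(chars, j, "i"))
      if ((xj == "1" || xj == "i") && canOff) out <- c(out, .substChar(chars, j, "d"))
      if (xj == "i") out <- c(out, .substChar(chars, j, "1"))
      if (xj == "d") out <- c(out, .substChar(chars, j, "0"))
    } else {
      if (xj == "0" && canOn) out <- c(out, .substChar(chars, j, "1"))
      else if (xj == "1" && canOff) out <- c(out, .substChar(chars, j, "0"))
    }
  }
  unique(out)
}

.checkMpState <- function(chars, jmask, state) {
  bad <- which(!(chars %in% c("0", "1", "i", "d")))
  if (length(bad) > 0L) {
    stop(sprintf("state '%s': level '%s' is not in {0,1,i,d}",
                 state, chars[bad[1L]]), call. = FALSE)
  }
  trans <- chars %in% c("i", "d")
  if (any(trans & !jmask)) {
    j <- which(trans & !jmask)[1L]
    stop(sprintf("state '%s': coordinate %d carries a transient level but is not updated most-permissively",
                 state, j), call. = FALSE)
  }
}

#' Successor states under the asynchronous scheme
#'
#' One successor per component whose level differs from its target value:
#' that component moves one step toward its target, all others keep their
#' level.
#'
#' @param model A [BooleanModel-class].
#' @param state A Boolean state string.
#' @return Character vector of successor states (empty at a fixed point).
#' @examples
#' m <- parseBooleanModel("a, !b\nb, a")
#' asyncSuccessors(m, "00")
#' @export
asyncSuccessors <- function(model, state) {
  stopifnot(is(model, "BooleanModel"))
  n <- length(model@components)
  .checkStateArity(state, n)
  if (!.isBooleanState(state)) {
    stop(sprintf("asynchronous updating requires a Boolean state, got '%s'", state),
         call. = FALSE)
  }
  chars <- .stateChars(state)
  if (!all(chars %in% c("0", "1"))) {
    stop(sprintf("state '%s' has levels outside {0,1}", state), call. = FALSE)
  }
  tt <- .modelTT(model)
  pow2 <- 2L^((n - 1L):0L)
  .partialSucc(tt, pow2, chars, rep(FALSE, n))
}

#' Successor states under the most permissive scheme
#'
#' Every component is updated most-permissively: a component can start
#' increasing (`0`/`d` to `i`) when some gamma completion of the state makes
#' its rule true, start decreasing (`1`/`i` to `d`) when some completion
#' makes it false, and commit a transient level to its Boolean endpoint
#' (`i` to `1`, `d` to `0`) at any time.
#'
#' @param model A [BooleanModel-class].
#' @param state A state string over `0`, `1`, `i`, `d`.
#' @return Character vector of successor states.
#' @export
mpSuccessors <- function(model, state) {
  stopifnot(is(model, "BooleanModel"))
  n <- length(model@components)
  .checkStateArity(state, n)
  chars <- .stateChars(state)
  jmask <- rep(TRUE, n)
  .checkMpState(chars, jmask, state)
  tt <- .modelTT(model)
  pow2 <- 2L^((n - 1L):0L)
  .partialSucc(tt, pow2, chars, jmask)
}

#' Successor states under the partial most permissive scheme
#'
#' The components of `mpComponents` follow the most-permissive rules over
#' `{0,1,i,d}`; all other components stay Boolean and jump directly between
#' `0` and `1` when some gamma completion of the current state licenses the
#' jump.  With an empty set this is exactly the asynchronous scheme; with
#' the full component set it is exactly the most permissive scheme.
#'
#' @param model A [BooleanModel-class].
#' @param mpComponents Character vector of component names updated
#'   most-permissively (the set J).
#' @param state A state string: `{0,1,i,d}` on `mpComponents` coordinates,
#'   `{0,1}` elsewhere.
#' @return Character vector of successor states.
#' @export
partialMpSuccessors <- function(model, mpComponents, state) {
  stopifnot(is(model, "BooleanModel"))
  bad <- setdiff(mpComponents, model@components)
  if (length(bad) > 0L) {
    stop(sprintf("unknown component(s) in mpComponents: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  n <- length(model@components)
  .checkStateArity(state, n)
  chars <- .stateChars(state)
  jmask <- model@components %in% mpComponents
  .checkMpState(chars, jmask, state)
  tt <- .modelTT(model)
  pow2 <- 2L^((n - 1L):0L)
  .partialSucc(tt, pow2, chars, jmask)
}

# --- multivalued refinements ---------------------------------------------

# Compile the thresholded update rules of a refinement: for each target, a
# list of clauses, each clause a list of literal conditions
# (regulator index, polarity, threshold s).  A plain literal at threshold s
# is satisfied at regulator levels >= s+1, a negated literal at levels <= s.
# Regulators outside the multivalued set have s = 0, which reduces to the
# Boolean reading.
.compileRefinement <- function(ref) {
  base <- ref@base
  comps <- base@components
  th <- ref@thresholds
  lapply(comps, function(k) {
    clauses <- base@dnf[[k]]
    lapply(seq_along(clauses), function(ci) {
      clause <- clauses[[ci]]
      lapply(seq_along(clause), function(li) {
        nm <- names(clause)[li]
        s <- 0L
        if (nm %in% ref@mpComponents) {
          row <- which(th$regulator == nm & th$target == k & th$clause == ci)
          if (length(row) != 1L) {
            stop(sprintf("refinement lacks a unique threshold for (%s -> %s, clause %d)",
                         nm, k, ci), call. = FALSE)
          }
          s <- th$s[row]
        }
        list(reg = match(nm, comps), pos = clause[[li]] == 1L, s = as.integer(s))
      })
    })
  })
}

# Tendency of each component at integer level vector lv: +1 when the
# thresholded rule is satisfied, -1 otherwise.
.tendencyLv <- function(compiled, lv) {
  vapply(compiled, function(clauses) {
    if (length(clauses) == 0L) return(-1L)  # constant-0 rule
    for (clause in clauses) {
      ok <- TRUE
      for (lit in clause) {
        sat <- if (lit$pos) lv[lit$reg] >= lit$s + 1L else lv[lit$reg] <= lit$s
        if (!sat) {
          ok <- FALSE
          break
        }
      }
      if (ok) return(1L)
    }
    -1L
  }, integer(1))
}

#' Tendencies of a multivalued refinement at a state
#'
#' The tendency of a component is `+1` when its thresholded rule calls it to
#' increase (toward its maximum level) and `-1` when it calls it to
#' decrease; the realized update clamps at `0` and at the maximum level.
#'
#' @param refinement A [MultivaluedRefinement-class].
#' @param state A multivalued state string (digit levels within range).
#' @return Named integer vector of `+1`/`-1`, one per component.
#' @export
tendencies <- function(refinement, state) {
  stopifnot(is(refinement, "MultivaluedRefinement"))
  lv <- .stateLevels(state, refinement@maxLevels)
  stats::setNames(.tendencyLv(.compileRefinement(refinement), lv),
                  refinement@base@components)
}

#' Successor states of a multivalued refinement (asynchronous updating)
#'
#' One coordinate moves per transition: component `j` steps up when its
#' tendency is `+1` and it is below its maximum level, and steps down when
#' its tendency is `-1` and it is above zero.
#'
#' @param refinement A [MultivaluedRefinement-class].
#' @param state A multivalued state string.
#' @return Character vector of successor states (empty at a fixed point).
#' @export
refinementSuccessors <- function(refinement, state) {
  stopifnot(is(refinement, "MultivaluedRefinement"))
  lv <- .stateLevels(state, refinement@maxLevels)
  .refSuccLv(.compileRefinement(refinement), lv, refinement@maxLevels)
}

.refSuccLv <- function(compiled, lv, maxLevels) {
  H <- .tendencyLv(compiled, lv)
  out <- character(0)
  for (j in seq_along(lv)) {
    if (H[j] > 0L && lv[j] < maxLevels[j]) {
      nxt <- lv
      nxt[j] <- lv[j] + 1L
      out <- c(out, paste(nxt, collapse = ""))
    } else if (H[j] < 0L && lv[j] > 0L) {
      nxt <- lv
      nxt[j] <- lv[j] - 1L
      out <- c(out, paste(nxt, collapse = ""))
    }
  }
  out
}

# --- state transition graphs ---------------------------------------------

.enumStates <- function(alphabets, stateCap) {
  total <- prod(vapply(alphabets, length, numeric(1)))
  if (total > stateCap) {
    .capacityStop(sprintf(
      "full state space has %.0f states, exceeding the cap of %.0f; supply a root or raise stateCap",
      total, stateCap))
  }
  grid <- expand.grid(rev(alphabets), stringsAsFactors = FALSE)
  states <- apply(as.matrix(grid)[, rev(seq_along(alphabets)), drop = FALSE],
                  1L, paste, collapse = "")
  sort(states, method = "radix")
}

#' Build an explicit state transition graph
#'
#' Without a `root` the full system is enumerated (all states over the
#' scheme's alphabets); with a `root` only the states reachable from it are
#' included (breadth-first closure).  Enumeration and closure refuse to
#' exceed `stateCap` with a capacity error rather than truncating silently.
#'
#' @param x A [BooleanModel-class] or a [MultivaluedRefinement-class] (the
#'   latter always uses its multivalued asynchronous dynamics).
#' @param scheme For a Boolean model: `"asynchronous"`, `"mp"` or
#'   `"partial"`.
#' @param mpComponents The set J for `scheme = "partial"`.
#' @param root Optional initial state string.
#' @param stateCap Maximum number of states (default `2^22`).
#' @param ... Passed between methods.
#' @return A [TransitionSystem-class].
#' @examples
#' toy <- toyModel()
#' buildSTG(toy, "asynchronous")
#' buildSTG(toy, "partial", mpComponents = "g1")
#' @export
setGeneric("buildSTG", function(x, ...) standardGeneric("buildSTG"))

#' @rdname buildSTG
#' @export
setMethod("buildSTG", "BooleanModel",
  function(x, scheme = c("asynchronous", "mp", "partial"),
           mpComponents = character(0), root = NULL, stateCap = 2^22) {
    scheme <- match.arg(scheme)
    n <- length(x@components)
    if (scheme == "asynchronous" && length(mpComponents) > 0L) {
      stop("mpComponents is only meaningful for the partial scheme", call. = FALSE)
    }
    jmask <- switch(scheme,
      asynchronous = rep(FALSE, n),
      mp = rep(TRUE, n),
      partial = x@components %in% mpComponents)
    if (scheme == "partial") {
      bad <- setdiff(mpComponents, x@components)
      if (length(bad) > 0L) {
        stop(sprintf("unknown component(s) in mpComponents: %s",
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
    }
    tt <- .modelTT(x)
    pow2 <- 2L^((n - 1L):0L)
    succFun <- function(state) .partialSucc(tt, pow2, .stateChars(state), jmask)
    if (is.null(root)) {
      alphabets <- lapply(jmask, function(j) if (j) c("0", "1", "d", "i") else c("0", "1"))
      states <- .enumStates(alphabets, stateCap)
    } else {
      .checkStateArity(root, n)
      .checkMpState(.stateChars(root), jmask, root)
      states <- .bfsClosure(root, succFun, stateCap)
    }
    .edgesToTS(states, succFun, scheme,
               mpComponents = x@components[jmask], components = x@components,
               maxLevels = integer(0), root = if (is.null(root)) character(0) else root)
  })

#' @rdname buildSTG
#' @export
setMethod("buildSTG", "MultivaluedRefinement",
  function(x, root = NULL, stateCap = 2^22, ...) {
    compiled <- .compileRefinement(x)
    m <- x@maxLevels
    succFun <- function(state) {
      .refSuccLv(compiled, as.integer(.stateChars(state)), m)
    }
    if (is.null(root)) {
      alphabets <- lapply(m, function(mx) as.character(0:mx))
      states <- .enumStates(alphabets, stateCap)
    } else {
      .stateLevels(root, m)
      states <- .bfsClosure(root, succFun, stateCap)
    }
    .edgesToTS(states, succFun, "multivalued",
               mpComponents = x@mpComponents, components = x@base@components,
               maxLevels = m, root = if (is.null(root)) character(0) else root)
  })

.bfsClosure <- function(root, succFun, stateCap) {
  seen <- new.env(parent = emptyenv())
  assign(root, TRUE, envir = seen)
  queue <- root
  count <- 1L
  head <- 1L
  while (head <= length(queue)) {
    cur <- queue[head]
    head <- head + 1L
    for (s in succFun(cur)) {
      if (!exists(s, envir = seen, inherits = FALSE)) {
        count <- count + 1L
        if (count > stateCap) {
          .capacityStop(sprintf(
            "reachable set from '%s' exceeds the state cap of %.0f", root, stateCap))
        }
        assign(s, TRUE, envir = seen)
        queue <- c(queue, s)
      }
    }
  }
  sort(queue, method = "radix")
}

.edgesToTS <- function(states, succFun, scheme, mpComponents, components,
                       maxLevels, root) {
  froms <- vector("list", length(states))
  tos <- vector("list", length(states))
  for (k in seq_along(states)) {
    succ <- succFun(states[k])
    if (length(succ) > 0L) {
      froms[[k]] <- rep.int(states[k], length(succ))
      tos[[k]] <- sort(succ, method = "radix")
    }
  }
  new("TransitionSystem", scheme = scheme, components = components,
      mpComponents = mpComponents, maxLevels = maxLevels, states = states,
      from = as.character(unlist(froms)), to = as.character(unlist(tos)),
      root = root)
}

# Named adjacency list of a transition system.
.adjacency <- function(ts) {
  adj <- split(ts@to, factor(ts@from, levels = ts@states))
  names(adj) <- ts@states
  adj
}

#' Project a most-permissive system onto its Boolean states
#'
#' The projected system has the Boolean states of the input as nodes and an
#' edge `u -> v` exactly when `v` is reachable from `u` through a nonempty
#' path whose intermediate states are all non-Boolean.  A system without
#' transient states is returned unchanged.
#'
#' @param ts A [TransitionSystem-class] built under the `mp` or `partial`
#'   scheme.
#' @return A [TransitionSystem-class] with scheme `"boolean-projection"`.
#' @export
projectBoolean <- function(ts) {
  stopifnot(is(ts, "TransitionSystem"))
  boolean <- ts@states[!grepl("[id]", ts@states)]
  if (length(boolean) == length(ts@states)) return(ts)
  adj <- .adjacency(ts)
  froms <- vector("list", length(boolean))
  tos <- vector("list", length(boolean))
  for (k in seq_along(boolean)) {
    u <- boolean[k]
    # BFS from u through non-Boolean states only
    reached <- character(0)
    seen <- new.env(parent = emptyenv())
    queue <- adj[[u]]
    while (length(queue) > 0L) {
      s <- queue[1L]
      queue <- queue[-1L]
      if (exists(s, envir = seen, inherits = FALSE)) next
      assign(s, TRUE, envir = seen)
      if (!grepl("[id]", s)) {
        reached <- c(reached, s)
      } else {
        queue <- c(queue, adj[[s]])
      }
    }
    reached <- unique(reached)
    if (length(reached) > 0L) {
      froms[[k]] <- rep.int(u, length(reached))
      tos[[k]] <- sort(reached, method = "radix")
    }
  }
  root <- ts@root
  if (length(root) == 1L && grepl("[id]", root)) root <- character(0)
  new("TransitionSystem", scheme = "boolean-projection",
      components = ts@components, mpComponents = ts@mpComponents,
      maxLevels = integer(0), states = boolean,
      from = as.character(unlist(froms)), to = as.character(unlist(tos)),
      root = root)
}
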