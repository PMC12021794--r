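# The minimal-multivalued-set search: iterate over admissible component
# subsets J of growing size until the required property holds in the
# partial J-m.p. dynamics, then parameterize refinements exhaustively.

#' Property specifications
#'
#' Three variants are supported: `reachProperty(from, to)` asks for a
#' trajectory from one Boolean state to a target fixed point;
#' `reachSetProperty(from, to)` (parallel vectors) asks for all of a set of
#' such trajectories; `basinEqualProperty(fixedPoints)` asks that the basin
#' of every listed fixed point contains as many Boolean states as it does
#' under the full most-permissive dynamics.
#'
#' @param from,to Boolean state strings (targets must be fixed points of
#'   the model the property is evaluated on).
#' @return A property object (list with class `mrbmProperty`).
#' @examples
#' reachProperty("010", "011")
#' basinEqualProperty("011")
#' @export
reachProperty <- function(from, to) {
  structure(list(variant = "reach",
                 pairs = data.frame(from = from, to = to, stringsAsFactors = FALSE)),
            class = "mrbmProperty")
}

#' @rdname reachProperty
#' @export
reachSetProperty <- function(from, to) {
  stopifnot(length(from) == length(to))
  structure(list(variant = "reach_set",
                 pairs = data.frame(from = from, to = to, stringsAsFactors = FALSE)),
            class = "mrbmProperty")
}

#' @rdname reachProperty
#' @param fixedPoints Character vector of fixed-point state strings.
#' @export
basinEqualProperty <- function(fixedPoints) {
  structure(list(variant = "basin_equal", fixedPoints = as.character(fixedPoints)),
            class = "mrbmProperty")
}

#' @rdname reachProperty
#' @param text JSON text: `{"reach": [{"from": "010", "to": "011"}]}` or
#'   `{"basin_equal": ["011"]}`.
#' @export
parseProperty <- function(text) {
  obj <- jsonlite::fromJSON(text, simplifyVector = TRUE)
  if (!is.null(obj$reach)) {
    pairs <- as.data.frame(obj$reach, stringsAsFactors = FALSE)
    if (nrow(pairs) == 1L) {
      return(reachProperty(pairs$from, pairs$to))
    }
    return(reachSetProperty(pairs$from, pairs$to))
  }
  if (!is.null(obj$basin_equal)) {
    return(basinEqualProperty(obj$basin_equal))
  }
  stop("property JSON must contain 'reach' or 'basin_equal'", call. = FALSE)
}

#' @rdname reachProperty
#' @param property A property object.
#' @export
serializeProperty <- function(property) {
  stopifnot(inherits(property, "mrbmProperty"))
  obj <- if (property$variant == "basin_equal") {
    list(basin_equal = property$fixedPoints)
  } else {
    list(reach = property$pairs)
  }
  jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
}

.describeProperty <- function(property) {
  if (property$variant == "basin_equal") {
    sprintf("basin of {%s} as large as under the most permissive scheme",
            paste(property$fixedPoints, collapse = ", "))
  } else {
    sprintf("reachability %s",
            paste(sprintf("%s->%s", property$pairs$from, property$pairs$to),
                  collapse = ", "))
  }
}

.propertyTargets <- function(property) {
  if (property$variant == "basin_equal") property$fixedPoints else property$pairs$to
}

#' Check the preconditions of the minimal-set search
#'
#' The search assumes a model whose asynchronous dynamics has at least two
#' fixed points and no cyclic attractor.
#'
#' @param model A [BooleanModel-class].
#' @param stateCap State cap for the asynchronous system.
#' @return A list with elements `pass`, `fixedPoints`, `nCyclic`,
#'   `messages`.
#' @export
checkPreconditions <- function(model, stateCap = 2^22) {
  ts <- buildSTG(model, "asynchronous", stateCap = stateCap)
  atts <- attractors(ts)
  kinds <- vapply(atts, function(a) a@kind, character(1))
  fps <- unlist(lapply(atts[kinds == "fixed_point"], function(a) a@states))
  nCyclic <- sum(kinds == "cyclic")
  msgs <- character(0)
  if (length(fps) < 2L) {
    msgs <- c(msgs, sprintf("asynchronous dynamics has %d fixed point(s); need at least 2",
                            length(fps)))
  }
  if (nCyclic > 0L) {
    msgs <- c(msgs, sprintf("asynchronous dynamics has %d cyclic attractor(s)", nCyclic))
  }
  list(pass = length(msgs) == 0L,
       fixedPoints = if (is.null(fps)) character(0) else fps,
       nCyclic = nCyclic, messages = msgs)
}

#' Evaluate a property under an updating scheme
#'
#' Reachability properties are decided on rooted state transition graphs;
#' basin-equality properties compare the Boolean-state count of each listed
#' fixed point's basin under the scheme with its count under the full most
#' permissive scheme.
#'
#' @param model A [BooleanModel-class].
#' @param property An `mrbmProperty` (see [reachProperty()]).
#' @param scheme `"asynchronous"`, `"mp"`, or `"partial"`.
#' @param mpComponents The set J when `scheme = "partial"`.
#' @param stateCap State cap per constructed system.
#' @return Logical scalar.
#' @export
evaluateProperty <- function(model, property, scheme = "asynchronous",
                             mpComponents = character(0), stateCap = 2^22) {
  stopifnot(is(model, "BooleanModel"), inherits(property, "mrbmProperty"))
  fps <- fixedPoints(model)
  bad <- setdiff(.propertyTargets(property), fps)
  if (length(bad) > 0L) {
    stop(sprintf("property target(s) not fixed points: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (property$variant %in% c("reach", "reach_set")) {
    for (i in seq_len(nrow(property$pairs))) {
      ts <- buildSTG(model, scheme = scheme, mpComponents = mpComponents,
                     root = property$pairs$from[i], stateCap = stateCap)
      if (!property$pairs$to[i] %in% ts@states) return(FALSE)
    }
    return(TRUE)
  }
  # basin_equal
  if (scheme == "mp") return(TRUE)
  mpTS <- buildSTG(model, "mp", stateCap = stateCap)
  ts <- buildSTG(model, scheme = scheme, mpComponents = mpComponents,
                 stateCap = stateCap)
  for (fp in property$fixedPoints) {
    ref <- length(basin(mpTS, fp)@booleanMembers)
    got <- length(basin(ts, fp)@booleanMembers)
    if (got != ref) return(FALSE)
  }
  TRUE
}

#' Evaluate a property on a refinement's asynchronous dynamics
#'
#' Boolean states of the property are mapped to the refinement's corner
#' subspace; basin-equality compares corner-state counts with the base
#' model's most-permissive Boolean counts.
#'
#' @param refinement A [MultivaluedRefinement-class].
#' @param property An `mrbmProperty`.
#' @param stateCap State cap per constructed system.
#' @return Logical scalar.
#' @export
evaluateRefinementProperty <- function(refinement, property, stateCap = 2^22) {
  stopifnot(is(refinement, "MultivaluedRefinement"),
            inherits(property, "mrbmProperty"))
  if (property$variant %in% c("reach", "reach_set")) {
    for (i in seq_len(nrow(property$pairs))) {
      from <- booleanToCorner(refinement, property$pairs$from[i])
      to <- booleanToCorner(refinement, property$pairs$to[i])
      ts <- buildSTG(refinement, root = from, stateCap = stateCap)
      if (!to %in% ts@states) return(FALSE)
    }
    return(TRUE)
  }
  mpTS <- buildSTG(refinement@base, "mp", stateCap = stateCap)
  ts <- buildSTG(refinement, stateCap = stateCap)
  for (fp in property$fixedPoints) {
    ref <- length(basin(mpTS, fp)@booleanMembers)
    got <- length(basin(ts, booleanToCorner(refinement, fp))@booleanMembers)
    if (got != ref) return(FALSE)
  }
  TRUE
}

#' Enumerate component subsets of a given size
#'
#' Deterministic lexicographic enumeration over the sorted component pool,
#' as used by the minimal-set search.
#'
#' @param components Character vector (the admissible pool).
#' @param size Subset size (0 yields the single empty set).
#' @return List of character vectors.
#' @export
enumerateComponentSets <- function(components, size) {
  pool <- sort(unique(components), method = "radix")
  if (size == 0L) return(list(character(0)))
  if (size > length(pool)) return(list())
  cmb <- utils::combn(pool, size, simplify = FALSE)
  cmb
}

#' Search minimal component sets restoring a property
#'
#' Starting from size 0 (the asynchronous dynamics itself), the search
#' tests every admissible component subset J of the current size for
#' satisfaction of the property in the partial J-m.p. dynamics, and stops
#' at the first size with satisfying sets, returning all of them.  The
#' property must hold under the full most permissive dynamics -- otherwise
#' no multivalued refinement can restore it and the search errors out.
#'
#' @param model A [BooleanModel-class].
#' @param property An `mrbmProperty`.
#' @param maxSize Largest set size to try (default: all admissible
#'   components).
#' @param force Run even when [checkPreconditions()] reports violations.
#' @param stateCap State cap per constructed system.
#' @return A [SearchResult-class].
#' @examples
#' res <- mrbmSearch(toyModel(), basinEqualProperty("011"))
#' searchSets(res)
#' @export
mrbmSearch <- function(model, property, maxSize = NULL, force = FALSE,
                       stateCap = 2^22) {
  stopifnot(is(model, "BooleanModel"))
  pre <- checkPreconditions(model, stateCap = stateCap)
  if (!pre$pass && !force) {
    stop(paste(c("model violates the search preconditions:", pre$messages),
               collapse = "\n  "), call. = FALSE)
  }
  if (!evaluateProperty(model, property, "mp", stateCap = stateCap)) {
    stop("property does not hold even under the most permissive dynamics; no refinement can restore it",
         call. = FALSE)
  }
  adm <- sort(admissibleComponents(model), method = "radix")
  if (is.null(maxSize)) maxSize <- length(adm)
  logRows <- list()
  for (size in 0:maxSize) {
    sets <- enumerateComponentSets(adm, size)
    hits <- list()
    for (J in sets) {
      sat <- if (size == 0L) {
        evaluateProperty(model, property, "asynchronous", stateCap = stateCap)
      } else {
        evaluateProperty(model, property, "partial", mpComponents = J,
                         stateCap = stateCap)
      }
      logRows[[length(logRows) + 1L]] <- data.frame(
        size = size, set = paste(J, collapse = ","), satisfied = sat,
        stringsAsFactors = FALSE)
      if (sat) hits[[length(hits) + 1L]] <- J
    }
    if (length(hits) > 0L) {
      return(new("SearchResult", propertyDescription = .describeProperty(property),
                 size = as.integer(size), sets = hits,
                 log = do.call(rbind, logRows)))
    }
  }
  new("SearchResult", propertyDescription = .describeProperty(property),
      size = NA_integer_, sets = list(),
      log = if (length(logRows) > 0L) do.call(rbind, logRows) else
        data.frame(size = integer(0), set = character(0), satisfied = logical(0)))
}

#' Exhaustive threshold parameterization of a component set
#'
#' Runs through a schedule of maximum-level assignments -- first every
#' multivalued component at level 2, then (if needed) one component at a
#' time raised to `maxLevelCap`, in lexicographic order -- and, within each
#' stage, enumerates every complete threshold assignment, builds the
#' refinement, and keeps those whose asynchronous dynamics satisfies the
#' property.  The schedule stops at the first stage with solutions; an
#' exhausted schedule returns an empty result (difficulty in finding a
#' refinement may indicate an incomplete base model, not an error).
#'
#' @param model A [BooleanModel-class].
#' @param mpComponents The multivalued set J (typically from
#'   [mrbmSearch()]).
#' @param property An `mrbmProperty`.
#' @param maxLevelCap Highest maximum level tried per component (default 3).
#' @param stateCap State cap per constructed system.
#' @return A list with elements `refinements` (list of
#'   [MultivaluedRefinement-class], possibly empty), `maxLevels` (the
#'   successful stage's levels, or `NULL`), `stage` (index, or `NA`), and
#'   `tested` (total assignments examined).
#' @export
exhaustiveParameterization <- function(model, mpComponents, property,
                                       maxLevelCap = 3L, stateCap = 2^22) {
  stopifnot(is(model, "BooleanModel"))
  J <- sort(as.character(mpComponents), method = "radix")
  stages <- list()
  if (length(J) == 0L) {
    stages[[1L]] <- stats::setNames(integer(0), character(0))
  } else {
    stages[[1L]] <- stats::setNames(rep(2L, length(J)), J)
    if (maxLevelCap >= 3L) {
      for (comp in J) {
        lv <- stats::setNames(rep(2L, length(J)), J)
        lv[comp] <- as.integer(maxLevelCap)
        stages[[length(stages) + 1L]] <- lv
      }
    }
  }
  tested <- 0L
  for (k in seq_along(stages)) {
    lv <- stages[[k]]
    hits <- list()
    for (th in enumerateThresholdAssignments(model, J, lv)) {
      ref <- buildRefinement(model, J, lv, th)
      ok <- isRefinement(ref, model)
      if (!isTRUE(ok)) {
        w <- attr(ok, "witness")
        stop(sprintf("constructed candidate is not a refinement (witness: state %s, component %s); this indicates a construction bug",
                     w$state, w$component), call. = FALSE)
      }
      tested <- tested + 1L
      if (evaluateRefinementProperty(ref, property, stateCap = stateCap)) {
        hits[[length(hits) + 1L]] <- ref
      }
    }
    if (length(hits) > 0L) {
      return(list(refinements = hits, maxLevels = lv, stage = k, tested = tested))
    }
  }
  list(refinements = list(), maxLevels = NULL, stage = NA_integer_, tested = tested)
}

#' Annotate one shortest trajectory between two states
#'
#' Finds a shortest path by breadth-first search with deterministic
#' (radix-sorted) successor ordering and labels every step with the
#' component that changed and the kind of change (`0->i`, `i->1`, `1->d`,
#' `d->0`, `0->1`, `1->0`, `+1`, `-1`).
#'
#' @param ts A [TransitionSystem-class].
#' @param source,target State strings of the system.
#' @return A `data.frame` with columns `from`, `to`, `component`, `change`;
#'   zero rows when `source == target`.
#' @export
annotatePath <- function(ts, source, target) {
  stopifnot(is(ts, "TransitionSystem"))
  for (s in c(source, target)) {
    if (!s %in% ts@states) {
      stop(sprintf("state '%s' is not a state of the system", s), call. = FALSE)
    }
  }
  if (source == target) {
    return(data.frame(from = character(0), to = character(0),
                      component = character(0), change = character(0),
                      stringsAsFactors = FALSE))
  }
  adj <- .adjacency(ts)
  pred <- new.env(parent = emptyenv())
  assign(source, NA_character_, envir = pred)
  queue <- source
  head <- 1L
  found <- FALSE
  while (head <= length(queue) && !found) {
    cur <- queue[head]
    head <- head + 1L
    for (s in adj[[cur]]) {          # successors are stored radix-sorted
      if (!exists(s, envir = pred, inherits = FALSE)) {
        assign(s, cur, envir = pred)
        if (s == target) {
          found <- TRUE
          break
        }
        queue <- c(queue, s)
      }
    }
  }
  if (!found) {
    stop(sprintf("'%s' is not reachable from '%s'", target, source), call. = FALSE)
  }
  path <- target
  while (!is.na(get(path[1L], envir = pred))) {
    path <- c(get(path[1L], envir = pred), path)
  }
  steps <- data.frame(from = path[-length(path)], to = path[-1L],
                      stringsAsFactors = FALSE)
  lab <- t(mapply(function(u, v) {
    cu <- .stateChars(u)
    cv <- .stateChars(v)
    j <- which(cu != cv)
    chg <- if (grepl("^[0-9]$", cu[j]) && grepl("^[0-9]$", cv[j]) &&
               ts@scheme == "multivalued") {
      if (as.integer(cv[j]) > as.integer(cu[j])) "+1" else "-1"
    } else {
      sprintf("%s->%s", cu[j], cv[j])
    }
    c(ts@components[j], chg)
  }, steps$from, steps$to))
  steps$component <- lab[, 1L]
  steps$change <- lab[, 2L]
  rownames(steps) <- NULL
  steps
}
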