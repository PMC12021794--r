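# Fixed points, attractors (terminal SCCs), reachability queries, and
# basins of attraction with Boolean/corner normalization so that basin
# sizes are comparable across updating schemes.

.tsGraph <- function(ts) {
  igraph::graph_from_data_frame(
    data.frame(from = ts@from, to = ts@to, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = ts@states, stringsAsFactors = FALSE))
}

#' Fixed points of a Boolean model
#'
#' States `x` with `f(x) = x`, found by exhaustive enumeration of the
#' Boolean state space.  Fixed points are shared by the asynchronous, most
#' permissive and every partial most permissive dynamics.
#'
#' @param model A [BooleanModel-class].
#' @return Character vector of fixed-point state strings, in radix order.
#' @examples
#' fixedPoints(toyModel())
#' @export
fixedPoints <- function(model) {
  stopifnot(is(model, "BooleanModel"))
  n <- length(model@components)
  tt <- .modelTT(model)
  mat <- .boolStateMatrix(n)
  fp <- which(rowSums(tt != mat) == 0L)
  if (length(fp) == 0L) return(character(0))
  apply(mat[fp, , drop = FALSE], 1L, paste, collapse = "")
}

#' Fixed points of a multivalued refinement
#'
#' States of the multivalued state space where no component can move.
#'
#' @param refinement A [MultivaluedRefinement-class].
#' @return Character vector of fixed-point state strings.
#' @export
refinementFixedPoints <- function(refinement) {
  stopifnot(is(refinement, "MultivaluedRefinement"))
  compiled <- .compileRefinement(refinement)
  m <- refinement@maxLevels
  alphabets <- lapply(m, function(mx) as.character(0:mx))
  states <- .enumStates(alphabets, 2^22)
  keep <- vapply(states, function(s) {
    length(.refSuccLv(compiled, as.integer(.stateChars(s)), m)) == 0L
  }, logical(1))
  states[keep]
}

#' Attractors of a transition system
#'
#' Attractors are the terminal strongly connected components of the full
#' state transition graph: strongly connected sets of states with no
#' outgoing transition.  Size-1 attractors are fixed points; larger ones
#' are cyclic attractors.
#'
#' @param ts A full (un-rooted) [TransitionSystem-class].
#' @return List of [Attractor-class] objects, ordered by their smallest
#'   state string.
#' @export
attractors <- function(ts) {
  stopifnot(is(ts, "TransitionSystem"))
  g <- .tsGraph(ts)
  comp <- igraph::components(g, mode = "strong")
  member <- comp$membership
  # an SCC is terminal iff no edge leaves it
  leaving <- unique(member[match(ts@from, ts@states)][
    member[match(ts@from, ts@states)] != member[match(ts@to, ts@states)]])
  terminal <- setdiff(seq_len(comp$no), leaving)
  out <- lapply(terminal, function(ci) {
    states <- sort(ts@states[member == ci], method = "radix")
    new("Attractor", states = states,
        kind = if (length(states) == 1L) "fixed_point" else "cyclic")
  })
  firsts <- vapply(out, function(a) a@states[1L], character(1))
  out[order(firsts, method = "radix")]
}

#' Reachability between two states
#'
#' `TRUE` when a (possibly empty) trajectory leads from `source` to
#' `target` in the transition system.  In most-permissive systems the
#' trajectory may traverse transient states freely, so Boolean-to-Boolean
#' queries have the intended cross-scheme meaning.
#'
#' @param ts A [TransitionSystem-class].
#' @param source,target State strings present in the system.
#' @return Logical scalar.
#' @export
isReachable <- function(ts, source, target) {
  stopifnot(is(ts, "TransitionSystem"))
  for (s in c(source, target)) {
    if (!s %in% ts@states) {
      stop(sprintf("state '%s' is not a state of the system", s), call. = FALSE)
    }
  }
  if (source == target) return(TRUE)
  g <- .tsGraph(ts)
  target %in% names(igraph::subcomponent(g, source, mode = "out"))
}

.cornerToBooleanString <- function(state, maxLevels) {
  lv <- as.integer(.stateChars(state))
  paste(ifelse(lv == maxLevels, "1", "0"), collapse = "")
}

.isCorner <- function(state, maxLevels) {
  lv <- as.integer(.stateChars(state))
  all(lv == 0L | lv == maxLevels)
}

#' Basin of attraction
#'
#' All states from which the attractor is reachable (backward closure).
#' The reported size counts Boolean states only -- for a multivalued system
#' the members lying in the corner subspace, mapped back to Boolean states
#' -- as a percentage of the `2^n` Boolean states, so that sizes are
#' comparable across updating schemes.
#'
#' @param ts A full [TransitionSystem-class].
#' @param attractor An [Attractor-class] (or a character vector of its
#'   states).
#' @return A [Basin-class].
#' @examples
#' ts <- buildSTG(toyModel(), "asynchronous")
#' basin(ts, attractors(ts)[[1]])
#' @export
basin <- function(ts, attractor) {
  stopifnot(is(ts, "TransitionSystem"))
  states <- if (is(attractor, "Attractor")) attractor@states else as.character(attractor)
  if (!all(states %in% ts@states)) {
    stop("attractor states must belong to the transition system", call. = FALSE)
  }
  if (!is(attractor, "Attractor")) {
    attractor <- new("Attractor", states = sort(states, method = "radix"),
                     kind = if (length(states) == 1L) "fixed_point" else "cyclic")
  }
  g <- .tsGraph(ts)
  members <- unique(unlist(lapply(states, function(s) {
    names(igraph::subcomponent(g, s, mode = "in"))
  })))
  members <- sort(members, method = "radix")
  n <- length(ts@components)
  if (ts@scheme == "multivalued") {
    corners <- members[vapply(members, .isCorner, logical(1), maxLevels = ts@maxLevels)]
    boolMembers <- sort(vapply(corners, .cornerToBooleanString, character(1),
                               maxLevels = ts@maxLevels), method = "radix")
  } else {
    boolMembers <- members[!grepl("[id]", members)]
  }
  new("Basin", attractor = attractor, members = members,
      booleanMembers = unname(boolMembers),
      sizePercent = 100 * length(boolMembers) / 2^n)
}

.schemeSpec <- function(spec) {
  # normalize a scheme specification: "asynchronous" | "mp" |
  # list(scheme="partial", mpComponents=...) | "partial:g1,g4"
  if (is.list(spec)) {
    return(list(scheme = spec$scheme,
                mpComponents = if (is.null(spec$mpComponents)) character(0) else spec$mpComponents))
  }
  if (grepl("^partial:", spec)) {
    return(list(scheme = "partial",
                mpComponents = strsplit(sub("^partial:", "", spec), ",")[[1L]]))
  }
  list(scheme = spec, mpComponents = character(0))
}

.schemeLabel <- function(sp) {
  if (sp$scheme == "partial") {
    sprintf("partial:%s", paste(sp$mpComponents, collapse = ","))
  } else {
    sp$scheme
  }
}

#' Fixed-point reachability across updating schemes
#'
#' Evaluates, for every combination of source state, target fixed point and
#' updating scheme, whether the target is reachable from the source, and
#' flags the (source, target) pairs on which the schemes disagree.
#'
#' @param model A [BooleanModel-class].
#' @param schemes List of scheme specifications: `"asynchronous"`, `"mp"`,
#'   or `"partial:g1,g2"` / `list(scheme = "partial", mpComponents = ...)`.
#' @param sources Character vector of Boolean source states.
#' @param targets Character vector of target fixed points.
#' @param stateCap Per-query cap on explored states.
#' @return A `data.frame` with columns `source`, `target`, `scheme`,
#'   `reachable`, and a logical `disagreement` column marking rows of
#'   (source, target) pairs whose result differs between schemes.
#' @export
reachabilityTable <- function(model, schemes, sources, targets, stateCap = 2^22) {
  stopifnot(is(model, "BooleanModel"))
  fps <- fixedPoints(model)
  bad <- setdiff(targets, fps)
  if (length(bad) > 0L) {
    stop(sprintf("target(s) not fixed points of the model: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (length(sources) == 0L) {
    return(data.frame(source = character(0), target = character(0),
                      scheme = character(0), reachable = logical(0),
                      disagreement = logical(0), stringsAsFactors = FALSE))
  }
  specs <- lapply(schemes, .schemeSpec)
  rows <- list()
  for (sp in specs) {
    label <- .schemeLabel(sp)
    for (src in sources) {
      ts <- buildSTG(model, scheme = sp$scheme, mpComponents = sp$mpComponents,
                     root = src, stateCap = stateCap)
      for (tg in targets) {
        rows[[length(rows) + 1L]] <- data.frame(
          source = src, target = tg, scheme = label,
          reachable = tg %in% ts@states, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  key <- paste(out$source, out$target, sep = "->")
  disag <- vapply(split(out$reachable, key), function(v) length(unique(v)) > 1L, logical(1))
  out$disagreement <- disag[key]
  rownames(out) <- NULL
  out
}

#' Export a transition system to DOT or GraphML
#'
#' Nodes carry a `boolean` attribute (`"yes"`/`"no"`) distinguishing
#' Boolean from transient states.
#'
#' @param ts A [TransitionSystem-class].
#' @param file Output path.
#' @param format `"dot"` or `"graphml"`.
#' @return `file`, invisibly.
#' @export
writeSTG <- function(ts, file, format = c("dot", "graphml")) {
  format <- match.arg(format)
  g <- .tsGraph(ts)
  igraph::V(g)$boolean <- ifelse(grepl("[id]", ts@states), "no", "yes")
  igraph::write_graph(g, file, format = format)
  invisible(file)
}
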