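# Independent oracles used to cross-check the package's implementations.
# They deliberately avoid the package's expression/graph machinery: rules
# are evaluated with R's own parser (bnet's !, &, | are valid R syntax),
# and reachability closures are computed by Floyd-Warshall on dense logical
# matrices.

# Evaluate a bnet rule string at a named 0/1 assignment.
oracleEvalRule <- function(ruleText, assignment) {
  env <- as.list(as.integer(assignment))
  names(env) <- names(assignment)
  as.integer(isTRUE(eval(parse(text = ruleText), envir = env) != 0))
}

# All Boolean states (as named rows) for components `comps`.
oracleStates <- function(comps) {
  n <- length(comps)
  grid <- expand.grid(rep(list(c(0L, 1L)), n))[, n:1, drop = FALSE]
  colnames(grid) <- comps
  as.matrix(grid)
}

oracleStateString <- function(row) paste(row, collapse = "")

# Asynchronous successors from raw rule strings.
oracleAsyncSuccessors <- function(rules, state) {
  comps <- names(rules)
  x <- as.integer(strsplit(state, "")[[1L]])
  names(x) <- comps
  out <- character(0)
  for (j in seq_along(comps)) {
    fx <- oracleEvalRule(rules[[j]], x)
    if (fx != x[j]) {
      y <- x
      y[j] <- fx
      out <- c(out, paste(y, collapse = ""))
    }
  }
  sort(out)
}

# Reflexive-transitive closure of an edge list over `states`.
oracleClosure <- function(states, from, to) {
  n <- length(states)
  M <- matrix(FALSE, n, n, dimnames = list(states, states))
  if (length(from) > 0L) M[cbind(from, to)] <- TRUE
  diag(M) <- TRUE
  for (k in seq_len(n)) {
    M <- M | outer(M[, k], M[k, ])
  }
  M
}

# Terminal SCCs from a closure matrix: mutual-reachability classes with no
# edge to another class.
oracleTerminalSCCs <- function(closure) {
  states <- rownames(closure)
  seen <- character(0)
  out <- list()
  for (s in states) {
    if (s %in% seen) next
    scc <- states[closure[s, ] & closure[, s]]
    seen <- c(seen, scc)
    outside <- setdiff(states[Reduce(`|`, lapply(scc, function(u) closure[u, ]))], scc)
    if (length(outside) == 0L) out[[length(out) + 1L]] <- sort(scc)
  }
  out[order(vapply(out, `[`, character(1), 1L))]
}

# Boolean-to-Boolean reachability matrix of a transition system: BFS from
# every Boolean (or corner) state over the raw transition lists.
booleanReachMatrix <- function(ts) {
  states <- mrbm::stateSet(ts)
  tr <- mrbm::transitions(ts)
  adj <- split(tr$to, factor(tr$from, levels = states))
  boolean <- states[!grepl("[id]", states)]
  M <- matrix(FALSE, length(boolean), length(boolean),
              dimnames = list(boolean, boolean))
  for (b in boolean) {
    visited <- new.env(parent = emptyenv())
    queue <- b
    while (length(queue) > 0L) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      if (exists(cur, envir = visited, inherits = FALSE)) next
      assign(cur, TRUE, envir = visited)
      queue <- c(queue, adj[[cur]])
    }
    hit <- intersect(ls(visited), boolean)
    M[b, hit] <- TRUE
  }
  M
}

# Corner-to-corner reachability matrix of a multivalued system, with rows
# and columns labelled by the corresponding Boolean states.
cornerReachMatrix <- function(ts, maxLevels) {
  states <- mrbm::stateSet(ts)
  tr <- mrbm::transitions(ts)
  adj <- split(tr$to, factor(tr$from, levels = states))
  lv <- lapply(strsplit(states, ""), as.integer)
  isCorner <- vapply(lv, function(v) all(v == 0L | v == maxLevels), logical(1))
  corners <- states[isCorner]
  labels <- vapply(lv[isCorner], function(v) {
    paste(ifelse(v == maxLevels, 1L, 0L), collapse = "")
  }, character(1))
  M <- matrix(FALSE, length(corners), length(corners),
              dimnames = list(labels, labels))
  for (k in seq_along(corners)) {
    visited <- new.env(parent = emptyenv())
    queue <- corners[k]
    while (length(queue) > 0L) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      if (exists(cur, envir = visited, inherits = FALSE)) next
      assign(cur, TRUE, envir = visited)
      queue <- c(queue, adj[[cur]])
    }
    hit <- match(intersect(ls(visited), corners), corners)
    M[k, hit] <- TRUE
  }
  M
}

# Fast Boolean-to-Boolean (or corner-to-corner) reachability closure for
# the cross-scheme invariant suites.  Unlike the oracles above this relies
# on igraph; it is used where the object under test is the transition
# relation itself, not the closure computation.
tsReachClosure <- function(ts, maxLevels = NULL) {
  states <- mrbm::stateSet(ts)
  tr <- mrbm::transitions(ts)
  g <- igraph::graph_from_data_frame(tr, directed = TRUE,
                                     vertices = data.frame(name = states))
  if (is.null(maxLevels)) {
    keep <- states[!grepl("[id]", states)]
    labels <- keep
  } else {
    lv <- lapply(strsplit(states, ""), as.integer)
    isCorner <- vapply(lv, function(v) all(v == 0L | v == maxLevels), logical(1))
    keep <- states[isCorner]
    labels <- vapply(lv[isCorner], function(v) {
      paste(ifelse(v == maxLevels, 1L, 0L), collapse = "")
    }, character(1))
  }
  d <- igraph::distances(g, v = keep, to = keep, mode = "out")
  M <- is.finite(d)
  dimnames(M) <- list(labels, labels)
  M[order(labels), order(labels), drop = FALSE]
}

# A tiny hand-written two-component switch used across files.
switchModel <- function() {
  mrbm::parseBooleanModel("a, !b\nb, !a")
}
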