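# Construction and validation of multivalued refinements.

#' Threshold slots of a multivalued component set
#'
#' One slot per occurrence of a multivalued regulator in a clause of a
#' target's canonical DNF (the regulator's own rule included).  Slots are
#' ordered lexicographically by (regulator, target, clause), which is the
#' enumeration order of [enumerateThresholdAssignments()].
#'
#' @param base A [BooleanModel-class].
#' @param mpComponents The multivalued component set J.
#' @return A `data.frame` with columns `regulator`, `target`, `clause`.
#' @export
thresholdSlots <- function(base, mpComponents) {
  stopifnot(is(base, "BooleanModel"))
  rows <- list()
  for (k in base@components) {
    clauses <- base@dnf[[k]]
    for (ci in seq_along(clauses)) {
      for (nm in intersect(names(clauses[[ci]]), mpComponents)) {
        rows[[length(rows) + 1L]] <- data.frame(
          regulator = nm, target = k, clause = ci, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(regulator = character(0), target = character(0),
                      clause = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$regulator, out$target, out$clause, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.checkRefinableSet <- function(base, mpComponents) {
  bad <- setdiff(mpComponents, base@components)
  if (length(bad) > 0L) {
    stop(sprintf("unknown component(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  g <- deriveRegulatoryGraph(base)
  selfReg <- unique(g$source[g$source == g$target])
  bad <- intersect(mpComponents, selfReg)
  if (length(bad) > 0L) {
    stop(sprintf(paste0(
      "component(s) %s occur in their own rule and cannot be multivalued: ",
      "with forced +/-1 tendencies a self-regulated component violates the ",
      "refinement condition at interior levels"),
      paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# Polarity of each slot's literal in the target's DNF clause.
.slotPolarity <- function(base, slots) {
  vapply(seq_len(nrow(slots)), function(i) {
    clause <- base@dnf[[slots$target[i]]][[slots$clause[i]]]
    clause[[slots$regulator[i]]] == 1L
  }, logical(1))
}

# A threshold assignment is consistent when, for every (regulator, target)
# pair, every positive-occurrence threshold is <= every negative-occurrence
# threshold.  Otherwise a dual regulation has a "dead zone": an
# intermediate regulator level at which no thresholded clause is active
# although every Boolean reading of the state satisfies the target's rule,
# and the forced -1 tendency then violates the refinement condition.
# Returns NULL, or the offending (regulator, target) pair.
.thresholdInconsistency <- function(base, thresholds) {
  if (nrow(thresholds) == 0L) return(NULL)
  pos <- .slotPolarity(base, thresholds)
  key <- paste(thresholds$regulator, thresholds$target, sep = "\r")
  for (k in unique(key)) {
    sPos <- thresholds$s[key == k & pos]
    sNeg <- thresholds$s[key == k & !pos]
    if (length(sPos) > 0L && length(sNeg) > 0L && max(sPos) > min(sNeg)) {
      return(strsplit(k, "\r", fixed = TRUE)[[1L]])
    }
  }
  NULL
}

#' Build a multivalued refinement from per-clause thresholds
#'
#' Every occurrence of a multivalued regulator `j` in a clause of a
#' target's rule is rewritten with its threshold `s`: a plain literal
#' becomes "level of `j` at least `s+1`", a negated literal "level of `j`
#' at most `s`".  The tendency of a target is `+1` where the rewritten rule
#' holds and `-1` elsewhere, and updates clamp to `[0, m]`.  With all
#' maximum levels at 1 and all thresholds at 0 the dynamics degenerates to
#' the base model's asynchronous dynamics.
#'
#' Members of `mpComponents` may not occur in their own rule (no
#' self-regulation): a self-regulated component with forced `+/-1`
#' tendencies cannot satisfy the refinement condition at interior levels.
#' For a dual regulation (a regulator occurring with both polarities on one
#' target) the thresholds must not leave a dead zone: every
#' positive-occurrence threshold must be at most every negative-occurrence
#' threshold for that (regulator, target) pair.  Under these two rules the
#' construction provably always satisfies the refinement condition.
#'
#' @param base A [BooleanModel-class].
#' @param mpComponents The multivalued component set J (subset of
#'   [admissibleComponents()] without self-regulators).
#' @param maxLevels Named integer vector giving the maximum level of each
#'   member of J (components outside J are implicitly 1), or a single
#'   integer applied to all of J.
#' @param thresholds A `data.frame` with columns `regulator`, `target`,
#'   `clause`, `s` covering every slot of [thresholdSlots()], or a numeric
#'   vector of `s` values in slot order.
#' @return A [MultivaluedRefinement-class]; the result always satisfies
#'   [isRefinement()] against `base`.
#' @examples
#' toy <- toyModel()
#' ref <- buildRefinement(toy, "g1", maxLevels = 2,
#'                        thresholds = c(1, 0))  # slots: (g1,g2,1), (g1,g3,1)
#' refinementFixedPoints(ref)
#' @export
buildRefinement <- function(base, mpComponents, maxLevels, thresholds) {
  stopifnot(is(base, "BooleanModel"))
  .checkRefinableSet(base, mpComponents)
  if (length(maxLevels) == 1L && is.null(names(maxLevels))) {
    maxLevels <- stats::setNames(rep(as.integer(maxLevels), length(mpComponents)),
                                 mpComponents)
  }
  m <- stats::setNames(rep(1L, length(base@components)), base@components)
  m[names(maxLevels)] <- as.integer(maxLevels)
  slots <- thresholdSlots(base, mpComponents)
  if (is.numeric(thresholds) && is.null(dim(thresholds))) {
    if (length(thresholds) != nrow(slots)) {
      stop(sprintf("expected %d threshold values (one per slot), got %d",
                   nrow(slots), length(thresholds)), call. = FALSE)
    }
    slots$s <- as.integer(thresholds)
    thresholds <- slots
  } else {
    thresholds <- as.data.frame(thresholds, stringsAsFactors = FALSE)
    need <- c("regulator", "target", "clause", "s")
    if (!all(need %in% names(thresholds))) {
      stop("thresholds must have columns regulator, target, clause, s", call. = FALSE)
    }
    thresholds$clause <- as.integer(thresholds$clause)
    thresholds$s <- as.integer(thresholds$s)
    key <- function(df) paste(df$regulator, df$target, df$clause, sep = "\r")
    missing <- setdiff(key(slots), key(thresholds))
    if (length(missing) > 0L) {
      parts <- strsplit(missing, "\r", fixed = TRUE)
      stop(sprintf("missing threshold entr%s: %s",
                   if (length(missing) == 1L) "y" else "ies",
                   paste(vapply(parts, function(p)
                     sprintf("(%s -> %s, clause %s)", p[1L], p[2L], p[3L]),
                     character(1)), collapse = ", ")), call. = FALSE)
    }
    extra <- setdiff(key(thresholds), key(slots))
    if (length(extra) > 0L) {
      stop("thresholds contain entries that match no clause slot", call. = FALSE)
    }
    thresholds <- thresholds[match(key(slots), key(thresholds)),
                             c("regulator", "target", "clause", "s"), drop = FALSE]
    rownames(thresholds) <- NULL
  }
  bad <- .thresholdInconsistency(base, thresholds)
  if (!is.null(bad)) {
    stop(sprintf(paste0(
      "inconsistent thresholds for the dual regulation %s -> %s: a positive-",
      "occurrence threshold exceeds a negative-occurrence threshold, leaving ",
      "a dead zone where the tendency cannot be licensed by any Boolean reading"),
      bad[1L], bad[2L]), call. = FALSE)
  }
  new("MultivaluedRefinement", base = base,
      mpComponents = as.character(mpComponents), maxLevels = m,
      thresholds = thresholds)
}

#' Enumerate all complete threshold assignments
#'
#' Yields every assignment of a threshold `s` in `0 ... m_regulator - 1` to
#' every slot of [thresholdSlots()], in lexicographic order (the first slot
#' varies slowest).  Without dual regulations the total count is the
#' product of the regulators' maximum levels over the slots; assignments
#' that would leave a dual regulation with a dead zone (see
#' [buildRefinement()]) are omitted.
#'
#' @inheritParams buildRefinement
#' @return List of threshold `data.frame`s, each acceptable to
#'   [buildRefinement()].
#' @export
enumerateThresholdAssignments <- function(base, mpComponents, maxLevels) {
  stopifnot(is(base, "BooleanModel"))
  if (length(maxLevels) == 1L && is.null(names(maxLevels))) {
    maxLevels <- stats::setNames(rep(as.integer(maxLevels), length(mpComponents)),
                                 mpComponents)
  }
  slots <- thresholdSlots(base, mpComponents)
  if (nrow(slots) == 0L) {
    return(list(cbind(slots, data.frame(s = integer(0)))))
  }
  choices <- lapply(slots$regulator, function(r) 0:(maxLevels[[r]] - 1L))
  grid <- expand.grid(rev(choices))
  grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
  out <- lapply(seq_len(nrow(grid)), function(i) {
    asg <- slots
    asg$s <- as.integer(unlist(grid[i, ]))
    asg
  })
  keep <- vapply(out, function(asg) is.null(.thresholdInconsistency(base, asg)),
                 logical(1))
  out[keep]
}

#' Check the refinement condition against a Boolean base model
#'
#' A multivalued model `h` refines a Boolean model `f` when, at every
#' multivalued state `x` and component `j`, a decrease of `j` under `h` is
#' licensed by some Boolean reading `x'` of `x` (via [alphaStates()]) with
#' `f_j(x') = 0` and `x'_j = 1`, and symmetrically for increases.  The
#' check is exhaustive over the multivalued state space.
#'
#' @param candidate A [MultivaluedRefinement-class], or a function
#'   `h(levels)` returning the target integer level vector (then
#'   `maxLevels` must be supplied).
#' @param base A [BooleanModel-class].
#' @param maxLevels Required when `candidate` is a function.
#' @return `TRUE`, or `FALSE` with attribute `witness` = list(state,
#'   component) locating a violation.  A candidate violating the unit-step
#'   condition `|h_j(x) - x_j| <= 1` raises an error instead.
#' @export
isRefinement <- function(candidate, base, maxLevels = NULL) {
  stopifnot(is(base, "BooleanModel"))
  n <- length(base@components)
  if (is(candidate, "MultivaluedRefinement")) {
    m <- candidate@maxLevels
    compiled <- .compileRefinement(candidate)
    hFun <- function(lv) {
      H <- .tendencyLv(compiled, lv)
      pmin(pmax(lv + H, 0L), m)
    }
  } else if (is.function(candidate)) {
    if (is.null(maxLevels)) stop("maxLevels required for a function candidate", call. = FALSE)
    m <- as.integer(maxLevels)
    hFun <- candidate
  } else {
    stop("candidate must be a MultivaluedRefinement or a function", call. = FALSE)
  }
  tt <- .modelTT(base)
  pow2 <- 2L^((n - 1L):0L)
  alphabets <- lapply(m, function(mx) as.character(0:mx))
  states <- .enumStates(alphabets, 2^22)
  for (s in states) {
    lv <- as.integer(.stateChars(s))
    h <- as.integer(hFun(lv))
    step <- h - lv
    if (any(abs(step) > 1L) || any(h < 0L) || any(h > m)) {
      stop(sprintf("candidate violates the unit-step condition at state '%s'", s),
           call. = FALSE)
    }
    idx <- .alphaIndices(lv, m, pow2)
    for (j in which(step != 0L)) {
      jbit <- bitwAnd(idx - 1L, pow2[j]) > 0L
      ok <- if (step[j] < 0L) {
        any(tt[idx[jbit], j] == 0L)      # some reading with x'_j = 1, f_j = 0
      } else {
        any(tt[idx[!jbit], j] == 1L)     # some reading with x'_j = 0, f_j = 1
      }
      if (!ok) {
        res <- FALSE
        attr(res, "witness") <- list(state = s, component = base@components[j])
        return(res)
      }
    }
  }
  TRUE
}

#' Map corner states of a refinement to Boolean states and back
#'
#' The corner subspace (every coordinate at 0 or at its maximum) of a
#' multivalued refinement corresponds one-to-one with the Boolean state
#' space of the base model.
#'
#' @param refinement A [MultivaluedRefinement-class].
#' @param state A corner state string (for `cornerToBoolean`) or a Boolean
#'   state string (for `booleanToCorner`).
#' @return The corresponding state string.
#' @examples
#' ref <- buildRefinement(toyModel(), "g1", 2, c(1, 0))
#' cornerToBoolean(ref, "201")
#' booleanToCorner(ref, "101")
#' @export
cornerToBoolean <- function(refinement, state) {
  stopifnot(is(refinement, "MultivaluedRefinement"))
  m <- refinement@maxLevels
  .stateLevels(state, m)
  if (!.isCorner(state, m)) {
    stop(sprintf("state '%s' is not a corner state", state), call. = FALSE)
  }
  .cornerToBooleanString(state, m)
}

#' @rdname cornerToBoolean
#' @export
booleanToCorner <- function(refinement, state) {
  stopifnot(is(refinement, "MultivaluedRefinement"))
  m <- refinement@maxLevels
  chars <- .stateChars(state)
  if (length(chars) != length(m) || !all(chars %in% c("0", "1"))) {
    stop(sprintf("'%s' is not a Boolean state of the base model", state), call. = FALSE)
  }
  paste(ifelse(chars == "1", m, 0L), collapse = "")
}

# --- JSON I/O -------------------------------------------------------------

#' Read and write multivalued refinements as JSON
#'
#' The format stores the base model as bnet text, the multivalued set, the
#' maximum levels, and one threshold entry per clause slot:
#' `{"base_model": "...", "mp_components": [...], "max_levels": {...},
#' "thresholds": [{"regulator": ..., "target": ..., "clause_index": ...,
#' "s": ...}]}`.  `clause_index` is 1-based into the target's canonical
#' DNF; `s` follows the convention that the regulation is exerted at
#' regulator levels `s+1` and above.
#'
#' @param text JSON text (or a file path for `readRefinement`).
#' @return A [MultivaluedRefinement-class].
#' @export
parseRefinement <- function(text) {
  obj <- jsonlite::fromJSON(text, simplifyVector = TRUE)
  for (field in c("base_model", "mp_components", "max_levels", "thresholds")) {
    if (is.null(obj[[field]])) {
      stop(sprintf("refinement JSON lacks field '%s'", field), call. = FALSE)
    }
  }
  base <- parseBooleanModel(obj$base_model)
  m <- unlist(obj$max_levels)
  th <- as.data.frame(obj$thresholds, stringsAsFactors = FALSE)
  if (nrow(th) > 0L) {
    need <- c("regulator", "target", "clause_index", "s")
    if (!all(need %in% names(th))) {
      stop("each threshold entry needs fields regulator, target, clause_index, s",
           call. = FALSE)
    }
    th <- data.frame(regulator = th$regulator, target = th$target,
                     clause = as.integer(th$clause_index), s = as.integer(th$s),
                     stringsAsFactors = FALSE)
  }
  buildRefinement(base, as.character(obj$mp_components),
                  stats::setNames(as.integer(m), names(m)), th)
}

#' @rdname parseRefinement
#' @param file Path to a refinement `.json` file.
#' @export
readRefinement <- function(file) {
  parseRefinement(paste(readLines(file, warn = FALSE), collapse = "\n"))
}

#' @rdname parseRefinement
#' @param refinement A [MultivaluedRefinement-class].
#' @export
serializeRefinement <- function(refinement) {
  stopifnot(is(refinement, "MultivaluedRefinement"))
  th <- refinement@thresholds
  obj <- list(
    base_model = paste(serializeModel(refinement@base), collapse = "\n"),
    mp_components = refinement@mpComponents,
    max_levels = as.list(refinement@maxLevels[refinement@mpComponents]),
    thresholds = data.frame(regulator = th$regulator, target = th$target,
                            clause_index = th$clause, s = th$s,
                            stringsAsFactors = FALSE))
  jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
}

#' @rdname parseRefinement
#' @export
writeRefinement <- function(refinement, file) {
  writeLines(serializeRefinement(refinement), file)
  invisible(file)
}
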