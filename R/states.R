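# State-string helpers.  States are compact strings, one character per
# component: 0/1 for Boolean levels, i/d for the transient most-permissive
# levels, digits up to 9 for multivalued levels.

.stateChars <- function(state) strsplit(state, "", fixed = TRUE)[[1L]]

.charsToState <- function(chars) paste(chars, collapse = "")

.isBooleanState <- function(state) !grepl("[id]", state)

.checkStateArity <- function(state, n) {
  if (length(state) != 1L || !is.character(state)) {
    stop("a state must be a single character string", call. = FALSE)
  }
  if (nchar(state) != n) {
    stop(sprintf("state '%s' has %d coordinates, model has %d",
                 state, nchar(state), n), call. = FALSE)
  }
}

# Row indices (into a 2^n truth table) of the Boolean states compatible
# with a state over {0,1,i,d}: i/d coordinates freed to both values,
# Boolean coordinates pinned.
.gammaIndices <- function(chars, pow2) {
  base <- sum(pow2[chars == "1"])
  idx <- base
  for (w in pow2[chars %in% c("i", "d")]) idx <- c(idx, idx + w)
  idx + 1L
}

#' Boolean completions of a most-permissive state
#'
#' A component at a transient level (`i` or `d`) can be read by its targets
#' as either inactive or active; `gammaStates()` returns all Boolean states
#' obtained by freeing every transient coordinate to both values while
#' pinning the Boolean coordinates.
#'
#' @param state A state string over `0`, `1`, `i`, `d`.
#' @return Character vector of Boolean state strings, in radix order.
#' @examples
#' gammaStates("di1")
#' @export
gammaStates <- function(state) {
  chars <- .stateChars(state)
  if (!all(chars %in% c("0", "1", "i", "d"))) {
    stop(sprintf("state '%s' has levels outside {0,1,i,d}", state), call. = FALSE)
  }
  n <- length(chars)
  opts <- lapply(chars, function(ch) if (ch %in% c("i", "d")) c("0", "1") else ch)
  grid <- expand.grid(rev(opts), stringsAsFactors = FALSE)
  out <- apply(as.matrix(grid)[, rev(seq_len(n)), drop = FALSE], 1L, paste, collapse = "")
  sort(out, method = "radix")
}

#' Boolean readings of a multivalued state
#'
#' For a state of a multivalued model, a coordinate at level 0 is read as 0,
#' a coordinate at its maximum level as 1, and intermediate levels as either
#' value.  This is the correspondence under which a multivalued model
#' qualifies as a refinement of a Boolean model.
#'
#' @param state A multivalued state string (digit levels).
#' @param maxLevels Integer vector of per-component maximum levels.
#' @return Character vector of Boolean state strings, in radix order.
#' @examples
#' alphaStates("021", c(2, 2, 2))
#' @export
alphaStates <- function(state, maxLevels) {
  lv <- .stateLevels(state, maxLevels)
  opts <- lapply(seq_along(lv), function(j) {
    if (lv[j] == 0L) "0"
    else if (lv[j] == maxLevels[j]) "1"
    else c("0", "1")
  })
  grid <- expand.grid(rev(opts), stringsAsFactors = FALSE)
  out <- apply(as.matrix(grid)[, rev(seq_along(lv)), drop = FALSE], 1L, paste, collapse = "")
  sort(out, method = "radix")
}

# Parse a multivalued state string into integer levels, checking range.
.stateLevels <- function(state, maxLevels) {
  chars <- .stateChars(state)
  if (length(chars) != length(maxLevels)) {
    stop(sprintf("state '%s' has %d coordinates, expected %d",
                 state, length(chars), length(maxLevels)), call. = FALSE)
  }
  if (!all(grepl("^[0-9]$", chars))) {
    stop(sprintf("state '%s' has non-digit levels", state), call. = FALSE)
  }
  lv <- as.integer(chars)
  if (any(lv > maxLevels)) {
    j <- which(lv > maxLevels)[1L]
    stop(sprintf("level %d of coordinate %d exceeds its maximum %d in '%s'",
                 lv[j], j, maxLevels[j], state), call. = FALSE)
  }
  lv
}

# Truth-table row indices of the alpha set of a multivalued level vector.
.alphaIndices <- function(lv, maxLevels, pow2) {
  base <- sum(pow2[lv == maxLevels])
  free <- which(lv > 0L & lv < maxLevels)
  idx <- base
  for (w in pow2[free]) idx <- c(idx, idx + w)
  idx + 1L
}
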