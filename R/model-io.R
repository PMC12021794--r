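#' Parse a Boolean model in bnet format
#'
#' The bnet dialect has one `target, factors` line per component, with
#' operators `&` (and), `|` (or), `!` (not), parentheses, and the constants
#' `0` and `1`.  A `targets, factors` header line, `#` comments and blank
#' lines are allowed; names are case-sensitive and whitespace is
#' insignificant.  Component order is the file order and fixes the
#' coordinate order of all state strings.
#'
#' @param text The model source, either a single string or a character
#'   vector of lines.
#' @return A [BooleanModel-class].
#' @examples
#' m <- parseBooleanModel("a, !b\nb, a")
#' componentNames(m)
#' @export
parseBooleanModel <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(text)
  }
  lines <- sub("#.*$", "", lines)
  comps <- character(0)
  rules <- list()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (ln == "") next
    if (grepl("^targets[[:space:]]*,[[:space:]]*factors$", ln, ignore.case = TRUE)) next
    pos <- regexpr(",", ln, fixed = TRUE)
    if (pos < 0L) {
      stop(sprintf("line %d: expected 'target, factors'", k), call. = FALSE)
    }
    target <- trimws(substr(ln, 1L, pos - 1L))
    body <- trimws(substr(ln, pos + 1L, nchar(ln)))
    if (!grepl("^[A-Za-z_.][A-Za-z0-9_.]*$", target)) {
      stop(sprintf("line %d: invalid component name '%s'", k, target), call. = FALSE)
    }
    if (target %in% comps) {
      stop(sprintf("line %d: duplicate target '%s'", k, target), call. = FALSE)
    }
    rules[[target]] <- .parseRule(body, where = sprintf("rule for '%s' (line %d)", target, k))
    comps <- c(comps, target)
  }
  if (length(comps) == 0L) stop("no rules found", call. = FALSE)
  for (nm in comps) {
    bad <- setdiff(.exprSupport(rules[[nm]]), comps)
    if (length(bad) > 0L) {
      stop(sprintf("rule for '%s' references undeclared component(s): %s",
                   nm, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  dnf <- lapply(rules, .exprToDNF)
  new("BooleanModel", components = comps, rules = rules, dnf = dnf)
}

#' @rdname parseBooleanModel
#' @param file Path to a `.bnet` file.
#' @export
readBooleanModel <- function(file) {
  parseBooleanModel(readLines(file, warn = FALSE))
}

#' Serialize a Boolean model to bnet text
#'
#' Rules are printed from the canonical DNF, so `parseBooleanModel()` of the
#' output reproduces the model exactly (canonical-form round trip).
#'
#' @param model A [BooleanModel-class].
#' @return A character vector of lines.
#' @export
serializeModel <- function(model) {
  stopifnot(is(model, "BooleanModel"))
  c("targets, factors",
    vapply(model@components,
           function(nm) sprintf("%s, %s", nm, .dnfToString(model@dnf[[nm]])),
           character(1)))
}

#' @rdname serializeModel
#' @param file Output path.
#' @export
writeBooleanModel <- function(model, file) {
  writeLines(serializeModel(model), file)
  invisible(file)
}

# Truth table of f over all 2^n Boolean states; row r holds f(state with
# index r-1), where the state index weights component 1 most significantly
# (so row order matches radix order of the state strings).
.modelTT <- function(model) {
  n <- length(model@components)
  if (n > 22L) stop("truth-table enumeration supports at most 22 components", call. = FALSE)
  mat <- .boolStateMatrix(n, model@components)
  tt <- matrix(0L, nrow = nrow(mat), ncol = n,
               dimnames = list(NULL, model@components))
  for (nm in model@components) {
    tt[, nm] <- .evalExpr(model@rules[[nm]], mat)
  }
  tt
}

.boolStateMatrix <- function(n, names = NULL) {
  cols <- lapply(seq_len(n), function(j) {
    rep(rep(c(0L, 1L), each = 2L^(n - j)), times = 2L^(j - 1L))
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- names
  mat
}

#' Derive the signed regulatory graph
#'
#' An edge `source -> target` is present exactly when toggling the source's
#' level changes the target's function for some state (functional support).
#' The sign is `positive` when raising the source never decreases and
#' somewhere increases the target's function, `negative` for the symmetric
#' condition, and `dual` when both occur (context-dependent regulation).
#' Signs are established by exhaustive comparison over the whole state
#' space.
#'
#' @param model A [BooleanModel-class].
#' @return A `data.frame` with columns `source`, `target`, `sign`.
#' @examples
#' deriveRegulatoryGraph(parseBooleanModel("a, !b\nb, a"))
#' @export
deriveRegulatoryGraph <- function(model) {
  stopifnot(is(model, "BooleanModel"))
  n <- length(model@components)
  mat <- .boolStateMatrix(n, model@components)
  vals <- lapply(model@components, function(nm) .evalExpr(model@rules[[nm]], mat))
  names(vals) <- model@components
  pow2 <- 2L^((n - 1L):0L)
  src <- tgt <- sgn <- character(0)
  for (j in seq_len(n)) {
    lo <- which(mat[, j] == 0L)        # rows with source at 0
    hi <- lo + pow2[j]                 # same rows with source toggled to 1
    for (k in seq_len(n)) {
      d <- vals[[k]][hi] - vals[[k]][lo]
      pos <- any(d > 0L)
      neg <- any(d < 0L)
      if (pos || neg) {
        src <- c(src, model@components[j])
        tgt <- c(tgt, model@components[k])
        sgn <- c(sgn, if (pos && neg) "dual" else if (pos) "positive" else "negative")
      }
    }
  }
  data.frame(source = src, target = tgt, sign = sgn, stringsAsFactors = FALSE)
}

#' Components admissible for most-permissive updating
#'
#' Output components (no outgoing regulation) and self-inhibited components
#' (negative or dual self-edge) are excluded: multivaluing an output has no
#' consequence on reachability, and multivaluing a self-inhibited component
#' changes the attractor structure.  Self-activation does not exclude a
#' component here.
#'
#' @param model A [BooleanModel-class].
#' @return Character vector of admissible component names, in declaration
#'   order.
#' @export
admissibleComponents <- function(model) {
  g <- deriveRegulatoryGraph(model)
  outgoing <- unique(g$source[g$source != g$target])
  selfInhib <- unique(g$source[g$source == g$target & g$sign %in% c("negative", "dual")])
  keep <- model@components %in% outgoing & !model@components %in% selfInhib
  model@components[keep]
}

#' Export the regulatory graph in DOT format
#'
#' @param model A [BooleanModel-class].
#' @param file Optional output path; when missing the DOT lines are
#'   returned.
#' @return Character vector of DOT lines, invisibly when `file` is given.
#' @export
regulatoryGraphDot <- function(model, file = NULL) {
  g <- deriveRegulatoryGraph(model)
  style <- c(positive = "[sign=positive, arrowhead=normal, color=darkgreen]",
             negative = "[sign=negative, arrowhead=tee, color=red]",
             dual = "[sign=dual, arrowhead=diamond, color=gray40]")
  lines <- c("digraph regulatory {",
             sprintf("  \"%s\";", model@components),
             sprintf("  \"%s\" -> \"%s\" %s;", g$source, g$target, style[g$sign]),
             "}")
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}
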