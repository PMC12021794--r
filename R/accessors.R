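#' @rdname BooleanModel-class
#' @param x A model, refinement or transition system.
#' @export
setGeneric("componentNames", function(x) standardGeneric("componentNames"))

#' @rdname BooleanModel-class
#' @export
setMethod("componentNames", "BooleanModel", function(x) x@components)

#' @rdname MultivaluedRefinement-class
#' @param x A model, refinement or transition system.
#' @export
setMethod("componentNames", "MultivaluedRefinement", function(x) x@base@components)

#' @rdname TransitionSystem-class
#' @param x A model, refinement or transition system.
#' @export
setMethod("componentNames", "TransitionSystem", function(x) x@components)

#' @rdname BooleanModel-class
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname BooleanModel-class
#' @export
setMethod("nComponents", "BooleanModel", function(x) length(x@components))

#' @rdname MultivaluedRefinement-class
#' @export
setMethod("nComponents", "MultivaluedRefinement", function(x) length(x@base@components))

#' @rdname TransitionSystem-class
#' @export
setMethod("nComponents", "TransitionSystem", function(x) length(x@components))

#' Rule of one component
#'
#' Returns the canonical DNF string of a component's logical regulatory
#' function.
#'
#' @param model A [BooleanModel-class].
#' @param component Component name.
#' @return A character scalar such as `"!g1 & g3"`.
#' @export
ruleString <- function(model, component) {
  stopifnot(is(model, "BooleanModel"))
  if (!component %in% model@components) {
    stop(sprintf("unknown component '%s'", component), call. = FALSE)
  }
  .dnfToString(model@dnf[[component]])
}

#' @rdname MultivaluedRefinement-class
#' @export
setGeneric("maxLevels", function(x) standardGeneric("maxLevels"))

#' @rdname MultivaluedRefinement-class
#' @export
setMethod("maxLevels", "MultivaluedRefinement", function(x) x@maxLevels)

#' @rdname MultivaluedRefinement-class
#' @export
setGeneric("mpComponents", function(x) standardGeneric("mpComponents"))

#' @rdname MultivaluedRefinement-class
#' @export
setMethod("mpComponents", "MultivaluedRefinement", function(x) x@mpComponents)

#' @rdname TransitionSystem-class
#' @export
setMethod("mpComponents", "TransitionSystem", function(x) x@mpComponents)

#' @rdname MultivaluedRefinement-class
#' @export
setGeneric("baseModel", function(x) standardGeneric("baseModel"))

#' @rdname MultivaluedRefinement-class
#' @export
setMethod("baseModel", "MultivaluedRefinement", function(x) x@base)

#' @rdname MultivaluedRefinement-class
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname MultivaluedRefinement-class
#' @export
setMethod("thresholds", "MultivaluedRefinement", function(x) x@thresholds)

#' @rdname TransitionSystem-class
#' @export
setGeneric("schemeOf", function(x) standardGeneric("schemeOf"))

#' @rdname TransitionSystem-class
#' @export
setMethod("schemeOf", "TransitionSystem", function(x) x@scheme)

#' @rdname TransitionSystem-class
#' @export
setGeneric("stateSet", function(x) standardGeneric("stateSet"))

#' @rdname TransitionSystem-class
#' @export
setMethod("stateSet", "TransitionSystem", function(x) x@states)

#' @rdname TransitionSystem-class
#' @export
setGeneric("transitions", function(x) standardGeneric("transitions"))

#' @rdname TransitionSystem-class
#' @export
setMethod("transitions", "TransitionSystem", function(x) {
  data.frame(from = x@from, to = x@to, stringsAsFactors = FALSE)
})

#' @rdname Attractor-class
#' @param x An attractor or basin.
#' @export
setGeneric("attractorStates", function(x) standardGeneric("attractorStates"))

#' @rdname Attractor-class
#' @export
setMethod("attractorStates", "Attractor", function(x) x@states)

#' @rdname Attractor-class
#' @export
setGeneric("attractorKind", function(x) standardGeneric("attractorKind"))

#' @rdname Attractor-class
#' @export
setMethod("attractorKind", "Attractor", function(x) x@kind)

#' @rdname Basin-class
#' @param x A basin.
#' @export
setGeneric("basinMembers", function(x) standardGeneric("basinMembers"))

#' @rdname Basin-class
#' @export
setMethod("basinMembers", "Basin", function(x) x@members)

#' @rdname Basin-class
#' @export
setGeneric("basinSizePercent", function(x) standardGeneric("basinSizePercent"))

#' @rdname Basin-class
#' @export
setMethod("basinSizePercent", "Basin", function(x) x@sizePercent)

#' @rdname SearchResult-class
#' @param x A search result.
#' @export
setGeneric("searchSets", function(x) standardGeneric("searchSets"))

#' @rdname SearchResult-class
#' @export
setMethod("searchSets", "SearchResult", function(x) x@sets)

#' @rdname SearchResult-class
#' @export
setGeneric("searchSize", function(x) standardGeneric("searchSize"))

#' @rdname SearchResult-class
#' @export
setMethod("searchSize", "SearchResult", function(x) x@size)

#' @rdname SearchResult-class
#' @export
setGeneric("searchLog", function(x) standardGeneric("searchLog"))

#' @rdname SearchResult-class
#' @export
setMethod("searchLog", "SearchResult", function(x) x@log)

setMethod("show", "BooleanModel", function(object) {
  cat(sprintf("BooleanModel with %d components\n", length(object@components)))
  for (nm in object@components) {
    cat(sprintf("  %s, %s\n", nm, .dnfToString(object@dnf[[nm]])))
  }
})

setMethod("show", "MultivaluedRefinement", function(object) {
  cat(sprintf("MultivaluedRefinement of a %d-component model\n",
              length(object@base@components)))
  cat(sprintf("  multivalued: %s\n",
              paste(sprintf("%s (max %d)", object@mpComponents,
                            object@maxLevels[object@mpComponents]),
                    collapse = ", ")))
  th <- object@thresholds
  if (nrow(th) > 0L) {
    cat("  thresholds (regulation active from level s+1):\n")
    for (i in seq_len(nrow(th))) {
      cat(sprintf("    %s -> %s [clause %d]: s = %d\n",
                  th$regulator[i], th$target[i], th$clause[i], th$s[i]))
    }
  }
})

setMethod("show", "TransitionSystem", function(object) {
  cat(sprintf("TransitionSystem (%s scheme): %d states, %d transitions\n",
              object@scheme, length(object@states), length(object@from)))
  if (length(object@mpComponents) > 0L && object@scheme %in% c("partial", "multivalued")) {
    cat(sprintf("  m.p./multivalued components: %s\n",
                paste(object@mpComponents, collapse = ", ")))
  }
  if (length(object@root) == 1L) cat(sprintf("  rooted at %s\n", object@root))
})

setMethod("show", "Attractor", function(object) {
  cat(sprintf("Attractor (%s): {%s}\n", object@kind,
              paste(object@states, collapse = ", ")))
})

setMethod("show", "Basin", function(object) {
  cat(sprintf("Basin of {%s}: %d states, %.1f%% of the Boolean state space\n",
              paste(object@attractor@states, collapse = ", "),
              length(object@members), object@sizePercent))
})

setMethod("show", "SearchResult", function(object) {
  if (is.na(object@size)) {
    cat("SearchResult: no satisfying set found (search exhausted)\n")
  } else {
    cat(sprintf("SearchResult: minimal size %d, %d satisfying set(s)\n",
                object@size, length(object@sets)))
    for (s in object@sets) {
      cat(sprintf("  {%s}\n", paste(s, collapse = ", ")))
    }
  }
  cat(sprintf("  property: %s; %d candidate sets tested\n",
              object@propertyDescription, nrow(object@log)))
})
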