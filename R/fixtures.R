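# Built-in models: the three-component demonstration network and a seeded
# random-model generator used by the property-style test suites.

#' The three-component demonstration model
#'
#' A small mutual-inhibition network: g1 and g2 repress each other, g1
#' activates g3, and g3 activates g2 and sustains itself.  Its asynchronous
#' dynamics has exactly two fixed points (101 and 011) and no cyclic
#' attractor, and the state 011 is reachable from 010 under the most
#' permissive scheme but not asynchronously, which makes the model a
#' convenient benchmark for the minimal-multivalued-set search.
#'
#' The model ships as a `.bnet` file under `inst/extdata` and is validated
#' on every load against its known fixed points and basin sizes
#' (asynchronous basins 87.5\% and 50\%, most-permissive basin of 011
#' 75\%); a failure indicates a corrupted installation.
#'
#' @return A [BooleanModel-class].
#' @examples
#' toy <- toyModel()
#' fixedPoints(toy)
#' @export
toyModel <- function() {
  path <- system.file("extdata", "toy.bnet", package = "mrbm", mustWork = TRUE)
  model <- readBooleanModel(path)
  fps <- fixedPoints(model)
  asyn <- buildSTG(model, "asynchronous")
  ok <- identical(fps, c("011", "101")) &&
    basin(asyn, "101")@sizePercent == 87.5 &&
    basin(asyn, "011")@sizePercent == 50 &&
    basin(buildSTG(model, "mp"), "011")@sizePercent == 75
  if (!ok) {
    stop("built-in model failed its self-test; the installed toy.bnet is corrupted",
         call. = FALSE)
  }
  model
}

#' Configuration for the random-model generator
#'
#' @param n Number of components.
#' @param seed Integer seed; the same configuration always yields the same
#'   model.
#' @param maxClauses Upper bound on the number of clauses per rule (rules
#'   are generated directly in DNF).
#' @param negationProb Probability that a sampled literal is negated.
#' @param forbidSelfInhibition Regenerate rules that give a component a
#'   negative or dual self-edge.
#' @param requireFixedPointsOnly Rejection-sample whole models until the
#'   asynchronous attractors are all fixed points (needs `n <= 12`).
#' @param maxAttempts Attempt cap for both rejection loops.
#' @return A list of class `mrbmGeneratorConfig`.
#' @export
generatorConfig <- function(n = 4L, seed = 1L, maxClauses = 2L,
                            negationProb = 0.3, forbidSelfInhibition = TRUE,
                            requireFixedPointsOnly = FALSE, maxAttempts = 200L) {
  stopifnot(n >= 1L, maxClauses >= 1L, negationProb >= 0, negationProb <= 1)
  if (requireFixedPointsOnly && n > 12L) {
    stop("requireFixedPointsOnly supports at most 12 components", call. = FALSE)
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 maxClauses = as.integer(maxClauses),
                 negationProb = negationProb,
                 forbidSelfInhibition = isTRUE(forbidSelfInhibition),
                 requireFixedPointsOnly = isTRUE(requireFixedPointsOnly),
                 maxAttempts = as.integer(maxAttempts)),
            class = "mrbmGeneratorConfig")
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.randomRule <- function(comps, self, maxClauses, negationProb) {
  nClauses <- sample.int(maxClauses, 1L)
  clauses <- lapply(seq_len(nClauses), function(i) {
    size <- sample.int(min(length(comps), 3L), 1L)
    regs <- sample(comps, size)
    .exprAnd(lapply(regs, function(r) {
      lit <- .exprVar(r)
      if (stats::runif(1) < negationProb) .exprNot(lit) else lit
    }))
  })
  .exprOr(clauses)
}

#' Generate a reproducible random Boolean model
#'
#' Rules are sampled directly in disjunctive normal form: a few clauses of
#' up to three literals each, with random negations.  With
#' `forbidSelfInhibition` every rule that induces a negative or dual
#' self-edge is re-sampled; with `requireFixedPointsOnly` whole models are
#' re-sampled until the asynchronous attractors are all fixed points.
#'
#' @param config An `mrbmGeneratorConfig` from [generatorConfig()].
#' @return A [BooleanModel-class] with components `g1 ... gn`.
#' @examples
#' m <- randomModel(generatorConfig(n = 3, seed = 42))
#' identical(serializeModel(m),
#'           serializeModel(randomModel(generatorConfig(n = 3, seed = 42))))
#' @export
randomModel <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "mrbmGeneratorConfig"))
  comps <- paste0("g", seq_len(config$n))
  .withSeed(config$seed, {
    for (attempt in seq_len(config$maxAttempts)) {
      rules <- stats::setNames(lapply(comps, function(nm) {
        .randomRule(comps, nm, config$maxClauses, config$negationProb)
      }), comps)
      model <- new("BooleanModel", components = comps, rules = rules,
                   dnf = lapply(rules, .exprToDNF))
      if (config$forbidSelfInhibition) {
        ok <- FALSE
        for (inner in seq_len(config$maxAttempts)) {
          g <- deriveRegulatoryGraph(model)
          bad <- unique(g$source[g$source == g$target &
                                 g$sign %in% c("negative", "dual")])
          if (length(bad) == 0L) {
            ok <- TRUE
            break
          }
          for (nm in bad) {
            rules[[nm]] <- .randomRule(comps, nm, config$maxClauses,
                                       config$negationProb)
          }
          model <- new("BooleanModel", components = comps, rules = rules,
                       dnf = lapply(rules, .exprToDNF))
        }
        if (!ok) {
          stop("could not avoid self-inhibition within maxAttempts; relax the configuration",
               call. = FALSE)
        }
      }
      if (!config$requireFixedPointsOnly) return(model)
      atts <- attractors(buildSTG(model, "asynchronous"))
      if (all(vapply(atts, function(a) a@kind, character(1)) == "fixed_point")) {
        return(model)
      }
    }
    stop("no model with only fixed-point attractors within maxAttempts; relax the configuration",
         call. = FALSE)
  })
}
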