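test_that("alpha pins extreme levels and frees interior ones", {
  expect_identical(alphaStates("021", c(2, 2, 2)), c("010", "011"))
  expect_identical(alphaStates("020", c(2, 2, 1)), "010")  # all pinned
  expect_identical(alphaStates("111", c(2, 2, 2)),
                   sort(apply(oracleStates(letters[1:3]), 1, paste, collapse = "")))
  expect_error(alphaStates("031", c(2, 2, 2)), "exceeds")
})

test_that("threshold slots cover every occurrence of a multivalued regulator", {
  toy <- toyModel()
  slots <- thresholdSlots(toy, "g1")
  expect_identical(slots$target, c("g2", "g3"))
  expect_identical(slots$clause, c(1L, 1L))
  expect_identical(nrow(thresholdSlots(toy, character(0))), 0L)
})

test_that("threshold assignments enumerate the full product, in order", {
  toy <- toyModel()
  asg <- enumerateThresholdAssignments(toy, "g1", 2)
  expect_length(asg, 4L)  # two slots, two choices each
  expect_identical(asg[[1]]$s, c(0L, 0L))
  expect_identical(asg[[2]]$s, c(0L, 1L))  # last slot varies fastest
  expect_identical(asg[[4]]$s, c(1L, 1L))
  expect_length(enumerateThresholdAssignments(toy, "g1", 1), 1L)
  expect_length(enumerateThresholdAssignments(toy, character(0), integer(0)), 1L)
  asg3 <- enumerateThresholdAssignments(toy, "g1", 3)
  expect_length(asg3, 9L)
})

test_that("built refinements satisfy the refinement condition", {
  toy <- toyModel()
  for (th in enumerateThresholdAssignments(toy, "g1", 2)) {
    ref <- buildRefinement(toy, "g1", 2, th)
    expect_true(isTRUE(isRefinement(ref, toy)))
  }
  for (seed in 1:6) {
    m <- randomModel(generatorConfig(n = 4, seed = seed + 40))
    g <- deriveRegulatoryGraph(m)
    selfReg <- unique(g$source[g$source == g$target])
    pool <- setdiff(admissibleComponents(m), selfReg)
    if (length(pool) == 0L) next
    J <- pool[1L]
    asg <- enumerateThresholdAssignments(m, J, 2)
    for (th in asg[unique(c(1L, length(asg)))]) {
      ref <- buildRefinement(m, J, 2, th)
      expect_true(isTRUE(isRefinement(ref, m)),
                  info = sprintf("seed %d, J={%s}", seed, J))
    }
  }
})

test_that("the refinement checker detects violations and bad steps", {
  base <- parseBooleanModel("a, 0\nb, a")
  # a candidate that increases `a` although f_a is constantly 0
  up <- function(lv) pmin(lv + c(1L, 0L), c(2L, 1L))
  res <- isRefinement(up, base, maxLevels = c(2L, 1L))
  expect_false(isTRUE(res))
  expect_identical(attr(res, "witness")$component, "a")
  # a candidate jumping two levels violates the unit-step condition
  jump <- function(lv) c(2L, lv[2L])
  expect_error(isRefinement(jump, base, maxLevels = c(2L, 1L)), "unit-step")
})

test_that("dual regulations reject threshold assignments with dead zones", {
  # g3 acts on g4 with both polarities; a positive threshold above a
  # negative one leaves level 1 in neither regime although every Boolean
  # reading of the state satisfies the rule
  m <- parseBooleanModel("g1, g3\ng3, g1 & g6\ng4, (!g3 & g5) | (g1 & g3)\ng5, g4\ng6, g5")
  slots <- thresholdSlots(m, "g3")
  gapped <- slots
  gapped$s <- ifelse(gapped$target == "g4" & slots$clause == 2L, 1L, 0L)
  expect_error(buildRefinement(m, "g3", 2, gapped), "dead zone")
  asg <- enumerateThresholdAssignments(m, "g3", 2)
  for (th in asg) {
    ref <- buildRefinement(m, "g3", 2, th)
    expect_true(isTRUE(isRefinement(ref, m)), info = paste(th$s, collapse = ","))
  }
  # consistent dual assignments remain, gapped ones are filtered out
  expect_true(length(asg) > 0L && length(asg) < 2L^nrow(slots))
})

test_that("self-regulated components are refused as multivalued components", {
  m <- parseBooleanModel("a, a | b\nb, !a\nc, b")
  expect_error(buildRefinement(m, "a", 2, c(0, 0, 0)), "own rule")
})

test_that("missing and extra threshold entries are named", {
  toy <- toyModel()
  one <- data.frame(regulator = "g1", target = "g3", clause = 1L, s = 0L)
  expect_error(buildRefinement(toy, "g1", 2, one), "\\(g1 -> g2, clause 1\\)")
  extra <- rbind(one,
                 data.frame(regulator = "g1", target = "g2", clause = 1L, s = 1L),
                 data.frame(regulator = "g1", target = "g2", clause = 2L, s = 0L))
  expect_error(buildRefinement(toy, "g1", 2, extra), "no clause slot")
})

test_that("corner states map bijectively onto Boolean states", {
  toy <- toyModel()
  ref <- buildRefinement(toy, "g1", 2, c(1, 0))
  expect_identical(cornerToBoolean(ref, "201"), "101")
  expect_identical(booleanToCorner(ref, "101"), "201")
  boolStates <- stateSet(buildSTG(toy, "asynchronous"))
  for (b in boolStates) {
    expect_identical(cornerToBoolean(ref, booleanToCorner(ref, b)), b)
  }
  expect_error(cornerToBoolean(ref, "101"), "not a corner")
})

test_that("corner fixed points correspond to the base fixed points", {
  toy <- toyModel()
  for (th in enumerateThresholdAssignments(toy, "g1", 2)) {
    ref <- buildRefinement(toy, "g1", 2, th)
    fps <- refinementFixedPoints(ref)
    corners <- fps[vapply(fps, function(s) mrbm:::.isCorner(s, maxLevels(ref)),
                          logical(1))]
    mapped <- sort(vapply(corners, cornerToBoolean, character(1),
                          refinement = ref))
    expect_identical(unname(mapped), fixedPoints(toy),
                     info = paste(th$s, collapse = ","))
  }
})

test_that("the all-Boolean refinement degenerates to the base dynamics", {
  toy <- toyModel()
  ref <- buildRefinement(toy, character(0), integer(0),
                         data.frame(regulator = character(0),
                                    target = character(0),
                                    clause = integer(0), s = integer(0)))
  boolStates <- stateSet(buildSTG(toy, "asynchronous"))
  for (s in boolStates) {
    expect_identical(sort(refinementSuccessors(ref, s)),
                     sort(asyncSuccessors(toy, s)), info = s)
  }
})
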