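test_that("gamma frees transient coordinates and pins Boolean ones", {
  expect_identical(gammaStates("di1"), c("001", "011", "101", "111"))
  expect_identical(gammaStates("010"), "010")
  expect_identical(gammaStates("ii"), c("00", "01", "10", "11"))
  expect_error(gammaStates("2i0"), "outside")
})

test_that("asynchronous successors step one component toward its target", {
  toy <- toyModel()
  for (fp in fixedPoints(toy)) {
    expect_length(asyncSuccessors(toy, fp), 0L)
  }
  neg <- parseBooleanModel("a, !a")
  expect_identical(asyncSuccessors(neg, "0"), "1")
  expect_identical(asyncSuccessors(neg, "1"), "0")
  # cross-check against direct rule evaluation on every toy state
  rules <- c(g1 = "!g2", g2 = "!g1 & g3", g3 = "g1 | g3")
  for (s in stateSet(buildSTG(toy, "asynchronous"))) {
    expect_identical(sort(asyncSuccessors(toy, s)),
                     oracleAsyncSuccessors(rules, s), info = s)
  }
  expect_error(asyncSuccessors(toy, "0i1"), "Boolean")
})

test_that("most permissive successors realize the four transition cases", {
  toy <- toyModel()
  # a committed decrease, read either way by other components
  expect_true("1d1" %in% mpSuccessors(toy, "111"))
  expect_true("001" %in% mpSuccessors(toy, "0d1"))
  # trajectory replay: every step of a known m.p. trajectory is licensed
  traj <- c("111", "1d1", "dd1", "0d1", "001")
  for (k in seq_len(length(traj) - 1L)) {
    expect_true(traj[k + 1L] %in% mpSuccessors(toy, traj[k]),
                info = sprintf("%s -> %s", traj[k], traj[k + 1L]))
  }
  # Boolean fixed points have no m.p. successors either
  for (fp in fixedPoints(toy)) {
    expect_length(mpSuccessors(toy, fp), 0L)
  }
})

test_that("partial scheme interpolates between asynchronous and m.p.", {
  toy <- toyModel()
  boolStates <- stateSet(buildSTG(toy, "asynchronous"))
  for (s in boolStates) {
    expect_identical(sort(partialMpSuccessors(toy, character(0), s)),
                     sort(asyncSuccessors(toy, s)), info = s)
  }
  for (s in stateSet(buildSTG(toy, "mp"))) {
    expect_identical(sort(partialMpSuccessors(toy, componentNames(toy), s)),
                     sort(mpSuccessors(toy, s)), info = s)
  }
  expect_true("i01" %in% partialMpSuccessors(toy, "g1", "i00"))
  # transient level on a non-m.p. coordinate is rejected
  expect_error(partialMpSuccessors(toy, "g1", "0i0"), "transient")
})

test_that("full systems enumerate the whole state space", {
  toy <- toyModel()
  expect_length(stateSet(buildSTG(toy, "asynchronous")), 8L)
  expect_length(stateSet(buildSTG(toy, "mp")), 64L)
  expect_length(stateSet(buildSTG(toy, "partial", mpComponents = "g1")), 16L)
  ts <- buildSTG(toy, "partial", mpComponents = "g1")
  tr <- transitions(ts)
  expect_true(all(tr$from %in% stateSet(ts)) && all(tr$to %in% stateSet(ts)))
})

test_that("rooted systems contain exactly the reachable states", {
  toy <- toyModel()
  ts <- buildSTG(toy, "asynchronous", root = "100")
  expect_identical(stateSet(ts), c("100", "101"))
  full <- buildSTG(toy, "partial", mpComponents = "g1")
  rooted <- buildSTG(toy, "partial", mpComponents = "g1", root = "010")
  M <- booleanReachMatrix(full)
  # every state of the rooted system is reachable from the root in the full one
  expect_true(all(rooted@root == "010"))
  expect_true("011" %in% stateSet(rooted))
})

test_that("the state cap raises a capacity error instead of truncating", {
  toy <- toyModel()
  expect_error(buildSTG(toy, "mp", stateCap = 10),
               class = "mrbm_capacity_error")
  expect_error(buildSTG(toy, "mp", root = "111", stateCap = 3),
               class = "mrbm_capacity_error")
})

test_that("boolean projection contracts transient interiors into edges", {
  toy <- toyModel()
  mp <- buildSTG(toy, "mp")
  pb <- projectBoolean(mp)
  expect_identical(schemeOf(pb), "boolean-projection")
  expect_length(stateSet(pb), 8L)
  tr <- transitions(pb)
  expect_true(any(tr$from == "111" & tr$to == "001"))
  # projection preserves Boolean-to-Boolean reachability exactly
  expect_identical(booleanReachMatrix(pb), booleanReachMatrix(mp))
  # an asynchronous system has no transient states and is returned unchanged
  asyn <- buildSTG(toy, "asynchronous")
  expect_identical(projectBoolean(asyn), asyn)
})

test_that("refinement successors follow clamped tendencies", {
  toy <- toyModel()
  ref <- buildRefinement(toy, "g1", 2, c(1, 0))
  # hand-evaluated: at 010 only g2 can move (down)
  expect_identical(refinementSuccessors(ref, "010"), "000")
  expect_identical(unname(tendencies(ref, "010")), c(-1L, -1L, -1L))
  # the activation g1 -> g3 fires from level 1 on
  expect_true("101" %in% refinementSuccessors(ref, "100"))
  # the inhibition g1 -| g2 needs full activity: at level 1, g2 may rise
  expect_true("111" %in% refinementSuccessors(ref, "101"))
  # corner fixed points have no successors
  expect_length(refinementSuccessors(ref, "201"), 0L)
  expect_length(refinementSuccessors(ref, "011"), 0L)
  expect_error(refinementSuccessors(ref, "301"), "exceeds")
})
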