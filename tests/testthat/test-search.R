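test_that("precondition report demands several fixed points, no cycles", {
  pre <- checkPreconditions(toyModel())
  expect_true(pre$pass)
  expect_identical(sort(pre$fixedPoints), c("011", "101"))
  bad <- checkPreconditions(parseBooleanModel("a, !a"))
  expect_false(bad$pass)
  expect_true(bad$nCyclic > 0L)
  # the identity map leaves every state fixed: >= 2 fixed points, no cycle
  ident <- checkPreconditions(parseBooleanModel("a, a\nb, b"))
  expect_true(ident$pass)
})

test_that("property evaluation matches the scheme dynamics", {
  toy <- toyModel()
  p1 <- reachProperty("010", "011")
  expect_false(evaluateProperty(toy, p1, "asynchronous"))
  expect_true(evaluateProperty(toy, p1, "mp"))
  expect_true(evaluateProperty(toy, p1, "partial", mpComponents = "g1"))
  expect_false(evaluateProperty(toy, p1, "partial", mpComponents = "g3"))
  p2 <- basinEqualProperty("011")
  expect_false(evaluateProperty(toy, p2, "asynchronous"))
  expect_true(evaluateProperty(toy, p2, "partial", mpComponents = "g1"))
  expect_false(evaluateProperty(toy, p2, "partial", mpComponents = "g2"))
  expect_error(evaluateProperty(toy, reachProperty("010", "111")),
               "not fixed points")
})

test_that("property JSON round-trips", {
  p <- parseProperty('{"reach": [{"from": "010", "to": "011"}]}')
  expect_identical(p$variant, "reach")
  expect_identical(p$pairs$to, "011")
  p2 <- parseProperty(serializeProperty(basinEqualProperty(c("011", "101"))))
  expect_identical(p2$fixedPoints, c("011", "101"))
  expect_error(parseProperty('{"foo": 1}'), "reach")
})

test_that("search finds all minimal satisfying sets, with an audit log", {
  toy <- toyModel()
  res <- mrbmSearch(toy, reachProperty("010", "011"))
  expect_identical(searchSize(res), 1L)
  expect_identical(searchSets(res), list("g1", "g2"))
  log <- searchLog(res)
  # minimality is certified by the log: no smaller set satisfied
  expect_false(any(log$satisfied[log$size < searchSize(res)]))
  expect_identical(sort(log$set[log$size == 1L]), c("g1", "g2", "g3"))
  # determinism
  res2 <- mrbmSearch(toy, reachProperty("010", "011"))
  expect_identical(searchSets(res2), searchSets(res))
  expect_identical(searchLog(res2), searchLog(res))
})

test_that("search returns the unique basin-restoring singleton", {
  res <- mrbmSearch(toyModel(), basinEqualProperty("011"))
  expect_identical(searchSize(res), 1L)
  expect_identical(searchSets(res), list("g1"))
})

test_that("a property already satisfied asynchronously yields the empty set", {
  res <- mrbmSearch(toyModel(), reachProperty("001", "011"))
  expect_identical(searchSize(res), 0L)
  expect_identical(searchSets(res), list(character(0)))
})

test_that("hopeless searches and precondition violations are refused", {
  toy <- toyModel()
  # from one fixed point to another: impossible even most-permissively
  expect_error(mrbmSearch(toy, reachProperty("101", "011")),
               "most permissive")
  neg <- parseBooleanModel("a, !a\nb, a")
  expect_error(mrbmSearch(neg, reachProperty("00", "11")), "precondition")
})

test_that("component-set enumeration is lexicographic and complete", {
  sets <- enumerateComponentSets(c("b", "a", "c"), 2)
  expect_identical(sets, list(c("a", "b"), c("a", "c"), c("b", "c")))
  expect_identical(enumerateComponentSets(letters[1:4], 0), list(character(0)))
  expect_length(enumerateComponentSets(letters[1:5], 3), choose(5, 3))
})

test_that("exhaustive parameterization finds the documented refinement", {
  toy <- toyModel()
  out <- exhaustiveParameterization(toy, "g1", reachProperty("010", "011"))
  expect_identical(out$stage, 1L)
  expect_true(length(out$refinements) > 0L)
  # the hand-derived assignment (inhibition threshold 2, activation 1)
  found <- vapply(out$refinements, function(ref) {
    th <- thresholds(ref)
    th$s[th$target == "g2"] == 1L && th$s[th$target == "g3"] == 0L
  }, logical(1))
  expect_true(any(found))
  for (ref in out$refinements) {
    expect_true(evaluateRefinementProperty(ref, reachProperty("010", "011")))
  }
})

test_that("parameterization handles the empty set and impossible properties", {
  toy <- toyModel()
  sat <- exhaustiveParameterization(toy, character(0), reachProperty("001", "011"))
  expect_length(sat$refinements, 1L)
  unsat <- exhaustiveParameterization(toy, character(0), reachProperty("010", "011"))
  expect_length(unsat$refinements, 0L)
  expect_true(is.na(unsat$stage))
  # a fixed point has no outgoing trajectory in any refinement
  none <- exhaustiveParameterization(toy, "g1", reachProperty("101", "011"))
  expect_length(none$refinements, 0L)
})

test_that("partial dynamics can strictly over-approximate threshold refinements", {
  # The partial scheme's existential readings let a transient component be
  # read as absent by one rule and as present by another along a single
  # trajectory.  A threshold refinement has no such freedom, so the
  # partial dynamics is an upper envelope that individual refinements need
  # not attain: with J = {g2} the partial system reaches 011 from 010
  # (basin 62.5%), yet every 3-level threshold refinement of g2 stays at
  # the asynchronous basin (50%, unreachable).  With J = {g1} the envelope
  # is attained by the two-threshold refinement.
  toy <- toyModel()
  g2ts <- buildSTG(toy, "partial", mpComponents = "g2")
  expect_true(isReachable(g2ts, "010", "011"))
  expect_equal(basinSizePercent(basin(g2ts, "011")), 62.5)
  for (th in enumerateThresholdAssignments(toy, "g2", 2)) {
    ref <- buildRefinement(toy, "g2", 2, th)
    ts <- buildSTG(ref)
    expect_false(isReachable(ts, booleanToCorner(ref, "010"),
                             booleanToCorner(ref, "011")))
    expect_equal(basinSizePercent(basin(ts, booleanToCorner(ref, "011"))), 50)
  }
  best <- vapply(enumerateThresholdAssignments(toy, "g1", 2), function(th) {
    ref <- buildRefinement(toy, "g1", 2, th)
    basinSizePercent(basin(buildSTG(ref), booleanToCorner(ref, "011")))
  }, numeric(1))
  expect_equal(max(best), 75)
})

test_that("annotated shortest paths replay as valid trajectories", {
  toy <- toyModel()
  g1 <- buildSTG(toy, "partial", mpComponents = "g1")
  path <- annotatePath(g1, "010", "011")
  expect_identical(nrow(path), 6L)
  for (k in seq_len(nrow(path))) {
    expect_true(path$to[k] %in%
                  partialMpSuccessors(toy, "g1", path$from[k]),
                info = sprintf("step %d", k))
  }
  expect_identical(path$from[1L], "010")
  expect_identical(path$to[nrow(path)], "011")
  expect_true(all(path$change %in%
                    c("0->1", "1->0", "0->i", "i->1", "1->d", "d->0", "i->d", "d->i")))
  expect_identical(nrow(annotatePath(g1, "010", "010")), 0L)
  asyn <- buildSTG(toy, "asynchronous")
  expect_error(annotatePath(asyn, "010", "011"), "not reachable")
})
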