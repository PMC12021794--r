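test_that("fixed points equal the brute-force scan and survive scheme changes", {
  toy <- toyModel()
  expect_identical(fixedPoints(toy), c("011", "101"))
  expect_identical(fixedPoints(parseBooleanModel("a, !a")), character(0))
  for (seed in 1:8) {
    m <- randomModel(generatorConfig(n = 4, seed = seed,
                                     forbidSelfInhibition = FALSE))
    rules <- vapply(componentNames(m), function(nm) ruleString(m, nm), character(1))
    states <- oracleStates(componentNames(m))
    scan <- character(0)
    for (r in seq_len(nrow(states))) {
      fx <- vapply(rules, oracleEvalRule, integer(1), assignment = states[r, ])
      if (all(fx == states[r, ])) scan <- c(scan, oracleStateString(states[r, ]))
    }
    expect_identical(fixedPoints(m), scan, info = sprintf("seed %d", seed))
    # fixed points are exactly the singleton terminal SCCs of the STG
    ts <- buildSTG(m, "asynchronous")
    atts <- attractors(ts)
    singles <- unlist(lapply(atts, function(a)
      if (attractorKind(a) == "fixed_point") attractorStates(a) else character(0)))
    if (is.null(singles)) singles <- character(0)
    expect_identical(sort(singles), scan)
  }
})

test_that("attractors are the terminal SCCs, matching a closure oracle", {
  toy <- toyModel()
  atts <- attractors(buildSTG(toy, "asynchronous"))
  expect_length(atts, 2L)
  expect_setequal(unlist(lapply(atts, attractorStates)), c("011", "101"))
  neg <- parseBooleanModel("a, !a")
  cyc <- attractors(buildSTG(neg, "asynchronous"))
  expect_length(cyc, 1L)
  expect_identical(attractorKind(cyc[[1]]), "cyclic")
  expect_identical(attractorStates(cyc[[1]]), c("0", "1"))
  for (seed in 1:6) {
    m <- randomModel(generatorConfig(n = 4, seed = seed + 100,
                                     forbidSelfInhibition = FALSE))
    ts <- buildSTG(m, "asynchronous")
    tr <- transitions(ts)
    clo <- oracleClosure(stateSet(ts), tr$from, tr$to)
    expected <- oracleTerminalSCCs(clo)
    got <- lapply(attractors(ts), attractorStates)
    expect_identical(got, expected, info = sprintf("seed %d", seed))
  }
})

test_that("reachability queries answer trajectory existence", {
  toy <- toyModel()
  asyn <- buildSTG(toy, "asynchronous")
  mp <- buildSTG(toy, "mp")
  expect_false(isReachable(asyn, "010", "011"))
  expect_true(isReachable(mp, "010", "011"))
  expect_true(isReachable(asyn, "010", "010"))  # empty trajectory
  expect_error(isReachable(asyn, "0i0", "011"), "not a state")
})

test_that("basins are backward closures with Boolean-normalized sizes", {
  toy <- toyModel()
  asyn <- buildSTG(toy, "asynchronous")
  b101 <- basin(asyn, "101")
  b011 <- basin(asyn, "011")
  expect_equal(basinSizePercent(b101), 87.5)
  expect_equal(basinSizePercent(b011), 50)
  expect_setequal(basinMembers(b011), c("011", "001", "111", "110"))
  expect_equal(basinSizePercent(basin(buildSTG(toy, "mp"), "011")), 75)
  # basin membership is closed under predecessors and contains the attractor
  tr <- transitions(asyn)
  for (b in list(b101, b011)) {
    members <- basinMembers(b)
    expect_true(all(attractorStates(b@attractor) %in% members))
    preds <- tr$from[tr$to %in% members]
    expect_true(all(preds %in% members))
  }
  # a model whose single fixed point attracts everything
  sink <- parseBooleanModel("a, 1\nb, a")
  ts <- buildSTG(sink, "asynchronous")
  expect_equal(basinSizePercent(basin(ts, "11")), 100)
})

test_that("multivalued basins count corner states only", {
  toy <- toyModel()
  ref <- buildRefinement(toy, "g1", 2, c(1, 0))
  ts <- buildSTG(ref)
  expect_length(stateSet(ts), 12L)
  b <- basin(ts, "011")
  expect_true(all(grepl("^[0-9]+$", basinMembers(b))))
  expect_true(all(b@booleanMembers %in% stateSet(buildSTG(toy, "asynchronous"))))
  expect_equal(basinSizePercent(b), 100 * length(b@booleanMembers) / 8)
})

test_that("reachability tables flag scheme disagreements", {
  toy <- toyModel()
  tab <- reachabilityTable(toy, list("asynchronous", "mp", "partial:g1"),
                           sources = "010", targets = "011")
  expect_identical(tab$reachable,
                   c(FALSE, TRUE, TRUE))
  expect_true(all(tab$disagreement))
  tab2 <- reachabilityTable(toy, list("asynchronous", "mp"),
                            sources = c("110", "001"), targets = c("011", "101"))
  expect_false(any(tab2$disagreement))
  empty <- reachabilityTable(toy, list("asynchronous"), character(0), "011")
  expect_identical(nrow(empty), 0L)
  expect_error(reachabilityTable(toy, list("asynchronous"), "010", "111"),
               "not fixed points")
})
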