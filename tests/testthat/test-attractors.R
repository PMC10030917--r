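test_that("descent lands in the exhaustively computed basin (oracle)", {
  set.seed(17)
  for (seed in 1:20) {
    m <- generateRandomNetwork(8, nInputs = 1, maxInDegree = 3,
                               seed = 600 + seed)
    for (ctx in partitionEnvironments(m)) {
      oracles <- oracle_enumerate(m, ctx)
      s <- setNames(as.integer(runif(8) < 0.5), nodeNames(m))
      s[names(ctx)] <- ctx
      a <- descendToAttractor(m, s, context = ctx)
      # the attractor's state set must be one of the oracle's cycles, and
      # it must be the one containing the state's forward orbit
      expect_true(any(vapply(oracles, identical, logical(1),
                             attractor_keyset(a))))
      walk <- s
      for (i in 1:300) walk <- oracle_sync_step(m, walk)
      expect_true(paste(walk, collapse = "") %in% attractor_keyset(a))
    }
  }
})

test_that("one-node self-activator descends to the state it starts in", {
  m <- parseBooleanNet("A *= A\nB *= A", inputs = character(0))
  # A is self-sustaining but not declared an input, so it is part of the
  # dynamical system and bistable
  expect_identical(inputNodes(m), character(0))
  a0 <- descendToAttractor(m, c(A = 0L, B = 0L))
  a1 <- descendToAttractor(m, c(A = 1L, B = 1L))
  expect_equal(attractorPeriod(a0), 1L)
  expect_false(attractorId(a0) == attractorId(a1))
})

test_that("toggle switch enumerates 2 fixed points and 1 cycle", {
  atts <- enumerateAttractors(toggle_switch())
  periods <- sort(vapply(atts, attractorPeriod, integer(1)))
  expect_identical(periods, c(1L, 1L, 2L))
})

test_that("constant network has exactly one fixed point", {
  atts <- enumerateAttractors(constant_off_model(6))
  expect_length(atts, 1L)
  expect_equal(attractorPeriod(atts[[1]]), 1L)
  expect_true(all(attractorStates(atts[[1]]) == 0L))
})

test_that("enumeration refuses oversized subspaces", {
  m <- generateRandomNetwork(30, nInputs = 0, maxInDegree = 2, seed = 1)
  expect_error(enumerateAttractors(m), "cap")
})

test_that("canonical ids collide exactly for rotations of one cycle", {
  m <- negative_ring()
  a <- descendToAttractor(m, c(A = 0L, B = 0L, C = 0L))
  expect_equal(attractorPeriod(a), 6L)
  # descending from every state of the cycle gives the identical object
  for (i in seq_len(6)) {
    s <- setNames(attractorStates(a)[i, ], nodeNames(m))
    expect_identical(attractorId(descendToAttractor(m, s)),
                     attractorId(a))
  }
  # a different attractor in the same model gets a different id
  b <- descendToAttractor(m, c(A = 0L, B = 1L, C = 0L))
  expect_equal(attractorPeriod(b), 2L)
  expect_false(attractorId(b) == attractorId(a))
  # same states in different contexts do not collide
  m2 <- parseBooleanNet("I *= I\nA *= not B\nB *= not A")
  x1 <- descendToAttractor(m2, c(I = 0L, A = 1L, B = 0L))
  x2 <- descendToAttractor(m2, c(I = 1L, A = 1L, B = 0L))
  expect_false(attractorId(x1) == attractorId(x2))
})

test_that("sampling recovers the exhaustive attractor set on fixtures", {
  set.seed(303)
  for (seed in 1:20) {
    m <- generateRandomNetwork(10, nInputs = sample(0:2, 1),
                               maxInDegree = 3, seed = 700 + seed)
    ex <- sort(vapply(enumerateAttractors(m), attractorId, character(1)))
    sp <- sampleAttractors(m, nRnd = 200, nSeries = 5, pNoise = 0.02)
    got <- sort(vapply(attractors(sp), attractorId, character(1)))
    expect_identical(got, ex, info = paste("seed", seed))
  }
})

test_that("nSeries = 0 with zero noise degenerates to random descents", {
  m <- toggle_switch()
  set.seed(4)
  sp <- sampleAttractors(m, nRnd = 50, nSeries = 0, pNoise = 0,
                         scanNeighbors = FALSE)
  expect_true(length(attractors(sp)) >= 2L)  # both fixed points reachable
})

test_that("a 1x1 convergence grid equals a single sampling run", {
  m <- generateRandomNetwork(9, nInputs = 1, maxInDegree = 2, seed = 12)
  g <- convergenceGrid(m, nRow = 1, nCol = 1, step = 20, seed = 31)
  s <- sampleAttractors(m, nRnd = 20, nSeries = 20, seed = 31)
  expect_identical(sort(vapply(attractors(g), attractorId, character(1))),
                   sort(vapply(attractors(s), attractorId, character(1))))
  expect_equal(nrow(convergenceHeatmap(g)), 1L)
})

test_that("grid union dominates every individual cell", {
  m <- generateRandomNetwork(10, nInputs = 1, maxInDegree = 3, seed = 77)
  g <- convergenceGrid(m, nRow = 3, nCol = 3, step = 5, seed = 5)
  expect_true(all(convergenceHeatmap(g)$nFound <= length(attractors(g))))
})

test_that("environment transitions agree with exhaustive enumeration", {
  set.seed(41)
  m <- generateRandomNetwork(9, nInputs = 2, maxInDegree = 3, seed = 55)
  rep <- sampleAttractors(m, nRnd = 100, nSeries = 5)
  tm <- environmentTransitionMap(m, rep)
  for (i in seq_len(nrow(tm$transitions))) {
    row <- tm$transitions[i, ]
    from <- Filter(function(a) attractorId(a) == row$from, tm$attractors)[[1]]
    ctx <- attractorContext(from)
    ctx[row$input] <- 1L - ctx[row$input]
    target <- descendToAttractor(
      m, setNames(attractorStates(from)[1, ], nodeNames(m)), context = ctx)
    expect_identical(attractorId(target), row$to)
    # the target must exist in the new context's exhaustive set
    exIds <- vapply(enumerateAttractors(m, context = ctx), attractorId,
                    character(1))
    expect_true(row$to %in% exIds)
  }
})

test_that("flipping an input no gate reads gives a self-like transition", {
  m <- parseBooleanNet("I *= I\nJ *= J\nA *= not B or J\nB *= not A")
  rep <- sampleAttractors(m, nRnd = 50, nSeries = 3, seed = 2)
  tm <- environmentTransitionMap(m, rep)
  # flipping I never changes the non-input part of the state
  tI <- tm$transitions[tm$transitions$input == "I", ]
  for (i in seq_len(nrow(tI))) {
    from <- Filter(function(a) attractorId(a) == tI$from[i],
                   tm$attractors)[[1]]
    to <- Filter(function(a) attractorId(a) == tI$to[i],
                 tm$attractors)[[1]]
    free <- setdiff(nodeNames(m), inputNodes(m))
    expect_identical(attractorStates(to)[, free, drop = FALSE],
                     attractorStates(from)[, free, drop = FALSE])
  }
})

test_that("attractor tables export nodes, period and context", {
  m <- toggle_switch()
  atts <- enumerateAttractors(m)
  df <- attractorTable(atts)
  expect_equal(ncol(df), length(atts) + 1L)
  expect_true(all(c("A", "B", "period", "context") %in% df$row))
  p <- tempfile(fileext = ".csv")
  attractorTable(atts, path = p, model = m, seed = 7)
  lines <- readLines(p)
  expect_match(lines[1], "model_hash=")
  expect_match(lines[2], "seed=7")
})
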