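test_that("synchronous step matches the expression oracle on random nets", {
  for (seed in 1:10) {
    m <- generateRandomNetwork(10, nInputs = 2, maxInDegree = 3,
                               seed = seed)
    set.seed(seed + 100)
    for (rep in 1:5) {
      s <- setNames(as.integer(runif(10) < 0.5), nodeNames(m))
      expect_identical(syncStep(m, s), oracle_sync_step(m, s))
    }
  }
})

test_that("negative-feedback ring has the hand-enumerated orbits", {
  m <- negative_ring()
  # (A,B,C) = (0,0,0) -> 100 -> 110 -> 111 -> 011 -> 001 -> 000 (period 6)
  s <- c(A = 0L, B = 0L, C = 0L)
  orbit <- list(s)
  for (i in 1:6) orbit[[i + 1L]] <- syncStep(m, orbit[[i]])
  expect_identical(unname(orbit[[2]]), c(1L, 0L, 0L))
  expect_identical(unname(orbit[[3]]), c(1L, 1L, 0L))
  expect_identical(unname(orbit[[4]]), c(1L, 1L, 1L))
  expect_identical(unname(orbit[[5]]), c(0L, 1L, 1L))
  expect_identical(unname(orbit[[6]]), c(0L, 0L, 1L))
  expect_identical(orbit[[7]], s)
  a <- descendToAttractor(m, s)
  expect_equal(attractorPeriod(a), 6L)
})

test_that("a state at a fixed point maps to itself", {
  m <- toggle_switch()
  fp <- c(A = 1L, B = 0L)
  expect_identical(syncStep(m, fp), fp)
})

test_that("inputs never change within a fixed context, any engine", {
  m <- generateRandomNetwork(10, nInputs = 3, maxInDegree = 3, seed = 9)
  s <- setNames(rep(1L, 10), nodeNames(m))
  set.seed(5)
  for (engine in c("sync", "noisy", "async", "biased-async")) {
    tr <- runTrajectory(m, s, nSteps = 50, engine = engine, pNoise = 0.3)
    expect_true(all(tr$states[, inputNodes(m)] == 1L), info = engine)
  }
})

test_that("zero noise reduces the noisy step to the synchronous step", {
  m <- negative_ring()
  s <- c(A = 1L, B = 0L, C = 1L)
  expect_identical(noisySyncStep(m, s, pNoise = 0), syncStep(m, s))
})

test_that("per-node flip frequency concentrates at pNoise", {
  m <- constant_off_model(5)
  s0 <- setNames(integer(5), nodeNames(m))
  p <- 0.05; n <- 20000
  set.seed(71)
  tr <- runTrajectory(m, s0, nSteps = n, engine = "noisy", pNoise = p)
  # after each sync step the state resets to all-OFF, so each recorded
  # row is an independent Bernoulli(p) draw per node
  freq <- colMeans(tr$states[-1, ])
  sigma <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) < 3 * sigma))
})

test_that("biased order places start and end nodes as specified", {
  # C oscillates; A copies C.  Updating C before A propagates the new C
  # within the step, so the order is observable from the outcome.
  m <- parseBooleanNet("C *= not C\nA *= C")
  s <- c(C = 0L, A = 0L)
  startBias <- updateBias(start = data.frame(node = "C",
                                             condition = "ALWAYS"))
  endBias <- updateBias(end = data.frame(node = "C", condition = "ALWAYS"))
  expect_identical(biasedAsyncStep(m, s, bias = startBias),
                   c(C = 1L, A = 1L))
  expect_identical(biasedAsyncStep(m, s, bias = endBias),
                   c(C = 1L, A = 0L))
  # end list: the first listed node updates last
  endBoth <- updateBias(end = data.frame(node = c("C", "A"),
                                         condition = "ALWAYS"))
  expect_identical(biasedAsyncStep(m, s, bias = endBoth),
                   c(C = 1L, A = 0L))  # order A then C
  endBoth2 <- updateBias(end = data.frame(node = c("A", "C"),
                                          condition = "ALWAYS"))
  expect_identical(biasedAsyncStep(m, s, bias = endBoth2),
                   c(C = 1L, A = 1L))  # order C then A; A sees the new C
})

test_that("bias conditions are evaluated on the pre-step state", {
  m <- parseBooleanNet("C *= not C\nA *= C")
  s <- c(C = 1L, A = 0L)
  # IF_ON holds at the start (C = 1), so C goes first even though it
  # turns OFF during the step
  b <- updateBias(start = data.frame(node = "C", condition = "IF_ON"))
  expect_identical(biasedAsyncStep(m, s, bias = b), c(C = 0L, A = 0L))
  # IF_OFF does not hold; both nodes land in the random block
  b2 <- updateBias(start = data.frame(node = "C", condition = "IF_OFF"))
  set.seed(1)
  res <- replicate(50, biasedAsyncStep(m, s, bias = b2)[["A"]])
  expect_setequal(unique(res), c(0L, 1L))  # both orders occur
})

test_that("a node in both bias lists triggers a warning, start wins", {
  expect_warning(
    b <- updateBias(start = data.frame(node = "C", condition = "ALWAYS"),
                    end = data.frame(node = "C", condition = "ALWAYS")),
    "both start and end")
  m <- parseBooleanNet("C *= not C\nA *= C")
  expect_identical(biasedAsyncStep(m, c(C = 0L, A = 0L), bias = b),
                   c(C = 1L, A = 1L))
})

test_that("fixed points are invariant under every engine (property)", {
  set.seed(2024)
  checked <- 0L
  for (seed in 1:50) {
    m <- generateRandomNetwork(sample(4:12, 1), nInputs = sample(0:2, 1),
                               maxInDegree = 3, seed = 4000 + seed)
    for (a in enumerateAttractors(m)) {
      if (attractorPeriod(a) != 1L) next
      fp <- setNames(attractorStates(a)[1, ], nodeNames(m))
      expect_identical(syncStep(m, fp), fp)
      for (k in 1:5) {
        expect_identical(asyncStep(m, fp), fp)
        expect_identical(noisySyncStep(m, fp, pNoise = 0), fp)
      }
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 20L)
})

test_that("identical seeds give bitwise identical trajectories", {
  m <- generateRandomNetwork(10, nInputs = 2, maxInDegree = 3, seed = 5)
  s <- setNames(as.integer(runif(10) < 0.5), nodeNames(m))
  for (engine in c("noisy", "async", "biased-async")) {
    set.seed(99); t1 <- runTrajectory(m, s, 100, engine = engine)
    set.seed(99); t2 <- runTrajectory(m, s, 100, engine = engine)
    expect_identical(t1$states, t2$states, info = engine)
  }
})

test_that("toggle-switch fixed points survive thousands of biased steps", {
  m <- toggle_switch()
  set.seed(8)
  for (fp in list(c(A = 1L, B = 0L), c(A = 0L, B = 1L))) {
    for (i in 1:500) expect_identical(asyncStep(m, fp), fp)
  }
})
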