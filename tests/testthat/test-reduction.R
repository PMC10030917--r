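test_that("OR-gate reduction keeps the remaining regulator functional", {
  spec <- compileTruthTable("B or C")
  red <- reduceGateFrozenInputs(spec, "C")
  expect_identical(red$regulators, "B")
  expect_identical(red$table, c(0L, 1L))  # the gate "B"
  expect_identical(attr(red, "frozen"), c(C = 0L))
  expect_true(attr(red, "allFunctional"))
})

test_that("random 4-input gates reduce exactly as brute force (oracle)", {
  set.seed(99)
  regs <- sprintf("R%d", 1:4)
  pairs <- combn(4, 2)
  for (g in 1:60) {
    tab <- as.integer(runif(16) < runif(1, 0.2, 0.8))
    spec <- list(regulators = regs, table = tab)
    for (p in seq_len(ncol(pairs))) {
      removed <- regs[pairs[, p]]
      got <- reduceGateFrozenInputs(spec, removed)
      want <- brute_reduce(regs, tab, removed)
      expect_identical(got$table, want$red,
                       info = sprintf("gate %d removed %s", g,
                                      paste(removed, collapse = "+")))
      expect_identical(attr(got, "frozen"), want$frozen)
    }
  }
})

test_that("entropy of the chosen reduction dominates functional rivals", {
  set.seed(13)
  regs <- sprintf("R%d", 1:4)
  H_of <- function(tab) {
    p <- mean(tab == 0L)
    if (p == 0 || p == 1) 0 else -p * log(p) - (1 - p) * log(1 - p)
  }
  for (g in 1:20) {
    tab <- as.integer(runif(16) < 0.5)
    got <- reduceGateFrozenInputs(list(regulators = regs, table = tab),
                                  c("R2", "R4"))
    if (!attr(got, "allFunctional")) next
    want <- brute_reduce(regs, tab, c("R2", "R4"))
    expect_gte(H_of(got$table) + 1e-12, want$H)
  }
})

test_that("removing every regulator freezes to the majority output", {
  spec <- compileTruthTable("B or C")  # 3 of 4 outputs ON
  expect_warning(red <- reduceGateFrozenInputs(spec, c("B", "C")),
                 "majority")
  expect_identical(red$table, 1L)
  specAnd <- compileTruthTable("B and C")  # 1 of 4 ON; majority OFF
  expect_warning(redAnd <- reduceGateFrozenInputs(specAnd, c("B", "C")),
                 "majority")
  expect_identical(redAnd$table, 0L)
  # exact tie breaks toward OFF
  specXorish <- list(regulators = c("B", "C"), table = c(0L, 1L, 1L, 0L))
  expect_warning(redTie <- reduceGateFrozenInputs(specXorish, c("B", "C")))
  expect_identical(redTie$table, 0L)
})

test_that("isolating the whole model is the identity", {
  m <- buildEmtSwitch()
  iso <- isolateModule(m, nodeNames(m))
  for (v in nodeNames(m))
    expect_identical(truthTable(iso, v), truthTable(m, v))
})

test_that("module isolation reduces outside regulators away", {
  # X in the module depends on outside node O; isolation freezes O
  m <- parseBooleanNet("O *= not X\nX *= Y or O\nY *= X")
  iso <- isolateModule(m, c("X", "Y"))
  expect_setequal(nodeNames(iso), c("X", "Y"))
  expect_identical(regulatorsOf(iso, "X"), "Y")  # O frozen OFF keeps Y functional
  expect_identical(truthTable(iso, "X"), c(0L, 1L))
  # module nodes fed only from outside become environmental inputs
  m2 <- parseBooleanNet("O *= O\nX *= O\nY *= X and Y")
  iso2 <- isolateModule(m2, c("X", "Y"))
  expect_identical(inputNodes(iso2), "X")
  expect_error(isolateModule(m, character(0)), "empty")
})

test_that("a mutant ensemble with zero errors is the wild type", {
  m <- toggle_switch()
  for (kind in c("node_lock", "link_removal", "gate_flip")) {
    ens <- generateMutantEnsemble(m, kind, errorsPerNetwork = 0,
                                  ensembleSize = 3, seed = 1)
    for (mut in ens)
      for (v in nodeNames(m))
        expect_identical(truthTable(mut, v), truthTable(m, v))
  }
})

test_that("gate flips change exactly one truth-table row", {
  m <- generateRandomNetwork(8, nInputs = 2, maxInDegree = 3, seed = 21)
  ens <- generateMutantEnsemble(m, "gate_flip", errorsPerNetwork = 3,
                                ensembleSize = 10, seed = 2)
  for (mut in ens) {
    dist <- vapply(nodeNames(m), function(v)
      sum(truthTable(mut, v) != truthTable(m, v)), integer(1))
    expect_identical(sum(dist), 3L)
    expect_true(all(dist <= 1L))
    expect_true(all(dist[inputNodes(m)] == 0L))
  }
})

test_that("node locks spare environmental inputs", {
  # every non-input gate has regulators, so locks are exactly detectable
  m <- parseBooleanNet(paste(
    "I1 *= I1", "I2 *= I2", "A *= I1 and B", "B *= not A",
    "C *= A or B", "D *= C and not I2", "E *= D or A", "F *= E and B",
    sep = "\n"))
  ens <- generateMutantEnsemble(m, "node_lock", errorsPerNetwork = 4,
                                ensembleSize = 10, seed = 3)
  for (mut in ens) {
    locked <- nodeNames(m)[vapply(nodeNames(m), function(v)
      length(regulatorsOf(mut, v)) == 0L, logical(1))]
    expect_length(locked, 4L)
    expect_length(intersect(locked, inputNodes(m)), 0L)
    expect_true(all(vapply(locked, function(v)
      truthTable(mut, v) %in% c(0L, 1L), logical(1))))
  }
})

test_that("link-removal mutants match direct reduction (oracle)", {
  m <- generateRandomNetwork(8, nInputs = 1, maxInDegree = 3, seed = 23)
  set.seed(77)
  ens <- suppressWarnings(
    generateMutantEnsemble(m, "link_removal", errorsPerNetwork = 2,
                           ensembleSize = 20))
  for (mut in ens) {
    for (v in nodeNames(m)) {
      gone <- setdiff(regulatorsOf(m, v), regulatorsOf(mut, v))
      if (!length(gone)) {
        expect_identical(truthTable(mut, v), truthTable(m, v))
      } else if (length(gone) == length(regulatorsOf(m, v))) {
        # every link removed: the documented majority-output freeze
        expect_identical(truthTable(mut, v),
                         as.integer(mean(truthTable(m, v)) > 0.5))
      } else {
        want <- brute_reduce(regulatorsOf(m, v), truthTable(m, v), gone)
        expect_identical(truthTable(mut, v), want$red)
      }
    }
  }
  expect_error(generateMutantEnsemble(m, "link_removal",
                                      errorsPerNetwork = 1000,
                                      ensembleSize = 1), "links")
})
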