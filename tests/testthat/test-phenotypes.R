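cycle_nodes <- c("Replication", "CyclinB", "A_Kinetochores", "Cdc20",
                 "Cytokinesis", "f4N_DNA")

test_that("signature files parse, including the starred hybrid line", {
  sig <- loadSignatures(paste(
    "Hybrid_EM = (*miR_34*=0, *miR_200*=1, *Ecadherin_mRNA*=1,",
    "*ZEB1_H*=0, *ZEB1*=1, *SNAI1*=1)"))
  expect_named(sig, "Hybrid_EM")
  expect_identical(sig$Hybrid_EM,
                   c(miR_34 = 0L, miR_200 = 1L, Ecadherin_mRNA = 1L,
                     ZEB1_H = 0L, ZEB1 = 1L, SNAI1 = 1L))
  expect_error(loadSignatures("Oops = (X=2)"), "malformed")
})

test_that("the packaged defaults carry the seven standard phenotypes", {
  sig <- defaultSignatures()
  expect_setequal(names(sig),
                  c("CIP", "noCIP", "Migratory", "Non-migratory",
                    "Epithelial", "Mesenchymal", "Hybrid_EM"))
  emt <- buildEmtSwitch()
  expect_error(bindSignatures(sig, emt), "CIP|ApicalBasal")
  emtSig <- structure(sig[c("Epithelial", "Mesenchymal", "Hybrid_EM")],
                      class = "phenotypeSignatures")
  expect_silent(bindSignatures(emtSig, emt))
})

test_that("an empty constraint list matches every state", {
  sig <- loadSignatures("Anything = ()")
  expect_identical(classifyState(c(X = 0L), sig), "Anything")
})

test_that("classification equals the conjunction of bit tests (oracle)", {
  sig <- loadSignatures(c("P = (a=1, b=0)", "Q = (c=1)"))
  set.seed(9)
  states <- matrix(as.integer(runif(3000) < 0.5), ncol = 3,
                   dimnames = list(NULL, c("a", "b", "c")))
  cls <- classifyTrajectory(states, sig)
  expect_identical(unname(cls[, "P"]),
                   states[, "a"] == 1L & states[, "b"] == 0L)
  expect_identical(unname(cls[, "Q"]), states[, "c"] == 1L)
  # frequency of a k-constraint signature over random states is ~2^-k
  expect_lt(abs(mean(cls[, "P"]) - 0.25),
            3 * sqrt(0.25 * 0.75 / nrow(states)))
})

test_that("each attractor of the EMT switch maps to its phenotype", {
  emt <- buildEmtSwitch()
  sig <- structure(defaultSignatures()[c("Epithelial", "Mesenchymal",
                                         "Hybrid_EM")],
                   class = "phenotypeSignatures")
  atts <- enumerateAttractors(emt)
  got <- sort(vapply(atts, function(a)
    classifyState(attractorStates(a)[1, ], sig), character(1)))
  expect_identical(got, c("Epithelial", "Hybrid_EM", "Mesenchymal"))
})

test_that("a quiescent trajectory scores zero events", {
  tr <- scriptedTrajectory(cycle_nodes, 30)
  ev <- detectCycleEvents(tr)
  expect_true(all(ev == 0L))
  expect_error(detectCycleEvents(tr[, -1, drop = FALSE]), "Replication")
})

test_that("scripted marker sequences trigger exactly one counter each", {
  # normal cycle: replication, 4N, CyclinB with attached kinetochores,
  # Cdc20 while attached, cytokinesis
  normal <- scriptedTrajectory(cycle_nodes, 30, list(
    Replication = 3, f4N_DNA = 5:15, CyclinB = 8:12,
    A_Kinetochores = 10:13, Cdc20 = 12, Cytokinesis = 14))
  expect_identical(
    unname(detectCycleEvents(normal)), c(1L, 0L, 0L, 0L))

  # G2 reset: second replication fires with 4N DNA and no CyclinB pulse
  g2 <- scriptedTrajectory(cycle_nodes, 30, list(
    Replication = c(3, 20), f4N_DNA = 5:25))
  expect_identical(unname(detectCycleEvents(g2)), c(0L, 1L, 0L, 0L))

  # aberrant mitosis: Cdc20 pulse without kinetochore attachment
  ab <- scriptedTrajectory(cycle_nodes, 30, list(
    Replication = 3, f4N_DNA = 5:15, CyclinB = 8:12, Cdc20 = 12))
  expect_identical(unname(detectCycleEvents(ab)), c(0L, 0L, 1L, 0L))

  # failed cytokinesis: mitosis (CyclinB) but no cytokinesis before the
  # next replication start
  fc <- scriptedTrajectory(cycle_nodes, 30, list(
    Replication = c(3, 20), f4N_DNA = 5:15, CyclinB = 8:12,
    A_Kinetochores = 10:13, Cdc20 = 12))
  ev <- detectCycleEvents(fc)
  expect_identical(unname(ev["failed_cytokinesis"]), 1L)
  expect_identical(unname(ev["normal_cycle"]), 0L)
})

test_that("periodic cycles count once per period and normalize to 21", {
  # a 21-step cycle repeated 10 times
  one <- list(Replication = 2, f4N_DNA = 4:16, CyclinB = 9:13,
              A_Kinetochores = 11:14, Cdc20 = 13, Cytokinesis = 15)
  pulses <- lapply(one, function(ts)
    as.vector(outer(ts, 21 * (0:9), `+`)))
  tr <- scriptedTrajectory(cycle_nodes, 210, pulses)
  ev <- detectCycleEvents(tr)
  expect_identical(unname(ev["normal_cycle"]), 10L)
  # rate per minimum cycle length: 10 cycles / (210/21) = 1.0
  expect_equal(unname(ev["normal_cycle"] / (nrow(tr) / 21)), 1.0)
})

test_that("dwell fractions converge to the stationary law (oracle)", {
  # one node locked OFF by its gate, flipped ON by noise with rate p:
  # successive states are i.i.d. Bernoulli(p), stationary P(ON) = p
  m <- constant_off_model(1)
  sig <- loadSignatures("On = (N1=1)")
  p <- 0.1; tLive <- 20000L
  set.seed(21)
  st <- runPhenotypeStatistics(m, setNames(0L, "N1"), engine = "noisy",
                               pNoise = p, signatures = sig,
                               tMinLive = tLive)
  expect_equal(st$counters$live_steps, tLive)
  expect_lt(abs(st$dwellFractions[["On"]] - p),
            3 * sqrt(p * (1 - p) / tLive))
})

test_that("apoptotic runs restart until the live-time target is met", {
  # X counts up to death: death signature hit every ~4 steps
  m <- parseBooleanNet(c("A *= B", "B *= C", "C *= D", "D *= True"))
  sig <- loadSignatures("Alive = ()")
  set.seed(2)
  st <- runPhenotypeStatistics(
    m, c(A = 0L, B = 0L, C = 0L, D = 0L), signatures = sig,
    apoptosisSignature = c(A = 1L), tMinLive = 200L)
  expect_gte(st$counters$live_steps, 200L)
  expect_gt(st$counters$apoptoses, 40L)  # dies every 4th step
  expect_false(st$degenerate)
})

test_that("an immediately lethal environment is flagged, not zeroed", {
  m <- parseBooleanNet("X *= True")
  sig <- loadSignatures("On = (X=1)")
  st <- runPhenotypeStatistics(m, c(X = 1L), signatures = sig,
                               apoptosisSignature = c(X = 1L),
                               tMinLive = 100L, maxRestarts = 50L)
  expect_true(st$degenerate)
  expect_true(is.na(st$dwellFractions[["On"]]))
})

test_that("exclusive phenotype dwell fractions sum to at most one", {
  emt <- buildEmtSwitch()
  sig <- structure(defaultSignatures()[c("Epithelial", "Mesenchymal",
                                         "Hybrid_EM")],
                   class = "phenotypeSignatures")
  set.seed(6)
  s0 <- setNames(as.integer(runif(10) < 0.5), nodeNames(emt))
  st <- runPhenotypeStatistics(emt, s0, engine = "noisy", pNoise = 0.05,
                               signatures = sig, tMinLive = 5000L)
  expect_lte(sum(st$dwellFractions), 1 + 1e-12)
})

test_that("doubling the live-time target leaves rates stable", {
  m <- constant_off_model(1)
  sig <- loadSignatures("On = (N1=1)")
  set.seed(31)
  s1 <- runPhenotypeStatistics(m, c(N1 = 0L), engine = "noisy",
                               pNoise = 0.2, signatures = sig,
                               tMinLive = 10000L)
  s2 <- runPhenotypeStatistics(m, c(N1 = 0L), engine = "noisy",
                               pNoise = 0.2, signatures = sig,
                               tMinLive = 20000L)
  expect_lt(abs(s1$dwellFractions[["On"]] - s2$dwellFractions[["On"]]),
            4 * sqrt(0.2 * 0.8 / 10000))
})
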