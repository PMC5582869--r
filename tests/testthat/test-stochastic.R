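test_that("deterministic-to-stochastic conversion round-trips", {
  p <- referencePalmParams()
  sp <- toMoleculeUnits(p, nCopies = 1600)
  expect_equal(sum(sp$xss), 1600, tolerance = 1e-6)
  # first-order rates unchanged, zero-order and Km-type scaled by omega
  expect_equal(sp$params@kd, p@kd)
  expect_equal(sp$params@kFold, p@kFold)
  expect_equal(sp$params@kSyn, p@kSyn * sp$omega)
  expect_equal(sp$params@KmPal, p@KmPal * sp$omega)
  # inverse scaling recovers the original parameters
  back <- sp$params
  back@kSyn <- back@kSyn / sp$omega
  back@KmPal <- back@KmPal / sp$omega
  back@KmDepal <- back@KmDepal / sp$omega
  back@e16Total <- back@e16Total / sp$omega
  back@apt2Total <- back@apt2Total / sp$omega
  expect_equal(back, p, tolerance = 1e-12)
  # identity when the copy target equals the deterministic total
  tot <- sum(solveSteadyState(p))
  sp1 <- toMoleculeUnits(p, nCopies = tot)
  expect_equal(sp1$omega, 1, tolerance = 1e-8)
})

test_that("SSA produces no events without rates and is seed-reproducible", {
  p <- applyMutant(tinyParams(kSyn = 0, kFold = 0, kd = 0, kcat = 0,
                              kcatD = 0), "AAA")
  out <- simulateSSA(p, tEnd = 5, seed = 1,
                     x0 = c(U = 3, C = 7))
  expect_true(all(out[, "U"] == 3) && all(out[, "C"] == 7))
  q <- applyMutant(tinyParams(), "CAA")
  a <- simulateSSA(q, tEnd = 5, seed = 42, x0 = c(U = 5, C0 = 5, C1 = 0))
  b <- simulateSSA(q, tEnd = 5, seed = 42, x0 = c(U = 5, C0 = 5, C1 = 0))
  expect_identical(a, b)
})

test_that("pure birth-death counts are Poisson distributed at stationarity", {
  # synthesis + degradation of U only (no folding): N ~ Poisson(kSyn/kdU)
  p <- applyMutant(tinyParams(kSyn = 20, kFold = 0, kd = 0, kcat = 0,
                              kcatD = 0, kdU = 1), "AAA")
  lambda <- 20
  out <- simulateSSA(p, tEnd = 600, seed = 7,
                     x0 = c(U = round(lambda), C = 0),
                     recordTimes = seq(10, 600, 1))
  n <- out[, "U"]
  # chi-square against Poisson(lambda) with pooled tails
  br <- c(-Inf, qpois(seq(0.1, 0.9, 0.1), lambda), Inf)
  obs <- table(cut(n, br))
  pr <- diff(ppois(c(-Inf, qpois(seq(0.1, 0.9, 0.1), lambda), Inf),
                   lambda))
  # counts are autocorrelated; thin the series
  nth <- n[seq(1, length(n), 5)]
  obs <- as.vector(table(cut(nth, br)))
  cs <- suppressWarnings(chisq.test(obs, p = pr, rescale.p = TRUE))
  expect_gt(cs$p.value, 0.01)
})

test_that("SSA population mean tracks the ODE solution", {
  q <- applyMutant(tinyParams(kSyn = 30, kFold = 2, kd = 0.3), "AAA")
  times <- c(0, 1, 2, 4, 8)
  ode <- simulateNetwork(q, times)
  nrep <- 200
  acc <- matrix(0, length(times), 2)
  acc2 <- matrix(0, length(times), 2)
  for (i in seq_len(nrep)) {
    out <- simulateSSA(q, tEnd = 8, seed = 1000 + i,
                       x0 = c(U = 0, C = 0), recordTimes = times)
    acc <- acc + out[, -1]
    acc2 <- acc2 + out[, -1]^2
  }
  mean_ <- acc / nrep
  se <- sqrt(pmax(acc2 / nrep - mean_^2, 0) / nrep)
  for (j in 1:2) {
    expect_true(all(abs(mean_[-1, j] - ode[-1, j + 1]) <=
                      3 * se[-1, j] + 1e-9))
  }
})

test_that("siteless molecules pass exactly once through U and the folded state", {
  p <- applyMutant(tinyParams(kFold = 5, kd = 0.5), "AAA")
  st <- trackSingleMolecules(p, nMolecules = 500, seed = 3)
  expect_equal(unname(st@passages[["U"]]), 1)
  expect_equal(unname(st@passages[["C"]]), 1)
  # exponential residence in the folded state with rate kd
  ks <- suppressWarnings(
    ks.test(st@visitTimes[["C"]], "pexp", rate = 0.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("refuses tracking when no molecule can ever degrade", {
  p <- applyMutant(tinyParams(kd = 0, kdU = 0), "AAA")
  expect_error(trackSingleMolecules(p, nMolecules = 10, seed = 1),
               "never absorb")
})

test_that("trajectory bookkeeping: entries minus exits and event censuses", {
  p <- referencePalmParams()
  st <- trackSingleMolecules(p, nMolecules = 400, seed = 5)
  tc <- st@transitionCounts
  # per state: total entries (incl. synthesis into U) minus exits equals 0;
  # exits include degradation, so every entry is matched
  n <- nrow(tc) - 1
  entries <- colSums(tc)[1:n]
  entries[1] <- entries[1] + st@nMolecules        # synthesis into U
  exits <- rowSums(tc)[1:n]
  expect_equal(unname(entries), unname(exits))
  # zero palmitoylation -> no palmitoylation events anywhere
  p0 <- tinyParams(kcat = 0)
  st0 <- trackSingleMolecules(p0, nMolecules = 100, seed = 6)
  expect_equal(countTransitionEvents(st0, c("C000", "C100")), 0)
  expect_equal(countTransitionEvents(st0, "C011"), 0)
  expect_error(countTransitionEvents(st0, "C9"), "unknown state")
})

test_that("single-site passage counts match absorbing-chain algebra", {
  p <- tinyParams(kd = 0.15)
  pc <- applyMutant(p, "CAA")
  st <- trackSingleMolecules(pc, nMolecules = 4000, seed = 9)
  oracle <- expectedVisitsOracle(pc)
  for (s in c("C0", "C1")) {
    se <- sqrt(oracle[[s]] / st@nMolecules)   # coarse visit-count scale
    expect_lt(abs(st@passages[[s]] - oracle[[s]]), 3 * max(se, 0.02))
  }
})

test_that("occupancy-time fractions agree with the deterministic distribution", {
  p <- referencePalmParams()
  st <- trackSingleMolecules(p, nMolecules = 1500, seed = 10)
  totals <- vapply(names(st@visitTimes), function(s)
    sum(st@visitTimes[[s]]), numeric(1))
  frac <- totals[-1] / sum(totals[-1])          # folded states only
  x <- solveSteadyState(p)
  ref <- speciesDistribution(x)
  expect_lt(max(abs(frac - ref[names(frac)])), 0.03)
})
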