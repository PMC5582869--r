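test_that("label-resolved state space has 3^m states with consistent projections", {
  wt <- expandLabelStates("WT")
  expect_equal(nrow(wt), 27)
  expect_equal(nrow(expandLabelStates("CAA")), 3)
  expect_equal(nrow(expandLabelStates("AAA")), 1)
  # projecting labels onto occupancy recovers each occupancy state
  # 2^(occupied sites) label assignments... summed over states = 3^m
  expect_setequal(unique(wt$occupancy), enumerateStates("WT"))
  counts <- table(wt$occupancy)
  bits <- nchar(gsub("0", "", sub("C", "", names(counts))))
  expect_equal(unname(as.integer(counts)), 2^bits)
})

test_that("35S chase is flat without degradation and exponential for the siteless chain", {
  p0 <- tinyParams(kd = 0, kdU = 0)
  tc <- simulatePulseChase35S(protocol("S35_pulse_chase", chaseTimes = 0:5),
                              p0)
  expect_equal(tc$signal_pct, rep(100, 6), tolerance = 1e-6)
  # AAA with fast folding: single exponential with half-life ln2/kd
  p1 <- applyMutant(tinyParams(kFold = 1000, kd = 0.1, kdU = 0), "AAA")
  tc1 <- simulatePulseChase35S(
    protocol("S35_pulse_chase", construct = "AAA",
             chaseTimes = c(0, 3, 6.93, 10)), p1)
  expect_equal(tc1$signal_pct[3], 50, tolerance = 1)
  expect_equal(tc1$signal_pct[1], 100, tolerance = 1e-8)
})

test_that("35S cohort equals the frozen-steady-state linear solver", {
  p <- randomParams(13)
  times <- seq(0, 24, 3)
  tc <- simulatePulseChase35S(
    protocol("S35_pulse_chase", chaseTimes = times), p)
  model <- palmcycle:::compileModel(p)
  xss <- unname(solveSteadyState(p))
  fast <- palmcycle:::.fast35S(model, xss, 1 / 3, times)
  expect_equal(tc$signal_pct, fast, tolerance = 1e-5)
})

test_that("palmitate incorporation is zero without sites and 100 for WT by construction", {
  p <- referencePalmParams()
  inc <- simulatePalmIncorporation(protocol("H3_incorporation"), p)
  expect_equal(inc[["WT"]], 100)
  expect_equal(inc[["AAA"]], 0)
  expect_true(all(inc >= 0))
})

test_that("single-site incorporation matches the closed-form flux integral", {
  # one site, no depalmitoylation: at stationary background the hot
  # palmitate count obeys dH/dt = v_pal - kd(C100) H, so
  # H(t) = v/kd (1 - exp(-kd t))
  p <- tinyParams(kcatD = 0, kd = 0.05, kdU = 0)
  pc <- applyMutant(p, "CAA")
  pu <- palmcycle:::.hotPalmPulse(protocol("H3_incorporation",
                                           construct = "CAA"), p)
  net <- buildNetwork("CAA")
  xss <- solveSteadyState(pc, net)
  fl <- reactionFluxes(pc, xss, net)
  v <- fl$flux[fl$kind == "palmitoylation"]
  kd <- pc@kd[["C100"]]
  expect_equal(pu$endOfPulse, v / kd * (1 - exp(-kd * 2)),
               tolerance = 1e-4)
})

test_that("palmitate release decays only when loss paths exist and is monotone", {
  p0 <- tinyParams(kcatD = 0, kd = 0, kdU = 0)
  tc0 <- simulatePalmChase(protocol("H3_chase"), p0)
  expect_equal(tc0$signal_pct, rep(100, 9), tolerance = 1e-6)
  p <- referencePalmParams()
  tc <- simulatePalmChase(protocol("H3_chase"), p)
  expect_equal(tc$signal_pct[1], 100)
  expect_true(all(diff(tc$signal_pct) <= 1e-8))
})

test_that("single-site release matches the analytic label chain", {
  # CAA without degradation: hot site-1 palmitate is lost at the constant
  # per-molecule depalmitoylation rate -> exponential decay
  p <- tinyParams(kd = 1e-4, kdU = 0)
  pc <- applyMutant(p, "CAA")
  net <- buildNetwork("CAA")
  model <- palmcycle:::compileModel(pc, net)
  xss <- unname(solveSteadyState(pc, net))
  kDep <- palmcycle:::.tqssaPerMolecule(xss[model$depal$sub],
                                        model$depal$kcat,
                                        model$depal$Km, model$APT2)
  lam <- kDep[1] + pc@kd[["C100"]]
  tc <- simulatePalmChase(protocol("H3_chase", construct = "CAA",
                                   chaseTimes = 0:6), p)
  expect_equal(tc$signal_pct, 100 * exp(-lam * (0:6)), tolerance = 0.01)
})

test_that("label-resolved model projects exactly onto the unlabelled model", {
  p <- randomParams(17)
  model <- palmcycle:::compileModel(p)
  ls <- palmcycle:::.labelStructure(model)
  xss <- unname(solveSteadyState(p))
  y0 <- palmcycle:::.allColdInit(xss, ls)
  times <- seq(0, 2, 0.5)
  lab <- palmcycle:::.integrateLabel(y0, model, ls, times, mode = "hot")
  ref <- simulateNetwork(p, times, x0 = xss)
  for (i in seq_along(times)) {
    tot <- palmcycle:::.accum(nrow(model$net@bits), ls$occIdx,
                              lab[i, -1])
    expect_equal(unname(c(lab[i, 1], tot)), unname(ref[i, -1]),
                 tolerance = 1e-7)
  }
})

test_that("tracer response is linear in the cohort size", {
  p <- randomParams(19)
  model <- palmcycle:::compileModel(p)
  xss <- unname(solveSteadyState(p))
  A <- palmcycle:::.perMoleculeGenerator(xss, model)
  h0 <- runif(model$n)
  t1 <- palmcycle:::.linPropagate(A, h0, c(1, 2))
  t2 <- palmcycle:::.linPropagate(A, 2 * h0, c(1, 2))
  expect_equal(2 * t1, t2, tolerance = 1e-10)
})

test_that("steady-state stoichiometry distribution is a probability law", {
  p <- referencePalmParams()
  d <- simulatePegylation(p)
  expect_equal(sum(d), 1, tolerance = 1e-10)
  expect_named(d, c("0", "1", "2", "3"))
  dAAA <- simulatePegylation(applyMutant(p, "AAA"))
  expect_equal(unname(dAAA[["0"]]), 1)
  dU <- simulatePegylation(p, includeUnfolded = TRUE)
  expect_gt(dU[["0"]], d[["0"]] - 1)  # still a distribution
  expect_equal(sum(dU), 1, tolerance = 1e-10)
})

test_that("apparent half-life interpolates the first 50% crossing", {
  tc <- data.frame(time_hr = 0:5, signal_pct = 100 * exp(-log(2) * 0:5))
  expect_equal(apparentHalfLife(tc), 1, tolerance = 1e-6)
  flat <- data.frame(time_hr = 0:5, signal_pct = rep(100, 6))
  expect_error(apparentHalfLife(flat), class = "palmcycle_no_halflife")
  # biexponential against a dense root-find oracle
  f <- function(t) 40 * exp(-t * log(2) / 1) + 60 * exp(-t * log(2) / 50)
  tg <- seq(0, 40, 0.5)
  tc2 <- data.frame(time_hr = tg, signal_pct = f(tg))
  oracle <- uniroot(function(t) f(t) - 50, c(0, 40), tol = 1e-10)$root
  expect_equal(apparentHalfLife(tc2), oracle, tolerance = 0.01)
})
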