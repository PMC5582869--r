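makeToyObjectives <- function() {
  p <- referencePalmParams()
  df <- generateDataset(p, noise = noiseModel(sigma = 0))
  list(truth = p, data = df, obj = makeObjectives(df))
}

test_that("objectives vanish at the generating parameters and scale as mean squares", {
  toy <- makeToyObjectives()
  v <- toy$obj$evalParams(toy$truth)
  expect_lt(max(v), 1e-10)
  expect_length(v, 12)    # the default calibration partition
  # constant +10% offset on one experiment -> objective = 100
  g1 <- toy$obj$groups[[1]]
  shifted <- g1
  shifted$signal_pct <- shifted$signal_pct + 10
  obj2 <- makeObjectives(shifted)
  expect_equal(unname(obj2$evalParams(toy$truth)), 100, tolerance = 1e-6)
})

test_that("objective equals the hand-computed mean squared residual", {
  p <- referencePalmParams()
  tc <- simulatePulseChase35S(
    protocol("S35_pulse_chase", chaseTimes = c(0, 4, 8)), p)
  df <- data.frame(time_hr = c(0, 4, 8),
                   signal_pct = c(95, 60, 40),
                   experiment = "S35_20min", construct = "WT",
                   condition = "control", replicate = 1)
  obj <- makeObjectives(df)
  got <- unname(obj$evalParams(p))
  want <- mean((tc$signal_pct - df$signal_pct)^2)
  expect_equal(got, want, tolerance = 1e-4)
})

test_that("GA locates the optimum of a convex quadratic", {
  f <- function(x) sum((x - c(0.3, -0.7, 1.2))^2) + 0.5
  cfg <- gaConfig(popSize = 50, generations = 100, space = NULL,
                  lower = rep(-2, 3), upper = rep(2, 3), seed = 4)
  ens <- runGA(list(f), cfg)
  best <- min(scores(ens)[, 1])
  expect_lt((best - 0.5) / 0.5, 0.01)
})

test_that("GA front is nondominated and seed-deterministic", {
  f1 <- function(x) sum(x^2)
  f2 <- function(x) sum((x - 1)^2)
  cfg <- gaConfig(popSize = 40, generations = 25, space = NULL,
                  lower = rep(-1, 2), upper = rep(2, 2), seed = 9)
  ens <- runGA(list(f1, f2), cfg)
  F <- scores(ens)
  # brute-force pairwise nondomination
  for (i in seq_len(nrow(F))) for (j in seq_len(nrow(F))) {
    if (i != j)
      expect_false(all(F[j, ] <= F[i, ]) && any(F[j, ] < F[i, ]))
  }
  ens2 <- runGA(list(f1, f2), cfg)
  expect_identical(scores(ens), scores(ens2))
  expect_identical(ens@provenance$par, ens2@provenance$par)
})

test_that("gaConfig rejects degenerate settings", {
  expect_error(gaConfig(popSize = 2, space = NULL, lower = 0, upper = 1),
               ">= 4")
  expect_error(gaConfig(space = NULL, lower = 1, upper = 0), "infeasible")
})

test_that("ensemble selection ranks by normalized aggregate score", {
  mem <- lapply(1:4, function(i) i)
  sc <- rbind(c(1, 10), c(2, 20), c(0.5, 5), c(3, 30))
  front <- new("ParetoEnsemble", members = mem, scores = sc,
               provenance = list())
  sel <- selectEnsemble(front, 1)
  expect_identical(members(sel)[[1]], 3L)        # dominates on both
  expect_length(members(selectEnsemble(front, 10)), 4)
  # large synthetic front: selection equals the sort-based oracle
  set.seed(1)
  n <- 2000
  sc2 <- cbind(runif(n), runif(n))
  front2 <- new("ParetoEnsemble", members = as.list(seq_len(n)),
                scores = sc2, provenance = list())
  k <- 152
  sel2 <- selectEnsemble(front2, k)
  norm <- apply(sc2, 2, function(cl) (cl - min(cl)) / diff(range(cl)))
  agg <- rowSums(norm)
  oracle <- order(agg, seq_len(n))[seq_len(k)]
  expect_identical(unlist(members(sel2)), oracle)
  expect_length(members(sel2), 152)
  expect_lte(max(agg[oracle]), min(agg[-oracle]))
})

test_that("ensemble prediction reports mean, population sd and quartiles", {
  mkP <- function(x) x
  singleton <- new("ParetoEnsemble", members = list(5),
                   scores = matrix(0, 1, 1), provenance = list())
  pr <- ensemblePredict(singleton, function(m) c(a = m * 2))
  expect_equal(pr$mean, 10)
  expect_equal(pr$sd, 0)
  expect_equal(pr$q1, pr$q3)
  two <- new("ParetoEnsemble", members = list(80, 120),
             scores = matrix(0, 2, 1), provenance = list())
  pr2 <- ensemblePredict(two, function(m) m)
  expect_equal(pr2$mean, 100)
  expect_equal(pr2$sd, 20)
  # failing member flagged, not silent
  bad <- new("ParetoEnsemble", members = list(1, "boom", 3),
             scores = matrix(0, 3, 1), provenance = list())
  expect_warning(pr3 <- ensemblePredict(bad, function(m) {
    if (is.character(m)) stop("no") else m
  }), "excluded")
  expect_equal(pr3$mean, 2)
  # quartiles match a sort-based oracle on a synthetic ensemble
  set.seed(2)
  vals <- rnorm(152, 100, 10)
  ens <- new("ParetoEnsemble", members = as.list(vals),
             scores = matrix(0, 152, 1), provenance = list())
  pr4 <- ensemblePredict(ens, function(m) m)
  expect_equal(pr4$q1, unname(quantile(vals, 0.25)))
  expect_equal(pr4$q3, unname(quantile(vals, 0.75)))
})
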