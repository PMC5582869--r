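test_that("state enumeration covers the occupancy hypercube", {
  wt <- enumerateStates("WT")
  expect_length(wt, 8)
  expect_identical(wt[1], "C000")
  expect_identical(sort(wt), wt)            # canonical lexicographic order
  expect_setequal(wt, paste0("C", apply(expand.grid(0:1, 0:1, 0:1), 1,
                                        paste, collapse = "")))
  expect_identical(enumerateStates("CAA"), c("C0", "C1"))
  expect_identical(enumerateStates("AAA"), "C")
  expect_error(enumerateStates("XYZ"), "unknown mutant")
})

test_that("network reaction counts match brute-force enumeration", {
  # every free site of every state is palmitoylatable: m * 2^(m-1) edges
  for (mt in c("WT", "ACC", "CAA", "AAA")) {
    m <- length(activeSites(mt))
    net <- buildNetwork(mt)
    k <- table(factor(net@reactions$kind,
                      levels = c("synthesis", "folding", "palmitoylation",
                                 "depalmitoylation", "degradation")))
    expect_equal(unname(k[["palmitoylation"]]), m * 2^(m - 1))
    expect_equal(unname(k[["depalmitoylation"]]), m * 2^(m - 1))
    expect_equal(unname(k[["degradation"]]), 1 + 2^m)
    expect_equal(unname(k[["synthesis"]]), 1)
    expect_equal(unname(k[["folding"]]), 1)
  }
  expect_equal(nrow(buildNetwork("WT")@reactions), 35)
  expect_equal(nrow(buildNetwork("AAA")@reactions), 4)
  expect_equal(nrow(buildNetwork("CAA")@reactions), 7)
})

test_that("palmitoylation edges flip exactly one site 0 -> 1", {
  net <- buildNetwork("WT")
  rx <- net@reactions
  bits <- function(lab) as.integer(strsplit(sub("C", "", lab), "")[[1]])
  for (i in which(rx$kind == "palmitoylation")) {
    d <- bits(rx$to[i]) - bits(rx$from[i])
    expect_equal(sum(d == 1), 1)
    expect_equal(sum(d != 0), 1)
    expect_identical(rx$enzyme[i], "ZDHHC16")
  }
  for (i in which(rx$kind == "depalmitoylation")) {
    d <- bits(rx$to[i]) - bits(rx$from[i])
    expect_equal(sum(d == -1), 1)
    expect_equal(sum(d != 0), 1)
    expect_identical(rx$enzyme[i], "APT2")
  }
})

test_that("mutant restriction maps states and parameters consistently", {
  p <- referencePalmParams()
  caa <- applyMutant(p, "CAA")
  expect_identical(caa@mutant, "CAA")
  expect_setequal(names(caa@kd), c("C000", "C100"))
  expect_equal(caa@kd[["C100"]], p@kd[["C100"]])
  expect_equal(caa@kcatPal[["Cys328"]], p@kcatPal[["Cys328"]])
  # identity on same mutant
  expect_identical(applyMutant(p, "WT"), p)
  # AAA network collapses to U and the siteless folded state
  aaa <- applyMutant(p, "AAA")
  expect_identical(buildNetwork("AAA")@species, c("U", "C"))
  expect_equal(aaa@kd[["C000"]], p@kd[["C000"]])
})

test_that("site knockout equals kcat = 0 restriction of the full network", {
  p <- tinyParams()
  times <- seq(0, 20, 1)
  # WT with sites 2,3 silenced and never initially occupied
  p0 <- p
  p0@kcatPal[c("Cys329", "Cys343")] <- 0
  full <- simulateNetwork(p0, times)
  red <- simulateNetwork(applyMutant(p, "CAA"), times)
  expect_lt(max(abs(full[, "C000"] - red[, "C0"])), 1e-8)
  expect_lt(max(abs(full[, "C100"] - red[, "C1"])), 1e-8)
  expect_lt(max(abs(full[, "U"] - red[, "U"])), 1e-8)
})

test_that("hypercube symmetry: permuting sites with their parameters permutes the solution", {
  p <- randomParams(11)
  # swap sites 1 and 2 (Cys328 <-> Cys329) in parameters
  swp <- function(v) v[c("Cys329", "Cys328", "Cys343")]
  kd2 <- p@kd
  relab <- function(lab) {
    b <- strsplit(sub("C", "", lab), "")[[1]]
    paste0("C", paste(b[c(2, 1, 3)], collapse = ""))
  }
  names(kd2) <- vapply(names(p@kd), relab, "")
  q <- palmParams(kSyn = p@kSyn, kFold = p@kFold, kdU = p@kdU,
                  kd = kd2[names(p@kd)],
                  kcatPal = stats::setNames(unname(swp(p@kcatPal)),
                                            names(p@kcatPal)),
                  KmPal = stats::setNames(unname(swp(p@KmPal)),
                                          names(p@KmPal)),
                  kcatDepal = stats::setNames(unname(swp(p@kcatDepal)),
                                              names(p@kcatDepal)),
                  KmDepal = stats::setNames(unname(swp(p@KmDepal)),
                                            names(p@KmDepal)),
                  e16Total = p@e16Total, apt2Total = p@apt2Total)
  x1 <- solveSteadyState(p)
  x2 <- solveSteadyState(q)
  for (s in names(x1)[-1]) {
    expect_equal(x2[[relab(s)]], x1[[s]], tolerance = 1e-6)
  }
})
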