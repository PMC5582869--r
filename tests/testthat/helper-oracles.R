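# Shared fixtures and independent oracles, built in code.

# small single-site parameter set (CAA-like network passed as its own WT
# would be invalid; use applyMutant on a compact WT set)
tinyParams <- function(kSyn = 1, kFold = 5, kd = 0.2, kcat = 1, Km = 5,
                       kcatD = 0.8, KmD = 5, E16 = 2, APT2 = 2,
                       kdU = 0) {
  states <- enumerateStates("WT")
  palmParams(kSyn = kSyn, kFold = kFold, kdU = kdU,
             kd = stats::setNames(rep(kd, 8), states),
             kcatPal = rep(kcat, 3), KmPal = rep(Km, 3),
             kcatDepal = rep(kcatD, 3), KmDepal = rep(KmD, 3),
             e16Total = E16, apt2Total = APT2, mutant = "WT")
}

# random WT parameter set in a tQSSA-friendly regime, reproducible
randomParams <- function(seed) {
  set.seed(seed)
  states <- enumerateStates("WT")
  palmParams(kSyn = runif(1, 0.5, 2), kFold = runif(1, 2, 8), kdU = 0,
             kd = stats::setNames(10^runif(8, -2.5, -0.5), states),
             kcatPal = 10^runif(3, -1, 0.5), KmPal = 10^runif(3, 0.3, 1.3),
             kcatDepal = 10^runif(3, -1, 0.5),
             KmDepal = 10^runif(3, 0.3, 1.3),
             e16Total = runif(1, 1, 4), apt2Total = runif(1, 1, 4),
             mutant = "WT")
}

# random parameters in the regime where the closed-form tQSSA rate is a
# faithful reduction of the binding scheme: fast binding equilibration,
# enzyme below Km + substrate, enzyme of the order of substrate totals
oracleParams <- function(seed) {
  set.seed(seed)
  states <- enumerateStates("WT")
  palmParams(kSyn = 1, kFold = runif(1, 2, 6), kdU = 0,
             kd = stats::setNames(runif(8, 0.05, 0.3), states),
             kcatPal = runif(3, 0.3, 1.5), KmPal = runif(3, 5, 15),
             kcatDepal = runif(3, 0.3, 1.5), KmDepal = runif(3, 5, 15),
             e16Total = runif(1, 0.5, 1.5),
             apt2Total = runif(1, 0.5, 1.5), mutant = "WT")
}

# Independent mass-action oracle: explicit enzyme-substrate complexes for
# every palmitoylation/depalmitoylation reaction of a mutant network.
# Binding kon = (koff + kcat) / Km with koff = koffFactor * kcat (fast
# binding equilibration).  Species: U, folded states, free E16, free APT2,
# one complex per enzymatic reaction.  Returns total (free + complexed)
# occupancy-state trajectories on the requested grid.
massActionTrajectory <- function(p, times, koffFactor = 100) {
  net <- buildNetwork(p@mutant)
  rx <- net@reactions
  pal <- rx[rx$kind == "palmitoylation", , drop = FALSE]
  dep <- rx[rx$kind == "depalmitoylation", , drop = FALSE]
  sp <- net@species
  ns <- length(sp)
  nPal <- nrow(pal); nDep <- nrow(dep)
  siteName <- function(site) c("Cys328", "Cys329", "Cys343")[site]
  konP <- koffP <- kcP <- numeric(nPal)
  for (j in seq_len(nPal)) {
    kc <- p@kcatPal[[siteName(pal$site[j])]]
    Km <- p@KmPal[[siteName(pal$site[j])]]
    kcP[j] <- kc; koffP[j] <- koffFactor * max(kc, 0.1)
    konP[j] <- (koffP[j] + kc) / Km
  }
  konD <- koffD <- kcD <- numeric(nDep)
  for (j in seq_len(nDep)) {
    kc <- p@kcatDepal[[siteName(dep$site[j])]]
    Km <- p@KmDepal[[siteName(dep$site[j])]]
    kcD[j] <- kc; koffD[j] <- koffFactor * max(kc, 0.1)
    konD[j] <- (koffD[j] + kc) / Km
  }
  kdAll <- c(p@kdU, p@kd[net@fullLabels])
  iE <- ns + 1L; iA <- ns + 2L
  iCP <- ns + 2L + seq_len(nPal)
  iCD <- ns + 2L + nPal + seq_len(nDep)
  nTot <- ns + 2L + nPal + nDep
  rhs <- function(t, y, parms) {
    dy <- numeric(nTot)
    dy[1] <- p@kSyn - p@kFold * y[1] - p@kdU * y[1]
    dy[2] <- dy[2] + p@kFold * y[1]
    dy[1:ns] <- dy[1:ns] - kdAll * y[1:ns]
    for (j in seq_len(nPal)) {
      s <- match(pal$from[j], sp); pr <- match(pal$to[j], sp)
      vb <- konP[j] * y[iE] * y[s]
      vu <- koffP[j] * y[iCP[j]]
      vc <- kcP[j] * y[iCP[j]]
      vd <- kdAll[s] * y[iCP[j]]      # complexed substrate degrades too
      dy[s] <- dy[s] - vb + vu
      dy[iE] <- dy[iE] - vb + vu + vc + vd
      dy[iCP[j]] <- dy[iCP[j]] + vb - vu - vc - vd
      dy[pr] <- dy[pr] + vc
    }
    for (j in seq_len(nDep)) {
      s <- match(dep$from[j], sp); pr <- match(dep$to[j], sp)
      vb <- konD[j] * y[iA] * y[s]
      vu <- koffD[j] * y[iCD[j]]
      vc <- kcD[j] * y[iCD[j]]
      vd <- kdAll[s] * y[iCD[j]]
      dy[s] <- dy[s] - vb + vu
      dy[iA] <- dy[iA] - vb + vu + vc + vd
      dy[iCD[j]] <- dy[iCD[j]] + vb - vu - vc - vd
      dy[pr] <- dy[pr] + vc
    }
    list(dy)
  }
  y0 <- numeric(nTot); y0[iE] <- p@e16Total; y0[iA] <- p@apt2Total
  out <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12, maxsteps = 50000)
  out <- unname(as.matrix(out)[, -1, drop = FALSE])
  # totals: free species + the complexes whose substrate they are
  tot <- out[, 1:ns, drop = FALSE]
  for (j in seq_len(nPal)) {
    s <- match(pal$from[j], sp)
    tot[, s] <- tot[, s] + out[, iCP[j]]
  }
  for (j in seq_len(nDep)) {
    s <- match(dep$from[j], sp)
    tot[, s] <- tot[, s] + out[, iCD[j]]
  }
  colnames(tot) <- sp
  tot
}

# expected visits to each state of the mean-field single-molecule chain,
# starting from U, by absorbing-Markov-chain algebra (independent of the
# simulation code path)
expectedVisitsOracle <- function(p) {
  net <- buildNetwork(p@mutant)
  model <- palmcycle:::compileModel(p, net)
  xss <- unname(solveSteadyState(p, net))
  A <- palmcycle:::.perMoleculeGenerator(xss, model)
  n <- nrow(A)
  lam <- -diag(A)
  P <- t(A); diag(P) <- 0; P <- P / lam
  N <- solve(diag(n) - P)
  stats::setNames(N[1, ], net@species)
}
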