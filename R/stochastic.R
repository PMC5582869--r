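#' Convert deterministic parameters to molecule-count units
#'
#' Chooses the system size Omega so that the deterministic steady-state
#' total ZDHHC6 equals \code{nCopies} molecules (about 1600 per HeLa cell
#' for ZDHHC6), then rescales: concentrations and Km-type constants by
#' Omega, the zero-order synthesis rate by Omega, first-order rates
#' unchanged.
#'
#' @param p parameter set in concentration units (a.u.).
#' @param nCopies target steady-state copy number; default 1600.
#' @return list with the converted \code{params} (\linkS4class{PalmParams}
#'   in molecule units), \code{omega}, \code{nCopies}, and the
#'   molecule-unit steady state \code{xss}.
#' @export
toMoleculeUnits <- function(p, nCopies = 1600) {
  stopifnot(nCopies > 0)
  xss <- solveSteadyState(p)
  tot <- sum(xss)
  if (tot <= 0) stop("zero steady-state total; cannot scale", call. = FALSE)
  omega <- nCopies / tot
  sp <- p
  sp@kSyn <- p@kSyn * omega
  sp@KmPal <- p@KmPal * omega
  sp@KmDepal <- p@KmDepal * omega
  sp@e16Total <- p@e16Total * omega
  sp@apt2Total <- p@apt2Total * omega
  structure(list(params = sp, omega = omega, nCopies = nCopies,
                 xss = xss * omega),
            class = "palmStochParams")
}

#' Exact stochastic simulation of the population model
#'
#' Gillespie direct-method simulation of the molecule-count network, with
#' propensities given by the tQSSA rate expressions evaluated on current
#' counts (synthesis, folding and degradation follow mass action).
#'
#' @param sp output of \code{\link{toMoleculeUnits}} (or a
#'   \linkS4class{PalmParams} already in molecule units).
#' @param tEnd simulation horizon (h).
#' @param seed RNG seed.
#' @param x0 initial integer counts; default the rounded deterministic
#'   steady state.
#' @param recordTimes checkpoint times at which counts are sampled;
#'   default \code{seq(0, tEnd, length.out = 11)}.
#' @param maxEvents event budget guard.
#' @return matrix of counts, rows = checkpoints (column \code{time} first).
#' @export
simulateSSA <- function(sp, tEnd, seed = NULL, x0 = NULL,
                        recordTimes = NULL, maxEvents = 5e6) {
  p <- if (inherits(sp, "palmStochParams")) sp$params else sp
  if (!is.null(seed)) set.seed(seed)
  net <- buildNetwork(p@mutant)
  model <- compileModel(p, net)
  n <- model$n
  if (is.null(x0)) {
    x0 <- if (inherits(sp, "palmStochParams")) round(sp$xss)
          else round(solveSteadyState(p, net))
  }
  x <- unname(.asStateVector(x0, net))
  if (is.null(recordTimes)) recordTimes <- seq(0, tEnd, length.out = 11)
  recordTimes <- sort(unique(pmin(recordTimes, tEnd)))
  out <- matrix(NA_real_, length(recordTimes), n,
                dimnames = list(NULL, net@species))
  t <- 0; nextRec <- 1L
  # reaction table: stoichiometry targets
  nPal <- length(model$pal$sub); nDep <- length(model$depal$sub)
  for (ev in seq_len(maxEvents)) {
    a <- c(model$kSyn,                                   # synthesis
           model$kFold * x[1L],                          # folding
           c(model$kdU, model$kd) * x,                   # degradation
           .tqssaFamily(x[model$pal$sub], model$pal$kcat, model$pal$Km,
                        model$E16),
           .tqssaFamily(x[model$depal$sub], model$depal$kcat,
                        model$depal$Km, model$APT2))
    a0 <- sum(a)
    tNext <- if (a0 <= 0) tEnd + 1e-9 else t + stats::rexp(1L, a0)
    # the state is piecewise constant on [t, tNext): checkpoints in that
    # window see the pre-event state
    while (nextRec <= length(recordTimes) && recordTimes[nextRec] < tNext) {
      out[nextRec, ] <- x; nextRec <- nextRec + 1L
    }
    if (nextRec > length(recordTimes) || tNext > tEnd) break
    t <- tNext
    r <- sample.int(length(a), 1L, prob = a)
    if (r == 1L) x[1L] <- x[1L] + 1L
    else if (r == 2L) { x[1L] <- x[1L] - 1L; x[2L] <- x[2L] + 1L }
    else if (r <= 2L + n) { i <- r - 2L; x[i] <- x[i] - 1L }
    else if (r <= 2L + n + nPal) {
      j <- r - 2L - n
      x[model$pal$sub[j]] <- x[model$pal$sub[j]] - 1L
      x[model$pal$prod[j]] <- x[model$pal$prod[j]] + 1L
    } else {
      j <- r - 2L - n - nPal
      x[model$depal$sub[j]] <- x[model$depal$sub[j]] - 1L
      x[model$depal$prod[j]] <- x[model$depal$prod[j]] + 1L
    }
  }
  while (nextRec <= length(recordTimes)) {
    out[nextRec, ] <- x; nextRec <- nextRec + 1L
  }
  cbind(time = recordTimes, out)
}

#' Single-molecule tracking at stationarity
#'
#' Follows individual ZDHHC6 molecules from synthesis (state U) to
#' degradation as a continuous-time Markov chain whose jump rates are the
#' per-molecule tQSSA rates evaluated at the deterministic steady state
#' (mean-field background).  Returns passage counts, residence-time
#' medians, per-molecule cumulative-time medians and a transition-event
#' census aggregated over all molecules.
#'
#' @param p parameter set (concentration units; per-molecule rates are
#'   unit-free).
#' @param nMolecules number of independent molecules; default 10000.
#' @param seed RNG seed.
#' @param e16Scale,apt2Scale optional enzyme perturbation.
#' @param maxJumps per-simulation jump budget guard.
#' @return a \linkS4class{TrajectoryStats}.
#' @export
trackSingleMolecules <- function(p, nMolecules = 10000, seed = 1,
                                 e16Scale = 1, apt2Scale = 1,
                                 maxJumps = 1e4) {
  p <- perturbParams(p, e16Scale, apt2Scale)
  net <- buildNetwork(p@mutant)
  model <- compileModel(p, net)
  if (model$kdU == 0 && all(model$kd == 0))
    stop("all degradation rates are zero: molecules never absorb",
         call. = FALSE)
  xss <- unname(solveSteadyState(p, net))
  A <- .perMoleculeGenerator(xss, model)
  n <- model$n
  # rate matrix to n+1 states (last = degraded)
  R <- matrix(0, n, n + 1L)
  R[, 1:n] <- t(A); diag(R) <- 0
  R[, n + 1L] <- c(model$kdU, model$kd)
  lam <- rowSums(R)
  states <- c(net@species, "degraded")

  set.seed(seed)
  st <- rep(1L, nMolecules)          # all start in U
  alive <- seq_len(nMolecules)
  visitMol <- visitState <- integer(0)
  visitDwell <- numeric(0)
  trans <- matrix(0, n + 1L, n + 1L, dimnames = list(states, states))
  for (jump in seq_len(maxJumps)) {
    if (!length(alive)) break
    stuck <- lam[st[alive]] <= 0
    if (any(stuck)) {
      warning(sum(stuck), " molecule(s) reached a state with no exit ",
              "rate and were dropped")
      alive <- alive[!stuck]
      if (!length(alive)) break
    }
    cur <- st[alive]
    dwell <- stats::rexp(length(alive), lam[cur])
    visitMol <- c(visitMol, alive)
    visitState <- c(visitState, cur)
    visitDwell <- c(visitDwell, dwell)
    nxt <- integer(length(alive))
    for (s in unique(cur)) {
      i <- which(cur == s)
      nxt[i] <- sample.int(n + 1L, length(i), replace = TRUE,
                           prob = R[s, ])
    }
    tt <- table(factor(cur, levels = seq_len(n + 1L)),
                factor(nxt, levels = seq_len(n + 1L)))
    trans <- trans + matrix(as.integer(tt), n + 1L, n + 1L)
    st[alive] <- nxt
    alive <- alive[nxt <= n]
  }
  if (length(alive))
    warning(length(alive), " molecule(s) hit the jump budget before ",
            "degradation")

  passages <- tabulate(visitState, nbins = n) / nMolecules
  resMed <- vapply(seq_len(n), function(s) {
    d <- visitDwell[visitState == s]
    if (length(d)) stats::median(d) else NA_real_
  }, numeric(1))
  cumMed <- vapply(seq_len(n), function(s) {
    i <- visitState == s
    if (!any(i)) return(NA_real_)
    stats::median(rowsum(visitDwell[i], visitMol[i]))
  }, numeric(1))
  new("TrajectoryStats",
      passages = stats::setNames(passages, net@species),
      residenceMedian = stats::setNames(resMed, net@species),
      cumulativeMedian = stats::setNames(cumMed, net@species),
      transitionCounts = trans,
      visitTimes = split(visitDwell, factor(net@species[visitState],
                                            levels = net@species)),
      nMolecules = nMolecules, seed = seed)
}

#' Count palmitoylation/depalmitoylation events around a state
#'
#' Totals, over all tracked molecules, the palmitoylation and
#' depalmitoylation transition events adjacent to a focus state (all
#' hypercube edges touching it) or between an ordered/unordered pair of
#' states.
#'
#' @param stats a \linkS4class{TrajectoryStats}.
#' @param focus a single state label, or a length-2 vector (pair of
#'   neighbouring states; both directions are summed).
#' @return integer event count.
#' @export
countTransitionEvents <- function(stats, focus) {
  tc <- stats@transitionCounts
  labs <- rownames(tc)
  if (!all(focus %in% labs))
    stop("unknown state label: ",
         paste(setdiff(focus, labs), collapse = ", "), call. = FALSE)
  if (length(focus) == 2L)
    return(tc[focus[1L], focus[2L]] + tc[focus[2L], focus[1L]])
  # hypercube neighbours: state labels of equal length differing in one bit
  s <- focus
  bits <- function(lab) as.integer(strsplit(sub("^C", "", lab), "")[[1L]])
  nb <- labs[vapply(labs, function(l) {
    if (!grepl("^C[01]*$", l) || l == s || nchar(l) != nchar(s)) return(FALSE)
    sum(bits(l) != bits(s)) == 1L
  }, TRUE)]
  sum(vapply(nb, function(l) tc[s, l] + tc[l, s], numeric(1)))
}
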