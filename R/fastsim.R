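# Fast labelling-curve simulators used by calibration and ensemble
# prediction.  When the unlabelled background sits at steady state, every
# labelling protocol reduces to a linear constant-coefficient system for
# the labelled sub-population (the per-molecule tQSSA rates are frozen at
# their steady-state values), solved here with matrix exponentials.  The
# co-integrated solvers in labelling.R are the general reference; the two
# agree to integration tolerance because the protocols start from, and do
# not displace, the steady state.

# dense matrix exponential by scaling and squaring with a Taylor core
# (||A||/2^s <= 0.25 so 16 terms reach machine precision); the matrices
# here are small (<= ~30 x 30) generator matrices, where this is several
# times faster than S4-dispatched alternatives
.expmDense <- function(A) {
  n <- nrow(A)
  if (n == 0L) return(A)
  nrm <- max(colSums(abs(A)))
  s <- if (nrm > 0.25) ceiling(log2(nrm / 0.25)) else 0L
  As <- A / 2^s
  E <- diag(n) + As
  term <- As
  for (k in 2:16) {
    term <- term %*% As / k
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

.expmStep <- function(A, dt, cache) {
  key <- as.character(dt)
  if (is.null(cache[[key]]))
    cache[[key]] <- .expmDense(A * dt)
  cache[[key]]
}

# propagate dy/dt = A y (+ b) from y0 through sorted times (starting at 0);
# an expm cache may be shared across calls with the same A
.linPropagate <- function(A, y0, times, b = NULL, cache = NULL) {
  n <- length(y0)
  if (!is.null(b)) {          # augment constant source
    A <- rbind(cbind(A, b), 0)
    y0 <- c(y0, 1)
    cache <- NULL             # augmented matrix: do not share
  }
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  out <- matrix(NA_real_, length(times), n)
  y <- y0; tprev <- 0
  for (i in seq_along(times)) {
    dt <- times[i] - tprev
    if (dt > 0) y <- .expmStep(A, dt, cache) %*% y
    out[i, ] <- y[seq_len(n)]
    tprev <- times[i]
  }
  out
}

# 35S cohort curve at frozen steady state; returns % of end-of-pulse
# signal.  cc (optional) is a per-construct context carrying the
# generator and a shared chase-propagator cache.
.fast35S <- function(model, xss, pulse, times, cc = NULL) {
  A <- if (!is.null(cc$A)) cc$A else .perMoleculeGenerator(xss, model)
  src <- c(model$kSyn, numeric(model$n - 1L))
  h1 <- .linPropagate(A, numeric(model$n), pulse, b = src)[1L, ]
  ref <- sum(h1)
  h <- .linPropagate(A, h1, times, cache = cc$expmCache)
  100 * rowSums(h) / ref
}

# hot-palmitate count system: one block per site over the states carrying
# that site; returns generator B, pulse source b and block bookkeeping
.hotCountSystem <- function(model, xss) {
  net <- model$net
  m <- length(net@sites)
  if (m == 0L)
    return(list(B = matrix(0, 0, 0), b = numeric(0)))
  A <- .perMoleculeGenerator(xss, model)
  Aff <- A[-1L, -1L, drop = FALSE]
  vPal <- .tqssaFamily(xss[model$pal$sub], model$pal$kcat, model$pal$Km,
                       model$E16)
  blocks <- list()
  for (k in seq_len(m)) {
    idx <- which(net@bits[, k] == 1L)          # folded-state indices
    B <- Aff[idx, idx, drop = FALSE]
    b <- numeric(length(idx))
    r <- which(model$pal$site == net@sites[k])
    tgt <- match(model$pal$prod[r] - 1L, idx)
    b[tgt] <- vPal[r]
    blocks[[k]] <- list(B = B, b = b)
  }
  B <- as.matrix(Matrix::bdiag(lapply(blocks, `[[`, "B")))
  b <- unlist(lapply(blocks, `[[`, "b"))
  list(B = B, b = b)
}

# end-of-pulse hot palmitate count (population expectation, a.u.)
.fastH3Pulse <- function(model, xss, pulse) {
  hs <- .hotCountSystem(model, xss)
  if (!length(hs$b)) return(list(y = numeric(0), signal = 0))
  y <- .linPropagate(hs$B, numeric(length(hs$b)), pulse, b = hs$b)[1L, ]
  list(y = y, signal = sum(y), B = hs$B)
}

.fastH3Chase <- function(model, xss, pulse, times) {
  pu <- .fastH3Pulse(model, xss, pulse)
  if (!length(pu$y) || pu$signal <= 0) return(rep(0, length(times)))
  y <- .linPropagate(pu$B, pu$y, times)
  100 * rowSums(y) / pu$signal
}

# steady state with the cheap Newton path and integration fallback
.fastSS <- function(p, net = buildNetwork(p@mutant)) {
  x <- tryCatch(solveSteadyState(p, net, method = "newton"),
                error = function(e) NULL)
  if (is.null(x)) x <- solveSteadyState(p, net)
  x
}
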