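#' Integrate the deterministic model
#'
#' Stiff implicit integration (\code{deSolve::lsoda}) of the network ODE
#' from a given initial state.  Default tolerances rtol 1e-8, atol 1e-10.
#'
#' @param p a \linkS4class{PalmParams}.
#' @param times increasing time grid (h); must start at the initial time.
#' @param x0 initial state (named over species, or canonical order);
#'   defaults to the empty system.
#' @param net network, defaults to \code{p}'s mutant.
#' @param rtol,atol solver tolerances.
#' @return matrix of concentrations, rows = times (with a \code{"time"}
#'   column), columns named by species.
#' @export
simulateNetwork <- function(p, times, x0 = NULL, net = buildNetwork(p@mutant),
                            rtol = 1e-8, atol = 1e-10) {
  model <- compileModel(p, net)
  if (is.null(x0)) x0 <- numeric(model$n)
  x0 <- .asStateVector(x0, net)
  f <- function(t, y, parms) list(.rhs(pmax(y, 0), model))
  out <- deSolve::lsoda(y = stats::setNames(x0, net@species), times = times,
                        func = f, parms = NULL, rtol = rtol, atol = atol)
  class(out) <- "matrix"
  out
}

# Damped Newton root polish on the folded subsystem; U is solved exactly.
.newtonSteadyState <- function(model, x0, tol, maxit = 60L) {
  n <- model$n
  x <- x0
  x[1L] <- model$kSyn / (model$kFold + model$kdU)
  res <- .rhs(x, model)
  nrm <- max(abs(res))
  for (it in seq_len(maxit)) {
    if (nrm < tol) break
    # finite-difference Jacobian over folded states
    idx <- 2:n
    J <- matrix(0, n - 1L, n - 1L)
    for (j in seq_along(idx)) {
      h <- 1e-7 * max(abs(x[idx[j]]), 1e-6)
      xp <- x; xp[idx[j]] <- xp[idx[j]] + h
      J[, j] <- (.rhs(xp, model)[idx] - res[idx]) / h
    }
    step <- tryCatch(solve(J, -res[idx]), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      xn <- x
      xn[idx] <- pmax(x[idx] + lam * step, 0)
      rn <- .rhs(xn, model)
      if (max(abs(rn)) < nrm || lam < 1e-4) break
      lam <- lam / 2
    }
    if (max(abs(rn)) >= nrm && lam < 1e-4) return(NULL)
    x <- xn; res <- rn; nrm <- max(abs(rn))
  }
  if (nrm < tol) x else NULL
}

#' Solve for the steady state
#'
#' Finds the stationary concentration vector of the open network.  The
#' default strategy integrates the stiff ODE from the empty system over a
#' long horizon and polishes the endpoint with damped Newton iterations;
#' \code{method = "newton"} skips the integration and starts Newton from a
#' cheap heuristic (falling back to integration if it fails).  The result
#' satisfies \code{max |dx/dt| < tol * kSyn} and is non-negative.
#'
#' @inheritParams simulateNetwork
#' @param method \code{"integrate"} (default) or \code{"newton"}.
#' @param tol residual tolerance relative to \code{kSyn}.
#' @param tmax integration horizon (h) for the default method.
#' @return named steady-state vector over species.
#' @examples
#' xs <- solveSteadyState(referencePalmParams())
#' @export
solveSteadyState <- function(p, net = buildNetwork(p@mutant),
                             method = c("integrate", "newton"),
                             tol = 1e-8, tmax = 5000) {
  method <- match.arg(method)
  model <- compileModel(p, net)
  atol <- tol * max(model$kSyn, 1e-12)
  if (model$kSyn == 0) atol <- tol
  x <- NULL
  if (method == "newton") {
    guess <- numeric(model$n)
    guess[2L] <- model$kSyn / max(model$kd[1L], 1e-3)
    x <- .newtonSteadyState(model, guess, atol)
    if (is.null(x)) {
      # cheap staged relaxation before the expensive strict integration
      xe <- numeric(model$n)
      for (tEnd in c(tmax / 20, tmax)) {
        tr <- suppressWarnings(
          simulateNetwork(p, times = c(0, tEnd), x0 = xe, net = net,
                          rtol = 1e-6, atol = 1e-9))
        xe <- pmax(unname(tr[nrow(tr), -1L]), 0)
        x <- .newtonSteadyState(model, xe, atol)
        if (!is.null(x)) break
      }
    }
  }
  if (is.null(x)) {
    tr <- suppressWarnings(
      simulateNetwork(p, times = c(0, tmax / 10, tmax), net = net,
                      rtol = 1e-10, atol = 1e-12))
    xe <- pmax(tr[nrow(tr), -1L], 0)
    x <- .newtonSteadyState(model, unname(xe), atol)
    if (is.null(x)) {
      if (max(abs(.rhs(unname(xe), model))) < atol) x <- unname(xe)
      else stop("steady-state solve did not converge", call. = FALSE)
    }
  }
  stats::setNames(pmax(x, 0), net@species)
}
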