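#' Labelling protocol description
#'
#' Describes one in-silico labelling experiment: a metabolic 35S-Cys/Met
#' pulse-chase (backbone label), 3H-palmitate incorporation (scalar readout
#' at end of pulse), 3H-palmitate release (palmitate-label chase), or a
#' PEGylation stoichiometry snapshot at steady state.
#'
#' @param kind experiment kind.
#' @param construct mutant code.
#' @param pulse pulse duration (h).  Defaults: 1/3 h (20 min) for
#'   35S pulse-chase, 2 h for the 3H protocols.
#' @param chaseTimes chase sampling grid (h), starting at 0 = end of pulse.
#' @param e16Scale,apt2Scale enzyme perturbation factors.
#' @param condition free-text condition label used in data files.
#' @return a list of class \code{"palmProtocol"}.
#' @export
protocol <- function(kind = c("S35_pulse_chase", "H3_incorporation",
                              "H3_chase", "PEGylation"),
                     construct = "WT", pulse = NULL, chaseTimes = NULL,
                     e16Scale = 1, apt2Scale = 1, condition = "control") {
  kind <- match.arg(kind)
  if (is.null(pulse))
    pulse <- switch(kind, S35_pulse_chase = 1 / 3, PEGylation = 0, 2)
  if (is.null(chaseTimes))
    chaseTimes <- switch(kind,
                         S35_pulse_chase = seq(0, 30, by = 2),
                         H3_chase = 0:8, numeric(0))
  if (is.unsorted(chaseTimes) || any(chaseTimes < 0))
    stop("chaseTimes must be sorted and non-negative", call. = FALSE)
  if (pulse <= 0 && kind != "PEGylation")
    stop("pulse duration must be positive", call. = FALSE)
  structure(list(kind = kind, construct = .normMutant(construct),
                 pulse = pulse, chaseTimes = chaseTimes,
                 e16Scale = e16Scale, apt2Scale = apt2Scale,
                 condition = condition),
            class = "palmProtocol")
}

.protoParams <- function(proto, p) {
  perturbParams(applyMutant(p, proto$construct),
                e16Scale = proto$e16Scale, apt2Scale = proto$apt2Scale)
}

# pre-pulse background: the steady state when one exists; for degenerate
# parameterizations without a finite steady state (all degradation rates
# zero) a long-integration endpoint is used -- the labelling signals of
# interest are insensitive to the residual drift in that case
.backgroundState <- function(p, net) {
  tryCatch(unname(solveSteadyState(p, net)), error = function(e) {
    tr <- simulateNetwork(p, times = c(0, 500), net = net)
    unname(pmax(tr[nrow(tr), -1L], 0))
  })
}

#' Enumerate palmitate-label-resolved states
#'
#' Refines each occupancy state by the label of every attached palmitate
#' (\code{"-"} empty site, \code{"c"} cold, \code{"h"} hot/radiolabelled),
#' giving 3^m site-label states for m active sites.
#'
#' @inheritParams activeSites
#' @return data.frame with the label string, the underlying occupancy
#'   state, and the number of hot palmitates.
#' @examples
#' nrow(expandLabelStates("WT"))   # 27
#' @export
expandLabelStates <- function(mutant) {
  sites <- activeSites(mutant)
  m <- length(sites)
  L <- .labelMatrix(m)
  occ <- stateLabels(matrix(as.integer(L > 0), nrow(L), m))
  data.frame(label = .labelStrings(L),
             occupancy = occ,
             nHot = rowSums(L == 2L))
}

# (3^m x m) matrix over {0 empty, 1 cold, 2 hot}, lexicographic
.labelMatrix <- function(m) {
  if (m == 0L) return(matrix(integer(0), 1L, 0L))
  g <- as.matrix(expand.grid(rep(list(0:2), m))[, m:1, drop = FALSE])
  g <- g[order(apply(g, 1L, paste, collapse = "")), , drop = FALSE]
  dimnames(g) <- NULL
  g
}

.labelStrings <- function(L) {
  if (ncol(L) == 0L) return("C")
  paste0("C", apply(matrix(c("-", "c", "h")[L + 1L], nrow(L)), 1L,
                    paste, collapse = ""))
}

# Static structure of the label-resolved system for one compiled model.
.labelStructure <- function(model) {
  m <- length(model$net@sites)
  L <- .labelMatrix(m)
  nl <- nrow(L)
  occKey <- apply(matrix(as.integer(L > 0L), nl, m), 1L, paste, collapse = "")
  bitKey <- apply(model$net@bits, 1L, paste, collapse = "")
  occIdx <- match(occKey, bitKey)              # folded-state index
  labKey <- apply(L, 1L, paste, collapse = "")
  find <- function(row) match(paste(row, collapse = ""), labKey)
  palF <- palH <- palC <- palR <- integer(0)
  depF <- depT <- depR <- integer(0)
  for (i in seq_len(nl)) for (k in seq_len(m)) {
    sp <- 1L + occIdx[i]                       # species index of occupancy
    site <- model$net@sites[k]
    if (L[i, k] == 0L) {
      r <- which(model$pal$sub == sp & model$pal$site == site)
      a <- L[i, ]; a[k] <- 2L; h <- find(a); a[k] <- 1L; cc <- find(a)
      palF <- c(palF, i); palH <- c(palH, h); palC <- c(palC, cc)
      palR <- c(palR, r)
    } else {
      r <- which(model$depal$sub == sp & model$depal$site == site)
      a <- L[i, ]; a[k] <- 0L
      depF <- c(depF, i); depT <- c(depT, find(a)); depR <- c(depR, r)
    }
  }
  list(L = L, nl = nl, occIdx = occIdx, emptyIdx = find(rep(0L, m)),
       pal = list(from = palF, toHot = palH, toCold = palC, rx = palR),
       dep = list(from = depF, to = depT, rx = depR),
       nHot = rowSums(L == 2L))
}

.accum <- function(n, idx, vals) {
  out <- numeric(n)
  if (length(idx)) {
    s <- rowsum(vals, idx)
    out[as.integer(rownames(s))] <- s
  }
  out
}

# RHS of the label-resolved system; y = c(U, label states).  Saturation and
# competition are evaluated on the total (projected) pools, so summing the
# label states over label assignments reproduces the unlabelled model
# exactly.  mode: "hot" routes new palmitates to hot labels, "cold" to cold.
.labelRhs <- function(y, model, ls, mode) {
  tot <- .accum(nrow(model$net@bits), ls$occIdx, y[-1L])
  x <- c(y[1L], tot)
  kPal <- .tqssaPerMolecule(x[model$pal$sub], model$pal$kcat, model$pal$Km,
                            model$E16)
  kDep <- .tqssaPerMolecule(x[model$depal$sub], model$depal$kcat,
                            model$depal$Km, model$APT2)
  ny <- 1L + ls$nl
  dy <- numeric(ny)
  dy[1L] <- model$kSyn - (model$kFold + model$kdU) * y[1L]
  dy[1L + ls$emptyIdx] <- dy[1L + ls$emptyIdx] + model$kFold * y[1L]
  dy[-1L] <- dy[-1L] - model$kd[ls$occIdx] * y[-1L]
  pTo <- if (mode == "hot") ls$pal$toHot else ls$pal$toCold
  vP <- kPal[ls$pal$rx] * y[1L + ls$pal$from]
  vD <- kDep[ls$dep$rx] * y[1L + ls$dep$from]
  dy <- dy - .accum(ny, 1L + ls$pal$from, vP) + .accum(ny, 1L + pTo, vP)
  dy <- dy - .accum(ny, 1L + ls$dep$from, vD) + .accum(ny, 1L + ls$dep$to, vD)
  dy
}

# all-cold embedding of an occupancy state vector into the label space:
# cold = 1 numerically coincides with an occupied bit, so the all-cold
# representative of a folded state has label row equal to its bit row
.allColdInit <- function(x, ls) {
  y <- numeric(1L + ls$nl)
  y[1L] <- x[1L]
  labKey <- apply(ls$L, 1L, paste, collapse = "")
  bits <- matrix(as.integer(ls$L > 0L), ls$nl, ncol(ls$L))
  for (s in seq_along(x[-1L])) {
    i <- which(ls$occIdx == s)[1L]
    j <- match(paste(bits[i, ], collapse = ""), labKey)
    y[1L + j] <- x[1L + s]
  }
  y
}

.integrateLabel <- function(y0, model, ls, times, mode,
                            rtol = 1e-8, atol = 1e-10) {
  f <- function(t, y, parms) list(.labelRhs(pmax(y, 0), model, ls, mode))
  out <- deSolve::lsoda(y = y0, times = times, func = f, parms = NULL,
                        rtol = rtol, atol = atol)
  unname(as.matrix(out)[, -1L, drop = FALSE])
}

#' Simulate a 35S metabolic pulse-chase experiment
#'
#' The unlabelled system is first brought to steady state; during the pulse
#' window the synthesized cohort carries a hot backbone (total synthesis is
#' unchanged), and during the chase hot synthesis stops.  The cohort is
#' co-integrated with the full system so that enzymatic saturation and
#' competition are evaluated on total pools.  The signal is total hot
#' protein summed over all species, normalized to 100 at the end of the
#' pulse.
#'
#' @param proto a \code{\link{protocol}} of kind \code{"S35_pulse_chase"}.
#' @param p parameter set (any construct containing the protocol's sites).
#' @return data.frame with columns time_hr, signal_pct plus protocol
#'   metadata (a TimeCourse).
#' @export
simulatePulseChase35S <- function(proto, p) {
  stopifnot(inherits(proto, "palmProtocol"), proto$kind == "S35_pulse_chase")
  p <- .protoParams(proto, p)
  net <- buildNetwork(p@mutant)
  model <- compileModel(p, net)
  xss <- .backgroundState(p, net)
  n <- model$n
  f <- function(t, z, parms) {
    x <- pmax(z[1:n], 0); h <- z[(n + 1):(2 * n)]
    A <- .perMoleculeGenerator(x, model)
    src <- if (parms$hot) c(model$kSyn, numeric(n - 1L)) else numeric(n)
    list(c(.rhs(x, model), as.vector(A %*% h) + src))
  }
  z0 <- c(xss, numeric(n))
  pl <- deSolve::lsoda(z0, c(0, proto$pulse), f, parms = list(hot = TRUE),
                       rtol = 1e-8, atol = 1e-10)
  z1 <- unname(as.matrix(pl)[nrow(pl), -1L])
  times <- proto$chaseTimes
  ch <- deSolve::lsoda(z1, unique(c(0, times)), f, parms = list(hot = FALSE),
                       rtol = 1e-8, atol = 1e-10)
  ch <- unname(as.matrix(ch)[, -1L, drop = FALSE])
  hot <- rowSums(ch[, (n + 1):(2 * n), drop = FALSE])
  ref <- hot[1L]
  sig <- 100 * hot[match(times, unique(c(0, times)))] / ref
  .timeCourse(times, sig, "S35_pulse_chase", proto)
}

.timeCourse <- function(times, signal, experiment, proto, replicate = 1L) {
  data.frame(time_hr = times, signal_pct = signal,
             experiment = experiment, construct = proto$construct,
             condition = proto$condition, replicate = replicate)
}

#' Simulate 3H-palmitate incorporation
#'
#' From the background steady state, every palmitoylation event during the
#' pulse attaches a hot palmitate (palmitate in excess).  The readout is
#' the expected number of hot palmitates summed over the protein population
#' at the end of the pulse, reported as percent of the WT value when WT is
#' among the requested constructs (otherwise raw hot-palmitate counts).
#'
#' @param proto a \code{\link{protocol}} of kind \code{"H3_incorporation"}
#'   (its construct is ignored when \code{constructs} is given).
#' @param p WT parameter set.
#' @param constructs constructs to simulate; default all eight.
#' @return named numeric vector of signals.
#' @export
simulatePalmIncorporation <- function(proto, p, constructs = .MUTANTS) {
  stopifnot(inherits(proto, "palmProtocol"),
            proto$kind == "H3_incorporation")
  raw <- vapply(constructs, function(mt) {
    pr <- protocol("H3_incorporation", construct = mt, pulse = proto$pulse,
                   e16Scale = proto$e16Scale, apt2Scale = proto$apt2Scale,
                   condition = proto$condition)
    .hotPalmPulse(pr, p)$endOfPulse
  }, numeric(1))
  if ("WT" %in% constructs && raw[["WT"]] > 0) 100 * raw / raw[["WT"]] else raw
}

# run the hot-palmitate pulse on the label-resolved system; returns the
# end-of-pulse state and machinery for the chase
.hotPalmPulse <- function(proto, p) {
  p <- .protoParams(proto, p)
  net <- buildNetwork(p@mutant)
  model <- compileModel(p, net)
  ls <- .labelStructure(model)
  xss <- .backgroundState(p, net)
  y0 <- .allColdInit(xss, ls)
  yp <- .integrateLabel(y0, model, ls, c(0, proto$pulse), mode = "hot")
  yEnd <- yp[nrow(yp), ]
  list(model = model, ls = ls, yEnd = yEnd,
       endOfPulse = sum(ls$nHot * yEnd[-1L]))
}

#' Simulate a 3H-palmitate release (pulse-chase) experiment
#'
#' Hot palmitate is attached during the pulse as in
#' \code{\link{simulatePalmIncorporation}}; during the chase all new
#' palmitoylations are cold, and the hot signal decays through
#' depalmitoylation of hot sites and degradation of hot-carrying protein.
#' The signal is normalized to 100 at the end of the pulse and is monotone
#' non-increasing in chase time.
#'
#' @param proto a \code{\link{protocol}} of kind \code{"H3_chase"}.
#' @param p parameter set.
#' @return TimeCourse data.frame.
#' @export
simulatePalmChase <- function(proto, p) {
  stopifnot(inherits(proto, "palmProtocol"), proto$kind == "H3_chase")
  pu <- .hotPalmPulse(proto, p)
  times <- proto$chaseTimes
  grid <- unique(c(0, times))
  ch <- .integrateLabel(pu$yEnd, pu$model, pu$ls, grid, mode = "cold")
  hot <- as.vector(ch[, -1L, drop = FALSE] %*% pu$ls$nHot)
  ref <- hot[1L]
  if (ref <= 0) {
    sig <- rep(0, length(times))
  } else sig <- 100 * hot[match(times, grid)] / ref
  .timeCourse(times, sig, "H3_chase", proto)
}

#' Steady-state palmitoylation stoichiometry (in-silico PEGylation)
#'
#' Probability for a ZDHHC6 molecule to carry 0..m palmitates at steady
#' state.  The unfolded precursor U is excluded by default (the gel assay
#' detects the mature protein); \code{includeUnfolded = TRUE} counts U in
#' the zero-palmitate bin.
#'
#' @param p parameter set.
#' @param includeUnfolded include U in the denominator (and the 0 bin).
#' @return named numeric vector of probabilities summing to 1.
#' @export
simulatePegylation <- function(p, includeUnfolded = FALSE) {
  net <- buildNetwork(p@mutant)
  x <- solveSteadyState(p, net)
  counts <- rowSums(net@bits)
  m <- length(net@sites)
  mass <- vapply(0:m, function(k) sum(x[-1L][counts == k]), numeric(1))
  if (includeUnfolded) mass[1L] <- mass[1L] + x[[1L]]
  tot <- sum(mass)
  if (tot <= 0) stop("zero total protein at steady state", call. = FALSE)
  stats::setNames(mass / tot, as.character(0:m))
}

#' Apparent half-life of a normalized decay curve
#'
#' First crossing time of 50\% by linear interpolation between sampled
#' points of a curve normalized to 100 at time zero.  Signals an explicit
#' error of class \code{"palmcycle_no_halflife"} if the curve never crosses
#' 50\%.
#'
#' @param tc TimeCourse data.frame (columns time_hr, signal_pct) or a
#'   numeric signal vector with times in names/attribute.
#' @return half-life in hours.
#' @examples
#' tc <- data.frame(time_hr = 0:5, signal_pct = 100 * exp(-log(2) * 0:5))
#' apparentHalfLife(tc)   # 1
#' @export
apparentHalfLife <- function(tc) {
  t <- tc$time_hr; s <- tc$signal_pct
  below <- which(s <= 50)
  if (!length(below))
    stop(structure(class = c("palmcycle_no_halflife", "error", "condition"),
                   list(message = "undefined half-life: signal never crosses 50%",
                        call = sys.call())))
  i <- below[1L]
  if (s[i] == 50 || i == 1L) return(t[i])
  t[i - 1L] + (s[i - 1L] - 50) * (t[i] - t[i - 1L]) / (s[i - 1L] - s[i])
}
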