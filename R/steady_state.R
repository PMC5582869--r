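#' Intrinsic half-life of a palmitoylation state
#'
#' Returns \code{ln(2)/kd} for the state's first-order degradation
#' constant.  This is the intrinsic (state-resolved) half-life, not an
#' experimentally apparent turnover rate: a molecule keeps exchanging
#' between states, so its observed decay mixes several kd values (see
#' \code{\link{apparentHalfLife}} for the latter).  A state with kd = 0 has
#' infinite half-life, returned as \code{Inf}.
#'
#' @param p parameter set.
#' @param state full state label (\code{"C000"} ... \code{"C111"}); default
#'   all states of the construct.
#' @return half-life in hours (named if several states requested).
#' @examples
#' halfLife(referencePalmParams(), "C000")
#' @export
halfLife <- function(p, state = names(p@kd)) {
  bad <- setdiff(state, names(p@kd))
  if (length(bad)) stop("unknown state: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  kd <- p@kd[state]
  hl <- ifelse(kd > 0, log(2) / kd, Inf)
  if (length(hl) == 1L) unname(hl) else hl
}

#' Scale the enzyme totals of a parameter set
#'
#' Pure perturbation: multiplies total ZDHHC16 by \code{e16Scale} and total
#' APT2 by \code{apt2Scale}.  Named scenarios used throughout:
#' control (1, 1), ZDHHC16 overexpression (fold, 1; default fold 10),
#' APT2 silencing (1, 0), APT2 at 10\% (1, 0.1).
#'
#' @param p parameter set.
#' @param e16Scale,apt2Scale non-negative factors.
#' @return the perturbed \linkS4class{PalmParams}.
#' @export
perturbParams <- function(p, e16Scale = 1, apt2Scale = 1) {
  if (e16Scale < 0 || apt2Scale < 0)
    stop("perturbation scales must be non-negative", call. = FALSE)
  if (e16Scale == 1 && apt2Scale == 1) return(p)
  p@e16Total <- p@e16Total * e16Scale
  p@apt2Total <- p@apt2Total * apt2Scale
  p
}

#' Named perturbation scenarios
#'
#' @param oeFold ZDHHC16 overexpression fold (the experimental fold is not
#'   quantified; 10 is the package default).
#' @return named list of (e16Scale, apt2Scale) pairs.
#' @export
perturbationScenarios <- function(oeFold = 10) {
  list(control = c(e16Scale = 1, apt2Scale = 1),
       ZDHHC16_OE = c(e16Scale = oeFold, apt2Scale = 1),
       APT2_KD = c(e16Scale = 1, apt2Scale = 0),
       APT2_10pct = c(e16Scale = 1, apt2Scale = 0.1))
}

#' Per-reaction fluxes at a system state
#'
#' Evaluates every reaction's flux at \code{x} (by default the steady
#' state).  At steady state each species balances (|inflow - outflow| <
#' 1e-6 kSyn) and the synthesis flux equals the summed degradation flux.
#'
#' @inheritParams tqssaRate
#' @param x state vector; default the solved steady state.
#' @return data.frame: kind, from, to, site, enzyme, flux (a.u. h^-1).
#' @export
reactionFluxes <- function(p, x = NULL, net = buildNetwork(p@mutant)) {
  if (is.null(x)) x <- solveSteadyState(p, net)
  x <- .asStateVector(x, net)
  model <- compileModel(p, net)
  fl <- net@reactions
  fl$flux <- .reactionFluxVector(x, model)
  fl
}

#' Steady-state species distribution
#'
#' Fraction of total ZDHHC6 in each species, and (optionally) the total
#' relative to a reference condition.
#'
#' @param x state vector (named over species).
#' @param includeUnfolded include the unfolded precursor U; by default only
#'   mature (folded) species enter the denominator, consistent with
#'   Western-blot quantification of the mature protein.
#' @return named fractions summing to 1.
#' @export
speciesDistribution <- function(x, includeUnfolded = FALSE) {
  stopifnot(!is.null(names(x)))
  if (any(x < 0)) stop("negative concentration supplied", call. = FALSE)
  if (!includeUnfolded) x <- x[setdiff(names(x), "U")]
  tot <- sum(x)
  if (tot <= 0) stop("zero total protein", call. = FALSE)
  x / tot
}

#' Steady-state protein content under perturbation scenarios
#'
#' For each scenario and construct, solves the steady state and reports the
#' total (mature) ZDHHC6 content as percent of the WT control steady
#' state.  With an ensemble, every member is simulated independently and
#' pointwise mean, sd and quartiles are reported; members whose solve fails
#' are excluded with a warning.
#'
#' @param ens a \linkS4class{ParetoEnsemble} or a single
#'   \linkS4class{PalmParams}.
#' @param scenarios named list of c(e16Scale, apt2Scale); default
#'   \code{\link{perturbationScenarios}()}.
#' @param constructs mutant codes, default \code{"WT"}.
#' @param includeUnfolded count U in the content.
#' @return data.frame with scenario, construct and content statistics (%).
#' @export
contentResponse <- function(ens, scenarios = perturbationScenarios(),
                            constructs = "WT", includeUnfolded = FALSE) {
  mem <- if (is(ens, "ParetoEnsemble")) members(ens) else list(ens)
  rows <- list()
  perMember <- lapply(mem, function(p) {
    refX <- solveSteadyState(applyMutant(p, "WT"))
    ref <- sum(if (includeUnfolded) refX else refX[-1L])
    sapply(names(scenarios), function(sc) {
      sapply(constructs, function(mt) {
        pp <- perturbParams(applyMutant(p, mt),
                            scenarios[[sc]][["e16Scale"]],
                            scenarios[[sc]][["apt2Scale"]])
        x <- tryCatch(solveSteadyState(pp), error = function(e) NULL)
        if (is.null(x)) return(NA_real_)
        100 * sum(if (includeUnfolded) x else x[-1L]) / ref
      })
    })
  })
  for (sc in names(scenarios)) for (mt in constructs) {
    v <- vapply(perMember, function(mv) {
      mv <- matrix(mv, nrow = length(constructs),
                   dimnames = list(constructs, names(scenarios)))
      mv[mt, sc]
    }, numeric(1))
    if (anyNA(v)) {
      warning(sum(is.na(v)), " ensemble member(s) failed for ", sc, "/", mt,
              " and were excluded")
      v <- v[!is.na(v)]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = sc, construct = mt, content_pct = mean(v),
      sd = stats::sd(v), q1 = unname(stats::quantile(v, 0.25)),
      q3 = unname(stats::quantile(v, 0.75)))
  }
  do.call(rbind, rows)
}
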