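#' @import methods
NULL

#' Kinetic parameters of the palmitoylation network
#'
#' Holds every rate constant of the open synthesis/folding/degradation
#' network: zero-order synthesis of the unfolded species U, first-order
#' folding U -> C000, first-order degradation of U and of every folded
#' occupancy state, per-site catalytic constants and Michaelis constants for
#' ZDHHC16-catalysed palmitoylation and APT2-catalysed depalmitoylation, and
#' the two (constant) enzyme totals.  Time is in hours, concentrations in
#' arbitrary units (a.u.).
#'
#' Degradation rates are keyed by the \emph{full} three-site state label
#' (\code{"C000"} ... \code{"C111"}), with removed sites reading 0, so the
#' same keys work across mutants.  Site-level parameters are keyed
#' \code{"Cys328"}, \code{"Cys329"}, \code{"Cys343"} and restricted to the
#' mutant's active sites.
#'
#' @slot kSyn synthesis rate of U (a.u. h^-1).
#' @slot kFold folding rate U -> C000 (h^-1).
#' @slot kdU degradation rate of U (h^-1); 0 by default.
#' @slot kd named degradation rates of the folded states (h^-1).
#' @slot kcatPal,KmPal per-site palmitoylation kcat (h^-1) and Km (a.u.).
#' @slot kcatDepal,KmDepal per-site depalmitoylation kcat (h^-1) and Km (a.u.).
#' @slot e16Total total ZDHHC16 (a.u.).
#' @slot apt2Total total APT2 (a.u.).
#' @slot mutant construct code (see \link{mutants}).
#' @seealso \code{\link{palmParams}}, \code{\link{referencePalmParams}}
#' @export
setClass("PalmParams", representation(
  kSyn = "numeric", kFold = "numeric", kdU = "numeric", kd = "numeric",
  kcatPal = "numeric", KmPal = "numeric",
  kcatDepal = "numeric", KmDepal = "numeric",
  e16Total = "numeric", apt2Total = "numeric", mutant = "character"
))

setValidity("PalmParams", function(object) {
  msg <- character(0)
  sites <- activeSites(object@mutant)
  m <- length(sites)
  sn <- .SITE_NAMES[sites]
  want <- fullLabels(stateBits(m), sites)
  for (s in c("kSyn", "kFold", "kdU", "e16Total", "apt2Total")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0)
      msg <- c(msg, paste0(s, " must be a single non-negative number"))
  }
  if (!identical(sort(names(object@kd)), sort(want)))
    msg <- c(msg, paste0("kd must be named by the states ",
                         paste(want, collapse = ", ")))
  if (any(object@kd < 0)) msg <- c(msg, "kd must be non-negative")
  for (s in c("kcatPal", "KmPal", "kcatDepal", "KmDepal")) {
    v <- slot(object, s)
    if (!identical(sort(names(v)), sort(sn)))
      msg <- c(msg, paste0(s, " must be named by the active sites ",
                           paste(sn, collapse = ", ")))
    if (s %in% c("KmPal", "KmDepal")) {
      if (any(v <= 0)) msg <- c(msg, paste0(s, " must be strictly positive"))
    } else if (any(v < 0)) msg <- c(msg, paste0(s, " must be non-negative"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PalmParams object
#'
#' @param kSyn,kFold,kdU scalar rates (h^-1; kSyn in a.u. h^-1).
#' @param kd named numeric of degradation rates, keyed by full state labels
#'   (\code{"C000"}...\code{"C111"} for WT).
#' @param kcatPal,KmPal,kcatDepal,KmDepal per-site enzymatic constants,
#'   either named by \code{"Cys328"}/\code{"Cys329"}/\code{"Cys343"} or
#'   unnamed vectors over the mutant's active sites in order.
#' @param e16Total,apt2Total enzyme totals (a.u.).
#' @param mutant construct code, default \code{"WT"}.
#' @return a \linkS4class{PalmParams} object.
#' @examples
#' p <- palmParams(kSyn = 1, kFold = 3, kd = setNames(rep(0.1, 8),
#'                 enumerateStates("WT")),
#'                 kcatPal = c(1, 1, 1), KmPal = c(1, 1, 1),
#'                 kcatDepal = c(1, 1, 1), KmDepal = c(1, 1, 1),
#'                 e16Total = 0.5, apt2Total = 1)
#' @export
palmParams <- function(kSyn, kFold, kd, kcatPal, KmPal, kcatDepal, KmDepal,
                       e16Total, apt2Total, kdU = 0, mutant = "WT") {
  mutant <- .normMutant(mutant)
  sites <- activeSites(mutant)
  sn <- .SITE_NAMES[sites]
  nameSite <- function(v) {
    if (is.null(names(v))) {
      stopifnot(length(v) == length(sn))
      names(v) <- sn
    }
    v[sn]
  }
  kd <- unlist(kd)
  new("PalmParams", kSyn = kSyn, kFold = kFold, kdU = kdU, kd = kd,
      kcatPal = nameSite(kcatPal), KmPal = nameSite(KmPal),
      kcatDepal = nameSite(kcatDepal), KmDepal = nameSite(KmDepal),
      e16Total = e16Total, apt2Total = apt2Total, mutant = mutant)
}

setMethod("show", "PalmParams", function(object) {
  cat("PalmParams (", object@mutant, "): ",
      length(object@kd), " folded states, ",
      length(object@kcatPal), " active site(s)\n", sep = "")
  cat("  kSyn=", object@kSyn, " kFold=", object@kFold,
      " kdU=", object@kdU, "\n", sep = "")
  cat("  kd: ", paste(names(object@kd), signif(object@kd, 3),
                      sep = "=", collapse = " "), "\n", sep = "")
  cat("  E16=", object@e16Total, " APT2=", object@apt2Total, "\n", sep = "")
})

#' Reaction network over palmitoylation states
#'
#' Species are the unfolded precursor \code{"U"} followed by the folded
#' occupancy states in canonical order.  Reactions are synthesis, folding,
#' one palmitoylation and one depalmitoylation per (state, site) pair
#' forming the m-dimensional hypercube, and degradation of every species.
#'
#' @slot mutant construct code.
#' @slot sites active site indices.
#' @slot species species labels (\code{"U"} first).
#' @slot bits occupancy matrix (one row per folded state).
#' @slot fullLabels full three-site labels of the folded states.
#' @slot reactions data.frame with columns kind, from, to, site, enzyme.
#' @seealso \code{\link{buildNetwork}}
#' @export
setClass("ReactionNetwork", representation(
  mutant = "character", sites = "integer", species = "character",
  bits = "matrix", fullLabels = "character", reactions = "data.frame"
))

setValidity("ReactionNetwork", function(object) {
  m <- length(object@sites)
  if (length(object@species) != 1L + 2^m)
    return("species must be U plus 2^m folded states")
  if (object@species[1L] != "U") return("first species must be U")
  TRUE
})

setMethod("show", "ReactionNetwork", function(object) {
  k <- table(object@reactions$kind)
  cat("ReactionNetwork (", object@mutant, "): ",
      length(object@species), " species, ",
      nrow(object@reactions), " reactions\n  ", sep = "")
  cat(paste(names(k), as.integer(k), sep = ": ", collapse = ", "), "\n")
})

#' Pareto ensemble of calibrated parameter sets
#'
#' Result of multi-objective calibration: a set of parameter sets together
#' with their per-objective scores, no member strictly dominated by another.
#'
#' @slot members list of \linkS4class{PalmParams}.
#' @slot scores numeric matrix (members x objectives).
#' @slot provenance list (seed, configuration hash, selection info).
#' @seealso \code{\link{runGA}}, \code{\link{selectEnsemble}}
#' @export
setClass("ParetoEnsemble", representation(
  members = "list", scores = "matrix", provenance = "list"
))

setValidity("ParetoEnsemble", function(object) {
  if (length(object@members) != nrow(object@scores))
    return("one score row per member required")
  TRUE
})

setMethod("show", "ParetoEnsemble", function(object) {
  cat("ParetoEnsemble: ", length(object@members), " members, ",
      ncol(object@scores), " objectives\n", sep = "")
  if (length(object@members))
    cat("  aggregate score range: ",
        paste(signif(range(rowMeans(object@scores)), 4), collapse = " .. "),
        "\n", sep = "")
})

#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' Ensemble members
#' @param x a \linkS4class{ParetoEnsemble}
#' @return list of \linkS4class{PalmParams}
#' @export
setMethod("members", "ParetoEnsemble", function(x) x@members)

#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' Per-objective scores of an ensemble
#' @param x a \linkS4class{ParetoEnsemble}
#' @return numeric matrix, one row per member
#' @export
setMethod("scores", "ParetoEnsemble", function(x) x@scores)

#' Single-molecule tracking statistics
#'
#' Aggregates over independent single-molecule trajectories simulated from
#' synthesis (state U) to degradation: mean number of passages through each
#' state, median per-visit residence time, median per-molecule cumulative
#' time in each state, and counts of every observed state-to-state
#' transition.
#'
#' @slot passages mean passages per molecule, named by state.
#' @slot residenceMedian median per-visit residence time (h), named by state.
#' @slot cumulativeMedian median per-molecule total time in state (h).
#' @slot transitionCounts square matrix of transition event counts
#'   (rows = from, cols = to; includes the absorbing "degraded" column).
#' @slot visitTimes list of per-visit residence times by state.
#' @slot nMolecules number of simulated molecules.
#' @slot seed RNG seed used.
#' @seealso \code{\link{trackSingleMolecules}}
#' @export
setClass("TrajectoryStats", representation(
  passages = "numeric", residenceMedian = "numeric",
  cumulativeMedian = "numeric", transitionCounts = "matrix",
  visitTimes = "list", nMolecules = "numeric", seed = "numeric"
))

setMethod("show", "TrajectoryStats", function(object) {
  cat("TrajectoryStats over", object@nMolecules, "molecules\n")
  print(round(data.frame(
    passages = object@passages,
    median_visit_hr = object@residenceMedian,
    median_total_hr = object@cumulativeMedian), 3))
})
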