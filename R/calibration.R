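#' Calibration parameter space
#'
#' The free parameters estimated during calibration, searched in log10
#' space: folding rate, the eight state degradation rates, per-site
#' palmitoylation/depalmitoylation kcat and Km, and the two enzyme
#' totals (23 parameters).  The synthesis rate is fixed (the labelling
#' signals are normalized percentages and carry no concentration scale)
#' and degradation of the unfolded precursor is fixed at \code{kdU}.
#'
#' @param kSyn fixed synthesis rate (a.u. h^-1).
#' @param kdU fixed degradation rate of U (h^-1).
#' @param rateBounds,scaleBounds log10 bounds for rate constants and for
#'   Km / enzyme totals.
#' @param kFoldBounds log10 bounds for the folding rate.  Folding and
#'   membrane insertion of the mature protein complete within tens of
#'   minutes, so the default restricts kFold to 0.5--20 h^-1.  Without
#'   this prior the normalized labelling data admit a degenerate
#'   slow-folding solution family in which the undegradable precursor
#'   buffers the labelled cohort and mimics slow degradation.
#' @return list with \code{names}, \code{lower}, \code{upper} (log10) and
#'   \code{decode(z)} mapping a log10 vector to a
#'   \linkS4class{PalmParams}.
#' @export
palmParamSpace <- function(kSyn = 1, kdU = 0,
                           rateBounds = c(-4, 2), scaleBounds = c(-2, 2),
                           kFoldBounds = log10(c(0.5, 20))) {
  states <- enumerateStates("WT")
  nm <- c("kFold", paste0("kd_", states),
          paste0("kcatPal_", .SITE_NAMES), paste0("KmPal_", .SITE_NAMES),
          paste0("kcatDepal_", .SITE_NAMES),
          paste0("KmDepal_", .SITE_NAMES),
          "e16Total", "apt2Total")
  isScale <- grepl("^Km|Total$|^e16|^apt2", nm)
  lower <- ifelse(isScale, scaleBounds[1], rateBounds[1])
  upper <- ifelse(isScale, scaleBounds[2], rateBounds[2])
  lower[1] <- kFoldBounds[1]
  upper[1] <- kFoldBounds[2]
  template <- palmParams(
    kSyn = kSyn, kFold = 1, kdU = kdU,
    kd = stats::setNames(rep(1, 8), states),
    kcatPal = rep(1, 3), KmPal = rep(1, 3),
    kcatDepal = rep(1, 3), KmDepal = rep(1, 3),
    e16Total = 1, apt2Total = 1, mutant = "WT")
  iKd <- match(paste0("kd_", states), nm)
  iKp <- match(paste0("kcatPal_", .SITE_NAMES), nm)
  iKmp <- match(paste0("KmPal_", .SITE_NAMES), nm)
  iKdp <- match(paste0("kcatDepal_", .SITE_NAMES), nm)
  iKmd <- match(paste0("KmDepal_", .SITE_NAMES), nm)
  decode <- function(z) {
    v <- 10^z
    q <- template                     # bounds keep every entry positive
    q@kFold <- v[[1L]]
    q@kd[] <- v[iKd]
    q@kcatPal[] <- v[iKp]
    q@KmPal[] <- v[iKmp]
    q@kcatDepal[] <- v[iKdp]
    q@KmDepal[] <- v[iKmd]
    q@e16Total <- v[[22L]]
    q@apt2Total <- v[[23L]]
    q
  }
  encode <- function(p) {
    z <- log10(c(p@kFold, unname(p@kd[states]), unname(p@kcatPal),
                 unname(p@KmPal), unname(p@kcatDepal), unname(p@KmDepal),
                 p@e16Total, p@apt2Total))
    stats::setNames(z, nm)
  }
  list(names = nm, lower = stats::setNames(lower, nm),
       upper = stats::setNames(upper, nm), decode = decode, encode = encode)
}

# scenario scales from a condition label
.conditionScales <- function(condition, oeFold = 10) {
  sc <- perturbationScenarios(oeFold)
  if (!condition %in% names(sc))
    stop("unknown condition label: ", condition, call. = FALSE)
  sc[[condition]]
}

# memoised (model, steady state) per construct x condition
.ctxModel <- function(ctx, construct, condition, oeFold) {
  key <- paste(construct, condition, sep = "|")
  if (is.null(ctx$cache[[key]])) {
    sc <- .conditionScales(condition, oeFold)
    pp <- perturbParams(applyMutant(ctx$p, construct), sc[[1L]], sc[[2L]])
    net <- buildNetwork(pp@mutant)
    model <- compileModel(pp, net)
    xss <- unname(solveSteadyState(pp, net, method = "newton"))
    cc <- new.env(parent = emptyenv())
    cc$model <- model
    cc$xss <- xss
    cc$A <- .perMoleculeGenerator(xss, model)
    cc$expmCache <- new.env(parent = emptyenv())
    ctx$cache[[key]] <- cc
  }
  ctx$cache[[key]]
}

# fast simulation of one experiment's signal at the observation times
# (times may be unsorted or duplicated, e.g. concatenated replicates)
.simulateExperimentFast <- function(ctx, experiment, construct, condition,
                                    times, oeFold = 10) {
  ts <- sort(unique(times))
  if (!identical(as.numeric(ts), as.numeric(times))) {
    sim <- .simulateExperimentFast(ctx, experiment, construct, condition,
                                   ts, oeFold)
    return(sim[match(times, ts)])
  }
  cc <- .ctxModel(ctx, construct, condition, oeFold)
  switch(experiment,
    S35_20min = .fast35S(cc$model, cc$xss, 1 / 3, times, cc),
    S35_2hr = .fast35S(cc$model, cc$xss, 2, times, cc),
    H3_chase = .fastH3Chase(cc$model, cc$xss, 2, times),
    H3_incorporation = {
      hs <- .hotCountSystem(cc$model, cc$xss)
      y <- .linPropagate(hs$B, numeric(length(hs$b)), times, b = hs$b)
      sig <- rowSums(y)
      ref <- sig[length(sig)]
      if (ref > 0) 100 * sig / ref else sig
    },
    H3_inc_panel = {
      inc <- function(mt) {
        c2 <- .ctxModel(ctx, mt, condition, oeFold)
        hs <- .hotCountSystem(c2$model, c2$xss)
        if (!length(hs$b)) return(0)
        sum(.linPropagate(hs$B, numeric(length(hs$b)), 2, b = hs$b)[1L, ])
      }
      rep(100 * inc(construct) / inc("WT"), length(times))
    },
    stop("no simulator for experiment kind: ", experiment, call. = FALSE))
}

#' Build per-experiment objective functions from a dataset
#'
#' One objective per experiment (unique combination of experiment kind,
#' construct and condition) in the calibration partition:
#' \code{objective(p) = mean((sim - obs)^2)} over the experiment's
#' observation rows, on the normalized percent scale, with the pulse time
#' included in the simulation.
#'
#' @param data TimeCourse data.frame (see \code{\link{readTimeCourseCsv}});
#'   if it has a logical \code{calibration} column only those rows are
#'   used, otherwise all rows.
#' @param oeFold ZDHHC16 overexpression fold assumed for perturbed
#'   conditions.
#' @return an object of class \code{"palmObjectives"}: a list of objective
#'   functions (each taking a \linkS4class{PalmParams}), with an
#'   \code{evalParams(p)} member evaluating all of them with shared
#'   steady-state solves.
#' @export
makeObjectives <- function(data, oeFold = 10) {
  if ("calibration" %in% names(data)) data <- data[data$calibration, ]
  if (!nrow(data)) stop("empty calibration dataset", call. = FALSE)
  groups <- split(data, interaction(data$experiment, data$construct,
                                    data$condition, drop = TRUE, sep = ":"))
  evalParams <- function(p) {
    ctx <- new.env(parent = emptyenv())
    ctx$p <- p
    ctx$cache <- list()
    vapply(groups, function(g) {
      sim <- .simulateExperimentFast(ctx, g$experiment[1L], g$construct[1L],
                                     g$condition[1L], g$time_hr, oeFold)
      mean((sim - g$signal_pct)^2)
    }, numeric(1))
  }
  fns <- lapply(names(groups), function(nm) {
    function(p) unname(evalParams(p)[nm])
  })
  names(fns) <- names(groups)
  structure(list(objectives = fns, groups = groups,
                 evalParams = evalParams, oeFold = oeFold),
            class = "palmObjectives")
}

#' Genetic-algorithm configuration
#'
#' @param popSize population size (>= 4, even).
#' @param generations number of generations.
#' @param lower,upper search-space bounds (log10 scale for the palm
#'   parameter space); default \code{\link{palmParamSpace}()} bounds.
#' @param space parameter space (with \code{decode}); default
#'   \code{\link{palmParamSpace}()}.  Set to \code{NULL} to optimize raw
#'   vectors (objectives then receive the vector itself).
#' @param pc,etaC crossover probability and SBX distribution index.
#' @param pm,etaM per-gene mutation probability (default 1/dimension) and
#'   polynomial-mutation index.
#' @param selection secondary selection criterion within a Pareto rank:
#'   \code{"aggregate"} (min-max-normalized objective sum; strong
#'   convergence pressure, suited to calibration where all objectives share
#'   an optimum) or \code{"crowding"} (classic crowding distance,
#'   preserving front spread).
#' @param seed RNG seed (the run is bit-reproducible given the seed).
#' @return list of class \code{"gaConfig"}.
#' @export
gaConfig <- function(popSize = 200, generations = 100,
                     space = palmParamSpace(),
                     lower = NULL, upper = NULL,
                     pc = 0.9, etaC = 15, pm = NULL, etaM = 20,
                     selection = c("aggregate", "crowding"), seed = 1) {
  selection <- match.arg(selection)
  if (is.null(lower)) lower <- if (is.null(space)) stop("need bounds")
                               else unname(space$lower)
  if (is.null(upper)) upper <- if (is.null(space)) stop("need bounds")
                               else unname(space$upper)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper))
    stop("infeasible bounds", call. = FALSE)
  if (popSize < 4) stop("population size must be >= 4", call. = FALSE)
  structure(list(popSize = popSize, generations = generations,
                 space = space, lower = lower, upper = upper, pc = pc,
                 etaC = etaC, pm = pm, etaM = etaM,
                 selection = selection, seed = seed),
            class = "gaConfig")
}

#' Run the multi-objective genetic algorithm
#'
#' Elitist nondominated-sorting GA (NSGA-II style) over the configured
#' parameter space, minimising every objective simultaneously; returns the
#' nondominated front of the final population.  Reproducible given the
#' seed; parameters are searched (crossed over, mutated) in log space
#' within the bounds.
#'
#' @param objectives a \code{"palmObjectives"} object from
#'   \code{\link{makeObjectives}}, or a plain list of functions
#'   \code{f(x) -> numeric(1)} evaluated on the raw search vector.
#' @param cfg a \code{\link{gaConfig}}.
#' @return a \linkS4class{ParetoEnsemble} (members are
#'   \linkS4class{PalmParams} when the config has a parameter space,
#'   otherwise raw vectors).  The provenance records seed, configuration
#'   and the initial-population median aggregate score.
#' @export
runGA <- function(objectives, cfg = gaConfig()) {
  set.seed(cfg$seed)
  isPalm <- inherits(objectives, "palmObjectives")
  if (!isPalm && !length(objectives)) stop("need at least one objective")
  decode <- if (!is.null(cfg$space)) cfg$space$decode else identity
  evalOne <- function(z) {
    res <- tryCatch({
      obj <- decode(z)
      if (isPalm) objectives$evalParams(obj)
      else vapply(objectives, function(f) f(obj), numeric(1))
    }, error = function(e) NULL)
    nObj <- if (isPalm) length(objectives$objectives)
            else length(objectives)
    if (is.null(res) || anyNA(res) || any(!is.finite(res)))
      rep(1e8, nObj) else res
  }
  evalFn <- function(X) {
    res <- apply(X, 1L, evalOne)
    if (is.null(dim(res))) matrix(res, ncol = 1L) else t(res)
  }
  res <- .nsga2(evalFn, cfg$lower, cfg$upper, cfg$popSize,
                cfg$generations, pc = cfg$pc, pm = cfg$pm,
                etaC = cfg$etaC, etaM = cfg$etaM,
                selection = cfg$selection)
  mem <- lapply(seq_len(nrow(res$par)), function(i) decode(res$par[i, ]))
  sc <- res$scores
  if (isPalm) colnames(sc) <- names(objectives$objectives)
  new("ParetoEnsemble", members = mem, scores = sc,
      provenance = list(seed = cfg$seed,
                        popSize = cfg$popSize,
                        generations = cfg$generations,
                        initMedianAggregate = res$initMedian,
                        par = res$par))
}

#' Select the best members of a Pareto front
#'
#' Ranks members by the sum of min-max-normalized objective scores and
#' returns the best k (all members if k >= size).  Ties are broken by
#' member index, so the selection is deterministic.
#'
#' @param front a \linkS4class{ParetoEnsemble}.
#' @param k number of members to keep (152 reproduces the published
#'   ensemble size from a 10,000-model population).
#' @return the selected \linkS4class{ParetoEnsemble}.
#' @export
selectEnsemble <- function(front, k) {
  stopifnot(k >= 1)
  if (!length(front@members)) stop("empty front", call. = FALSE)
  F <- front@scores
  norm <- apply(F, 2L, function(col) {
    r <- range(col)
    if (diff(r) == 0) rep(0, length(col)) else (col - r[1L]) / diff(r)
  })
  if (is.null(dim(norm))) norm <- matrix(norm, nrow = nrow(F))
  agg <- rowSums(norm)
  keep <- order(agg, seq_along(agg))[seq_len(min(k, length(agg)))]
  new("ParetoEnsemble", members = front@members[keep],
      scores = F[keep, , drop = FALSE],
      provenance = c(front@provenance,
                     list(selectedK = min(k, length(agg)),
                          aggregate = agg[keep])))
}

#' Ensemble-wise prediction with uncertainty bands
#'
#' Runs a simulation for every ensemble member independently and returns
#' pointwise mean, standard deviation (population convention, divisor n)
#' and first/third quartiles.  Members whose simulation fails are excluded
#' with a warning, never silently.
#'
#' @param ens a \linkS4class{ParetoEnsemble}.
#' @param simulate function taking a member's \linkS4class{PalmParams} and
#'   returning a numeric vector of outputs.
#' @return data.frame with columns mean, sd, q1, q3 (one row per output
#'   point).
#' @export
ensemblePredict <- function(ens, simulate) {
  stopifnot(length(ens@members) >= 1)
  outs <- lapply(seq_along(ens@members), function(i) {
    tryCatch(simulate(ens@members[[i]]), error = function(e) {
      warning("ensemble member ", i, " failed and was excluded: ",
              conditionMessage(e))
      NULL
    })
  })
  ok <- !vapply(outs, is.null, TRUE)
  if (!any(ok)) stop("all ensemble members failed", call. = FALSE)
  M <- do.call(rbind, outs[ok])
  popSd <- function(x) sqrt(mean((x - mean(x))^2))
  data.frame(mean = colMeans(M),
             sd = apply(M, 2L, popSd),
             q1 = apply(M, 2L, stats::quantile, 0.25),
             q3 = apply(M, 2L, stats::quantile, 0.75))
}
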