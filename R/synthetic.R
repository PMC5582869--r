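#' Reference (synthetic ground-truth) parameter set
#'
#' A hand-curated WT parameter set used as the package's default ground
#' truth for synthetic data generation and for worked examples.  It is a
#' synthetic construction, not a fitted result: the state degradation
#' constants reproduce the reported intrinsic half-lives (about 40 h for
#' C000, 5 h for C100, 0.3 h for C111, >100 h for C010, 18 h for C001),
#' and the enzymatic constants are chosen so that the system sits in the
#' reported qualitative regime -- most mature protein non-palmitoylated,
#' the dominant flux cycling Cys-328 (C000 <-> C100) with rapid Cys-328
#' depalmitoylation, palmitate loss on the hour scale, and writer/eraser
#' concentrations comparable to the substrate with APT2 more abundant
#' than ZDHHC16.
#'
#' With these defaults the WT system shows a 35S apparent half-life of
#' about 16 h (vs about 40 h for the siteless AAA mutant), loses half of
#' its pulse-incorporated 3H-palmitate in about 1.1 h, keeps about two
#' thirds of the mature protein non-palmitoylated, and is markedly more
#' robust than the single-site CAA mutant to ZDHHC16 overexpression --
#' the qualitative signature of the multi-site system.
#'
#' @return a \linkS4class{PalmParams} for WT.
#' @examples
#' p <- referencePalmParams()
#' halfLife(p, "C000")
#' @export
referencePalmParams <- function() {
  states <- enumerateStates("WT")
  hl <- c(C000 = 40, C001 = 18, C010 = 120, C011 = 60,
          C100 = 5, C101 = 1.6, C110 = 38, C111 = 0.3)
  palmParams(
    kSyn = 1, kFold = 3, kdU = 0,
    kd = log(2) / hl[states],
    kcatPal = c(Cys328 = 7.6, Cys329 = 0.31, Cys343 = 0.006),
    KmPal = c(Cys328 = 80, Cys329 = 80, Cys343 = 80),
    kcatDepal = c(Cys328 = 1.1, Cys329 = 0.12, Cys343 = 0.9),
    KmDepal = c(Cys328 = 17, Cys329 = 17, Cys343 = 17),
    e16Total = 4.3, apt2Total = 27,
    mutant = "WT")
}

#' Ground-truth specification for synthetic parameter draws
#'
#' @param seed RNG seed.
#' @param constraints enforce the qualitative orderings of the fitted
#'   regime: degradation fastest for every Cys-328-palmitoylated state,
#'   slowest for C010/C011 (slower than C000), and Cys-328
#'   depalmitoylation faster than that of the other two sites.
#' @param rateRange,kdRange,KmRange,enzymeRange sampling bounds
#'   (natural units) for catalytic/folding rates, degradation rates,
#'   Michaelis constants, and enzyme totals.
#' @param maxTries rejection-sampling attempt budget.
#' @return list of class \code{"groundTruthSpec"}.
#' @export
groundTruthSpec <- function(seed = 1, constraints = TRUE,
                            rateRange = c(1e-2, 10),
                            kdRange = c(1e-3, 1),
                            KmRange = c(1, 100),
                            enzymeRange = c(5, 100),
                            maxTries = 10000) {
  stopifnot(all(rateRange > 0), all(kdRange > 0), all(KmRange > 0),
            all(enzymeRange > 0))
  structure(list(seed = seed, constraints = constraints,
                 rateRange = rateRange, kdRange = kdRange,
                 KmRange = KmRange, enzymeRange = enzymeRange,
                 maxTries = maxTries),
            class = "groundTruthSpec")
}

#' Draw a ground-truth parameter set
#'
#' Log-uniform draw within the specification's bounds, rejection-sampled
#' until the qualitative constraints hold (if enabled).  Deterministic
#' given the seed.
#'
#' @param spec a \code{\link{groundTruthSpec}}.
#' @return a WT \linkS4class{PalmParams}.
#' @export
generateGroundTruth <- function(spec = groundTruthSpec()) {
  set.seed(spec$seed)
  states <- enumerateStates("WT")
  logU <- function(n, r) 10^stats::runif(n, log10(r[1]), log10(r[2]))
  for (i in seq_len(spec$maxTries)) {
    kd <- stats::setNames(logU(8, spec$kdRange), states)
    kcatDepal <- logU(3, spec$rateRange)
    if (spec$constraints) {
      c328on <- states[substr(states, 2, 2) == "1"]
      ok <- min(kd[c328on]) > kd["C000"] &&
        kd["C000"] > max(kd[c("C010", "C011")]) &&
        kcatDepal[1] > max(kcatDepal[2:3])
      if (!ok) next
    }
    p <- palmParams(
      kSyn = 1, kFold = logU(1, spec$rateRange), kdU = 0, kd = kd,
      kcatPal = logU(3, spec$rateRange),
      KmPal = logU(3, spec$KmRange),
      kcatDepal = kcatDepal,
      KmDepal = logU(3, spec$KmRange),
      e16Total = logU(1, spec$enzymeRange),
      apt2Total = logU(1, spec$enzymeRange),
      mutant = "WT")
    return(p)
  }
  stop("constraint set not satisfied within attempt budget", call. = FALSE)
}

#' Noise model for synthetic measurements
#'
#' @param kind multiplicative or additive Gaussian noise.
#' @param sigma noise magnitude: relative (fraction of signal) for
#'   multiplicative, in percent-signal units for additive.  Default 0.10.
#' @param replicates replicates per experiment (default 3).
#' @param seed RNG seed.
#' @return list of class \code{"noiseModel"}.
#' @export
noiseModel <- function(kind = c("multiplicative-gaussian",
                                "additive-gaussian"),
                       sigma = 0.10, replicates = 3, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(sigma >= 0, replicates >= 1)
  structure(list(kind = kind, sigma = sigma, replicates = replicates,
                 seed = seed),
            class = "noiseModel")
}

#' Default experiment roster
#'
#' The structure of the study's labelling campaign: the calibration
#' partition (35S decay for WT, ACC, CAA and AAA with both the 20-min and
#' the 2-h pulse -- the long-pulse decay experiments were pivotal for
#' parameter estimation because they separate folding from degradation
#' kinetics; the WT 3H-palmitate incorporation course over the 2 h pulse;
#' 3H-palmitate release for WT, ACC and CAA) plus validation experiments
#' (the cross-construct incorporation panel over all eight constructs;
#' ZDHHC16-overexpression and APT2-silencing variants of the WT/ACC/CAA
#' decay).
#'
#' @param s35Times,h3Times,incTimes observation grids (h).
#' @return data.frame with experiment, construct, condition, calibration
#'   flag and a list-column of times.
#' @export
defaultProtocolRoster <- function(s35Times = c(0, 1, 2, 4, 6, 8, 12, 16,
                                               24, 30),
                                  h3Times = 0:8,
                                  incTimes = c(0.25, 0.5, 1, 1.5, 2)) {
  row <- function(exp, mt, cond, cal, times)
    data.frame(experiment = exp, construct = mt, condition = cond,
               calibration = cal, times = I(list(times)))
  rows <- list()
  for (mt in c("WT", "ACC", "CAA", "AAA"))
    rows <- c(rows, list(row("S35_20min", mt, "control", TRUE, s35Times)))
  for (mt in c("WT", "ACC", "CAA", "AAA"))
    rows <- c(rows, list(row("S35_2hr", mt, "control", TRUE, s35Times)))
  rows <- c(rows, list(row("H3_incorporation", "WT", "control", TRUE,
                           incTimes)))
  for (mt in c("WT", "ACC", "CAA"))
    rows <- c(rows, list(row("H3_chase", mt, "control", TRUE, h3Times)))
  for (mt in .MUTANTS)
    rows <- c(rows, list(row("H3_inc_panel", mt, "control", FALSE, 2)))
  for (cond in c("ZDHHC16_OE", "APT2_KD"))
    for (mt in c("WT", "ACC", "CAA"))
      rows <- c(rows, list(row("S35_20min", mt, cond, FALSE, s35Times)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic labelling dataset
#'
#' Simulates every experiment of the roster from the ground-truth
#' parameter set, applies measurement noise per replicate, and (optionally)
#' writes the TimeCourse CSV files plus a JSON manifest recording the
#' parameters, seeds and noise settings.
#'
#' @param p ground-truth WT \linkS4class{PalmParams}.
#' @param roster experiment roster; default
#'   \code{\link{defaultProtocolRoster}()}.
#' @param noise a \code{\link{noiseModel}}; use \code{sigma = 0} for
#'   noise-free data.
#' @param oeFold ZDHHC16 overexpression fold used for perturbed
#'   conditions.
#' @param out optional output directory for CSV + manifest.
#' @return TimeCourse data.frame with a logical \code{calibration} column.
#' @export
generateDataset <- function(p = referencePalmParams(),
                            roster = defaultProtocolRoster(),
                            noise = noiseModel(), oeFold = 10,
                            out = NULL) {
  set.seed(noise$seed)
  ctx <- new.env(parent = emptyenv())
  ctx$p <- p
  ctx$cache <- list()
  rows <- list()
  for (i in seq_len(nrow(roster))) {
    times <- roster$times[[i]]
    sig <- .simulateExperimentFast(ctx, roster$experiment[i],
                                   roster$construct[i],
                                   roster$condition[i], times, oeFold)
    for (rep in seq_len(noise$replicates)) {
      s <- sig
      if (noise$sigma > 0) {
        eps <- stats::rnorm(length(s))
        s <- if (noise$kind == "multiplicative-gaussian")
          s * (1 + noise$sigma * eps) else s + noise$sigma * eps
        s <- pmax(s, 0)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        time_hr = times, signal_pct = s,
        sd_pct = noise$sigma * sig,
        experiment = roster$experiment[i],
        construct = roster$construct[i],
        condition = roster$condition[i],
        replicate = rep, calibration = roster$calibration[i])
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    writeTimeCourseCsv(df[df$calibration, ],
                       file.path(out, "calibration.csv"))
    writeTimeCourseCsv(df[!df$calibration, ],
                       file.path(out, "validation.csv"))
    manifest <- list(params = paramsToList(p),
                     noise = unclass(noise), oeFold = oeFold,
                     package = as.character(utils::packageVersion("palmcycle")))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  df
}
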