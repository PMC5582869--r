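.TC_EXPERIMENTS <- c("S35_20min", "S35_2hr", "S35_pulse_chase",
                     "H3_incorporation", "H3_chase", "H3_inc_panel")

#' Read a TimeCourse CSV file
#'
#' Validates the TimeCourse schema (columns \code{time_hr},
#' \code{signal_pct}, optional \code{sd_pct}, \code{experiment},
#' \code{construct}, \code{condition}, \code{replicate}, optional logical
#' \code{calibration}), rejecting unknown construct or experiment labels
#' with the offending row cited, and requiring monotone times within each
#' series.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
readTimeCourseCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_hr", "signal_pct", "experiment", "construct",
            "condition", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("TimeCourse schema violation: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  badc <- which(!df$construct %in% .MUTANTS)
  if (length(badc))
    stop("unknown construct '", df$construct[badc[1L]], "' at row ",
         badc[1L], call. = FALSE)
  bade <- which(!df$experiment %in% .TC_EXPERIMENTS)
  if (length(bade))
    stop("unknown experiment '", df$experiment[bade[1L]], "' at row ",
         bade[1L], call. = FALSE)
  if (any(df$signal_pct < 0))
    stop("negative signal_pct in ", path, call. = FALSE)
  series <- split(seq_len(nrow(df)),
                  interaction(df$experiment, df$construct, df$condition,
                              df$replicate, drop = TRUE))
  for (idx in series) {
    if (is.unsorted(df$time_hr[idx]))
      stop("non-monotone times within series starting at row ", idx[1L],
           call. = FALSE)
  }
  df
}

#' Write a TimeCourse CSV file
#'
#' @param df TimeCourse data.frame.
#' @param path output path.
#' @export
writeTimeCourseCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize parameters to a plain list
#'
#' @param p a \linkS4class{PalmParams}.
#' @return nested list suitable for YAML/JSON.
#' @export
paramsToList <- function(p) {
  list(mutant = p@mutant,
       parameters = list(
         kSyn = p@kSyn, kFold = p@kFold, kdU = p@kdU,
         kd = as.list(p@kd),
         kcatPal = as.list(p@kcatPal), KmPal = as.list(p@KmPal),
         kcatDepal = as.list(p@kcatDepal), KmDepal = as.list(p@KmDepal),
         e16Total = p@e16Total, apt2Total = p@apt2Total))
}

#' Rebuild parameters from a plain list
#'
#' @param x list as produced by \code{\link{paramsToList}} (or parsed from
#'   a YAML/JSON model configuration).
#' @return a \linkS4class{PalmParams}.
#' @export
paramsFromList <- function(x) {
  pr <- x$parameters
  palmParams(kSyn = pr$kSyn, kFold = pr$kFold,
             kdU = if (is.null(pr$kdU)) 0 else pr$kdU,
             kd = unlist(pr$kd),
             kcatPal = unlist(pr$kcatPal), KmPal = unlist(pr$KmPal),
             kcatDepal = unlist(pr$kcatDepal),
             KmDepal = unlist(pr$KmDepal),
             e16Total = pr$e16Total, apt2Total = pr$apt2Total,
             mutant = if (is.null(x$mutant)) "WT" else x$mutant)
}

#' Read a model configuration file
#'
#' YAML or JSON with schema \code{\{mutant, parameters\{...\},
#' perturbations\{e16_scale, apt2_scale\}\}}.
#'
#' @param path configuration file.
#' @return list with \code{params} (\linkS4class{PalmParams}, perturbation
#'   already applied), \code{e16Scale}, \code{apt2Scale}.
#' @export
readPalmConfig <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  p <- paramsFromList(x)
  e16 <- 1; apt2 <- 1
  if (!is.null(x$perturbations)) {
    if (!is.null(x$perturbations$e16_scale)) e16 <- x$perturbations$e16_scale
    if (!is.null(x$perturbations$apt2_scale))
      apt2 <- x$perturbations$apt2_scale
  }
  list(params = perturbParams(p, e16, apt2), e16Scale = e16,
       apt2Scale = apt2)
}

#' Write a Pareto ensemble to JSON
#'
#' Full parameter sets, per-objective scores and provenance.
#'
#' @param ens a \linkS4class{ParetoEnsemble}.
#' @param path output JSON path.
#' @export
writeEnsembleJson <- function(ens, path) {
  x <- list(
    members = lapply(ens@members, function(m)
      if (is(m, "PalmParams")) paramsToList(m) else as.list(m)),
    scores = ens@scores,
    objectives = colnames(ens@scores),
    provenance = ens@provenance[setdiff(names(ens@provenance), "par")])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a Pareto ensemble from JSON
#'
#' @param path JSON written by \code{\link{writeEnsembleJson}}.
#' @return a \linkS4class{ParetoEnsemble}.
#' @export
readEnsembleJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  mem <- lapply(x$members, function(m)
    if (!is.null(m$parameters)) paramsFromList(m) else unlist(m))
  sc <- do.call(rbind, lapply(x$scores, unlist))
  if (!is.null(x$objectives)) colnames(sc) <- unlist(x$objectives)
  new("ParetoEnsemble", members = mem, scores = sc,
      provenance = if (is.null(x$provenance)) list() else x$provenance)
}
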