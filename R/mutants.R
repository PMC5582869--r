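#' Cysteine mutants of the three-site palmitoylation network
#'
#' ZDHHC6 carries three palmitoylatable cysteines (Cys-328, Cys-329,
#' Cys-343), written in that order in all state labels.  A mutant name is a
#' three-letter code over \{C, A\}: position k is \code{"C"} if cysteine k is
#' present and \code{"A"} if it has been mutated to alanine.  \code{"WT"} is
#' an alias for \code{"CCC"}.
#'
#' @name mutants
NULL

.SITE_NAMES <- c("Cys328", "Cys329", "Cys343")

.MUTANTS <- c("WT", "ACC", "CAC", "CCA", "AAC", "ACA", "CAA", "AAA")

#' Active palmitoylation sites of a mutant
#'
#' @param mutant mutant code: one of \code{"WT"}, \code{"ACC"}, \code{"CAC"},
#'   \code{"CCA"}, \code{"AAC"}, \code{"ACA"}, \code{"CAA"}, \code{"AAA"}
#'   (or the explicit \code{"CCC"} for wild type).
#' @return integer vector of active site indices (subset of 1:3, where
#'   1 = Cys-328, 2 = Cys-329, 3 = Cys-343).
#' @examples
#' activeSites("WT")   # 1 2 3
#' activeSites("CAA")  # 1
#' @export
activeSites <- function(mutant) {
  mutant <- toupper(as.character(mutant))
  if (identical(mutant, "WT")) mutant <- "CCC"
  if (!grepl("^[CA]{3}$", mutant))
    stop("unknown mutant code: ", mutant, call. = FALSE)
  which(strsplit(mutant, "")[[1]] == "C")
}

.normMutant <- function(mutant) {
  mutant <- toupper(as.character(mutant))
  if (identical(mutant, "CCC")) mutant <- "WT"
  if (!mutant %in% .MUTANTS)
    stop("unknown mutant code: ", mutant, call. = FALSE)
  mutant
}

#' Enumerate palmitoylation occupancy states
#'
#' Returns the \code{2^m} occupancy states of a construct with m active
#' cysteines, in canonical (lexicographic) order with the fully
#' unmodified state first.  State labels are \code{"C"} followed by one
#' binary digit per \emph{active} site (so WT states run \code{"C000"}
#' ... \code{"C111"}; the single-site CAA mutant has \code{"C0"},
#' \code{"C1"}; the siteless AAA mutant has the single bare label
#' \code{"C"}).
#'
#' @inheritParams activeSites
#' @return character vector of state labels.
#' @examples
#' enumerateStates("WT")
#' enumerateStates("CAA")
#' @export
enumerateStates <- function(mutant) {
  m <- length(activeSites(mutant))
  stateLabels(stateBits(m))
}

# all 2^m occupancy bit-vectors, lexicographic, as a (2^m x m) 0/1 matrix
stateBits <- function(m) {
  if (m == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  g <- as.matrix(expand.grid(rep(list(0:1), m))[, m:1, drop = FALSE])
  g <- g[order(apply(g, 1L, paste, collapse = "")), , drop = FALSE]
  dimnames(g) <- NULL
  g
}

stateLabels <- function(bits) {
  paste0("C", apply(bits, 1L, paste, collapse = ""))
}

# full three-site label ("C000".."C111") for a reduced-network state:
# bits of the active sites are placed at their positions, removed sites read 0
fullLabels <- function(bits, sites) {
  full <- matrix(0L, nrow = nrow(bits), ncol = 3L)
  if (length(sites)) full[, sites] <- bits
  stateLabels(full)
}
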