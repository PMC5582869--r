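#' Total quasi-steady-state (tQSSA) reaction flux
#'
#' Evaluates the flux of a single reaction at a given system state.  For an
#' enzymatic step converting substrate species S via an enzyme of total
#' concentration E_T with per-site constants (kcat, Km), the competitive
#' tQSSA form is used:
#' \deqn{v = \frac{k_{cat} E_T S}{K_m (1 + \sum_{r' \ne r} S_{r'}/K_{m,r'})
#'            + E_T + S}}
#' where the competition sum runs over all other substrate/site pairings
#' served by the same enzyme in the current network.  The form reduces to
#' Michaelis-Menten kinetics when the enzyme is scarce and no competitors
#' are present, and is always bounded by \code{kcat * E_T}.  Synthesis,
#' folding and degradation reactions follow zero- or first-order mass
#' action.
#'
#' @param reaction one row of \code{net@reactions} (data.frame) or its row
#'   index.
#' @param x named (or canonically ordered) non-negative concentration
#'   vector over \code{net@species} (a.u.).
#' @param p a \linkS4class{PalmParams}.
#' @param net the \linkS4class{ReactionNetwork}; defaults to the network of
#'   \code{p}'s mutant.
#' @return flux in a.u. per hour.
#' @export
tqssaRate <- function(reaction, x, p, net = buildNetwork(p@mutant)) {
  if (any(x < 0)) stop("negative concentration supplied", call. = FALSE)
  if (is.numeric(reaction)) reaction <- net@reactions[reaction, , drop = FALSE]
  x <- .asStateVector(x, net)
  model <- compileModel(p, net)
  v <- .reactionFluxVector(x, model)
  kind <- reaction$kind
  rx <- net@reactions
  i <- which(rx$kind == kind &
             (is.na(reaction$from) | rx$from %in% reaction$from) &
             (is.na(reaction$site) | rx$site %in% reaction$site))
  if (length(i) != 1L) stop("reaction not uniquely identified", call. = FALSE)
  unname(v[i])
}

.asStateVector <- function(x, net) {
  if (!is.null(names(x))) {
    miss <- setdiff(net@species, names(x))
    if (length(miss)) stop("state vector lacks species: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    x <- x[net@species]
  }
  if (length(x) != length(net@species))
    stop("state vector length does not match network", call. = FALSE)
  unname(x)
}

# fluxes for every reaction, aligned with net@reactions rows
.reactionFluxVector <- function(x, model) {
  rx <- model$net@reactions
  v <- numeric(nrow(rx))
  v[rx$kind == "synthesis"] <- model$kSyn
  v[rx$kind == "folding"] <- model$kFold * x[1L]
  deg <- which(rx$kind == "degradation")
  kdAll <- c(model$kdU, model$kd)
  v[deg] <- kdAll[match(rx$from[deg], model$net@species)] *
    x[match(rx$from[deg], model$net@species)]
  v[rx$kind == "palmitoylation"] <-
    .tqssaFamily(x[model$pal$sub], model$pal$kcat, model$pal$Km, model$E16)
  v[rx$kind == "depalmitoylation"] <-
    .tqssaFamily(x[model$depal$sub], model$depal$kcat, model$depal$Km,
                 model$APT2)
  v
}

# fast right-hand side on a compiled model (unnamed numeric x)
.rhs <- function(x, model) {
  dx <- numeric(model$n)
  U <- x[1L]
  dx[1L] <- model$kSyn - model$kFold * U - model$kdU * U
  dx[2L] <- dx[2L] + model$kFold * U
  xf <- x[-1L]
  dx[-1L] <- dx[-1L] - model$kd * xf
  vPal <- .tqssaFamily(x[model$pal$sub], model$pal$kcat, model$pal$Km,
                       model$E16)
  vDep <- .tqssaFamily(x[model$depal$sub], model$depal$kcat,
                       model$depal$Km, model$APT2)
  if (length(vPal)) dx <- dx + as.vector(model$Spal %*% vPal)
  if (length(vDep)) dx <- dx + as.vector(model$Sdepal %*% vDep)
  dx
}

#' Deterministic time derivative of the network
#'
#' The unfolded species obeys \code{dU/dt = kSyn - kFold U - kdU U}; every
#' folded state gains the folding inflow (unmodified state only) plus its
#' tQSSA palmitoylation/depalmitoylation in-fluxes, and loses its
#' out-fluxes and first-order degradation.  Summed over species, the
#' derivative equals synthesis minus total degradation flux (mass
#' bookkeeping).
#'
#' @inheritParams tqssaRate
#' @return named derivative vector (a.u. h^-1) over \code{net@species}.
#' @examples
#' p <- referencePalmParams()
#' odeRHS(setNames(rep(0, 9), buildNetwork("WT")@species), p)
#' @export
odeRHS <- function(x, p, net = buildNetwork(p@mutant)) {
  if (any(x < 0)) stop("negative concentration supplied", call. = FALSE)
  x <- .asStateVector(x, net)
  model <- compileModel(p, net)
  stats::setNames(.rhs(x, model), net@species)
}

# Per-molecule generator A of the linear cohort/CTMC dynamics at background
# state x: A[i,j] = rate of a single molecule moving j -> i; diagonal
# includes all exit rates (transitions + degradation).  Synthesis is not in
# A (it is a source term).  colSums(A) = -degradation rates.
.perMoleculeGenerator <- function(x, model) {
  n <- model$n
  A <- matrix(0, n, n)
  A[2L, 1L] <- model$kFold
  kPal <- .tqssaPerMolecule(x[model$pal$sub], model$pal$kcat, model$pal$Km,
                            model$E16)
  kDep <- .tqssaPerMolecule(x[model$depal$sub], model$depal$kcat,
                            model$depal$Km, model$APT2)
  for (j in seq_along(kPal))
    A[model$pal$prod[j], model$pal$sub[j]] <-
      A[model$pal$prod[j], model$pal$sub[j]] + kPal[j]
  for (j in seq_along(kDep))
    A[model$depal$prod[j], model$depal$sub[j]] <-
      A[model$depal$prod[j], model$depal$sub[j]] + kDep[j]
  exit <- colSums(A) + c(model$kdU, model$kd)
  diag(A) <- diag(A) - exit
  A
}
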