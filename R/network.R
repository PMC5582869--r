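#' Build the reaction network of a construct
#'
#' Assembles the full open network: synthesis of U, folding U -> fully
#' unmodified state, one ZDHHC16-catalysed palmitoylation and one
#' APT2-catalysed depalmitoylation per (state, site) pair (the edges of the
#' m-dimensional hypercube over occupancy states), and first-order
#' degradation of every species including U.
#'
#' @inheritParams activeSites
#' @return a \linkS4class{ReactionNetwork}.
#' @examples
#' net <- buildNetwork("WT")   # 35 reactions
#' nrow(net@reactions)
#' @export
buildNetwork <- function(mutant) {
  mutant <- .normMutant(mutant)
  cached <- .palmCache$net[[mutant]]
  if (!is.null(cached)) return(cached)
  net <- .buildNetworkUncached(mutant)
  .palmCache$net[[mutant]] <- net
  net
}

# per-session cache of the (immutable) per-mutant network and compiled
# skeleton; S4/list value semantics keep returned objects safe to modify
.palmCache <- new.env(parent = emptyenv())
.palmCache$net <- list()
.palmCache$skel <- list()

.buildNetworkUncached <- function(mutant) {
  sites <- activeSites(mutant)
  m <- length(sites)
  bits <- stateBits(m)
  labs <- stateLabels(bits)
  species <- c("U", labs)

  rx <- list(
    data.frame(kind = "synthesis", from = NA, to = "U",
               site = NA_integer_, enzyme = NA),
    data.frame(kind = "folding", from = "U", to = labs[1L],
               site = NA_integer_, enzyme = NA),
    data.frame(kind = "degradation", from = species, to = NA,
               site = NA_integer_, enzyme = NA)
  )
  if (m > 0L) {
    for (s in seq_len(nrow(bits))) for (k in seq_len(m)) {
      b <- bits[s, ]
      other <- b; other[k] <- 1L - b[k]
      tgt <- labs[match(paste(other, collapse = ""),
                        apply(bits, 1L, paste, collapse = ""))]
      if (b[k] == 0L) {
        rx[[length(rx) + 1L]] <- data.frame(
          kind = "palmitoylation", from = labs[s], to = tgt,
          site = sites[k], enzyme = "ZDHHC16")
      } else {
        rx[[length(rx) + 1L]] <- data.frame(
          kind = "depalmitoylation", from = labs[s], to = tgt,
          site = sites[k], enzyme = "APT2")
      }
    }
  }
  reactions <- do.call(rbind, rx)
  rownames(reactions) <- NULL
  new("ReactionNetwork", mutant = mutant, sites = as.integer(sites),
      species = species, bits = bits,
      fullLabels = fullLabels(bits, sites), reactions = reactions)
}

#' Restrict a parameter set to a mutant sub-network
#'
#' Removing a site deletes every state in which that site is occupied; the
#' surviving states keep their degradation constants (looked up by full
#' three-site label) and the surviving sites keep their enzymatic
#' constants.  Simulating the reduced network is equivalent to simulating
#' the full network with the removed sites' palmitoylation kcat set to 0.
#'
#' @param p a \linkS4class{PalmParams} for a network containing the target
#'   mutant's sites (typically WT).
#' @param mutant target construct code.
#' @return a \linkS4class{PalmParams} on the reduced network.
#' @export
applyMutant <- function(p, mutant) {
  mutant <- .normMutant(mutant)
  sites <- activeSites(mutant)
  have <- activeSites(p@mutant)
  if (!all(sites %in% have))
    stop("parameter set for ", p@mutant, " lacks sites needed by ", mutant,
         call. = FALSE)
  if (identical(mutant, p@mutant)) return(p)
  keep <- fullLabels(stateBits(length(sites)), sites)
  sn <- .SITE_NAMES[sites]
  # restriction of a valid object stays valid; slots assigned directly
  q <- p
  q@mutant <- mutant
  q@kd <- p@kd[keep]
  q@kcatPal <- p@kcatPal[sn]
  q@KmPal <- p@KmPal[sn]
  q@kcatDepal <- p@kcatDepal[sn]
  q@KmDepal <- p@KmDepal[sn]
  q
}

# Parameter-independent skeleton of a mutant's compiled model: reaction
# index vectors and stoichiometry matrices, cached per mutant.
.modelSkeleton <- function(mutant) {
  cached <- .palmCache$skel[[mutant]]
  if (!is.null(cached)) return(cached)
  net <- buildNetwork(mutant)
  species <- net@species
  n <- length(species)
  rx <- net@reactions
  pick <- function(kind) {
    r <- rx[rx$kind == kind, , drop = FALSE]
    list(sub = match(r$from, species), prod = match(r$to, species),
         site = r$site, siteName = .SITE_NAMES[r$site])
  }
  pal <- pick("palmitoylation")
  depal <- pick("depalmitoylation")
  stoich <- function(r) {
    S <- matrix(0, n, length(r$sub))
    for (j in seq_along(r$sub)) {
      S[r$sub[j], j] <- S[r$sub[j], j] - 1
      S[r$prod[j], j] <- S[r$prod[j], j] + 1
    }
    S
  }
  sk <- list(net = net, n = n, species = species, pal = pal,
             depal = depal, Spal = stoich(pal), Sdepal = stoich(depal))
  .palmCache$skel[[mutant]] <- sk
  sk
}

# Precompile (params, network) into flat index vectors for fast repeated
# evaluation of rates, the ODE right-hand side, and per-molecule generators.
compileModel <- function(p, net = NULL) {
  sk <- .modelSkeleton(.normMutant(p@mutant))
  if (!is.null(net)) stopifnot(identical(sk$net@mutant, net@mutant))
  net <- sk$net
  pal <- sk$pal
  pal$kcat <- unname(p@kcatPal[pal$siteName])
  pal$Km <- unname(p@KmPal[pal$siteName])
  depal <- sk$depal
  depal$kcat <- unname(p@kcatDepal[depal$siteName])
  depal$Km <- unname(p@KmDepal[depal$siteName])
  list(n = sk$n, species = sk$species, kSyn = p@kSyn, kFold = p@kFold,
       kdU = p@kdU, kd = unname(p@kd[net@fullLabels]), E16 = p@e16Total,
       APT2 = p@apt2Total, pal = pal, depal = depal,
       Spal = sk$Spal, Sdepal = sk$Sdepal, net = net, params = p)
}

# competitive tQSSA fluxes for one enzyme's reaction family, vectorised
# over reactions: v_r = kcat_r E_T S_r / (Km_r (1 + sum_{r' != r} S_{r'}/Km_{r'})
#                                         + E_T + S_r).
# Reactions with kcat = 0 are absent (a knocked-out site): they neither
# carry flux nor compete for the enzyme, which makes site knockout exactly
# equivalent to restricting the network.
.tqssaFamily <- function(S, kcat, Km, ET) {
  if (!length(S)) return(numeric(0))
  act <- kcat > 0
  tot <- sum((S / Km)[act])
  den <- Km * (1 + tot - act * S / Km) + ET + S
  kcat * ET * S / den
}

# per-molecule (first-order) rate for each reaction of a family
.tqssaPerMolecule <- function(S, kcat, Km, ET) {
  if (!length(S)) return(numeric(0))
  act <- kcat > 0
  tot <- sum((S / Km)[act])
  den <- Km * (1 + tot - act * S / Km) + ET + S
  kcat * ET / den
}
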