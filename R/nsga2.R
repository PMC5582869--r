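# Elitist nondominated-sorting genetic algorithm (NSGA-II style):
# simulated binary crossover and polynomial mutation on real vectors,
# fast nondominated sorting and crowding-distance selection.

# rank 1 = nondominated; F is (n x k), minimised.  Pairwise dominance is
# computed with vectorised outer comparisons, fronts peeled iteratively.
.paretoRanks <- function(F) {
  n <- nrow(F)
  leq <- matrix(TRUE, n, n)
  lt <- matrix(FALSE, n, n)
  for (j in seq_len(ncol(F))) {
    o <- outer(F[, j], F[, j], "<=")
    leq <- leq & o
    lt <- lt | outer(F[, j], F[, j], "<")
  }
  dom <- leq & lt            # dom[i, j]: i dominates j
  ranks <- integer(n)
  remaining <- rep(TRUE, n)
  r <- 0L
  while (any(remaining)) {
    r <- r + 1L
    nDominators <- colSums(dom[remaining, , drop = FALSE])
    front <- remaining & nDominators == 0L
    ranks[front] <- r
    remaining <- remaining & !front
  }
  ranks
}

.crowding <- function(F) {
  n <- nrow(F)
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (j in seq_len(ncol(F))) {
    o <- order(F[, j])
    rng <- F[o[n], j] - F[o[1L], j]
    d[o[c(1L, n)]] <- Inf
    if (rng > 0)
      d[o[2:(n - 1L)]] <- d[o[2:(n - 1L)]] +
        (F[o[3:n], j] - F[o[1:(n - 2L)], j]) / rng
  }
  d
}

.sbx <- function(p1, p2, lower, upper, eta = 15, pc = 0.9) {
  d <- length(p1)
  c1 <- p1; c2 <- p2
  if (stats::runif(1) < pc) {
    swap <- stats::runif(d) < 0.5
    u <- stats::runif(d)
    beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                   (1 / (2 * (1 - u)))^(1 / (eta + 1)))
    m <- (p1 + p2) / 2; h <- abs(p1 - p2) / 2
    a <- m - beta * h; b <- m + beta * h
    c1 <- ifelse(swap, a, b); c2 <- ifelse(swap, b, a)
  }
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

.polyMutate <- function(x, lower, upper, eta = 20, pm = NULL) {
  d <- length(x)
  if (is.null(pm)) pm <- 1 / d
  hit <- stats::runif(d) < pm
  if (any(hit)) {
    u <- stats::runif(sum(hit))
    delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                    1 - (2 * (1 - u))^(1 / (eta + 1)))
    x[hit] <- x[hit] + delta * (upper[hit] - lower[hit])
  }
  pmin(pmax(x, lower), upper)
}

# binary tournament on (rank, secondary key); the key is "bigger wins"
.tournament <- function(ranks, key) {
  n <- length(ranks)
  a <- sample.int(n, 1L); b <- sample.int(n, 1L)
  if (ranks[a] < ranks[b]) return(a)
  if (ranks[b] < ranks[a]) return(b)
  if (key[a] >= key[b]) a else b
}

# secondary selection key within a rank ("bigger is better"):
# "crowding" preserves front spread (classic NSGA-II); "aggregate" uses the
# negative min-max-normalized objective sum, which keeps convergence
# pressure when many objectives share a common optimum (as in calibration
# to noise-consistent data, where the front collapses towards the origin)
.secondaryKey <- function(F, selection) {
  if (selection == "crowding") return(.crowding(F))
  norm <- apply(F, 2L, function(col) {
    r <- range(col)
    if (diff(r) == 0) rep(0, length(col)) else (col - r[1L]) / diff(r)
  })
  if (is.null(dim(norm))) norm <- matrix(norm, nrow = nrow(F))
  -rowSums(norm)
}

# core loop; evalFn(X) takes a matrix of row-vectors, returns score matrix
.nsga2 <- function(evalFn, lower, upper, popSize, generations,
                   pc = 0.9, pm = NULL, etaC = 15, etaM = 20,
                   selection = "aggregate", immigration = 0,
                   init = NULL) {
  d <- length(lower)
  X <- matrix(stats::runif(popSize * d, rep(lower, each = popSize),
                           rep(upper, each = popSize)), popSize, d)
  if (!is.null(init)) {
    k <- min(nrow(init), popSize)
    X[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
  }
  F <- evalFn(X)
  initMedian <- stats::median(rowSums(F))
  for (gen in seq_len(generations)) {
    ranks <- .paretoRanks(F)
    key <- numeric(popSize)
    for (r in unique(ranks)) {
      i <- ranks == r
      key[i] <- .secondaryKey(F[i, , drop = FALSE], selection)
    }
    # offspring
    Y <- matrix(NA_real_, popSize, d)
    i <- 1L
    while (i <= popSize) {
      pa <- .tournament(ranks, key); pb <- .tournament(ranks, key)
      ch <- .sbx(X[pa, ], X[pb, ], lower, upper, etaC, pc)
      Y[i, ] <- .polyMutate(ch[[1L]], lower, upper, etaM, pm)
      if (i + 1L <= popSize)
        Y[i + 1L, ] <- .polyMutate(ch[[2L]], lower, upper, etaM, pm)
      i <- i + 2L
    }
    # random immigrants keep exploration alive after the population
    # concentrates around a basin
    nImm <- floor(immigration * popSize)
    if (nImm > 0) {
      Y[popSize - seq_len(nImm) + 1L, ] <-
        matrix(stats::runif(nImm * d, rep(lower, each = nImm),
                            rep(upper, each = nImm)), nImm, d)
    }
    G <- evalFn(Y)
    # elitist environmental selection on the merged population
    Xall <- rbind(X, Y); Fall <- rbind(F, G)
    ranksAll <- .paretoRanks(Fall)
    keep <- integer(0)
    for (r in sort(unique(ranksAll))) {
      i <- which(ranksAll == r)
      if (length(keep) + length(i) <= popSize) {
        keep <- c(keep, i)
      } else {
        cd <- .secondaryKey(Fall[i, , drop = FALSE], selection)
        keep <- c(keep, i[order(-cd)][seq_len(popSize - length(keep))])
        break
      }
    }
    X <- Xall[keep, , drop = FALSE]
    F <- Fall[keep, , drop = FALSE]
  }
  front <- .paretoRanks(F) == 1L
  list(par = X[front, , drop = FALSE], scores = F[front, , drop = FALSE],
       pop = X, popScores = F, initMedian = initMedian)
}
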