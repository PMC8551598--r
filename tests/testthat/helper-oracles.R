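# Independent brute-force oracles used to verify the graph machinery.
# Everything here is written from the definitions (explicit loops,
# Floyd-Warshall, exhaustive partition scans) and never calls the package's
# own metric code.

bruteDistances <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[W > 0] <- 1 / W[W > 0]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

bruteBetweenness <- function(W, tol = 1e-9) {
  n <- nrow(W)
  D <- bruteDistances(W)
  L <- matrix(Inf, n, n)
  L[W > 0] <- 1 / W[W > 0]
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (t in order(D[s, ])) {
      if (t == s || !is.finite(D[s, t])) next
      preds <- which(is.finite(L[, t]) & abs(D[s, ] + L[, t] - D[s, t]) < tol)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || v == s || v == t || !is.finite(D[s, t])) next
    if (abs(D[s, v] + D[v, t] - D[s, t]) < tol)
      btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
  }
  btw / 2  # unordered pairs
}

bruteOnnela <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  Wn <- W / mx
  C <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n))
      if (j != i && h != i && j != h)
        s <- s + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
    C[i] <- s / (k * (k - 1))
  }
  C
}

bruteLocalEfficiency <- function(W) {
  n <- nrow(W)
  vapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) return(0)
    d <- bruteDistances(W[nb, nb, drop = FALSE])
    vals <- 1 / d[upper.tri(d)]
    vals[!is.finite(vals)] <- 0
    mean(vals)
  }, numeric(1))
}

bruteStrength <- function(W) rowSums(W)

bruteCharpath <- function(W) {
  d <- bruteDistances(W)
  off <- d[upper.tri(d)]
  mean(off[is.finite(off)])
}

bruteGlobalEfficiency <- function(W) {
  d <- bruteDistances(W)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

bruteParticipation <- function(W, module) {
  n <- nrow(W)
  s <- rowSums(W)
  vapply(seq_len(n), function(i) {
    if (s[i] == 0) return(0)
    tot <- 0
    for (m in unique(module)) {
      kis <- sum(W[i, module == m])
      tot <- tot + (kis / s[i])^2
    }
    1 - tot
  }, numeric(1))
}

bruteWithinModuleZ <- function(W, module) {
  n <- nrow(W)
  within <- vapply(seq_len(n), function(i) sum(W[i, module == module[i]]),
                   numeric(1))
  z <- numeric(n)
  for (m in unique(module)) {
    sel <- module == m
    sdm <- sd(within[sel])
    z[sel] <- if (is.na(sdm) || sdm == 0) 0 else
      (within[sel] - mean(within[sel])) / sdm
  }
  z
}

bruteAssortativity <- function(W) {
  s <- rowSums(W)
  n <- nrow(W)
  x <- c(); y <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) if (W[i, j] > 0) {
    x <- c(x, s[i], s[j]); y <- c(y, s[j], s[i])
  }
  cor(x, y)
}

# Signed modularity by the explicit formula (positive and negative null terms
# weighted by their total weights).
bruteQ <- function(W, ci, gamma = 1) {
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  sp <- sum(Wp); sn <- sum(Wn)
  kp <- rowSums(Wp); kn <- rowSums(Wn)
  same <- outer(ci, ci, "==")
  q <- 0
  if (sp > 0) q <- q + sum((Wp - gamma * outer(kp, kp) / sp)[same])
  if (sn > 0) q <- q - sum((Wn - gamma * outer(kn, kn) / sn)[same])
  q / (sp + sn)
}

# All set partitions of n items as restricted growth strings.
enumPartitions <- function(n) {
  out <- vector("list", 0L)
  rec <- function(prefix, maxLab) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (lab in seq_len(maxLab + 1L)) rec(c(prefix, lab), max(maxLab, lab))
  }
  rec(integer(0), 0L)
  out
}

bruteBestQ <- function(W, gamma = 1) {
  parts <- enumPartitions(nrow(W))
  best <- -Inf
  for (ci in parts) {
    q <- bruteQ(W, ci, gamma)
    if (q > best) best <- q
  }
  best
}

# Random connected-ish positive weighted graph fixture.
randPosGraph <- function(n, density = 0.6) {
  W <- matrix(0, n, n)
  up <- which(upper.tri(W))
  keep <- sample(up, max(2L, round(density * length(up))))
  W[keep] <- runif(length(keep), 0.1, 1)
  W <- W + t(W)
  W
}

# Random signed network fixture (correlation-like).
randSignedNet <- function(n) {
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- runif(n * (n - 1) / 2, -1, 1)
  W <- W + t(W)
  diag(W) <- 0
  W
}

# Planted two-block +1/-1 network.
plantedBlockNet <- function(sizes = c(5, 5)) {
  g <- rep(seq_along(sizes), sizes)
  W <- ifelse(outer(g, g, "=="), 1, -1)
  diag(W) <- 0
  list(W = W, truth = g)
}
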