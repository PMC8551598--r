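## Signed weighted Louvain community detection and consensus clustering.
## Correlation networks carry negative edges, so modularity uses the
## symmetric signed convention: separate positive/negative null terms,
## Q = Q+ * s+/(s+ + s-) - Q- * s-/(s+ + s-).

#' Signed modularity matrix
#'
#' @param W Symmetric weight matrix (may contain negative weights), zero diag.
#' @param gamma Resolution parameter.
#' @return Matrix `B` such that `Q = sum(B[same community])`.
#' @keywords internal
modularityMatrix <- function(W, gamma = 1) {
  Wp <- pmax(W, 0)
  Wn <- pmax(-W, 0)
  sp <- sum(Wp)
  sn <- sum(Wn)
  if (sp + sn == 0) stop("network has no edges (all weights zero)")
  kp <- rowSums(Wp)
  kn <- rowSums(Wn)
  B <- matrix(0, nrow(W), ncol(W))
  if (sp > 0) B <- B + (Wp - gamma * outer(kp, kp) / sp)
  if (sn > 0) B <- B - (Wn - gamma * outer(kn, kn) / sn)
  B / (sp + sn)
}

#' Modularity of an assignment under the signed convention
#'
#' @param W Symmetric weight matrix or [SubjectNetwork-class] /
#'   [Connectome-class].
#' @param assignment Integer community labels (one per node).
#' @param gamma Resolution parameter.
#' @return Modularity Q.
#' @export
computeModularity <- function(W, assignment, gamma = 1) {
  if (methods::is(W, "SubjectNetwork") || methods::is(W, "Connectome"))
    W <- connMatrix(W)
  B <- modularityMatrix(W, gamma)
  sum(B[outer(assignment, assignment, "==")])
}

## Greedy Louvain phase-and-aggregate on a (symmetric) modularity matrix.
## Returns the dense integer assignment for the original nodes. Uses the
## active RNG stream for sweep order.
louvainCore <- function(B, tol = 1e-10) {
  B <- (B + t(B)) / 2
  n <- nrow(B)
  map <- seq_len(n)                    # original node -> current community
  Bcur <- B
  repeat {
    m <- nrow(Bcur)
    comm <- seq_len(m)
    movedAny <- FALSE
    repeat {
      improved <- FALSE
      for (i in sample.int(m)) {
        cur <- comm[i]
        s <- rowsum(Bcur[i, ], comm)
        labs <- as.integer(rownames(s))
        s[labs == cur] <- s[labs == cur] - Bcur[i, i]
        gain <- s - s[labs == cur]
        best <- which.max(gain)
        if (gain[best] > tol && labs[best] != cur) {
          comm[i] <- labs[best]
          improved <- TRUE
          movedAny <- TRUE
        }
      }
      if (!improved) break
    }
    if (!movedAny) break
    comm <- match(comm, unique(comm))
    map <- comm[map]
    Bcur <- rowsum(t(rowsum(Bcur, comm)), comm)
    if (nrow(Bcur) == m) break
  }
  match(map, unique(map))
}

## Kernighan-Lin style fine-tuning of a partition on a modularity matrix:
## each pass moves every node exactly once (the globally best single move,
## even if negative), keeps the best configuration seen, and repeats while
## passes improve Q. Escapes the single-move local optima greedy Louvain can
## get stuck in on small dense graphs.
klRefine <- function(B, ci, maxPass = 100L, tol = 1e-12) {
  B <- (B + t(B)) / 2
  n <- nrow(B)
  ci <- match(ci, unique(ci))
  diagB <- diag(B)
  for (pass in seq_len(maxPass)) {
    cur <- ci
    k <- max(cur)
    S <- rowsum(B, cur)                       # community x node sums
    qCur <- sum(S[cbind(cur, seq_len(n))])
    qStart <- qCur
    bestQ <- qCur
    bestCi <- cur
    locked <- rep(FALSE, n)
    for (step in seq_len(n)) {
      free <- which(!locked)
      base <- S[cbind(cur[free], free)] - diagB[free]
      ## gain of moving node i to community b (2x because B is symmetric);
      ## an extra empty community is always available as a target
      G <- 2 * (rbind(S[, free, drop = FALSE], 0) -
                  matrix(base, k + 1L, length(free), byrow = TRUE))
      G[cbind(cur[free], seq_along(free))] <- -Inf
      w <- arrayInd(which.max(G), dim(G))
      i <- free[w[2]]
      target <- w[1]
      gain <- G[w]
      a <- cur[i]
      if (target > k) {                        # open a new community
        S <- rbind(S, 0)
        k <- k + 1L
      }
      S[a, ] <- S[a, ] - B[i, ]
      S[target, ] <- S[target, ] + B[i, ]
      cur[i] <- target
      qCur <- qCur + gain
      locked[i] <- TRUE
      if (qCur > bestQ + tol) {
        bestQ <- qCur
        bestCi <- cur
      }
    }
    if (bestQ > qStart + tol) ci <- match(bestCi, unique(bestCi)) else break
  }
  ci
}

#' Louvain partition of a signed weighted network
#'
#' Singleton initialisation, greedy node moves and aggregation until no
#' modularity gain, under the symmetric signed modularity convention,
#' followed by Kernighan-Lin fine-tuning of the converged partition.
#'
#' @param net A [SubjectNetwork-class], [Connectome-class], or symmetric
#'   weight matrix.
#' @param gamma Resolution parameter (default 1).
#' @param seed Integer seed controlling the node sweep order.
#' @return A [Partition-class] with the assignment and its modularity Q.
#' @export
louvainPartition <- function(net, gamma = 1, seed = NULL) {
  W <- if (methods::is(net, "SubjectNetwork") || methods::is(net, "Connectome"))
    connMatrix(net) else net
  if (!isSymmetricMat(W)) stop("network matrix must be symmetric")
  if (all(W == 0)) stop("network has no edges (all weights zero)")
  B <- modularityMatrix(W, gamma)
  ci <- withSeed(seed, louvainCore(B))
  ci <- klRefine(B, ci)
  ids <- rownames(W) %||% as.character(seq_len(nrow(W)))
  methods::new("Partition", assignment = stats::setNames(as.integer(ci), ids),
               Q = sum(B[outer(ci, ci, "==")]), gamma = gamma)
}

## Optimal matched-label agreement between two dense integer labelings.
## Exhaustive assignment for <= 8 labels, greedy otherwise.
bestLabelMatchCount <- function(a, b) {
  tab <- table(a, b)
  k <- max(dim(tab))
  padded <- matrix(0, k, k)
  padded[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  if (k <= 8L) {
    perms <- permuteAll(k)
    best <- 0
    idx <- seq_len(k)
    for (p in perms) {
      s <- sum(padded[cbind(idx, p)])
      if (s > best) best <- s
    }
    best
  } else {
    tot <- 0
    while (any(padded > 0)) {
      w <- which(padded == max(padded), arr.ind = TRUE)[1, ]
      tot <- tot + padded[w[1], w[2]]
      padded[w[1], ] <- -1
      padded[, w[2]] <- -1
    }
    tot
  }
}

permuteAll <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- permuteAll(k - 1L)
    out <- c(out, lapply(rest, function(p) c(i, ifelse(p >= i, p + 1L, p))))
  }
  out
}

#' Agreement between two partitions
#'
#' Fraction of nodes identically assigned after optimal community-label
#' matching (assignment-problem maximum on the contingency table), plus the
#' adjusted Rand index.
#'
#' @param p1,p2 [Partition-class] objects (or named integer assignments) over
#'   the same node set.
#' @return list with `agreement` (fraction in \[0, 1\]) and `ari`.
#' @export
partitionAgreement <- function(p1, p2) {
  a <- if (methods::is(p1, "Partition")) p1@assignment else p1
  b <- if (methods::is(p2, "Partition")) p2@assignment else p2
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("partitions cover different node sets")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("partitions cover different node sets")
  }
  list(agreement = bestLabelMatchCount(a, b) / length(a),
       ari = mclust::adjustedRandIndex(a, b))
}

#' Consensus community detection
#'
#' Runs [louvainPartition()] `nIter` times with derived seeds, builds the
#' node-by-node co-assignment (agreement) matrix, thresholds it at `tau`, and
#' re-clusters the thresholded agreement matrix iteratively until all runs
#' agree on one partition.
#'
#' @param net A [SubjectNetwork-class] or symmetric weight matrix.
#' @param nIter Number of base iterations (default 100).
#' @param tau Agreement threshold in \[0, 1\] (default 0.5).
#' @param gamma Resolution parameter.
#' @param seed Integer seed.
#' @param maxRounds Re-clustering round cap before declaring non-convergence.
#' @return A [ConsensusResult-class]. The consensus partition's Q is computed
#'   on the original network.
#' @export
consensusPartition <- function(net, nIter = 100L, tau = 0.5, gamma = 1,
                               seed = 1L, maxRounds = 25L) {
  stopifnot(nIter >= 2L)
  W <- if (methods::is(net, "SubjectNetwork")) connMatrix(net) else net
  n <- nrow(W)
  ids <- rownames(W) %||% as.character(seq_len(n))
  runs <- vapply(seq_len(nIter), function(i)
    louvainPartition(W, gamma, deriveSeed(seed, paste0("louvain", i)))@assignment,
    integer(n))
  agreement <- coAssignment(runs)
  dimnames(agreement) <- list(ids, ids)

  ## stability: nodes identically assigned across all runs after aligning
  ## each run's labels to the first run
  aligned <- apply(runs, 2L, alignLabels, ref = runs[, 1L])
  stab <- mean(apply(aligned, 1L, function(r) length(unique(r)) == 1L))

  cur <- runs
  A <- agreement
  consensus <- NULL
  for (round in seq_len(maxRounds)) {
    if (allRunsIdentical(cur)) { consensus <- cur[, 1L]; break }
    At <- A
    At[At < tau] <- 0
    diag(At) <- 0
    if (all(At == 0))
      stop("consensus failed: thresholded agreement matrix has no edges; ",
           "lower tau or inspect the network")
    cur <- vapply(seq_len(ncol(runs)), function(i)
      louvainPartition(At, gamma,
                       deriveSeed(seed, sprintf("cons%d_%d", round, i)))@assignment,
      integer(n))
    if (allRunsIdentical(cur)) { consensus <- cur[, 1L]; break }
    A <- coAssignment(cur)
  }
  if (is.null(consensus))
    stop(sprintf("consensus did not converge after %d rounds (tau = %g); ",
                 maxRounds, tau),
         "the agreement structure may be unstable")
  ci <- match(consensus, unique(consensus))
  part <- methods::new("Partition",
                       assignment = stats::setNames(as.integer(ci), ids),
                       Q = computeModularity(W, ci, gamma), gamma = gamma)
  methods::new("ConsensusResult", partition = part, agreement = agreement,
               nIterations = as.integer(nIter), stability = stab)
}

coAssignment <- function(runs) {
  n <- nrow(runs)
  A <- matrix(0, n, n)
  for (j in seq_len(ncol(runs)))
    A <- A + outer(runs[, j], runs[, j], "==")
  A / ncol(runs)
}

allRunsIdentical <- function(runs) {
  ref <- runs[, 1L]
  all(vapply(seq_len(ncol(runs)), function(j)
    all(alignLabels(runs[, j], ref) == alignLabels(ref, ref)), logical(1)))
}

## Relabel `x` to maximise agreement with `ref` (labels made dense first).
alignLabels <- function(x, ref) {
  x <- match(x, unique(x))
  ref <- match(ref, unique(ref))
  kx <- max(x); kr <- max(ref)
  k <- max(kx, kr)
  tab <- matrix(0, k, k)
  t0 <- table(x, ref)
  tab[seq_len(nrow(t0)), seq_len(ncol(t0))] <- t0
  if (k <= 8L) {
    perms <- permuteAll(k)
    idx <- seq_len(k)
    best <- NULL; bestScore <- -1
    for (p in perms) {
      s <- sum(tab[cbind(idx, p)])
      if (s > bestScore) { bestScore <- s; best <- p }
    }
    best[x]
  } else {
    mapping <- rep(NA_integer_, k)
    t2 <- tab
    repeat {
      w <- which(t2 == max(t2), arr.ind = TRUE)[1, ]
      if (t2[w[1], w[2]] < 0) break
      mapping[w[1]] <- w[2]
      t2[w[1], ] <- -1; t2[, w[2]] <- -1
      if (all(!is.na(mapping))) break
    }
    free <- setdiff(seq_len(k), mapping[!is.na(mapping)])
    mapping[is.na(mapping)] <- free
    mapping[x]
  }
}
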