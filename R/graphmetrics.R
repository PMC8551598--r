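## Weighted nodal and global graph metrics, degree/weight-preserving null
## ensembles, normalisation, and AUC across cost thresholds.
##
## Conventions (BCT-style): the weight-to-length map is length = 1/weight;
## weighted clustering is the Onnela geometric-mean form; disconnected pairs
## are excluded from the characteristic path length and contribute zero to
## efficiency; betweenness is reported as raw path counts.

lengthGraph <- function(W) {
  L <- W
  L[W > 0] <- 1 / W[W > 0]
  igraph::graph_from_adjacency_matrix(L, mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}

onnelaClustering <- function(W) {
  mx <- max(W)
  if (mx <= 0) return(rep(0, nrow(W)))
  Wn <- (W / mx)^(1 / 3)
  num <- diag(Wn %*% Wn %*% Wn)
  k <- rowSums(W > 0)
  out <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  unname(out)
}

localEfficiencyNodal <- function(W) {
  n <- nrow(W)
  vapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2L) return(0)
    sub <- W[nb, nb, drop = FALSE]
    if (all(sub == 0)) return(0)
    d <- igraph::distances(lengthGraph(sub))
    inv <- 1 / d[upper.tri(d)]
    inv[!is.finite(inv)] <- 0
    mean(inv)
  }, numeric(1))
}

#' Nodal graph metrics of a thresholded connectome
#'
#' Strength (weighted degree), betweenness centrality (raw shortest-path
#' counts on 1/weight lengths), participation coefficient
#' `1 - sum_s (k_is / k_i)^2` over the module partition, within-module degree
#' z-score, Onnela weighted clustering, and nodal local efficiency.
#'
#' @param conn A thresholded positive-weight [Connectome-class].
#' @param modulePartition Module label per region; defaults to the ICN map
#'   (subject-invariant, matching the ICN framing of the analysis).
#' @return data.frame with one row per region: region_id, strength,
#'   betweenness, participation, within_module_z, clustering,
#'   local_efficiency.
#' @export
nodalMetrics <- function(conn, modulePartition = NULL) {
  W <- connMatrix(conn)
  if (any(W < 0)) stop("nodal metrics require a thresholded positive-weight connectome")
  module <- modulePartition %||% unname(icnMap(conn)[conn@regionIds])
  stopifnot(length(module) == nrow(W))
  strength <- rowSums(W)
  g <- lengthGraph(W)
  btw <- unname(igraph::betweenness(g, directed = FALSE, normalized = FALSE))
  ## participation: module-wise strengths
  km <- rowsum(t(W), group = module)            # modules x nodes
  frac <- sweep(km, 2L, pmax(strength, .Machine$double.eps), "/")
  participation <- 1 - colSums(frac^2)
  participation[strength == 0] <- 0
  ## within-module degree z
  idx <- cbind(match(module, rownames(km)), seq_len(ncol(km)))
  within <- km[idx]
  z <- numeric(length(within))
  for (m in unique(module)) {
    sel <- module == m
    s <- stats::sd(within[sel])
    z[sel] <- if (is.na(s) || s == 0) 0 else (within[sel] - mean(within[sel])) / s
  }
  data.frame(region_id = conn@regionIds, strength = unname(strength),
             betweenness = btw, participation = unname(participation),
             within_module_z = z, clustering = onnelaClustering(W),
             local_efficiency = localEfficiencyNodal(W), row.names = NULL)
}

#' Global graph metrics of a thresholded connectome
#'
#' Mean strength, modularity (best of `nRestarts` Louvain runs on the
#' positive weights), characteristic path length (mean shortest path over
#' reachable pairs, 1/weight lengths), global efficiency (mean inverse
#' shortest path, disconnected pairs contribute 0), mean local efficiency,
#' mean Onnela clustering, raw small-worldness (clustering / path length),
#' and assortativity (Pearson correlation of endpoint strengths over edges;
#' `NaN` with a warning when strengths are constant).
#'
#' @param conn A thresholded positive-weight [Connectome-class] or matrix.
#' @param gamma Resolution for the modularity Louvain.
#' @param seed Seed for the Louvain sweep order.
#' @param nRestarts Louvain restarts for modularity (best Q kept).
#' @return Named numeric vector of the eight metrics; attribute
#'   `disconnected` flags unreachable node pairs.
#' @export
globalMetrics <- function(conn, gamma = 1, seed = 1L, nRestarts = 3L) {
  W <- if (methods::is(conn, "Connectome")) connMatrix(conn) else conn
  if (any(W < 0)) stop("global metrics require non-negative weights")
  n <- nrow(W)
  strength <- rowSums(W)
  d <- igraph::distances(lengthGraph(W))
  offd <- d[upper.tri(d)]
  reach <- is.finite(offd)
  charpath <- if (any(reach)) mean(offd[reach]) else NA_real_
  inv <- 1 / offd
  inv[!reach] <- 0
  geff <- mean(inv)
  clust <- mean(onnelaClustering(W))
  leff <- mean(localEfficiencyNodal(W))
  Q <- max(vapply(seq_len(nRestarts), function(r)
    louvainPartition(W, gamma, deriveSeed(seed, paste0("gm", r)))@Q, numeric(1)))
  up <- upperPairs(n)
  pos <- W[up] > 0
  si <- strength[up[pos, "i"]]
  sj <- strength[up[pos, "j"]]
  x <- c(si, sj); y <- c(sj, si)
  assort <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("assortativity undefined: endpoint strengths have zero variance")
    NaN
  } else stats::cor(x, y)
  out <- c(strength = mean(strength), modularity = Q, charpath = charpath,
           global_efficiency = geff, local_efficiency = leff,
           clustering = clust, smallworldness = clust / charpath,
           assortativity = assort)
  attr(out, "disconnected") <- sum(!reach)
  out
}

#' Degree- and weight-preserving null ensemble
#'
#' Generates `n` rewired versions of the connectome by Maslov-Sneppen
#' double-edge swaps that carry edge weights, so every null preserves the
#' degree sequence exactly and the multiset of edge weights exactly, and
#' computes global metrics for each null.
#'
#' @param conn A thresholded positive-weight [Connectome-class] or matrix.
#' @param n Number of nulls (default 100).
#' @param swapsPerEdge Accepted swaps per edge (default 10).
#' @param seed Integer seed.
#' @return list with `metrics` (n x 8 matrix of per-null global metrics),
#'   `nulls` (list of rewired matrices), `swapsPerEdge`, `seed`.
#' @export
nullEnsemble <- function(conn, n = 100L, swapsPerEdge = 10L, seed = 1L) {
  W <- if (methods::is(conn, "Connectome")) connMatrix(conn) else conn
  nulls <- lapply(seq_len(n), function(i)
    rewireWeighted(W, swapsPerEdge, deriveSeed(seed, paste0("null", i))))
  metrics <- t(vapply(seq_along(nulls), function(i)
    as.numeric(suppressWarnings(
      globalMetrics(nulls[[i]], seed = deriveSeed(seed, paste0("nullgm", i))))),
    numeric(8L)))
  colnames(metrics) <- c("strength", "modularity", "charpath",
                         "global_efficiency", "local_efficiency", "clustering",
                         "smallworldness", "assortativity")
  list(metrics = metrics, nulls = nulls, swapsPerEdge = swapsPerEdge,
       seed = seed)
}

#' Rewire a weighted graph preserving degrees and the weight multiset
#'
#' @param W Symmetric non-negative weight matrix.
#' @param swapsPerEdge Accepted double-edge swaps per edge.
#' @param seed Integer seed.
#' @return Rewired symmetric matrix.
#' @export
rewireWeighted <- function(W, swapsPerEdge = 10L, seed = 1L) {
  n <- nrow(W)
  up <- upperPairs(n)
  pos <- W[up] > 0
  ei <- up[pos, "i"]; ej <- up[pos, "j"]
  w <- W[up][pos]
  m <- length(w)
  if (m < 2L) stop("too few edges to rewire")
  res <- withSeed(seed,
    rewire_swaps(as.integer(ei), as.integer(ej), n, as.integer(swapsPerEdge * m),
                 as.integer(100L * swapsPerEdge * m)))
  out <- matrix(0, n, n, dimnames = dimnames(W))
  out[cbind(res$ei, res$ej)] <- w
  out[cbind(res$ej, res$ei)] <- w
  out
}

#' Normalise global metrics against a null ensemble
#'
#' Clustering, characteristic path length, global efficiency, local
#' efficiency, small-worldness and assortativity are divided by the null
#' ensemble means; strength and modularity are returned raw. Normalised
#' small-worldness is the sigma form, normalised clustering divided by
#' normalised path length; the raw ratio and raw assortativity remain
#' available in `raw`.
#'
#' @param raw Named metric vector from [globalMetrics()].
#' @param nulls A [nullEnsemble()] result computed on the same connectome.
#' @return list with `raw`, `normalised` (same names), and `nullMeans`.
#' @export
normaliseMetrics <- function(raw, nulls) {
  nm <- colMeans(nulls$metrics)
  normed <- raw
  for (k in c("clustering", "charpath", "global_efficiency",
              "local_efficiency", "assortativity"))
    normed[k] <- raw[k] / nm[k]
  normed["smallworldness"] <- normed["clustering"] / normed["charpath"]
  normed["strength"] <- raw["strength"]
  normed["modularity"] <- raw["modularity"]
  list(raw = raw, normalised = normed, nullMeans = nm)
}

#' Area under a metric-versus-cost curve
#'
#' Trapezoidal integral of the metric over the cost range (costs expressed as
#' proportions, e.g. 0.05-0.30).
#'
#' @param values Metric value at each cost.
#' @param costs Ascending cost thresholds (default the six standard costs).
#' @return Scalar AUC.
#' @export
aucOverCosts <- function(values, costs = c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30)) {
  trapz(costs, values)
}
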