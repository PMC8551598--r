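## Functional connectome construction, motion QC, proportional thresholding,
## and ICN block summaries.

#' Pearson correlation connectome from a regional time-series matrix
#'
#' @param ts Numeric matrix, regions x timepoints (rownames = region ids).
#' @param icnMap Named character, region -> ICN label.
#' @param subjectId Subject identifier.
#' @return An unthresholded [Connectome-class] (diagonal zeroed).
#' @export
correlationConnectome <- function(ts, icnMap, subjectId = "subject") {
  stopifnot(is.matrix(ts))
  if (ncol(ts) < 3L) stop("need at least 3 timepoints")
  sds <- apply(ts, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant time series for region(s): ",
         paste(rownames(ts)[sds == 0] %||% which(sds == 0), collapse = ", "))
  m <- stats::cor(t(ts))
  diag(m) <- 0
  ids <- rownames(ts) %||% names(icnMap)[seq_len(nrow(ts))]
  dimnames(m) <- list(ids, ids)
  methods::new("Connectome", matrix = m, regionIds = ids, icnMap = icnMap,
               subjectId = subjectId,
               provenance = list(threshold = "none", cost = NA_real_,
                                 normalised = FALSE))
}

#' Motion-based subject exclusion
#'
#' Applies the two-stage exclusion rule: first exclude subjects with high
#' average motion (mean framewise displacement above `fdCut`), then subjects
#' with a large fraction of motion spikes (FD above `spikeFd` in more than
#' `spikeCut` of volumes).
#'
#' @param fdTraces Named list or matrix (subject x volume) of framewise
#'   displacement traces in mm.
#' @param fdCut Mean-FD exclusion cutoff in mm (default 0.5).
#' @param spikeCut Maximum allowed spike fraction (default 0.2).
#' @param spikeFd FD defining a motion spike, in mm (default 0.5).
#' @return data.frame: subject_id, mean_fd, spike_fraction, included, reason.
#' @export
motionFilter <- function(fdTraces, fdCut = 0.5, spikeCut = 0.2, spikeFd = 0.5) {
  if (is.matrix(fdTraces))
    fdTraces <- stats::setNames(split(fdTraces, row(fdTraces)),
                                rownames(fdTraces) %||% seq_len(nrow(fdTraces)))
  stopifnot(length(fdTraces) > 0L, all(lengths(fdTraces) > 0L))
  meanFd <- vapply(fdTraces, mean, numeric(1))
  spikeFrac <- vapply(fdTraces, function(x) mean(x > spikeFd), numeric(1))
  reason <- rep("", length(fdTraces))
  reason[meanFd > fdCut] <- "mean FD"
  reason[reason == "" & spikeFrac > spikeCut] <- "spikes"
  data.frame(subject_id = names(fdTraces), mean_fd = meanFd,
             spike_fraction = spikeFrac, included = reason == "",
             reason = reason, row.names = NULL)
}

#' Mean functional connectivity per subject
#'
#' Average off-diagonal correlation of each (unthresholded) connectome.
#'
#' @param stack List of [Connectome-class] objects.
#' @return Named numeric vector.
#' @export
meanFc <- function(stack) {
  vapply(stack, function(cn) {
    m <- connMatrix(cn)
    mean(m[upper.tri(m)])
  }, numeric(1))
}

#' Mean-FC outlier exclusion
#'
#' Removes subjects whose mean functional connectivity lies more than
#' `nSd` standard deviations from the sample mean (single pass).
#'
#' @param stack List of [Connectome-class] objects (raw correlation matrices).
#' @param nSd Exclusion distance in SD units (default 3).
#' @return list with `included` (logical, named) and `mean_fc` (numeric).
#' @export
fcOutlierFilter <- function(stack, nSd = 3) {
  stopifnot(length(stack) >= 3L)
  fc <- meanFc(stack)
  s <- stats::sd(fc)
  included <- if (s == 0) rep(TRUE, length(fc)) else abs(fc - mean(fc)) <= nSd * s
  names(included) <- names(fc)
  list(included = included, mean_fc = fc)
}

## Shared edge-selection helper: indices (into the row-major upper triangle)
## of the top floor(cost * E) positive entries of `m`, ties broken by first
## occurrence in row-major upper-triangle order.
topPositiveEdges <- function(m, cost) {
  n <- nrow(m)
  up <- upperPairs(n)
  w <- m[up]
  E <- nrow(up)
  nKeep <- floor(cost * E)
  nPos <- sum(w > 0)
  if (nPos < nKeep)
    stop(sprintf("only %d positive edges available but cost %.2f requires %d",
                 nPos, cost, nKeep))
  ord <- order(-w, seq_along(w))
  sel <- ord[seq_len(nKeep)]
  up[sel, , drop = FALSE]
}

#' Group-level proportional thresholding
#'
#' Ranks the positive edges of the group-mean connectome, retains the top
#' `floor(cost * E)` (E = number of possible edges), and applies that single
#' binary mask to every subject so the same edges are compared across
#' individuals. Negative individual weights surviving the mask are set to a
#' small positive value (0.001) to minimise their influence.
#'
#' @param stack List of unthresholded [Connectome-class] objects with
#'   identical region sets.
#' @param cost Edge density to retain (default 0.25).
#' @return list with `stack` (thresholded connectomes), `mask` (logical
#'   region x region matrix), and `cost`.
#' @export
groupThreshold <- function(stack, cost = 0.25) {
  stopifnot(length(stack) >= 1L)
  mats <- lapply(stack, connMatrix)
  dims <- vapply(mats, nrow, integer(1))
  if (length(unique(dims)) != 1L) stop("all connectomes must share dimensions")
  meanM <- Reduce(`+`, mats) / length(mats)
  keep <- topPositiveEdges(meanM, cost)
  n <- nrow(meanM)
  mask <- matrix(FALSE, n, n, dimnames = dimnames(meanM))
  mask[keep] <- TRUE
  mask <- mask | t(mask)
  out <- lapply(stack, function(cn) {
    m <- connMatrix(cn)
    m[!mask] <- 0
    m[mask & m < 0] <- 0.001
    methods::initialize(cn, matrix = m,
                        provenance = list(threshold = "group", cost = cost,
                                          normalised = FALSE))
  })
  list(stack = out, mask = mask, cost = cost)
}

#' Individual proportional thresholding
#'
#' Retains the top `floor(cost * E)` positive edges of this subject's own
#' connectome.
#'
#' @param conn An unthresholded [Connectome-class].
#' @param cost Edge density to retain.
#' @return A thresholded [Connectome-class].
#' @export
individualThreshold <- function(conn, cost = 0.25) {
  m <- connMatrix(conn)
  keep <- topPositiveEdges(m, cost)
  n <- nrow(m)
  mask <- matrix(FALSE, n, n)
  mask[keep] <- TRUE
  mask <- mask | t(mask)
  m[!mask] <- 0
  methods::initialize(conn, matrix = m,
                      provenance = list(threshold = "individual", cost = cost,
                                        normalised = FALSE))
}

#' Normalise connectome edge weights to the individual maximum
#'
#' After normalisation the maximum retained weight is exactly 1 and weight
#' ratios are preserved.
#'
#' @param conn A [Connectome-class].
#' @return A [Connectome-class] with `normalised = TRUE` provenance.
#' @export
normaliseToMax <- function(conn) {
  m <- connMatrix(conn)
  mx <- max(m)
  if (mx <= 0) stop("cannot normalise: no positive weights")
  p <- conn@provenance
  p$normalised <- TRUE
  methods::initialize(conn, matrix = m / mx, provenance = p)
}

#' ICN block connectivity features
#'
#' Mean edge weight within each of the eight ICNs and between each of the 28
#' ICN pairs: 36 features per subject. Means are over retained (positive)
#' edges only; an empty block yields 0.
#'
#' @param conn A thresholded [Connectome-class].
#' @return Named numeric vector of 36 features (`within_<icn>`,
#'   `between_<icnA>_<icnB>`); attribute `emptyBlocks` lists blocks with no
#'   retained edges.
#' @export
icnFeatures <- function(conn) {
  m <- connMatrix(conn)
  icn <- icnMap(conn)[conn@regionIds]
  labs <- ICN_LABELS
  shortLab <- gsub("[ -]", ".", labs)
  feats <- numeric(0)
  empty <- character(0)
  blockMean <- function(sub) {
    w <- sub[sub > 0]
    if (!length(w)) NA_real_ else mean(w)
  }
  for (k in seq_along(labs)) {
    idx <- which(icn == labs[k])
    sub <- m[idx, idx, drop = FALSE]
    v <- blockMean(sub[upper.tri(sub)])
    nm <- paste0("within_", shortLab[k])
    if (is.na(v)) { empty <- c(empty, nm); v <- 0 }
    feats[nm] <- v
  }
  for (a in seq_len(length(labs) - 1L)) for (b in (a + 1L):length(labs)) {
    ia <- which(icn == labs[a]); ib <- which(icn == labs[b])
    v <- blockMean(as.vector(m[ia, ib, drop = FALSE]))
    nm <- paste0("between_", shortLab[a], "_", shortLab[b])
    if (is.na(v)) { empty <- c(empty, nm); v <- 0 }
    feats[nm] <- v
  }
  structure(feats, emptyBlocks = empty)
}

#' ICN feature matrix for a stack of connectomes
#'
#' @param stack Named list of thresholded [Connectome-class] objects.
#' @return Numeric matrix, subject x 36 features.
#' @export
icnFeatureMatrix <- function(stack) {
  out <- t(vapply(stack, function(cn) as.numeric(icnFeatures(cn)),
                  numeric(36L)))
  colnames(out) <- names(icnFeatures(stack[[1L]]))
  rownames(out) <- names(stack)
  out
}
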