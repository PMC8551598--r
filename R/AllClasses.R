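## Central S4 containers. Statistical procedure outputs (CV tables,
## permutation records, bootstrap summaries) are returned as plain lists and
## data.frames; the classes below carry the data objects that flow between
## pipeline stages and therefore need validity guarantees.

ICN_LABELS <- c("visual", "somatomotor", "dorsal attention", "ventral attention",
                "fronto-parietal", "default mode", "limbic", "subcortical")

SCALE_NAMES <- c("Inattention", "Hyperactivity/Impulsivity", "Learning Problems",
                 "Executive Function", "Aggression", "Peer Relations")

#' CohortSpec: parameters of the synthetic cohort generator
#'
#' Defines planted behavioural profiles (group-by-scale T-score means),
#' the intrinsic connectivity network (ICN) block covariance of the regional
#' time series, group-specific covariance perturbations, and covariate
#' distributions. All downstream stages are exercised against cohorts drawn
#' from this model.
#'
#' @slot nPerGroup integer, subjects per group.
#' @slot groups character, group labels (comparison group first).
#' @slot scaleNames character, behavioural scale labels.
#' @slot profileMeans numeric matrix (group x scale) of T-score means.
#' @slot behaviourNoiseSd numeric, independent per-scale noise SD (T-score units).
#' @slot tscoreRange numeric length-2, clipping range for generated T-scores.
#' @slot nRegions integer, number of brain regions.
#' @slot nTimepoints integer, number of retained fMRI volumes.
#' @slot icnMap named character, region id -> one of the eight ICN labels.
#' @slot regionVar numeric, time-series variance per region.
#' @slot withinCor numeric, model correlation between regions of the same ICN.
#' @slot betweenCor numeric, model correlation between regions of different ICNs.
#' @slot groupEffects list of lists with fields `pair` (two ICN labels),
#'   `delta` (additive correlation change), `groups` (character of affected groups).
#' @slot covariateModel list with fields `ageRange`, `pMale`, `fdMeanlog`,
#'   `fdSdlog`, `spikeProb`, `spikeRange`.
#' @slot seed integer master seed.
#' @exportClass CohortSpec
setClass("CohortSpec", representation(
  nPerGroup = "integer", groups = "character", scaleNames = "character",
  profileMeans = "matrix", behaviourNoiseSd = "numeric", tscoreRange = "numeric",
  nRegions = "integer", nTimepoints = "integer", icnMap = "character",
  regionVar = "numeric", withinCor = "numeric", betweenCor = "numeric",
  groupEffects = "list", covariateModel = "list", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPerGroup < 1L) msg <- c(msg, "nPerGroup must be >= 1")
  if (nrow(object@profileMeans) != length(object@groups))
    msg <- c(msg, "profileMeans must have one row per group")
  if (ncol(object@profileMeans) != length(object@scaleNames))
    msg <- c(msg, "profileMeans must have one column per scale")
  if (object@behaviourNoiseSd < 0) msg <- c(msg, "behaviourNoiseSd must be >= 0")
  if (length(object@icnMap) != object@nRegions)
    msg <- c(msg, "icnMap must assign every region")
  if (!all(object@icnMap %in% ICN_LABELS))
    msg <- c(msg, sprintf("icnMap labels must be among: %s",
                          paste(ICN_LABELS, collapse = ", ")))
  for (ge in object@groupEffects) {
    if (!all(c("pair", "delta", "groups") %in% names(ge)))
      msg <- c(msg, "each group effect needs fields pair, delta, groups")
    else if (!all(ge$pair %in% ICN_LABELS))
      msg <- c(msg, "group effect ICN pair labels must be valid ICNs")
  }
  ## positive definiteness of every group's covariance
  for (g in object@groups) {
    sig <- try(groupCovariance(object, g), silent = TRUE)
    if (inherits(sig, "try-error")) { msg <- c(msg, attr(sig, "condition")$message); next }
    ev <- min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-10) {
      offending <- vapply(object@groupEffects,
                          function(ge) g %in% ge$groups, logical(1))
      detail <- if (any(offending))
        paste(vapply(object@groupEffects[offending], function(ge)
          sprintf("(%s, %s) delta=%g", ge$pair[1], ge$pair[2], ge$delta),
          character(1)), collapse = "; ")
      else "base block covariance"
      msg <- c(msg, sprintf(
        "covariance for group '%s' is not positive definite (%s)", g, detail))
    }
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: generated behaviour, time series and covariates
#'
#' @slot behaviour data.frame with subject_id, group, and one column per scale.
#' @slot trueLabels named character, subject id -> planted group.
#' @slot timeseries named list of region x timepoint matrices.
#' @slot covariates data.frame with subject_id, age, sex, mean_fd.
#' @slot fdTrace numeric matrix, subject x timepoint framewise displacement (mm).
#' @slot icnMap named character, region -> ICN label.
#' @exportClass SyntheticCohort
setClass("SyntheticCohort", representation(
  behaviour = "data.frame", trueLabels = "character", timeseries = "list",
  covariates = "data.frame", fdTrace = "matrix", icnMap = "character"))

setValidity("SyntheticCohort", function(object) {
  ids <- object@behaviour$subject_id
  msg <- character()
  if (length(object@trueLabels) && !identical(names(object@trueLabels), ids))
    msg <- c(msg, "trueLabels must be indexed by the behaviour subject ids")
  if (length(object@timeseries)) {
    if (!identical(names(object@timeseries), ids))
      msg <- c(msg, "timeseries must be indexed by the behaviour subject ids")
    if (nrow(object@fdTrace) != length(ids))
      msg <- c(msg, "fdTrace must have one row per subject")
    if (nrow(object@covariates) &&
        max(abs(object@covariates$mean_fd - rowMeans(object@fdTrace))) > 1e-8)
      msg <- c(msg, "mean_fd must equal the mean of the FD trace")
  }
  if (length(msg)) msg else TRUE
})

#' SubjectNetwork: signed subject-by-subject behavioural correlation network
#'
#' @slot matrix symmetric subject x subject Pearson correlation matrix,
#'   diagonal set to zero.
#' @slot excluded data.frame with subject_id and reason for each exclusion.
#' @exportClass SubjectNetwork
setClass("SubjectNetwork",
         representation(matrix = "matrix", excluded = "data.frame"))

setValidity("SubjectNetwork", function(object) {
  m <- object@matrix
  msg <- character()
  if (!isSymmetricMat(m)) msg <- c(msg, "network matrix must be symmetric")
  if (any(abs(diag(m)) > 0)) msg <- c(msg, "diagonal must be zero")
  off <- m[upper.tri(m)]
  if (length(off) && (min(off) < -1 - 1e-8 || max(off) > 1 + 1e-8))
    msg <- c(msg, "off-diagonal correlations must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Partition: a community assignment with its modularity
#'
#' @slot assignment named integer, node id -> community id (1-based, dense).
#' @slot Q numeric, signed weighted modularity of the assignment.
#' @slot gamma numeric, resolution parameter used.
#' @exportClass Partition
setClass("Partition",
         representation(assignment = "integer", Q = "numeric", gamma = "numeric"))

setValidity("Partition", function(object) {
  if (anyNA(object@assignment)) "every node must be assigned a community" else TRUE
})

#' ConsensusResult: consensus community detection output
#'
#' @slot partition Partition, the consensus assignment and its Q on the
#'   original network.
#' @slot agreement numeric matrix, co-assignment frequency across iterations.
#' @slot nIterations integer, number of base iterations.
#' @slot stability numeric, fraction of nodes identically assigned (after
#'   label alignment) across all iterations.
#' @exportClass ConsensusResult
setClass("ConsensusResult", representation(
  partition = "Partition", agreement = "matrix", nIterations = "integer",
  stability = "numeric"))

setValidity("ConsensusResult", function(object) {
  a <- object@agreement
  msg <- character()
  if (!isSymmetricMat(a)) msg <- c(msg, "agreement matrix must be symmetric")
  if (length(a) && (min(a) < -1e-12 || max(a) > 1 + 1e-12))
    msg <- c(msg, "agreement values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Connectome: a weighted functional connectivity matrix with ICN labels
#'
#' @slot matrix symmetric region x region weight matrix, zero diagonal.
#' @slot regionIds character region identifiers.
#' @slot icnMap named character, region -> ICN label.
#' @slot subjectId character scalar.
#' @slot provenance list: threshold ("none", "group", "individual"),
#'   cost (proportion), normalised (flag).
#' @exportClass Connectome
setClass("Connectome", representation(
  matrix = "matrix", regionIds = "character", icnMap = "character",
  subjectId = "character", provenance = "list"))

setValidity("Connectome", function(object) {
  m <- object@matrix
  msg <- character()
  if (!isSymmetricMat(m)) msg <- c(msg, "connectome matrix must be symmetric")
  if (any(abs(diag(m)) > 0)) msg <- c(msg, "diagonal must be zero")
  if (length(object@regionIds) != nrow(m))
    msg <- c(msg, "regionIds must match matrix dimension")
  if (!all(object@regionIds %in% names(object@icnMap)))
    msg <- c(msg, "icnMap must cover every region")
  thr <- object@provenance$threshold
  if (!is.null(thr) && thr != "none" && any(m[upper.tri(m)] < 0))
    msg <- c(msg, "thresholded connectomes must have non-negative weights")
  if (length(msg)) msg else TRUE
})

#' PLSModel: NIPALS PLS2 regression model
#'
#' @slot xMeans,yMeans numeric, column centres used at fit time.
#' @slot weights numeric matrix (p x k), X weights.
#' @slot xLoadings numeric matrix (p x k).
#' @slot yLoadings numeric matrix (q x k).
#' @slot scores numeric matrix (n x k), X component scores.
#' @slot coef numeric matrix (p x q), regression coefficients on centred scale.
#' @slot k integer, number of components.
#' @exportClass PLSModel
setClass("PLSModel", representation(
  xMeans = "numeric", yMeans = "numeric", weights = "matrix",
  xLoadings = "matrix", yLoadings = "matrix", scores = "matrix",
  coef = "matrix", k = "integer"))
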