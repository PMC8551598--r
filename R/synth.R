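## Synthetic cohort generator: planted behavioural profiles, ICN
## block-covariance time series, and realistic covariates. The generator
## defines the study conditions every downstream stage is tested under.

#' Evenly split regions across the eight intrinsic connectivity networks
#'
#' @param nRegions Number of regions.
#' @return Named character vector, region id -> ICN label.
#' @export
defaultIcnMap <- function(nRegions) {
  sizes <- rep(nRegions %/% 8L, 8L)
  sizes[seq_len(nRegions %% 8L)] <- sizes[seq_len(nRegions %% 8L)] + 1L
  labels <- rep(ICN_LABELS, times = sizes)
  names(labels) <- sprintf("R%03d", seq_len(nRegions))
  labels
}

#' Construct a synthetic cohort specification
#'
#' Defaults come from the configuration shipped with the package
#' (`inst/extdata/default_cohort.yaml`): three planted behavioural profiles
#' plus a comparison group, ICN block covariance with a planted
#' limbic-dorsal-attention effect in group C2, and covariate distributions
#' (age uniform on 5-15 years, binary sex, log-normal framewise displacement
#' with occasional spikes). Every argument overrides the shipped value.
#'
#' @param nPerGroup Subjects per group.
#' @param seed Integer master seed; all generation is a pure function of
#'   (spec, seed).
#' @param nRegions,nTimepoints Dimensions of the regional time series.
#' @param behaviourNoiseSd Independent per-scale Gaussian noise SD (T-scores).
#' @param profileMeans Optional group x scale matrix of T-score means.
#' @param groups,scaleNames Optional label overrides (must match profileMeans).
#' @param icnMap Optional named character region -> ICN label.
#' @param withinCor,betweenCor,regionVar Block covariance parameters.
#' @param groupEffects List of planted effects, each
#'   `list(pair = c(icnA, icnB), delta = x, groups = c(...))`.
#' @param covariateModel List overriding the covariate distributions.
#' @param tscoreRange Clipping range for generated T-scores.
#' @return A validated [CohortSpec-class].
#' @examples
#' spec <- cohortSpec(nPerGroup = 10, nRegions = 40, seed = 1)
#' spec
#' @export
cohortSpec <- function(nPerGroup = 50L, seed = 1L,
                       nRegions = NULL, nTimepoints = NULL,
                       behaviourNoiseSd = NULL, profileMeans = NULL,
                       groups = NULL, scaleNames = NULL, icnMap = NULL,
                       withinCor = NULL, betweenCor = NULL, regionVar = NULL,
                       groupEffects = NULL, covariateModel = NULL,
                       tscoreRange = NULL) {
  cfg <- defaultCohortConfig()
  groups <- groups %||% cfg$profiles$groups
  scaleNames <- scaleNames %||% cfg$profiles$scale_names
  if (is.null(profileMeans)) {
    profileMeans <- do.call(rbind, cfg$profiles$means[groups])
    dimnames(profileMeans) <- list(groups, scaleNames)
  }
  nRegions <- as.integer(nRegions %||% cfg$n_regions)
  cm <- cfg$covariate_model
  if (!is.null(covariateModel)) cm[names(covariateModel)] <- covariateModel
  geRaw <- groupEffects %||% lapply(cfg$group_effects, function(ge)
    list(pair = unlist(ge$pair), delta = ge$delta, groups = unlist(ge$groups)))
  methods::new("CohortSpec",
    nPerGroup = as.integer(nPerGroup), groups = groups, scaleNames = scaleNames,
    profileMeans = profileMeans,
    behaviourNoiseSd = behaviourNoiseSd %||% cfg$behaviour_noise_sd,
    tscoreRange = tscoreRange %||% unlist(cfg$tscore_range),
    nRegions = nRegions,
    nTimepoints = as.integer(nTimepoints %||% cfg$n_timepoints),
    icnMap = icnMap %||% defaultIcnMap(nRegions),
    regionVar = regionVar %||% cfg$region_var,
    withinCor = withinCor %||% cfg$within_icn_cor,
    betweenCor = betweenCor %||% cfg$between_icn_cor,
    groupEffects = geRaw,
    covariateModel = list(ageRange = unlist(cm$age_range), pMale = cm$p_male,
                          fdMeanlog = cm$fd_meanlog, fdSdlog = cm$fd_sdlog,
                          spikeProb = cm$spike_prob,
                          spikeRange = unlist(cm$spike_range)),
    seed = as.integer(seed))
}

defaultCohortConfig <- function() {
  path <- system.file("extdata", "default_cohort.yaml", package = "behavconn")
  if (path == "") path <- file.path("inst", "extdata", "default_cohort.yaml")
  yaml::read_yaml(path)
}

#' Model covariance matrix of the regional time series for one group
#'
#' Base covariance is an ICN block model (`withinCor` within an ICN,
#' `betweenCor` between ICNs, unit-free variance `regionVar`), plus the
#' additive correlation deltas planted for the group.
#'
#' @param spec A [CohortSpec-class].
#' @param group Group label.
#' @return Symmetric positive definite matrix (region x region).
#' @export
groupCovariance <- function(spec, group) {
  icn <- spec@icnMap
  n <- spec@nRegions
  same <- outer(icn, icn, "==")
  R <- ifelse(same, spec@withinCor, spec@betweenCor)
  diag(R) <- 1
  for (ge in spec@groupEffects) {
    if (!group %in% ge$groups) next
    a <- icn == ge$pair[1]; b <- icn == ge$pair[2]
    block <- outer(a, b) | outer(b, a)
    if (ge$pair[1] == ge$pair[2]) block <- outer(a, a)
    diag(block) <- FALSE
    R[block] <- R[block] + ge$delta
  }
  dimnames(R) <- list(names(icn), names(icn))
  R * spec@regionVar
}

#' Generate a behavioural cohort
#'
#' Draws each subject's six scale T-scores as its group profile mean plus
#' independent Gaussian noise, rounded to integers and clipped to the
#' configured T-score range.
#'
#' @param spec A [CohortSpec-class].
#' @return data.frame with `subject_id`, `group`, and one column per scale.
#'   The planted labels are also available as the `group` column.
#' @examples
#' beh <- genBehaviourCohort(cohortSpec(nPerGroup = 5, seed = 2))
#' head(beh)
#' @export
genBehaviourCohort <- function(spec) {
  methods::validObject(spec)
  withSeed(deriveSeed(spec@seed, "behaviour"), {
    groups <- rep(spec@groups, each = spec@nPerGroup)
    n <- length(groups)
    mu <- spec@profileMeans[groups, , drop = FALSE]
    noise <- matrix(stats::rnorm(n * ncol(mu), sd = spec@behaviourNoiseSd),
                    nrow = n)
    scores <- round(mu + noise)
    scores <- pmin(pmax(scores, spec@tscoreRange[1]), spec@tscoreRange[2])
    out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                      group = groups, check.names = FALSE)
    out[spec@scaleNames] <- as.data.frame(scores)
    rownames(out) <- NULL
    out
  })
}

#' Generate a full synthetic cohort (behaviour, time series, covariates)
#'
#' Each subject's regional time series is drawn from a zero-mean multivariate
#' Gaussian whose covariance is the ICN block model plus that subject's group
#' deltas ([groupCovariance()]). Covariates follow the spec's covariate model;
#' the framewise displacement trace is log-normal with occasional spikes and
#' `mean_fd` is its mean.
#'
#' @param spec A [CohortSpec-class].
#' @return A [SyntheticCohort-class].
#' @examples
#' coh <- genTimeseriesCohort(cohortSpec(nPerGroup = 3, nRegions = 24,
#'                                       nTimepoints = 50, seed = 3))
#' coh
#' @export
genTimeseriesCohort <- function(spec) {
  methods::validObject(spec)
  behaviour <- genBehaviourCohort(spec)
  ids <- behaviour$subject_id
  n <- length(ids)
  chols <- lapply(spec@groups, function(g) chol(groupCovariance(spec, g)))
  names(chols) <- spec@groups
  withSeed(deriveSeed(spec@seed, "timeseries"), {
    ts <- vector("list", n)
    for (i in seq_len(n)) {
      R <- chols[[behaviour$group[i]]]
      z <- matrix(stats::rnorm(spec@nTimepoints * spec@nRegions),
                  nrow = spec@nTimepoints)
      x <- t(z %*% R)          # regions x timepoints
      dimnames(x) <- list(names(spec@icnMap),
                          sprintf("T%03d", seq_len(spec@nTimepoints)))
      ts[[i]] <- x
    }
    names(ts) <- ids
    cm <- spec@covariateModel
    age <- stats::runif(n, cm$ageRange[1], cm$ageRange[2])
    sex <- stats::rbinom(n, 1L, cm$pMale)
    fd <- matrix(stats::rlnorm(n * spec@nTimepoints, cm$fdMeanlog, cm$fdSdlog),
                 nrow = n)
    spikes <- matrix(stats::runif(n * spec@nTimepoints) < cm$spikeProb, nrow = n)
    fd[spikes] <- stats::runif(sum(spikes), cm$spikeRange[1], cm$spikeRange[2])
    dimnames(fd) <- list(ids, sprintf("T%03d", seq_len(spec@nTimepoints)))
    covariates <- data.frame(subject_id = ids, age = age, sex = sex,
                             mean_fd = unname(rowMeans(fd)))
    labels <- stats::setNames(behaviour$group, ids)
    methods::new("SyntheticCohort", behaviour = behaviour, trueLabels = labels,
                 timeseries = ts, covariates = covariates, fdTrace = fd,
                 icnMap = spec@icnMap)
  })
}

#' Permute a cohort's group labels (null-model resample)
#'
#' Returns the cohort with planted group labels randomly permuted across
#' subjects; all behaviour, time-series and covariate data are untouched.
#' Used to calibrate permutation tests against data with no true group effect
#' in the labels.
#'
#' @param cohort A [SyntheticCohort-class].
#' @param seed Integer seed.
#' @return A [SyntheticCohort-class] with permuted `group` / `trueLabels`.
#' @export
genNullRelabel <- function(cohort, seed) {
  stopifnot(nrow(cohort@behaviour) > 0L)
  withSeed(seed, {
    perm <- sample.int(nrow(cohort@behaviour))
    cohort@behaviour$group <- cohort@behaviour$group[perm]
    cohort@trueLabels <- stats::setNames(cohort@behaviour$group,
                                         names(cohort@trueLabels))
    cohort
  })
}
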