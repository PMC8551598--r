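## End-to-end orchestration: synthetic (or file-based) cohort -> behavioural
## profiles -> QC'd thresholded connectomes -> graph metrics and hubs -> PLS
## prediction of profile membership -> ANCOVA reports.

#' Build a pipeline run configuration
#'
#' All stage parameters with their defaults; one master seed deterministically
#' derives every stage seed. Unknown fields are rejected so typos fail fast.
#'
#' @param seed Master seed.
#' @param outDir Output directory, or `NULL` to skip writing artefacts.
#' @param stages Named logical overrides for stage toggles (synth, behaviour,
#'   connectome, metrics, hubs, pls, stats).
#' @param synth Overrides passed to [cohortSpec()] (e.g. nPerGroup, nRegions).
#' @param behaviour list: nIter, tau, gamma, niCutoff, comparisonGroup.
#' @param qc list: fdCut, spikeCut.
#' @param connectome list: cost.
#' @param metrics list: nNulls, swapsPerEdge.
#' @param hubs list: pct.
#' @param pls list: kMax, folds, repeats, nPerm, nBoot.
#' @param inputs list of file paths (`cohortDir`) used when the synth stage is
#'   disabled; see [readCohort()].
#' @return A validated config list of class `behavconnConfig`.
#' @export
runConfig <- function(seed = 1L, outDir = NULL, stages = list(),
                      synth = list(), behaviour = list(), qc = list(),
                      connectome = list(), metrics = list(), hubs = list(),
                      pls = list(), inputs = list()) {
  cfg <- list(
    seed = as.integer(seed), outDir = outDir,
    stages = list(synth = TRUE, behaviour = TRUE, connectome = TRUE,
                  metrics = TRUE, hubs = TRUE, pls = TRUE, stats = TRUE),
    synth = list(nPerGroup = 30L, nRegions = 100L, nTimepoints = 266L),
    behaviour = list(nIter = 100L, tau = 0.5, gamma = 1, niCutoff = NULL,
                     comparisonGroup = "comparison"),
    qc = list(fdCut = 0.5, spikeCut = 0.2),
    connectome = list(cost = 0.25),
    metrics = list(nNulls = 20L, swapsPerEdge = 10L),
    hubs = list(pct = 70),
    pls = list(kMax = 5L, folds = 5L, repeats = 10L, nPerm = 199L,
               nBoot = 200L),
    inputs = list(cohortDir = NULL))
  override <- function(base, user, where) {
    bad <- setdiff(names(user), names(base))
    if (length(bad))
      stop(sprintf("unknown %s option(s): %s", where, paste(bad, collapse = ", ")))
    base[names(user)] <- user
    base
  }
  cfg$stages <- override(cfg$stages, stages, "stages")
  cfg$synth <- utils::modifyList(cfg$synth, synth)   # cohortSpec validates
  cfg$behaviour <- override(cfg$behaviour, behaviour, "behaviour")
  cfg$qc <- override(cfg$qc, qc, "qc")
  cfg$connectome <- override(cfg$connectome, connectome, "connectome")
  cfg$metrics <- override(cfg$metrics, metrics, "metrics")
  cfg$hubs <- override(cfg$hubs, hubs, "hubs")
  cfg$pls <- override(cfg$pls, pls, "pls")
  cfg$inputs <- override(cfg$inputs, inputs, "inputs")
  validateConfig(cfg)
  class(cfg) <- "behavconnConfig"
  cfg
}

validateConfig <- function(cfg) {
  st <- cfg$stages
  if (!st$synth && is.null(cfg$inputs$cohortDir))
    stop("configuration error: synth disabled and no inputs$cohortDir given")
  downstream <- c("metrics", "hubs", "pls")
  for (d in downstream)
    if (st[[d]] && !st$connectome)
      stop(sprintf("configuration error: stage '%s' requires the connectome stage", d))
  if (st$stats && !st$metrics)
    stop("configuration error: stage 'stats' requires the metrics stage")
  if (st$pls && !st$behaviour)
    stop("configuration error: stage 'pls' requires the behaviour stage (group labels)")
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (cohort acquisition, behavioural
#' consensus profiling, connectome QC + thresholding, graph metrics with null
#' normalisation, hub classification, PLS prediction of profile membership
#' with permutation and bootstrap inference, ANCOVA group comparisons), writes
#' per-stage TSV/JSON artefacts plus a run manifest to `outDir` when set, and
#' returns all results. Deterministic: identical configs produce identical
#' bundles.
#'
#' @param config A [runConfig()] object.
#' @return list of per-stage results (invisible when writing to disk).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "behavconnConfig"))
  validateConfig(config)
  st <- config$stages
  out <- list(config = config)
  seed <- config$seed
  odir <- config$outDir
  if (!is.null(odir)) dir.create(odir, recursive = TRUE, showWarnings = FALSE)
  emitTsv <- function(x, name) if (!is.null(odir)) writeTsv(x, file.path(odir, name))
  emitJson <- function(x, name) if (!is.null(odir)) writeJsonReport(x, file.path(odir, name))
  emitMat <- function(x, name) if (!is.null(odir)) writeMatrixTsv(x, file.path(odir, name))

  ## --- cohort ---
  cohort <- if (st$synth) {
    spec <- do.call(cohortSpec, c(config$synth, list(seed = deriveSeed(seed, "synth"))))
    genTimeseriesCohort(spec)
  } else readCohort(config$inputs$cohortDir)
  out$cohort <- cohort
  ids <- cohort@behaviour$subject_id
  comparison <- config$behaviour$comparisonGroup

  ## --- behaviour: consensus profiles on the non-comparison sample ---
  if (st$behaviour) {
    bcfg <- config$behaviour
    learners <- cohort@behaviour[cohort@behaviour$group != comparison, , drop = FALSE]
    net <- buildSubjectNetwork(learners, niCutoff = bcfg$niCutoff)
    cons <- consensusPartition(net, nIter = bcfg$nIter, tau = bcfg$tau,
                               gamma = bcfg$gamma,
                               seed = deriveSeed(seed, "behaviour"))
    comm <- assignments(cons)
    profile <- stats::setNames(rep(comparison, length(ids)), ids)
    profile[names(comm)] <- paste0("P", comm)
    excludedIds <- excludedSubjects(net)$subject_id
    profile[excludedIds] <- NA_character_
    pstats <- profileGroupStats(
      cohort@behaviour[!is.na(profile), , drop = FALSE],
      profile[!is.na(profile)])
    out$behaviour <- list(network = net, consensus = cons, profile = profile,
                          stats = pstats)
    emitTsv(data.frame(subject_id = names(profile), profile = unname(profile)),
            "behaviour_profiles.tsv")
    emitMat(agreementMatrix(cons), "behaviour_agreement.tsv")
    emitTsv(pstats$scaleTests, "behaviour_scale_tests.tsv")
    emitJson(list(Q = qValue(cons), stability = stability(cons),
                  nCommunities = length(unique(comm))), "behaviour_summary.json")
  } else {
    profile <- stats::setNames(cohort@behaviour$group, ids)
  }

  ## --- connectome: QC, correlation, group threshold, ICN features ---
  if (st$connectome) {
    qc <- motionFilter(cohort@fdTrace, fdCut = config$qc$fdCut,
                       spikeCut = config$qc$spikeCut)
    keep <- qc$subject_id[qc$included]
    keep <- keep[!is.na(profile[keep])]
    raw <- lapply(keep, function(id)
      correlationConnectome(cohort@timeseries[[id]], cohort@icnMap, id))
    names(raw) <- keep
    fcFilter <- fcOutlierFilter(raw)
    raw <- raw[fcFilter$included]
    thr <- groupThreshold(raw, cost = config$connectome$cost)
    feats <- icnFeatureMatrix(thr$stack)
    included <- names(thr$stack)
    covTab <- cohort@covariates[match(included, cohort@covariates$subject_id), ]
    covMat <- cbind(age = covTab$age, sex = covTab$sex,
                    motion = covTab$mean_fd,
                    mean_fc = fcFilter$mean_fc[included])
    out$connectome <- list(qc = qc, fcIncluded = fcFilter$included,
                           stack = thr$stack, mask = thr$mask,
                           icnFeatures = feats, included = included,
                           covariates = covMat,
                           groups = unname(profile[included]))
    emitTsv(qc, "qc_motion.tsv")
    emitMat(feats, "icn_features.tsv")
  }

  ## --- graph metrics ---
  if (st$metrics) {
    stack <- out$connectome$stack
    rawGm <- t(vapply(stack, function(cn)
      as.numeric(suppressWarnings(globalMetrics(cn, seed = deriveSeed(seed, cn@subjectId)))),
      numeric(8L)))
    colnames(rawGm) <- c("strength", "modularity", "charpath",
                         "global_efficiency", "local_efficiency", "clustering",
                         "smallworldness", "assortativity")
    rownames(rawGm) <- names(stack)
    normGm <- rawGm
    nN <- config$metrics$nNulls
    if (nN > 0L) {
      for (i in seq_along(stack)) {
        ne <- nullEnsemble(stack[[i]], n = nN,
                           swapsPerEdge = config$metrics$swapsPerEdge,
                           seed = deriveSeed(seed, paste0("nulls", names(stack)[i])))
        nm <- suppressWarnings(normaliseMetrics(rawGm[i, ], ne))
        normGm[i, ] <- nm$normalised
      }
    }
    nodal <- lapply(stack, nodalMetrics)
    out$metrics <- list(raw = rawGm, normalised = normGm, nodal = nodal)
    emitMat(rawGm, "global_metrics_raw.tsv")
    emitMat(normGm, "global_metrics_normalised.tsv")
  }

  ## --- hubs ---
  if (st$hubs) {
    agg <- aggregateNodalMetrics(out$metrics$nodal)
    hubSet <- classifyHubs(agg, pct = config$hubs$pct)
    out$hubs <- list(aggregated = agg, hubSet = hubSet)
    emitTsv(data.frame(
      region_id = c(hubSet$connector, hubSet$provincial),
      type = c(rep("connector", length(hubSet$connector)),
               rep("provincial", length(hubSet$provincial)))), "hubs.tsv")
    emitJson(list(nConnector = length(hubSet$connector),
                  nProvincial = length(hubSet$provincial),
                  pct = hubSet$pct), "hubs_summary.json")
  }

  ## --- PLS ---
  if (st$pls) {
    pc <- config$pls
    feats <- out$connectome$icnFeatures
    grp <- out$connectome$groups
    covMat <- out$connectome$covariates
    kMax <- min(pc$kMax, ncol(feats), length(grp) - 1L)
    cv <- crossValidate(feats, grp, covMat, kMax = kMax, folds = pc$folds,
                        repeats = pc$repeats, seed = deriveSeed(seed, "cv"))
    kStar <- selectComponents(cv$byK)
    perm <- permutationTest(feats, grp, covMat, k = kStar, nPerm = pc$nPerm,
                            folds = pc$folds, repeats = pc$repeats,
                            seed = deriveSeed(seed, "perm"))
    boot <- bootstrapLoadings(feats, grp, covMat, k = kStar, nBoot = pc$nBoot,
                              seed = deriveSeed(seed, "boot"))
    sgt <- scoreGroupTest(boot$alignedScores, grp, nPerm = pc$nPerm,
                          seed = deriveSeed(seed, "sgt"))
    out$pls <- list(cv = cv, kStar = kStar, permutation = perm,
                    bootstrap = boot, scoreTests = sgt)
    emitTsv(cv$byK, "pls_cv.tsv")
    emitTsv(sgt, "pls_score_tests.tsv")
    emitJson(list(kStar = kStar, rmse = perm$observed,
                  accuracy = perm$observedAccuracy, p = perm$p),
             "pls_summary.json")
    emitMat(boot$ratio, "pls_bootstrap_ratio.tsv")
  }

  ## --- ANCOVA stats ---
  if (st$stats) {
    grp <- out$connectome$groups
    covMat <- out$connectome$covariates
    gm <- out$metrics$normalised
    gm[, c("strength", "modularity", "assortativity")] <-
      out$metrics$raw[, c("strength", "modularity", "assortativity")]
    tabs <- lapply(colnames(gm), function(m) {
      a <- ancovaGroup(gm[, m], grp, covMat, pairwise = FALSE)
      data.frame(metric = m, F = a$F, p = a$p, etaP2 = a$etaP2)
    })
    anc <- do.call(rbind, tabs)
    out$stats <- list(ancova = anc)
    emitTsv(anc, "ancova_global_metrics.tsv")
  }

  if (!is.null(odir)) {
    cfgPath <- file.path(odir, "config.json")
    cfgJson <- unclass(config)
    cfgJson$outDir <- NULL
    writeJsonReport(cfgJson, cfgPath)
    manifest <- list(package = "behavconn",
                     version = as.character(utils::packageVersion("behavconn")),
                     seed = seed,
                     configHash = unname(tools::md5sum(cfgPath)),
                     stages = names(which(unlist(st))))
    writeJsonReport(manifest, file.path(odir, "manifest.json"))
    return(invisible(out))
  }
  out
}
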