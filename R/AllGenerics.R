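#' Accessors for behavconn classes
#'
#' `assignments()` returns the community assignment of a [Partition-class] or
#' [ConsensusResult-class]; `qValue()` its modularity; `agreementMatrix()` and
#' `stability()` the consensus diagnostics; `connMatrix()` the weight matrix of
#' a [Connectome-class] or [SubjectNetwork-class]; `icnMap()` the region-to-ICN
#' labelling; `excludedSubjects()` the exclusion log of a
#' [SubjectNetwork-class]; `plsScores()` the component scores of a
#' [PLSModel-class].
#'
#' @param x An object of the documented class.
#' @return The slot value described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))
#' @rdname accessors
#' @export
setGeneric("qValue", function(x) standardGeneric("qValue"))
#' @rdname accessors
#' @export
setGeneric("agreementMatrix", function(x) standardGeneric("agreementMatrix"))
#' @rdname accessors
#' @export
setGeneric("stability", function(x) standardGeneric("stability"))
#' @rdname accessors
#' @export
setGeneric("connMatrix", function(x) standardGeneric("connMatrix"))
#' @rdname accessors
#' @export
setGeneric("icnMap", function(x) standardGeneric("icnMap"))
#' @rdname accessors
#' @export
setGeneric("excludedSubjects", function(x) standardGeneric("excludedSubjects"))
#' @rdname accessors
#' @export
setGeneric("plsScores", function(x) standardGeneric("plsScores"))

#' @rdname accessors
setMethod("assignments", "Partition", function(x) x@assignment)
#' @rdname accessors
setMethod("assignments", "ConsensusResult", function(x) x@partition@assignment)
#' @rdname accessors
setMethod("qValue", "Partition", function(x) x@Q)
#' @rdname accessors
setMethod("qValue", "ConsensusResult", function(x) x@partition@Q)
#' @rdname accessors
setMethod("agreementMatrix", "ConsensusResult", function(x) x@agreement)
#' @rdname accessors
setMethod("stability", "ConsensusResult", function(x) x@stability)
#' @rdname accessors
setMethod("connMatrix", "Connectome", function(x) x@matrix)
#' @rdname accessors
setMethod("connMatrix", "SubjectNetwork", function(x) x@matrix)
#' @rdname accessors
setMethod("icnMap", "Connectome", function(x) x@icnMap)
#' @rdname accessors
setMethod("icnMap", "CohortSpec", function(x) x@icnMap)
#' @rdname accessors
setMethod("icnMap", "SyntheticCohort", function(x) x@icnMap)
#' @rdname accessors
setMethod("excludedSubjects", "SubjectNetwork", function(x) x@excluded)
#' @rdname accessors
setMethod("plsScores", "PLSModel", function(x) x@scores)

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d groups x %d subjects, %d scales, %d regions x %d timepoints\n",
              length(object@groups), object@nPerGroup,
              length(object@scaleNames), object@nRegions, object@nTimepoints))
  cat(sprintf("  groups: %s\n", paste(object@groups, collapse = ", ")))
  cat(sprintf("  behaviour noise sd: %g T-score units; within/between ICN r: %g / %g\n",
              object@behaviourNoiseSd, object@withinCor, object@betweenCor))
  if (length(object@groupEffects))
    for (ge in object@groupEffects)
      cat(sprintf("  planted effect: (%s, %s) delta %+g in %s\n",
                  ge$pair[1], ge$pair[2], ge$delta, paste(ge$groups, collapse = ",")))
  invisible(NULL)
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d subjects (%s)\n", nrow(object@behaviour),
              paste(sprintf("%s=%d", names(table(object@behaviour$group)),
                            as.integer(table(object@behaviour$group))), collapse = ", ")))
  if (length(object@timeseries))
    cat(sprintf("  time series: %d regions x %d timepoints per subject\n",
                nrow(object@timeseries[[1]]), ncol(object@timeseries[[1]])))
  invisible(NULL)
})

setMethod("show", "SubjectNetwork", function(object) {
  cat(sprintf("SubjectNetwork: %d subjects, %d excluded\n",
              nrow(object@matrix), nrow(object@excluded)))
  invisible(NULL)
})

setMethod("show", "Partition", function(object) {
  cat(sprintf("Partition: %d nodes in %d communities, Q = %.4f (gamma = %g)\n",
              length(object@assignment), length(unique(object@assignment)),
              object@Q, object@gamma))
  invisible(NULL)
})

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult over %d iterations (stability %.3f):\n",
              object@nIterations, object@stability))
  show(object@partition)
  invisible(NULL)
})

setMethod("show", "Connectome", function(object) {
  p <- object@provenance
  cat(sprintf("Connectome '%s': %d regions, threshold %s%s%s\n",
              object@subjectId, nrow(object@matrix),
              p$threshold %||% "none",
              if (!is.null(p$cost)) sprintf(" (cost %g)", p$cost) else "",
              if (isTRUE(p$normalised)) ", max-normalised" else ""))
  invisible(NULL)
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d components, %d predictors, %d responses\n",
              object@k, nrow(object@xLoadings), nrow(object@yLoadings)))
  invisible(NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
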