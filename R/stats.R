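## ANCOVA group comparisons of global metrics and permutation AUC tests.

#' ANCOVA of a per-subject metric across groups with covariates
#'
#' Linear model with group dummies plus covariates; the group effect is tested
#' by Type II sums of squares (no interactions in the model). Partial eta
#' squared is `SS_group / (SS_group + SS_error)`. Constant covariate columns
#' are dropped (they are collinear with the intercept); any remaining rank
#' deficiency is an error naming the collinear columns. Significant main
#' effects can be followed up with pairwise ANCOVAs, Bonferroni-corrected.
#'
#' @param metric Numeric per-subject values.
#' @param groups Group label per subject.
#' @param covariates Optional numeric matrix/data.frame of covariates.
#' @param pairwise Run pairwise follow-up ANCOVAs (default TRUE).
#' @return list with `F`, `p`, `etaP2`, `dfEffect`, `dfError`,
#'   `covariateCoefficients`, `groupMeans` (mean and SD per group), and
#'   `pairwise` (data.frame with Bonferroni-corrected p per group pair).
#' @export
ancovaGroup <- function(metric, groups, covariates = NULL, pairwise = TRUE) {
  groups <- as.character(groups)
  stopifnot(length(metric) == length(groups))
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")
  dat <- data.frame(.y = metric, .g = factor(groups))
  covNames <- character()
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- vapply(covariates, function(x) stats::sd(x) > 0, logical(1))
    covariates <- covariates[, keep, drop = FALSE]
    covNames <- names(covariates)
    dat <- cbind(dat, covariates)
  }
  form <- stats::as.formula(paste(".y ~ .g",
                                  if (length(covNames))
                                    paste("+", paste(sprintf("`%s`", covNames),
                                                     collapse = " + ")) else ""))
  fit <- stats::lm(form, data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear columns: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  aov2 <- car::Anova(fit, type = 2)
  gRow <- which(rownames(aov2) == ".g")
  eRow <- which(rownames(aov2) == "Residuals")
  ssG <- aov2[gRow, "Sum Sq"]; ssE <- aov2[eRow, "Sum Sq"]
  res <- list(F = aov2[gRow, "F value"], p = aov2[gRow, "Pr(>F)"],
              etaP2 = ssG / (ssG + ssE),
              dfEffect = aov2[gRow, "Df"], dfError = aov2[eRow, "Df"],
              covariateCoefficients = stats::coef(fit)[covNames],
              groupMeans = data.frame(
                group = sort(unique(groups)),
                mean = tapply(metric, groups, mean)[sort(unique(groups))],
                sd = tapply(metric, groups, sd)[sort(unique(groups))],
                row.names = NULL))
  if (pairwise) {
    lv <- sort(unique(groups))
    prs <- utils::combn(lv, 2L, simplify = FALSE)
    tabs <- lapply(prs, function(pr) {
      sel <- groups %in% pr
      sub <- ancovaGroup(metric[sel], groups[sel],
                         if (!is.null(covariates))
                           covariates[sel, , drop = FALSE],
                         pairwise = FALSE)
      data.frame(group1 = pr[1], group2 = pr[2], F = sub$F, p = sub$p,
                 etaP2 = sub$etaP2)
    })
    pw <- do.call(rbind, tabs)
    pw$pBonferroni <- pmin(1, pw$p * nrow(pw))
    res$pairwise <- pw
  }
  res
}

#' Permutation test on the ANCOVA F of metric AUC over costs
#'
#' Each subject's metric curve over the cost thresholds is reduced to its
#' trapezoid AUC; the group ANCOVA F on the AUC is compared with `nPerm`
#' label permutations (covariate-metric pairing is preserved; only group
#' labels shuffle).
#'
#' @param metricByCost Numeric subject x cost matrix.
#' @param costs Ascending cost values.
#' @param groups Group label per subject.
#' @param covariates Optional covariate matrix.
#' @param nPerm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return list with `observedF`, `null`, `p`, `auc` (per-subject values).
#' @export
permutationFAuc <- function(metricByCost, costs, groups, covariates = NULL,
                            nPerm = 1000L, seed = 1L) {
  metricByCost <- as.matrix(metricByCost)
  stopifnot(ncol(metricByCost) == length(costs))
  auc <- apply(metricByCost, 1L, function(v) trapz(costs, v))
  groups <- as.character(groups)
  fStat <- function(g) {
    if (stats::sd(auc) == 0) return(0)
    ancovaGroup(auc, g, covariates, pairwise = FALSE)$F
  }
  observed <- fStat(groups)
  null <- withSeed(seed, vapply(seq_len(nPerm), function(b)
    fStat(sample(groups)), numeric(1)))
  list(observedF = observed, null = null,
       p = (1 + sum(null >= observed)) / (1 + nPerm), auc = auc, seed = seed)
}
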