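## PLS2 regression of one-hot group membership on connectivity features, with
## repeated stratified cross-validation, one-standard-error model selection,
## permutation significance, Procrustes-aligned bootstrap loadings, and
## component-score group tests.

## ---- preprocessing -------------------------------------------------------

## Fit covariate-residualisation + standardisation parameters on (training)
## rows. covarMat may be NULL.
fitPreproc <- function(X, covarMat = NULL) {
  coefs <- NULL
  if (!is.null(covarMat)) {
    C1 <- cbind(1, covarMat)
    coefs <- qr.solve(C1, X)
    X <- X - C1 %*% coefs
  }
  n <- nrow(X)
  ctr <- colMeans(X)
  scl <- sqrt(pmax(colSums(X^2) - n * ctr^2, 0) / (n - 1L))
  scl[scl == 0] <- 1
  list(coefs = coefs, center = ctr, scale = scl)
}

applyPreproc <- function(X, covarMat, pp) {
  if (!is.null(pp$coefs)) X <- X - cbind(1, covarMat) %*% pp$coefs
  X <- sweep(X, 2L, pp$center)
  sweep(X, 2L, pp$scale, "/")
}

#' Build PLS design matrices
#'
#' One-hot encodes group membership (one column per group level), optionally
#' residualises the feature matrix on covariates, and standardises each
#' feature to mean 0 / SD 1. The preprocessing record (covariate coefficients,
#' centres, scales) is estimated on the supplied subjects and stored so it can
#' be re-applied to held-out data without leakage.
#'
#' @param features Numeric matrix, subject x feature.
#' @param groups Group label per subject.
#' @param covariates Optional numeric matrix/data.frame of per-subject
#'   covariates (e.g. age, sex, motion, mean functional connectivity).
#' @param levels Group level order (defaults to sorted unique labels);
#'   determines the one-hot column order and argmax tie-breaking.
#' @return list with `X` (processed features), `Y` (one-hot matrix), `groups`,
#'   `levels`, `covariates`, `preproc`.
#' @export
buildDesign <- function(features, groups, covariates = NULL, levels = NULL) {
  features <- as.matrix(features)
  if (anyNA(features)) stop("features must be complete cases")
  levels <- levels %||% sort(unique(as.character(groups)))
  covarMat <- if (!is.null(covariates)) as.matrix(covariates) else NULL
  pp <- fitPreproc(features, covarMat)
  X <- applyPreproc(features, covarMat, pp)
  Y <- oneHot(groups, levels)
  list(X = X, Y = Y, groups = as.character(groups), levels = levels,
       covariates = covarMat, preproc = pp)
}

oneHot <- function(groups, levels) {
  g <- factor(as.character(groups), levels = levels)
  if (anyNA(g)) stop("group label outside the declared levels")
  Y <- matrix(0, length(g), length(levels),
              dimnames = list(NULL, levels))
  Y[cbind(seq_along(g), as.integer(g))] <- 1
  Y
}

## ---- NIPALS PLS2 ---------------------------------------------------------

#' Fit a PLS2 regression by NIPALS
#'
#' Multi-response partial least squares with NIPALS iteration and deflation.
#' Deterministic given the input (the initial Y-score is the response column
#' with the largest sum of squares).
#'
#' @param X Numeric predictor matrix (n x p), already standardised as desired.
#' @param Y Numeric response matrix (n x q), e.g. one-hot group membership.
#' @param k Number of components; must not exceed the rank of the centred X.
#' @param tol,maxIter NIPALS convergence controls.
#' @return A [PLSModel-class].
#' @export
fitPLS <- function(X, Y, k, tol = 1e-10, maxIter = 500L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  stopifnot(nrow(Y) == n, k >= 1L)
  if (k > min(n - 1L, p))
    stop(sprintf("k = %d exceeds the rank of the centred predictor matrix", k))
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2L, xm); Yc <- sweep(Y, 2L, ym)
  W <- matrix(0, p, k); P <- matrix(0, p, k)
  Qm <- matrix(0, q, k); Tm <- matrix(0, n, k)
  for (a in seq_len(k)) {
    u <- Yc[, which.max(colSums(Yc^2))]
    tOld <- rep(Inf, n)
    for (it in seq_len(maxIter)) {
      w <- crossprod(Xc, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12)
        stop(sprintf("k = %d exceeds the rank of the centred predictor matrix", a))
      w <- w / nw
      tt <- Xc %*% w
      qv <- crossprod(Yc, tt) / sum(tt^2)
      u <- Yc %*% qv / sum(qv^2)
      if (sum((tt - tOld)^2) < tol * sum(tt^2)) break
      tOld <- tt
    }
    ss <- sum(tt^2)
    if (ss < 1e-12)
      stop(sprintf("k = %d exceeds the rank of the centred predictor matrix", a))
    pv <- crossprod(Xc, tt) / ss
    Xc <- Xc - tt %*% t(pv)
    Yc <- Yc - tt %*% t(qv)
    W[, a] <- w; P[, a] <- pv; Qm[, a] <- qv; Tm[, a] <- tt
  }
  B <- W %*% solve(crossprod(P, W), t(Qm))
  dimnames(B) <- list(colnames(X), colnames(Y))
  methods::new("PLSModel", xMeans = xm, yMeans = ym, weights = W,
               xLoadings = P, yLoadings = Qm, scores = Tm, coef = B,
               k = as.integer(k))
}

#' Predict from a PLS model
#'
#' @param object A [PLSModel-class].
#' @param newdata Predictor matrix on the scale used at fit time.
#' @param k Number of components to use (default: all fitted).
#' @param ... Ignored.
#' @return Fitted response matrix.
#' @export
predictPLS <- function(object, newdata, k = object@k, ...) {
  stopifnot(k >= 1L, k <= object@k)
  B <- if (k == object@k) object@coef else {
    W <- object@weights[, seq_len(k), drop = FALSE]
    P <- object@xLoadings[, seq_len(k), drop = FALSE]
    Qm <- object@yLoadings[, seq_len(k), drop = FALSE]
    W %*% solve(crossprod(P, W), t(Qm))
  }
  sweep(as.matrix(newdata), 2L, object@xMeans) %*% B +
    matrix(object@yMeans, nrow(newdata), length(object@yMeans), byrow = TRUE)
}

## ---- cross-validation ----------------------------------------------------

casewiseRmse <- function(Y, Yhat) sqrt(rowMeans((Y - Yhat)^2))

makeStratifiedFolds <- function(groups, folds) {
  fold <- integer(length(groups))
  for (g in unique(groups)) {
    idx <- sample(which(groups == g))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

## Core CV engine: per fold x repeat, refit preprocessing and PLS on the
## training rows only and evaluate held-out casewise RMSE and accuracy for
## every k in 1..kMax (components are nested, so one kMax fit per fold).
cvEngine <- function(features, groups, covariates, kMax, folds, repeats, seed,
                     levels) {
  groups <- as.character(groups)
  covarMat <- if (!is.null(covariates)) as.matrix(covariates) else NULL
  nEst <- folds * repeats
  rmse <- matrix(NA_real_, nEst, kMax)
  acc <- matrix(NA_real_, nEst, kMax)
  withSeed(seed, {
    row <- 0L
    for (r in seq_len(repeats)) {
      fold <- makeStratifiedFolds(groups, folds)
      for (f in seq_len(folds)) {
        row <- row + 1L
        te <- fold == f
        tr <- !te
        if (length(unique(groups[tr])) < length(levels))
          stop("a training fold does not span all groups; increase group sizes")
        pp <- fitPreproc(features[tr, , drop = FALSE],
                         if (!is.null(covarMat)) covarMat[tr, , drop = FALSE])
        Xtr <- applyPreproc(features[tr, , drop = FALSE],
                            if (!is.null(covarMat)) covarMat[tr, , drop = FALSE], pp)
        Xte <- applyPreproc(features[te, , drop = FALSE],
                            if (!is.null(covarMat)) covarMat[te, , drop = FALSE], pp)
        Ytr <- oneHot(groups[tr], levels)
        Yte <- oneHot(groups[te], levels)
        fit <- fitPLS(Xtr, Ytr, kMax)
        trueIdx <- max.col(Yte, ties.method = "first")
        for (k in seq_len(kMax)) {
          Yhat <- predictPLS(fit, Xte, k = k)
          rmse[row, k] <- mean(casewiseRmse(Yte, Yhat))
          pred <- max.col(Yhat, ties.method = "first")
          acc[row, k] <- mean(pred == trueIdx)
        }
      }
    }
  })
  list(rmse = rmse, acc = acc)
}

#' Repeated stratified cross-validation of the PLS model
#'
#' Stratified k-fold cross-validation repeated with fresh random splits.
#' Preprocessing (covariate residualisation and standardisation) is refit
#' inside every training fold. Prediction error is the casewise RMSE (per
#' held-out subject, the root mean square error across one-hot response
#' columns) averaged over held-out subjects; accuracy is the fraction whose
#' predicted-score argmax matches the true group (ties to the lowest group
#' index).
#'
#' @param features Numeric subject x feature matrix (raw, unstandardised).
#' @param groups Group label per subject.
#' @param covariates Optional covariate matrix.
#' @param kMax Largest number of components to evaluate.
#' @param folds,repeats CV geometry (defaults 5 x 10).
#' @param seed Integer seed for the splits.
#' @param levels Optional group level order.
#' @return list with `byK` (data.frame: k, rmse, sem, accuracy, accuracySem),
#'   `folds`, `repeats`, and the per-fold estimate matrices.
#' @export
crossValidate <- function(features, groups, covariates = NULL, kMax,
                          folds = 5L, repeats = 10L, seed = 1L,
                          levels = NULL) {
  levels <- levels %||% sort(unique(as.character(groups)))
  eng <- cvEngine(features, groups, covariates, kMax, folds, repeats, seed,
                  levels)
  nEst <- nrow(eng$rmse)
  byK <- data.frame(
    k = seq_len(kMax),
    rmse = colMeans(eng$rmse),
    sem = apply(eng$rmse, 2L, stats::sd) / sqrt(nEst),
    accuracy = colMeans(eng$acc),
    accuracySem = apply(eng$acc, 2L, stats::sd) / sqrt(nEst))
  list(byK = byK, folds = folds, repeats = repeats,
       rmseByFold = eng$rmse, accByFold = eng$acc)
}

#' One-standard-error component selection
#'
#' The selected model is the simplest (smallest k) whose mean cross-validated
#' RMSE is within one standard error of the lowest mean RMSE.
#'
#' @param cvByK data.frame with columns k, rmse, sem (as from
#'   [crossValidate()]'s `byK`).
#' @return The selected k.
#' @export
selectComponents <- function(cvByK) {
  stopifnot(nrow(cvByK) >= 1L)
  best <- which.min(cvByK$rmse)
  cut <- cvByK$rmse[best] + cvByK$sem[best]
  cvByK$k[which(cvByK$rmse <= cut)[1L]]
}

## ---- permutation inference -----------------------------------------------

#' Permutation test of the cross-validated PLS fit
#'
#' Re-runs the full cross-validation pipeline (including fold-wise
#' preprocessing) on group labels randomly shuffled `nPerm` times and compares
#' the observed mean CV RMSE against the null distribution. Smaller RMSE is
#' better, so `p = (1 + #\{null <= observed\}) / (1 + nPerm)`.
#'
#' @inheritParams crossValidate
#' @param k Number of components (fixed at the observed selection).
#' @param nPerm Number of permutations (default 1000).
#' @return list with `observed`, `null` (numeric nPerm), `p`,
#'   `observedAccuracy`, `seed`.
#' @export
permutationTest <- function(features, groups, covariates = NULL, k,
                            nPerm = 1000L, folds = 5L, repeats = 10L,
                            seed = 1L, levels = NULL) {
  levels <- levels %||% sort(unique(as.character(groups)))
  obs <- crossValidate(features, groups, covariates, kMax = k, folds = folds,
                       repeats = repeats, seed = deriveSeed(seed, "obs"),
                       levels = levels)
  observed <- obs$byK$rmse[k]
  groups <- as.character(groups)
  null <- withSeed(deriveSeed(seed, "perm"), {
    vapply(seq_len(nPerm), function(b) {
      gPerm <- sample(groups)
      cvEngineMean(features, gPerm, covariates, k, folds, repeats, levels)
    }, numeric(1))
  })
  list(observed = observed, null = null,
       p = (1 + sum(null <= observed)) / (1 + nPerm),
       observedAccuracy = obs$byK$accuracy[k], seed = seed)
}

## Mean CV RMSE at exactly k components, using the active RNG stream for the
## splits (lean path for permutation loops).
cvEngineMean <- function(features, groups, covariates, k, folds, repeats,
                         levels) {
  covarMat <- if (!is.null(covariates)) as.matrix(covariates) else NULL
  tot <- 0; cnt <- 0L
  for (r in seq_len(repeats)) {
    fold <- makeStratifiedFolds(groups, folds)
    for (f in seq_len(folds)) {
      te <- fold == f
      tr <- !te
      pp <- fitPreproc(features[tr, , drop = FALSE],
                       if (!is.null(covarMat)) covarMat[tr, , drop = FALSE])
      Xtr <- applyPreproc(features[tr, , drop = FALSE],
                          if (!is.null(covarMat)) covarMat[tr, , drop = FALSE], pp)
      Xte <- applyPreproc(features[te, , drop = FALSE],
                          if (!is.null(covarMat)) covarMat[te, , drop = FALSE], pp)
      fit <- fitPLS(Xtr, oneHot(groups[tr], levels), k)
      Yhat <- predictPLS(fit, Xte)
      tot <- tot + mean(casewiseRmse(oneHot(groups[te], levels), Yhat))
      cnt <- cnt + 1L
    }
  }
  tot / cnt
}

#' Permutation test of the RMSE area under the cost curve
#'
#' The statistic is the trapezoid AUC of the cross-validated RMSE over the
#' cost thresholds; the same label-shuffling machinery as [permutationTest()]
#' applies.
#'
#' @param featuresByCost Named list of subject x feature matrices, one per
#'   cost, ascending cost order.
#' @param costs Numeric cost values matching `featuresByCost`.
#' @inheritParams permutationTest
#' @return list with `observed` (AUC), `null`, `p`, `perCost` observed RMSEs.
#' @export
permutationTestAuc <- function(featuresByCost, costs, groups,
                               covariates = NULL, k, nPerm = 1000L,
                               folds = 5L, repeats = 10L, seed = 1L,
                               levels = NULL) {
  stopifnot(length(featuresByCost) == length(costs), length(costs) >= 2L)
  levels <- levels %||% sort(unique(as.character(groups)))
  groups <- as.character(groups)
  statAuc <- function(g, sd0) {
    r <- vapply(seq_along(costs), function(i)
      withSeed(deriveSeed(sd0, paste0("cost", i)),
               cvEngineMean(featuresByCost[[i]], g, covariates, k, folds,
                            repeats, levels)),
      numeric(1))
    list(auc = trapz(costs, r), perCost = r)
  }
  obs <- statAuc(groups, deriveSeed(seed, "obs"))
  null <- withSeed(deriveSeed(seed, "perm"), {
    vapply(seq_len(nPerm), function(b) {
      gPerm <- sample(groups)
      statAuc(gPerm, deriveSeed(seed, paste0("b", b)))$auc
    }, numeric(1))
  })
  list(observed = obs$auc, null = null,
       p = (1 + sum(null <= obs$auc)) / (1 + nPerm),
       perCost = obs$perCost, seed = seed)
}

## ---- bootstrap loadings ---------------------------------------------------

#' Orthogonal Procrustes rotation
#'
#' The orthogonal matrix (reflections allowed) that best maps `L` onto `ref`
#' in least squares: the SVD solution of the cross-product.
#'
#' @param L,ref Matrices of identical dimension (features x components).
#' @return Orthogonal rotation matrix R minimising `||L R - ref||_F`.
#' @export
procrustesRotation <- function(L, ref) {
  sv <- svd(crossprod(L, ref))
  sv$u %*% t(sv$v)
}

#' Bootstrap stability of PLS loadings with Procrustes alignment
#'
#' Refits the PLS model on `nBoot` resamples of the subjects (with
#' replacement, preprocessing refit per resample), aligns each resample's
#' X-loading matrix to the full-sample reference by an orthogonal Procrustes
#' rotation (repairing sign and order indeterminacy), and summarises each
#' loading by its mean, bootstrap standard error, and their ratio.
#'
#' @inheritParams crossValidate
#' @param k Number of components.
#' @param nBoot Number of bootstrap resamples (default 1000).
#' @return list with `reference` ([PLSModel-class] on the full sample),
#'   `mean`, `sem`, `ratio` (feature x component matrices; ratio is NA where
#'   SEM is 0, flagged in `degenerate`), and `alignedScores` (subject x
#'   component mean bootstrap scores on the full sample).
#' @export
bootstrapLoadings <- function(features, groups, covariates = NULL, k,
                              nBoot = 1000L, seed = 1L, levels = NULL) {
  levels <- levels %||% sort(unique(as.character(groups)))
  d <- buildDesign(features, groups, covariates, levels)
  reference <- fitPLS(d$X, d$Y, k)
  p <- ncol(d$X); n <- nrow(d$X)
  sumL <- matrix(0, p, k); sumL2 <- matrix(0, p, k)
  sumS <- matrix(0, n, k)
  groups <- as.character(groups)
  covarMat <- if (!is.null(covariates)) as.matrix(covariates) else NULL
  withSeed(deriveSeed(seed, "boot"), {
    for (b in seq_len(nBoot)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(groups[idx])) < 2L) { idx <- seq_len(n) }
      pp <- fitPreproc(features[idx, , drop = FALSE],
                       if (!is.null(covarMat)) covarMat[idx, , drop = FALSE])
      Xb <- applyPreproc(features[idx, , drop = FALSE],
                         if (!is.null(covarMat)) covarMat[idx, , drop = FALSE], pp)
      fb <- fitPLS(Xb, oneHot(groups[idx], levels), k)
      R <- procrustesRotation(fb@xLoadings, reference@xLoadings)
      Lb <- fb@xLoadings %*% R
      sumL <- sumL + Lb
      sumL2 <- sumL2 + Lb^2
      ## re-computed component scores for the full sample under this resample
      Xfull <- applyPreproc(features,
                            covarMat, pp)
      Sb <- sweep(Xfull, 2L, fb@xMeans) %*% fb@weights %*%
        solve(crossprod(fb@xLoadings, fb@weights)) %*% R
      sumS <- sumS + Sb
    }
  })
  mL <- sumL / nBoot
  v <- pmax(sumL2 / nBoot - mL^2, 0) * nBoot / max(nBoot - 1L, 1L)
  semL <- sqrt(v)
  ratio <- mL / semL
  ratio[semL == 0] <- NA_real_
  dimnames(mL) <- dimnames(semL) <- dimnames(ratio) <-
    list(colnames(d$X), paste0("PLS", seq_len(k)))
  list(reference = reference, mean = mL, sem = semL, ratio = ratio,
       degenerate = which(semL == 0, arr.ind = TRUE),
       alignedScores = sumS / nBoot, nBoot = nBoot, seed = seed)
}

#' Flag the top fraction of loadings by bootstrap ratio
#'
#' @param bl A [bootstrapLoadings()] result.
#' @param fraction Fraction of features to flag per component (e.g. 0.25).
#' @return Logical feature x component matrix.
#' @export
topLoadings <- function(bl, fraction = 0.25) {
  apply(abs(bl$ratio), 2L, function(r) {
    cut <- stats::quantile(r, 1 - fraction, na.rm = TRUE, type = 7)
    out <- r > cut
    out[is.na(out)] <- FALSE
    out
  })
}

#' Permutation tests of group differences in component scores
#'
#' For every component and unordered group pair, the statistic is the
#' difference in group means of the component scores; the two-sided p-value
#' compares it with `nPerm` label permutations.
#'
#' @param scores Subject x component score matrix (e.g. reference model scores
#'   or mean aligned bootstrap scores).
#' @param groups Group label per subject.
#' @param nPerm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return data.frame: component, group1, group2, diff, p.
#' @export
scoreGroupTest <- function(scores, groups, nPerm = 1000L, seed = 1L) {
  scores <- as.matrix(scores)
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  rows <- list()
  for (comp in seq_len(ncol(scores))) {
    s <- scores[, comp]
    for (pr in pairs) {
      obs <- mean(s[groups == pr[1]]) - mean(s[groups == pr[2]])
      null <- withSeed(deriveSeed(seed, sprintf("sgt%d_%s_%s", comp, pr[1], pr[2])), {
        vapply(seq_len(nPerm), function(b) {
          gp <- sample(groups)
          mean(s[gp == pr[1]]) - mean(s[gp == pr[2]])
        }, numeric(1))
      })
      rows[[length(rows) + 1L]] <- data.frame(
        component = comp, group1 = pr[1], group2 = pr[2], diff = obs,
        p = (1 + sum(abs(null) >= abs(obs))) / (1 + nPerm))
    }
  }
  do.call(rbind, rows)
}
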