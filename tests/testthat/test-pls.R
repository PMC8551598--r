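test_that("design matrices are one-hot, residualised and standardised", {
  set.seed(1)
  X <- matrix(rnorm(40 * 8), 40)
  g <- rep(c("comparison", "C1", "C2", "C3"), 10)
  covars <- cbind(age = runif(40, 5, 15), sex = rbinom(40, 1, 0.5))
  d <- buildDesign(X, g, covars)
  expect_equal(ncol(d$Y), 4L)
  expect_true(all(rowSums(d$Y) == 1))
  ## residualised columns orthogonal to each covariate
  Xr <- sweep(d$X, 2L, d$preproc$scale, "*")  # undo scaling, keep residuals
  for (j in seq_len(ncol(covars)))
    expect_lt(max(abs(crossprod(scale(covars[, j], scale = FALSE), Xr))), 1e-8)
  expect_lt(max(abs(colMeans(d$X))), 1e-12)
  expect_equal(unname(apply(d$X, 2, sd)), rep(1, 8))
})

test_that("NIPALS PLS matches its oracles", {
  set.seed(2)
  X <- matrix(rnorm(30 * 10), 30)
  ## single response carried by one predictor whose centred column is
  ## orthogonal to all others: one component fits the training data exactly
  y <- scale(rnorm(30), scale = FALSE)
  E <- scale(matrix(rnorm(30 * 9), 30), scale = FALSE)
  E <- E - y %*% crossprod(y, E) / sum(y^2)
  Xo <- cbind(drop(y), E)
  f1 <- fitPLS(Xo, y, k = 1)
  expect_lt(max(abs(predictPLS(f1, Xo) - y)), 1e-8)
  ## full rank equals multivariate least squares
  Y <- matrix(rnorm(30 * 3), 30)
  f <- fitPLS(X, Y, k = 10)
  ols <- cbind(1, X) %*% qr.solve(cbind(1, X), Y)
  expect_lt(max(abs(predictPLS(f, X) - ols)), 1e-6)
  ## score orthogonality
  G <- crossprod(f@scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  ## k beyond rank errors
  Xdef <- cbind(X[, 1:3], X[, 1:3])
  expect_error(fitPLS(Xdef, Y, k = 5), "rank")
})

test_that("casewise RMSE of the constant 1/4 predictor is sqrt(0.1875)", {
  Y <- behavconn:::oneHot(rep(c("a", "b", "c", "d"), 5), c("a", "b", "c", "d"))
  Yhat <- matrix(0.25, 20, 4)
  expect_equal(unique(behavconn:::casewiseRmse(Y, Yhat)), sqrt(0.1875))
})

test_that("held-out subjects never influence training-fold preprocessing", {
  set.seed(3)
  X <- matrix(rnorm(40 * 6), 40)
  covars <- cbind(age = runif(40), fd = runif(40))
  tr <- 1:30; te <- 31:40
  pp1 <- behavconn:::fitPreproc(X[tr, ], covars[tr, ])
  ## move one held-out subject's features and covariates
  X2 <- X; X2[31, ] <- X2[31, ] + 100
  cv2 <- covars; cv2[31, ] <- cv2[31, ] + 100
  pp2 <- behavconn:::fitPreproc(X2[tr, ], cv2[tr, ])
  expect_identical(pp1, pp2)
  ## and the other held-out subjects' processed features are unchanged
  a1 <- behavconn:::applyPreproc(X[te, ], covars[te, ], pp1)
  a2 <- behavconn:::applyPreproc(X2[te, ], cv2[te, ], pp2)
  expect_equal(a1[-1, ], a2[-1, ])
  expect_false(isTRUE(all.equal(a1[1, ], a2[1, ])))
})

test_that("stratified folds span all groups", {
  g <- rep(c("a", "b", "c", "d"), each = 10)
  fold <- behavconn:::withSeed(1, behavconn:::makeStratifiedFolds(g, 5))
  for (f in 1:5) expect_setequal(unique(g[fold != f]), c("a", "b", "c", "d"))
})

test_that("a separable planted signal is learned almost perfectly", {
  set.seed(4)
  g <- rep(c("a", "b", "c", "d"), 15)
  Y <- behavconn:::oneHot(g, c("a", "b", "c", "d"))
  X <- cbind(Y %*% matrix(rnorm(4 * 6, sd = 3), 4), matrix(rnorm(60 * 4), 60)) +
    matrix(rnorm(60 * 10, sd = 0.05), 60)
  cv <- crossValidate(X, g, NULL, kMax = 3, folds = 5, repeats = 2, seed = 5)
  expect_gt(max(cv$byK$accuracy), 0.95)
  expect_lt(min(cv$byK$rmse), 0.2)
})

test_that("accuracy is at chance for features independent of groups", {
  set.seed(6)
  accs <- vapply(1:15, function(i) {
    X <- matrix(rnorm(40 * 5), 40)
    g <- rep(c("a", "b", "c", "d"), 10)
    crossValidate(X, g, NULL, kMax = 1, folds = 5, repeats = 1,
                  seed = i)$byK$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), 0.08)
})

test_that("the one-standard-error rule picks the simplest adequate model", {
  cv <- data.frame(k = 1:3, rmse = c(0.50, 0.466, 0.465),
                   sem = c(0.03, 0.025, 0.02))
  ## cut = 0.465 + 0.02 = 0.485; k=1 is above, k=2 below
  expect_equal(selectComponents(cv), 2L)
  flat <- data.frame(k = 1:4, rmse = rep(0.4, 4), sem = rep(0.01, 4))
  expect_equal(selectComponents(flat), 1L)
  steep <- data.frame(k = 1:4, rmse = c(0.9, 0.6, 0.3, 0.1),
                      sem = rep(1e-6, 4))
  expect_equal(selectComponents(steep), 4L)
})

test_that("permutation p hits the extreme bound for a strong signal", {
  set.seed(7)
  g <- rep(c("a", "b", "c", "d"), 10)
  Y <- behavconn:::oneHot(g, c("a", "b", "c", "d"))
  X <- Y %*% matrix(rnorm(4 * 8, sd = 3), 4) + matrix(rnorm(40 * 8, sd = 0.05), 40)
  pt <- permutationTest(X, g, NULL, k = 2, nPerm = 49, folds = 5, repeats = 1,
                        seed = 8)
  expect_equal(pt$p, 1 / 50)
  expect_true(all(pt$null > pt$observed))
})

test_that("Procrustes alignment repairs sign and order indeterminacy", {
  set.seed(9)
  L <- matrix(rnorm(12 * 3), 12)
  expect_lt(max(abs(procrustesRotation(L, L) - diag(3))), 1e-12)
  ## sign flip + component swap
  P <- diag(3)[, c(2, 1, 3)] %*% diag(c(-1, 1, 1))
  Lp <- L %*% P
  R <- procrustesRotation(Lp, L)
  expect_lt(max(abs(Lp %*% R - L)), 1e-10)
  ## grid-search oracle on a 2-component problem (rotations + reflections)
  L2 <- matrix(rnorm(8 * 2), 8)
  ref2 <- matrix(rnorm(8 * 2), 8)
  Rsvd <- procrustesRotation(L2, ref2)
  objective <- function(R) sum((L2 %*% R - ref2)^2)
  best <- Inf
  for (th in seq(0, 2 * pi, length.out = 10000)) {
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    refl <- rot %*% diag(c(1, -1))
    best <- min(best, objective(rot), objective(refl))
  }
  expect_lte(objective(Rsvd), best + 1e-6)
})

test_that("noiseless perturbed resamples align back with zero spread", {
  set.seed(10)
  L <- matrix(rnorm(10 * 2), 10)
  copies <- lapply(1:20, function(i) {
    flip <- diag(sample(c(-1, 1), 2, replace = TRUE))
    perm <- diag(2)[, sample(2)]
    L %*% (perm %*% flip)
  })
  aligned <- lapply(copies, function(Lb) Lb %*% procrustesRotation(Lb, L))
  stacked <- simplify2array(aligned)
  expect_lt(max(apply(stacked, c(1, 2), sd)), 1e-12)
})

test_that("bootstrap ratios rank contributing features above noise features", {
  set.seed(11)
  g <- rep(c("a", "b", "c", "d"), 15)
  Y <- behavconn:::oneHot(g, c("a", "b", "c", "d"))
  signal <- Y %*% matrix(rnorm(4 * 3, sd = 2), 4)
  X <- cbind(signal + matrix(rnorm(60 * 3, sd = 0.3), 60),
             matrix(rnorm(60 * 5), 60))
  colnames(X) <- c(paste0("sig", 1:3), paste0("noise", 1:5))
  bl <- bootstrapLoadings(X, g, NULL, k = 2, nBoot = 100, seed = 12)
  r <- abs(bl$ratio[, 1])
  expect_gt(median(r[1:3]), median(r[4:8]))
  expect_equal(dim(bl$mean), c(8L, 2L))
  tl <- topLoadings(bl, 0.25)
  expect_equal(colSums(tl), c(PLS1 = 2, PLS2 = 2))
})

test_that("component-score group tests are antisymmetric and detect shifts", {
  set.seed(13)
  g <- rep(c("a", "b"), each = 20)
  s <- matrix(rnorm(40), 40, 1)
  s[g == "a", 1] <- s[g == "a", 1] + 3   # 3 SD shift
  sgt <- scoreGroupTest(s, g, nPerm = 99, seed = 14)
  expect_equal(sgt$p, 1 / 100)
  gSwap <- ifelse(g == "a", "b", "a")
  sgt2 <- scoreGroupTest(s, gSwap, nPerm = 99, seed = 14)
  expect_equal(sgt2$diff, -sgt$diff)
})
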