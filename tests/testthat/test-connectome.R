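icn24 <- defaultIcnMap(24)

randTs <- function(nRegions, nT, icn = NULL) {
  ts <- matrix(rnorm(nRegions * nT), nRegions)
  rownames(ts) <- names(icn %||% defaultIcnMap(nRegions))
  ts
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("correlation connectome matches a hand-rolled two-pass oracle", {
  set.seed(1)
  ts <- randTs(10, 50, defaultIcnMap(10))
  cn <- correlationConnectome(ts, defaultIcnMap(10), "s1")
  m <- connMatrix(cn)
  oracle <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    if (i == j) next
    x <- ts[i, ]; y <- ts[j, ]
    oracle[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_lt(max(abs(m - oracle)), 1e-12)
  ## duplicated region rows correlate perfectly
  ts2 <- ts; ts2[2, ] <- ts2[1, ]
  m2 <- connMatrix(correlationConnectome(ts2, defaultIcnMap(10), "s2"))
  expect_equal(m2[1, 2], 1.0)
  ## orthogonal sine/cosine over a full period
  tt <- seq(0, 2 * pi, length.out = 41)[-41]
  ts3 <- ts; ts3[1, 1:40] <- sin(tt); ts3[2, 1:40] <- cos(tt)
  ts3 <- ts3[, 1:40]
  m3 <- connMatrix(correlationConnectome(ts3, defaultIcnMap(10), "s3"))
  expect_lt(abs(m3[1, 2]), 1e-8)
  ## constant rows are an error naming the region
  ts4 <- ts; ts4[3, ] <- 2
  expect_error(correlationConnectome(ts4, defaultIcnMap(10)), rownames(ts)[3])
})

test_that("motion filter applies the two-stage exclusion rule", {
  traces <- list(
    highMean = rep(0.6, 100),
    spiky = c(rep(0.2, 74), rep(0.9, 26)),          # mean 0.38, 26% spikes
    clean = c(rep(0.2, 95), rep(0.7, 5)))           # mean ~0.23, 5% spikes
  qc <- motionFilter(traces)
  expect_equal(qc$included, c(FALSE, FALSE, TRUE))
  expect_equal(qc$reason, c("mean FD", "spikes", ""))
  expect_equal(qc$spike_fraction[2], 0.26)
})

test_that("group threshold keeps the strongest mean edges for every subject", {
  set.seed(2)
  base <- matrix(0, 10, 10)
  base[upper.tri(base)] <- runif(45, 0.1, 1)
  base <- base + t(base)
  rownames(base) <- colnames(base) <- names(defaultIcnMap(10))
  mk <- function(m, id) new("Connectome", matrix = m,
                            regionIds = rownames(m), icnMap = defaultIcnMap(10),
                            subjectId = id,
                            provenance = list(threshold = "none", cost = NA_real_,
                                              normalised = FALSE))
  stack <- lapply(1:4, function(i) mk(base, paste0("s", i)))
  thr <- groupThreshold(stack, cost = 0.25)
  nKeep <- floor(0.25 * 45)
  up <- upper.tri(base)
  expect_equal(sum(thr$mask[up]), nKeep)
  cutoff <- sort(base[up], decreasing = TRUE)[nKeep]
  expect_true(all(base[thr$mask & up] >= cutoff))
  for (cn in thr$stack)
    expect_equal(connMatrix(cn) > 0, thr$mask)
  ## a negative individual weight surviving the mask becomes 0.001
  strongest <- which(base == max(base), arr.ind = TRUE)[1, ]
  base2 <- base
  base2[strongest[1], strongest[2]] <- base2[strongest[2], strongest[1]] <- 5
  stack2 <- lapply(1:4, function(i) mk(base2, paste0("s", i)))
  m2 <- base2
  m2[strongest[1], strongest[2]] <- m2[strongest[2], strongest[1]] <- -0.2
  thr2 <- groupThreshold(c(stack2, list(mk(m2, "s5"))), cost = 0.25)
  expect_true(thr2$mask[strongest[1], strongest[2]])  # group mean keeps it
  expect_equal(connMatrix(thr2$stack[[5]])[strongest[1], strongest[2]], 0.001)
})

test_that("masks are nested across costs and thresholding is idempotent", {
  set.seed(3)
  stack <- lapply(1:3, function(i) {
    ts <- randTs(20, 60)
    correlationConnectome(ts, defaultIcnMap(20), paste0("s", i))
  })
  masks <- lapply(c(0.05, 0.15, 0.30), function(cost)
    groupThreshold(stack, cost)$mask)
  expect_true(all(!(masks[[1]] & !masks[[2]])))
  expect_true(all(!(masks[[2]] & !masks[[3]])))
  ## idempotence at equal cost
  thr <- groupThreshold(stack, 0.25)
  thr2 <- groupThreshold(thr$stack, 0.25)
  for (i in seq_along(stack))
    expect_equal(connMatrix(thr2$stack[[i]]), connMatrix(thr$stack[[i]]))
  ## density monotone in cost
  dens <- vapply(c(0.05, 0.15, 0.30), function(cost) {
    m <- connMatrix(groupThreshold(stack, cost)$stack[[1]])
    mean(m[upper.tri(m)] > 0)
  }, numeric(1))
  expect_true(all(diff(dens) > 0))
})

test_that("infeasible cost (too few positive edges) is an error", {
  m <- matrix(-0.5, 8, 8); diag(m) <- 0
  m[1, 2] <- m[2, 1] <- 0.5
  rownames(m) <- colnames(m) <- names(defaultIcnMap(8))
  cn <- new("Connectome", matrix = m, regionIds = rownames(m),
            icnMap = defaultIcnMap(8), subjectId = "s",
            provenance = list(threshold = "none", cost = NA_real_,
                              normalised = FALSE))
  expect_error(groupThreshold(list(cn), cost = 0.5), "positive edges")
})

test_that("individual threshold and max-normalisation behave as specified", {
  set.seed(4)
  cn <- correlationConnectome(randTs(20, 60), defaultIcnMap(20), "s1")
  thr <- individualThreshold(cn, 0.25)
  E <- 20 * 19 / 2
  m <- connMatrix(thr)
  expect_equal(sum(m[upper.tri(m)] > 0), floor(0.25 * E))
  nrm <- normaliseToMax(thr)
  expect_equal(max(connMatrix(nrm)), 1.0)
  ## scale invariance: doubling weights before normalisation changes nothing
  doubled <- methods::initialize(thr, matrix = connMatrix(thr) * 2)
  expect_equal(connMatrix(normaliseToMax(doubled)), connMatrix(nrm))
})

test_that("mean-FC outlier filter removes constructed outliers only", {
  mk <- function(v, id) {
    m <- matrix(v, 6, 6); diag(m) <- 0
    rownames(m) <- colnames(m) <- names(defaultIcnMap(6))
    new("Connectome", matrix = m, regionIds = rownames(m),
        icnMap = defaultIcnMap(6), subjectId = id,
        provenance = list(threshold = "none", cost = NA_real_, normalised = FALSE))
  }
  equal <- lapply(1:5, function(i) mk(0.3, paste0("s", i)))
  names(equal) <- paste0("s", 1:5)
  expect_true(all(fcOutlierFilter(equal)$included))
  ## 30 tightly clustered subjects plus one far outlier (the single-pass
  ## whole-sample SD rule needs enough subjects for one case to exceed 3 SD)
  set.seed(9)
  vals <- c(rnorm(30, 0.30, 0.01), 0.95)
  stack <- lapply(seq_along(vals), function(i) mk(vals[i], paste0("s", i)))
  names(stack) <- paste0("s", seq_along(vals))
  inc <- fcOutlierFilter(stack)$included
  expect_false(inc[["s31"]])
  expect_true(all(inc[paste0("s", 1:30)]))
  ## order invariance
  perm <- c(31, 1:30)
  inc2 <- fcOutlierFilter(stack[perm])$included
  expect_equal(inc2[names(inc)], inc)
})

test_that("ICN features are the 36 block means over retained edges", {
  ## uniform weight w on a full mask: every feature equals w
  n <- 24
  m <- matrix(0.4, n, n); diag(m) <- 0
  rownames(m) <- colnames(m) <- names(icn24)
  cn <- new("Connectome", matrix = m, regionIds = rownames(m),
            icnMap = icn24, subjectId = "s",
            provenance = list(threshold = "group", cost = 1, normalised = FALSE))
  f <- icnFeatures(cn)
  expect_length(f, 36L)
  expect_equal(length(grep("^within_", names(f))), 8L)
  expect_equal(length(grep("^between_", names(f))), 28L)
  expect_true(all(f == 0.4))
  ## hand-built 6-node two-ICN example
  icn6 <- setNames(c(rep("visual", 3), rep("limbic", 3)), sprintf("R%03d", 1:6))
  h <- matrix(0, 6, 6)
  h[1, 2] <- 0.9; h[1, 3] <- 0.5              # within visual: mean 0.7
  h[4, 5] <- 0.2                              # within limbic: mean 0.2
  h[1, 4] <- 0.6; h[2, 5] <- 0.3; h[3, 6] <- 0.3  # between: mean 0.4
  h <- h + t(h)
  rownames(h) <- colnames(h) <- names(icn6)
  cn6 <- new("Connectome", matrix = h, regionIds = rownames(h),
             icnMap = icn6, subjectId = "s6",
             provenance = list(threshold = "group", cost = 0.5, normalised = FALSE))
  f6 <- icnFeatures(cn6)
  expect_equal(unname(f6["within_visual"]), 0.7)
  expect_equal(unname(f6["within_limbic"]), 0.2)
  expect_equal(unname(f6["between_visual_limbic"]), 0.4)
  ## blocks with no regions or no retained edges are 0 and logged
  expect_equal(unname(f6["within_subcortical"]), 0)
  expect_true("within_subcortical" %in% attr(f6, "emptyBlocks"))
})
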