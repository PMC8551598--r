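mkConn <- function(W, icn = defaultIcnMap(nrow(W))) {
  dimnames(W) <- list(names(icn), names(icn))
  methods::new("Connectome", matrix = W, regionIds = rownames(W), icnMap = icn,
               subjectId = "s",
               provenance = list(threshold = "group", cost = 0.25,
                                 normalised = FALSE))
}

test_that("nodal metrics match closed-form fixtures", {
  ## unit-weight triangle: clustering 1 everywhere
  W3 <- matrix(1, 3, 3); diag(W3) <- 0
  nm3 <- nodalMetrics(mkConn(W3, setNames(rep("visual", 3), c("R001", "R002", "R003"))))
  expect_equal(nm3$clustering, rep(1, 3))
  ## 5-node star: centre betweenness = C(4,2) = 6, leaves 0 (and degree-1)
  W5 <- matrix(0, 5, 5); W5[1, 2:5] <- 1; W5 <- W5 + t(W5)
  nm5 <- nodalMetrics(mkConn(W5, setNames(rep("visual", 5), sprintf("R%03d", 1:5))))
  expect_equal(nm5$betweenness, c(6, 0, 0, 0, 0))
  expect_equal(nm5$strength, c(4, 1, 1, 1, 1))
  ## participation formula limits
  icn <- setNames(c("visual", "visual", "limbic", "limbic"), sprintf("R%03d", 1:4))
  W4 <- matrix(0, 4, 4)
  W4[1, 2] <- 1            # node 1: all edges within its own module
  W4[2, 3] <- 1            # node 2: one edge per module, split equally
  W4 <- W4 + t(W4)
  nm4 <- nodalMetrics(mkConn(W4, icn))
  expect_equal(nm4$participation[1], 0)
  expect_equal(nm4$participation[2], 0.5)
})

test_that("global metrics match closed-form fixtures", {
  ## complete unit-weight graph on 5 nodes
  W <- matrix(1, 5, 5); diag(W) <- 0
  gm <- suppressWarnings(globalMetrics(mkConn(W), seed = 1))
  expect_equal(unname(gm["charpath"]), 1)
  expect_equal(unname(gm["global_efficiency"]), 1)
  expect_equal(unname(gm["clustering"]), 1)
  ## 3-node unit chain: (1 + 1 + 2) / 3
  Wc <- matrix(0, 3, 3); Wc[1, 2] <- Wc[2, 3] <- 1; Wc <- Wc + t(Wc)
  gmc <- suppressWarnings(globalMetrics(mkConn(Wc,
    setNames(rep("visual", 3), c("R001", "R002", "R003"))), seed = 1))
  expect_equal(unname(gmc["charpath"]), 4 / 3)
  ## strength-regular graph: assortativity undefined
  expect_warning(gm2 <- globalMetrics(mkConn(W), seed = 1), "zero variance")
  expect_true(is.nan(gm2[["assortativity"]]))
})

test_that("metrics agree with the brute-force oracles on random graphs", {
  set.seed(10)
  for (rep in 1:6) {
    n <- sample(5:8, 1)
    W <- randPosGraph(n, density = 0.7)
    icn <- setNames(sample(c("visual", "limbic", "default mode"), n, TRUE),
                    sprintf("R%03d", 1:n))
    cn <- mkConn(W, icn)
    nm <- nodalMetrics(cn)
    expect_equal(nm$strength, bruteStrength(W), tolerance = 1e-9)
    expect_equal(nm$betweenness, bruteBetweenness(W), tolerance = 1e-9)
    expect_equal(nm$clustering, bruteOnnela(W), tolerance = 1e-9)
    expect_equal(nm$local_efficiency, bruteLocalEfficiency(W), tolerance = 1e-9)
    expect_equal(nm$participation, bruteParticipation(W, unname(icn)),
                 tolerance = 1e-9)
    expect_equal(nm$within_module_z, bruteWithinModuleZ(W, unname(icn)),
                 tolerance = 1e-9)
    gm <- suppressWarnings(globalMetrics(cn, seed = rep))
    expect_equal(unname(gm["charpath"]), bruteCharpath(W), tolerance = 1e-9)
    expect_equal(unname(gm["global_efficiency"]), bruteGlobalEfficiency(W),
                 tolerance = 1e-9)
    expect_equal(unname(gm["assortativity"]), bruteAssortativity(W),
                 tolerance = 1e-9)
  }
})

test_that("participation bookkeeping conserves strength", {
  set.seed(11)
  W <- randPosGraph(12, 0.5)
  icn <- defaultIcnMap(12)
  km <- rowsum(t(W), group = unname(icn))
  expect_equal(unname(colSums(km)), unname(rowSums(W)), tolerance = 1e-12)
})

test_that("paths are invariant to uniform weight scaling", {
  set.seed(12)
  W <- randPosGraph(10, 0.5)
  cn1 <- mkConn(W); cn2 <- mkConn(3 * W)
  expect_equal(nodalMetrics(cn1)$betweenness, nodalMetrics(cn2)$betweenness)
  g1 <- suppressWarnings(globalMetrics(cn1, seed = 1))
  g2 <- suppressWarnings(globalMetrics(cn2, seed = 1))
  expect_equal(unname(g2["charpath"]), unname(g1["charpath"]) / 3,
               tolerance = 1e-12)
})

test_that("rewired nulls preserve degrees and the weight multiset", {
  set.seed(13)
  W <- randPosGraph(30, 0.3)
  for (i in 1:5) {
    Wn <- rewireWeighted(W, swapsPerEdge = 10, seed = i)
    expect_equal(rowSums(Wn > 0), rowSums(W > 0))
    expect_equal(sort(Wn[upper.tri(Wn)][Wn[upper.tri(Wn)] > 0]),
                 sort(W[upper.tri(W)][W[upper.tri(W)] > 0]))
    expect_equal(Wn, t(Wn))
    expect_true(all(diag(Wn) == 0))
  }
  ## rewiring is seed-deterministic and actually changes the graph
  expect_identical(rewireWeighted(W, 10, 1), rewireWeighted(W, 10, 1))
  expect_false(identical(rewireWeighted(W, 10, 1), W))
})

test_that("normalisation against the null ensemble behaves as defined", {
  set.seed(14)
  W <- randPosGraph(40, 0.25)
  cn <- mkConn(W, defaultIcnMap(40))
  raw <- suppressWarnings(globalMetrics(cn, seed = 2))
  ne <- nullEnsemble(cn, n = 20, seed = 3)
  nm <- normaliseMetrics(raw, ne)
  ## strength and modularity pass through raw
  expect_equal(nm$normalised[["strength"]], raw[["strength"]])
  expect_equal(nm$normalised[["modularity"]], raw[["modularity"]])
  ## definitional identity for sigma small-worldness
  expect_equal(nm$normalised[["smallworldness"]],
               nm$normalised[["clustering"]] / nm$normalised[["charpath"]])
  ## an ER-like graph self-normalises to ~1
  expect_lt(abs(nm$normalised[["clustering"]] - 1), 0.12)
  expect_lt(abs(nm$normalised[["charpath"]] - 1), 0.12)
  ## a lattice-like high-clustering graph normalises above 1
  n <- 30
  Wl <- matrix(0, n, n)
  for (i in seq_len(n)) for (d in 1:3) {
    j <- ((i + d - 1) %% n) + 1
    Wl[i, j] <- Wl[j, i] <- 1 - 0.01 * d
  }
  cnl <- mkConn(Wl, defaultIcnMap(n))
  rawl <- suppressWarnings(globalMetrics(cnl, seed = 4))
  nel <- nullEnsemble(cnl, n = 20, seed = 5)
  expect_gt(normaliseMetrics(rawl, nel)$normalised[["clustering"]], 1)
})

test_that("AUC over costs is the trapezoid integral", {
  costs <- c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30)
  expect_equal(aucOverCosts(rep(2, 6), costs), 2 * 0.25)
  ramp <- (costs - 0.05) / 0.25
  expect_equal(aucOverCosts(ramp, costs), 0.125)
  ## independent accumulation oracle on a quadratic profile
  v <- costs^2
  oracle <- 0
  for (i in 1:5) oracle <- oracle + (costs[i + 1] - costs[i]) * (v[i] + v[i + 1]) / 2
  expect_equal(aucOverCosts(v, costs), oracle, tolerance = 1e-12)
  expect_error(aucOverCosts(1:3, c(0.1, 0.1, 0.2)))
})
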