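# Correlation matrices, thresholded networks, topology metrics,
# permutation differences, KS comparisons and community detection.

test_that("pairwise correlations match the covariance-formula oracle", {
  # a printed 5-mouse toy table
  dens <- list(A = c(120, 340, 560, 210, 430),
               B = c(100, 300, 610, 180, 400),
               C = c(900, 120, 450, 760, 330))
  tab <- do.call(rbind, lapply(names(dens), function(a)
    densTable(dens[[a]], acronym = a)))
  cm <- pairwiseCorrelations(tab)
  for (pr in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    expect_equal(corValues(cm)[pr[1], pr[2]],
                 covFormulaCor(dens[[pr[1]]], dens[[pr[2]]]),
                 tolerance = 1e-12)
  }
  expect_equal(unique(as.vector(corN(cm))), 5L)
  # identical vectors -> 1; a vector vs its negation -> -1
  tab2 <- rbind(densTable(1:5, acronym = "A"),
                densTable(1:5, acronym = "B"),
                densTable(-(1:5) + 10, acronym = "C"))
  cm2 <- pairwiseCorrelations(tab2)
  expect_equal(corValues(cm2)["A", "B"], 1)
  expect_equal(corValues(cm2)["A", "C"], -1)
  expect_equal(corPvalues(cm2)["A", "B"], 0)
})

test_that("constant regions are reported missing with a warning", {
  tab <- rbind(densTable(c(1, 2, 3, 4), acronym = "A"),
               densTable(rep(5, 4), acronym = "flat"))
  expect_warning(cm <- pairwiseCorrelations(tab), "constant")
  expect_true(is.na(corValues(cm)["A", "flat"]))
  expect_error(pairwiseCorrelations(densTable(1:2, acronym = "A")),
               "at least 3")
})

test_that("correlation p-values follow the t transform", {
  expect_equal(correlationPvalue(0, 10), 1)
  expect_equal(correlationPvalue(1, 5), 0)
  expect_equal(correlationPvalue(-1, 5), 0)
  expect_equal(correlationPvalue(0.9, 5), integratedCorPvalue(0.9, 5),
               tolerance = 1e-8)
  expect_error(correlationPvalue(0.5, 2), "at least 3")
  # decreasing in |r| at fixed n, decreasing in n at fixed |r| > 0
  rs <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(correlationPvalue(rs, 8)) < 0))
  ns <- c(4, 6, 10, 20, 50)
  expect_true(all(diff(correlationPvalue(0.5, ns)) < 0))
  expect_equal(correlationPvalue(-0.5, 8), correlationPvalue(0.5, 8))
})

test_that("network thresholding keeps strong significant edges", {
  r <- matrix(c(1, 0.95, -0.95, 0.5,
                0.95, 1, 0.2, 0.92,
                -0.95, 0.2, 1, 0.1,
                0.5, 0.92, 0.1, 1), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  p <- matrix(0.001, 4, 4, dimnames = dimnames(r)); diag(p) <- NA
  p["B", "D"] <- p["D", "B"] <- 0.02   # strong but not significant
  cm <- new("CorrelationMatrix", regions = LETTERS[1:4], r = r, p = p,
            n = matrix(6L, 4, 4))
  nw <- buildNetwork(cm, rMin = 0.9, alpha = 0.01)
  e <- networkEdges(nw)
  expect_equal(nrow(e), 2)
  expect_true(any(e$r < 0))               # anti-correlated edge kept
  # signed mode drops the negative edge
  nwS <- buildNetwork(cm, rMin = 0.9, alpha = 0.01, signed = TRUE)
  expect_equal(nrow(networkEdges(nwS)), 1)
  # monotone in alpha and rMin
  for (a in c(0.005, 0.05, 0.5)) {
    e1 <- nrow(networkEdges(buildNetwork(cm, 0.9, a)))
    e2 <- nrow(networkEdges(buildNetwork(cm, 0.9, min(a * 10, 0.9))))
    expect_lte(e1, e2)
  }
  expect_lte(nrow(networkEdges(buildNetwork(cm, 0.93, 0.05))),
             nrow(networkEdges(buildNetwork(cm, 0.5, 0.05))))
})

test_that("topology metrics match hand-enumerated small graphs", {
  # triangle: degree 2, clustering 1, efficiency 1, betweenness 0
  A3 <- matrix(1, 3, 3) - diag(3)
  m3 <- nodeMetrics(netFromAdjacency(A3))
  expect_equal(m3$nodes$degree, rep(2L, 3))
  expect_equal(m3$nodes$clustering, rep(1, 3))
  expect_equal(m3$nodes$efficiency, rep(1, 3))
  expect_equal(m3$nodes$betweenness, rep(0, 3))
  # path a-b-c
  Ap <- matrix(0, 3, 3); Ap[1, 2] <- Ap[2, 1] <- Ap[2, 3] <- Ap[3, 2] <- 1
  mp <- nodeMetrics(netFromAdjacency(Ap))
  expect_equal(mp$nodes$betweenness[2], 1)
  expect_equal(mp$nodes$clustering, rep(0, 3))
  expect_equal(unname(mp$network["global_efficiency"]), (1 + 1 + 0.5) / 3)
  # star with 3 leaves: centre betweenness 3
  As <- matrix(0, 4, 4); As[1, 2:4] <- As[2:4, 1] <- 1
  ms <- nodeMetrics(netFromAdjacency(As))
  expect_equal(ms$nodes$betweenness, c(3, 0, 0, 0))
  # isolated node: clustering and efficiency 0
  Ai <- matrix(0, 3, 3); Ai[1, 2] <- Ai[2, 1] <- 1
  mi <- nodeMetrics(netFromAdjacency(Ai))
  expect_equal(mi$nodes$efficiency[3], 0)
  expect_equal(mi$nodes$clustering[3], 0)
})

test_that("metrics agree with the brute-force oracle on random graphs", {
  set.seed(20)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    A <- matrix(0, n, n)
    ut <- which(upper.tri(A))
    on <- ut[runif(length(ut)) < 0.5]
    if (!length(on)) on <- ut[1]
    A[on] <- 1; A <- A + t(A)
    m <- nodeMetrics(netFromAdjacency(A))
    o <- bruteGraphMetrics(A)
    expect_equal(m$nodes$degree, as.integer(o$degree))
    expect_equal(m$nodes$clustering, o$clustering, tolerance = 1e-12)
    expect_equal(m$nodes$efficiency, o$efficiency, tolerance = 1e-12)
    expect_equal(m$nodes$betweenness, o$betweenness, tolerance = 1e-9)
  }
})

test_that("threshold sweeps are monotone and hit the extremes", {
  sim <- simulateRegionCounts(countSimSpec(nPerGroup = 8,
                                           regions = paste0("R", 1:6),
                                           targetCorr = 0.7), seed = 2)
  cm <- pairwiseCorrelations(sim$tables$CT)
  sw <- thresholdSweep(cm, alphas = c(1e-12, 0.01, 0.5, 0.999999),
                       rMin = 0)
  expect_true(all(diff(sw$mean_degree) >= 0))
  # alpha ~ 1, rMin = 0 on an all-finite matrix -> complete graph
  expect_equal(sw$mean_degree[4], 5)
  # alpha below the smallest p -> empty graph, all means 0
  expect_equal(sw$mean_degree[1], 0)
  expect_equal(sw$global_efficiency[1], 0)
  expect_error(thresholdSweep(cm, alphas = c(0.5, 0.1)), "sorted")
})

test_that("identical groups give zero differences and p = 1", {
  sim <- simulateRegionCounts(countSimSpec(nPerGroup = 5,
                                           regions = paste0("R", 1:4)),
                              seed = 1)
  tab <- sim$tables$CT
  tabB <- tab; tabB$mouse_id <- paste0("x", tabB$mouse_id)
  pr <- permutationCorrelationDiff(tab, tabB, nPerm = 199, seed = 1)
  expect_equal(max(abs(permPairs(pr)$d)), 0)
  expect_equal(unique(permPairs(pr)$p), 1)
})

test_that("permutation results are seed-deterministic", {
  sim <- simulateRegionCounts(countSimSpec(nPerGroup = 6,
                                           regions = paste0("R", 1:5),
                                           plantedDiffs =
                                             list("R1|R2" = c(0.9, -0.9))),
                              seed = 3)
  p1 <- permutationCorrelationDiff(sim$tables$CT, sim$tables$IS,
                                   nPerm = 200, seed = 7)
  p2 <- permutationCorrelationDiff(sim$tables$CT, sim$tables$IS,
                                   nPerm = 200, seed = 7)
  expect_identical(permPairs(p1), permPairs(p2))
  p3 <- permutationCorrelationDiff(sim$tables$CT, sim$tables$IS,
                                   nPerm = 200, seed = 8)
  expect_false(identical(permPairs(p1)$p, permPairs(p3)$p))
  expect_warning(permutationCorrelationDiff(sim$tables$CT, sim$tables$IS,
                                            nPerm = 50, seed = 1),
                 "coarse")
  # p-values respect the add-one lower bound
  expect_true(all(permPairs(p1)$p >= 1 / 201))
})

test_that("KS comparison follows the ECDF arithmetic", {
  mkCM <- function(vals, regions) {
    k <- length(regions)
    r <- diag(k); r[1, -1] <- vals; r[-1, 1] <- vals
    # fill remaining off-diagonals arbitrarily but symmetrically
    r[lower.tri(r) & r == 0] <- 0.1
    r[upper.tri(r)] <- t(r)[upper.tri(r)]
    diag(r) <- 1
    dimnames(r) <- list(regions, regions)
    new("CorrelationMatrix", regions = regions, r = r,
        p = matrix(NA_real_, k, k), n = matrix(5L, k, k))
  }
  regions <- c("SNr", paste0("R", 1:4))
  a <- mkCM(c(0.1, 0.2, 0.5, 0.6), regions)
  b <- mkCM(c(0.1, 0.2, 0.5, 0.9), regions)
  ks <- ksRegionDistributions(a, b, "SNr")
  expect_equal(ks$statistic, 0.25)
  ksSame <- ksRegionDistributions(a, a, "SNr")
  expect_equal(ksSame$statistic, 0)
  expect_equal(ksSame$p.value, 1)
  c1 <- mkCM(c(0.1, 0.2, 0.3, 0.35) * 2, regions)   # {.2,.4,.6,.7}
  c2 <- mkCM(c(0.8, 0.85, 0.9, 0.95), regions)
  expect_equal(ksRegionDistributions(c1, c2, "SNr")$statistic, 1)
  expect_error(ksRegionDistributions(a, b, "nope"), "absent")
})

test_that("leading-eigenvector split recovers planted communities", {
  # two disconnected triangles
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; diag(A) <- 0
  part <- leadingEigenvectorPartition(netFromAdjacency(A))
  expect_equal(length(unique(part$membership[1:3])), 1)
  expect_equal(length(unique(part$membership[4:6])), 1)
  expect_false(part$membership[1] == part$membership[4])
  # matches exhaustive modularity maximization
  brute <- bruteBestTwoSplit(A)
  expect_equal(part$modularity, brute$Q, tolerance = 1e-12)
  # complete graph: indivisible -> single community
  K4 <- matrix(1, 4, 4) - diag(4)
  pk <- leadingEigenvectorPartition(netFromAdjacency(K4))
  expect_equal(length(unique(pk$membership)), 1)
  expect_equal(bruteBestTwoSplit(K4)$Q, 0)
  # one edge plus an isolated node: the edge pair stays together
  A3 <- matrix(0, 3, 3); A3[1, 2] <- A3[2, 1] <- 1
  p3 <- leadingEigenvectorPartition(netFromAdjacency(A3))
  expect_equal(p3$membership[["n1"]], p3$membership[["n2"]])
  expect_error(leadingEigenvectorPartition(
    new("FunctionalNetwork", nodes = c("a", "b"),
        edges = data.frame(region_a = character(), region_b = character(),
                           r = numeric(), p = numeric()),
        rMin = 0.9, alpha = 0.01)), "no edges")
})
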