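# Correlation matrices with asymptotic p-values, thresholded functional
# networks, node/network topology metrics, threshold sweeps, permutation
# analysis of group correlation differences, KS comparison of regional
# correlation distributions, and leading-eigenvector communities.

#' @importFrom igraph graph_from_adjacency_matrix degree betweenness
#'   transitivity distances
NULL

# Long region-count table (one group, one channel unless `channel` NULL
# and unique) -> mice x regions density matrix.
densityMatrix <- function(table, channel = NULL) {
  if (!is.null(channel)) table <- table[table$channel == channel, ]
  if (length(unique(table$channel)) > 1L)
    stop("table holds several channels; pick one with `channel`")
  mice <- sort(unique(table$mouse_id))
  regions <- sort(unique(table$acronym))
  m <- matrix(NA_real_, length(mice), length(regions),
              dimnames = list(mice, regions))
  m[cbind(match(table$mouse_id, mice), match(table$acronym, regions))] <-
    table$density
  m
}

#' Two-sided asymptotic p-value of a Pearson correlation
#'
#' The t transform: t = r sqrt(n - 2) / sqrt(1 - r^2) referred to a t
#' distribution with n - 2 degrees of freedom (two-sided); |r| = 1 gives
#' p = 0 by the limit convention.
#'
#' @param r correlation(s) in [-1, 1].
#' @param n number(s) of paired observations, >= 3.
#' @return two-sided p-value(s), vectorized over \code{r} and \code{n}.
#' @examples
#' correlationPvalue(0.9, 5)   # ~0.0374
#' @export
correlationPvalue <- function(r, n) {
  if (any(n < 3, na.rm = TRUE)) stop("n must be at least 3")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1")
  r <- pmin(pmax(r, -1), 1)
  p <- ifelse(abs(r) >= 1, 0, {
    tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
    2 * stats::pt(-abs(tt), df = n - 2)
  })
  p
}

#' Pairwise regional Pearson correlations for one group
#'
#' Pairwise-complete Pearson correlations between regional densities
#' across the mice of one group, with asymptotic two-sided p-values and
#' the per-pair number of complete observations. Pairs with fewer than 3
#' complete observations, and pairs involving a region constant across
#' mice, are reported missing (with a warning for constant regions).
#'
#' @param table region-count data.frame for one group (one channel), or a
#'   mice x regions density matrix.
#' @param channel channel to select when the table has several.
#' @return a \code{\link{CorrelationMatrix-class}}.
#' @export
pairwiseCorrelations <- function(table, channel = NULL) {
  m <- if (is.matrix(table)) table else densityMatrix(table, channel)
  if (nrow(m) < 3L) stop("at least 3 mice are required")
  regions <- colnames(m)
  n <- crossprod(!is.na(m))
  storage.mode(n) <- "integer"
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0))
    warning("region(s) constant across mice: ",
            paste(regions[!is.na(sds) & sds == 0], collapse = ", "),
            "; their correlations are reported missing")
  r[n < 3L] <- NA_real_
  diag(r) <- 1
  p <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  off <- upper.tri(r)
  ok <- off & !is.na(r) & n >= 3L
  p[ok] <- correlationPvalue(r[ok], n[ok])
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  new("CorrelationMatrix", regions = regions, r = r, p = p, n = n)
}

#' Threshold a correlation matrix into a functional network
#'
#' An edge joins two regions when the correlation passes both the strength
#' threshold (absolute value by default, so strong anti-correlations also
#' connect; \code{signed = TRUE} restricts to r > rMin) and the
#' significance threshold p < alpha. Edge weights carry the signed r.
#'
#' @param corr a \code{\link{CorrelationMatrix-class}}.
#' @param rMin strength threshold in [0, 1) (default 0.9).
#' @param alpha significance threshold in (0, 1).
#' @param signed if TRUE threshold on signed r instead of |r|.
#' @return a \code{\link{FunctionalNetwork-class}}.
#' @export
buildNetwork <- function(corr, rMin = 0.9, alpha = 0.01, signed = FALSE) {
  stopifnot(alpha > 0, alpha < 1, rMin >= 0, rMin < 1)
  r <- corValues(corr); p <- corPvalues(corr)
  regions <- corRegions(corr)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[ut]; pv <- p[ut]
  strength <- if (signed) rv else abs(rv)
  keep <- !is.na(rv) & !is.na(pv) & strength > rMin & pv < alpha
  edges <- data.frame(region_a = regions[ut[keep, 1]],
                      region_b = regions[ut[keep, 2]],
                      r = rv[keep], p = pv[keep])
  rownames(edges) <- NULL
  new("FunctionalNetwork", nodes = regions, edges = edges, rMin = rMin,
      alpha = alpha)
}

asIgraph <- function(network) {
  A <- matrix(0, length(network@nodes), length(network@nodes),
              dimnames = list(network@nodes, network@nodes))
  e <- network@edges
  if (nrow(e)) {
    A[cbind(e$region_a, e$region_b)] <- 1
    A[cbind(e$region_b, e$region_a)] <- 1
  }
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

#' Node and network topology metrics
#'
#' Computed on the unweighted, sign-ignored skeleton of the thresholded
#' network: degree (edge count), clustering coefficient
#' (2 triangles / (deg (deg - 1)), 0 when degree < 2), nodal efficiency
#' (mean inverse shortest-path length to the other nodes, with 1/Inf = 0
#' for disconnected pairs), and betweenness centrality (unnormalized,
#' each unordered pair counted once). Network means of each metric are
#' attached; global efficiency is the mean nodal efficiency.
#'
#' @param network a \code{\link{FunctionalNetwork-class}}.
#' @param normalizedBetweenness divide betweenness by
#'   (n-1)(n-2)/2 (default FALSE, matching the unnormalized presentation).
#' @return list with \code{nodes} (data.frame: region, degree, clustering,
#'   efficiency, betweenness) and \code{network} (named means:
#'   mean_degree, mean_clustering, global_efficiency, mean_betweenness).
#' @export
nodeMetrics <- function(network, normalizedBetweenness = FALSE) {
  g <- asIgraph(network)
  nn <- length(network@nodes)
  deg <- igraph::degree(g)
  clus <- igraph::transitivity(g, type = "localundirected",
                               isolates = "zero")
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  if (normalizedBetweenness && nn > 2)
    btw <- btw / ((nn - 1) * (nn - 2) / 2)
  sp <- igraph::distances(g)
  inv <- 1 / sp
  diag(inv) <- NA
  eff <- if (nn > 1) rowMeans(inv, na.rm = TRUE) else 0
  eff[!is.finite(eff)] <- 0
  nodes <- data.frame(region = network@nodes, degree = as.integer(deg),
                      clustering = as.numeric(clus),
                      efficiency = as.numeric(eff),
                      betweenness = as.numeric(btw))
  rownames(nodes) <- NULL
  list(nodes = nodes,
       network = c(mean_degree = mean(nodes$degree),
                   mean_clustering = mean(nodes$clustering),
                   global_efficiency = mean(nodes$efficiency),
                   mean_betweenness = mean(nodes$betweenness)))
}

#' Network-mean metrics across a range of significance thresholds
#'
#' Rebuilds the thresholded network at each alpha and tabulates the
#' network-mean topology metrics, the stability check used to show that
#' group-level conclusions do not hinge on one significance cutoff.
#'
#' @param corr a \code{\link{CorrelationMatrix-class}}.
#' @param alphas increasing vector of significance thresholds.
#' @param rMin strength threshold applied throughout.
#' @param signed passed to \code{\link{buildNetwork}}.
#' @return data.frame: alpha, n_edges, mean_degree, mean_clustering,
#'   global_efficiency, mean_betweenness.
#' @export
thresholdSweep <- function(corr, alphas, rMin = 0.9, signed = FALSE) {
  stopifnot(!is.unsorted(alphas))
  rows <- lapply(alphas, function(a) {
    nw <- buildNetwork(corr, rMin = rMin, alpha = a, signed = signed)
    mt <- nodeMetrics(nw)$network
    data.frame(alpha = a, n_edges = nrow(networkEdges(nw)),
               mean_degree = mt["mean_degree"],
               mean_clustering = mt["mean_clustering"],
               global_efficiency = mt["global_efficiency"],
               mean_betweenness = mt["mean_betweenness"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation test of group differences in regional correlations
#'
#' For every region pair, the observed difference d = r(group B) -
#' r(group A) is compared against a null distribution generated by
#' shuffling the group labels of the mice (preserving group sizes) and
#' recomputing the correlation difference for each shuffle. Two-sided
#' p-values use the add-one estimator
#' p = (#\{|d_null| >= |d_obs|\} + 1) / (nPerm + 1). No multiple-testing
#' correction is applied.
#'
#' @param tableA,tableB region-count tables (or density matrices) for the
#'   two groups, sharing the same regions.
#' @param nPerm number of label shuffles (default 1000; < 100 warns).
#' @param seed RNG seed for reproducible shuffles.
#' @param channel channel selector for table input.
#' @param groups labels recorded in the result (A then B).
#' @return a \code{\link{PermutationResult-class}}.
#' @export
permutationCorrelationDiff <- function(tableA, tableB, nPerm = 1000,
                                       seed = NULL, channel = NULL,
                                       groups = c("A", "B")) {
  mA <- if (is.matrix(tableA)) tableA else densityMatrix(tableA, channel)
  mB <- if (is.matrix(tableB)) tableB else densityMatrix(tableB, channel)
  shared <- intersect(colnames(mA), colnames(mB))
  if (length(shared) < 2L) stop("fewer than 2 shared regions")
  mA <- mA[, shared, drop = FALSE]; mB <- mB[, shared, drop = FALSE]
  nA <- nrow(mA); nB <- nrow(mB)
  if (nA < 3L || nB < 3L) stop("each group needs at least 3 mice")
  if (nPerm < 100) warning("fewer than 100 shuffles: p-values are coarse")
  corAB <- function(X, ia, ib) {
    suppressWarnings(stats::cor(X[ib, , drop = FALSE],
                                use = "pairwise.complete.obs") -
                     stats::cor(X[ia, , drop = FALSE],
                                use = "pairwise.complete.obs"))
  }
  X <- rbind(mA, mB)
  rA <- suppressWarnings(stats::cor(mA, use = "pairwise.complete.obs"))
  rB <- suppressWarnings(stats::cor(mB, use = "pairwise.complete.obs"))
  dObs <- rB - rA
  ut <- which(upper.tri(dObs), arr.ind = TRUE)
  geq <- matrix(0L, length(shared), length(shared))
  withSeed(seed, {
    for (b in seq_len(nPerm)) {
      idx <- sample.int(nA + nB)
      dNull <- corAB(X, idx[seq_len(nA)], idx[nA + seq_len(nB)])
      geq <- geq + (!is.na(dNull) & !is.na(dObs) &
                      abs(dNull) >= abs(dObs) - 1e-12)
    }
  })
  pairs <- data.frame(region_a = shared[ut[, 1]], region_b = shared[ut[, 2]],
                      r_a = rA[ut], r_b = rB[ut], d = dObs[ut],
                      p = (geq[ut] + 1) / (nPerm + 1))
  pairs$p[is.na(pairs$d)] <- NA_real_
  new("PermutationResult", pairs = pairs, nPerm = nPerm,
      seed = if (is.null(seed)) NA_real_ else seed, groups = groups)
}

#' Compare a region's correlation distributions between groups
#'
#' Two-sample Kolmogorov-Smirnov test on the vectors of correlation
#' coefficients a region forms with every other region (self-correlation
#' excluded), one vector per group.
#'
#' @param corrA,corrB \code{\link{CorrelationMatrix-class}} objects.
#' @param region the region acronym to compare.
#' @return list: \code{statistic} (D), \code{p.value}, and the two
#'   correlation vectors.
#' @export
ksRegionDistributions <- function(corrA, corrB, region) {
  pull <- function(cm) {
    i <- match(region, corRegions(cm))
    if (is.na(i))
      stop(sprintf("region '%s' absent from a correlation matrix", region))
    v <- corValues(cm)[i, -i]
    v[!is.na(v)]
  }
  a <- pull(corrA); b <- pull(corrB)
  if (length(a) < 3L || length(b) < 3L)
    stop("fewer than 3 correlations on one side")
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       valuesA = a, valuesB = b)
}

#' Two-community split by the leading eigenvector of the modularity matrix
#'
#' Forms the modularity matrix B = A - k k^T / (2m) of the unweighted
#' network skeleton, takes the eigenvector of the largest eigenvalue, and
#' separates nodes into two communities by the sign of their element,
#' followed by the method's standard fine-tuning stage (single vertices
#' are moved between the communities while modularity improves). If the
#' leading eigenvalue is not positive, or no split improves on a single
#' community, the network is indivisible and one community is returned.
#'
#' @param network a \code{\link{FunctionalNetwork-class}} with >= 1 edge.
#' @return list: \code{membership} (named integer vector, 1/2),
#'   \code{modularity} of the split, \code{leadingEigenvalue}.
#' @export
leadingEigenvectorPartition <- function(network) {
  nodes <- network@nodes
  e <- network@edges
  if (!nrow(e)) stop("the network has no edges")
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  A[cbind(e$region_a, e$region_b)] <- 1
  A[cbind(e$region_b, e$region_a)] <- 1
  k <- rowSums(A)
  m2 <- sum(k)            # 2m
  B <- A - tcrossprod(k) / m2
  ev <- eigen(B, symmetric = TRUE)
  lead <- ev$values[1]
  if (lead <= 1e-12) {
    membership <- stats::setNames(rep(1L, length(nodes)), nodes)
    return(list(membership = membership, modularity = 0,
                leadingEigenvalue = lead))
  }
  Qof <- function(s) as.numeric(t(s) %*% B %*% s) / (2 * m2)
  # Kernighan-Lin-style fine-tuning: in each pass every vertex is flipped
  # exactly once (most favourable move first, even when unfavourable) and
  # the best intermediate state of the pass is kept; passes repeat while
  # they improve modularity
  refine <- function(s) {
    repeat {
      Qstart <- Qof(s)
      cur <- s; free <- rep(TRUE, length(s))
      bestS <- s; bestQ <- Qstart
      for (step in seq_along(s)) {
        gains <- rep(-Inf, length(s))
        for (i in which(free)) {
          s2 <- cur; s2[i] <- -s2[i]
          gains[i] <- Qof(s2) - Qof(cur)
        }
        i <- which.max(gains)
        cur[i] <- -cur[i]; free[i] <- FALSE
        q <- Qof(cur)
        if (q > bestQ + 1e-12) { bestQ <- q; bestS <- cur }
      }
      if (bestQ <= Qstart + 1e-12) break
      s <- bestS
    }
    s
  }
  # fine-tune from each positive-eigenvalue eigenvector's sign pattern
  # (spectral bisection candidates) and keep the best split
  s <- NULL; Q <- -Inf
  for (j in which(ev$values > 1e-12)) {
    sj <- refine(ifelse(ev$vectors[, j] >= 0, 1, -1))
    qj <- Qof(sj)
    if (qj > Q + 1e-12) { Q <- qj; s <- sj }
  }
  if (Q <= 1e-12 || length(unique(s)) == 1L) {
    membership <- stats::setNames(rep(1L, length(nodes)), nodes)
    return(list(membership = membership, modularity = 0,
                leadingEigenvalue = lead))
  }
  membership <- stats::setNames(ifelse(s > 0, 1L, 2L), nodes)
  list(membership = membership, modularity = Q, leadingEigenvalue = lead)
}

#' Write network-module outputs as CSV
#'
#' Helpers for the on-disk result bundle: correlation matrices, edge
#' lists, metric tables and permutation results.
#'
#' @param corr a \code{\link{CorrelationMatrix-class}}.
#' @param path output path (CSV).
#' @export
writeCorrelationMatrix <- function(corr, path) {
  utils::write.csv(data.frame(region = corRegions(corr), corValues(corr),
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCorrelationMatrix
#' @param network a \code{\link{FunctionalNetwork-class}}.
#' @export
writeEdgeList <- function(network, path) {
  utils::write.csv(networkEdges(network), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCorrelationMatrix
#' @param result a \code{\link{PermutationResult-class}}.
#' @export
writePermutationResult <- function(result, path) {
  utils::write.csv(permPairs(result), path, row.names = FALSE)
  invisible(path)
}
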