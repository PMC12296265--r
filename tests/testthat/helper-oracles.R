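# Independent oracles used across the suite. These re-derive graph
# metrics, modularity partitions and correlation p-values from first
# principles (matrix powers, exhaustive enumeration, numeric integration)
# so the package implementations are checked against a separate route.

# Build a FunctionalNetwork from an adjacency matrix (nodes a, b, c, ...).
netFromAdjacency <- function(A) {
  n <- nrow(A)
  nodes <- paste0("n", seq_len(n))
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  edges <- data.frame(region_a = nodes[idx[, 1]], region_b = nodes[idx[, 2]],
                      r = 1, p = 1e-6)
  new("FunctionalNetwork", nodes = nodes, edges = edges, rMin = 0,
      alpha = 0.01)
}

# Graph metrics from scratch: Floyd-Warshall distances, shortest-path
# counts via adjacency-matrix powers, triangles via A^3.
bruteGraphMetrics <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  # distances
  D <- ifelse(A > 0, 1, Inf); diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  # number of shortest paths between each pair: powers of A
  pow <- vector("list", n)
  pow[[1]] <- A
  for (k in seq_len(n - 1)) if (k + 1 <= n) pow[[k + 1]] <- pow[[k]] %*% A
  sigma <- function(s, t) {
    d <- D[s, t]
    if (!is.finite(d) || d == 0) return(if (s == t) 1 else 0)
    pow[[d]][s, t]
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in seq(s + 1, n)) {
        if (s == v || t == v) next
        st <- sigma(s, t)
        if (st == 0) next
        dsv <- D[s, v]; dvt <- D[v, t]
        if (is.finite(dsv) && is.finite(dvt) && dsv + dvt == D[s, t])
          btw[v] <- btw[v] + sigma(s, v) * sigma(v, t) / st
      }
    }
  }
  tri <- diag(A %*% A %*% A) / 2
  clus <- ifelse(deg < 2, 0, 2 * tri / (deg * (deg - 1)))
  inv <- 1 / D; diag(inv) <- NA
  eff <- rowMeans(inv, na.rm = TRUE)
  eff[!is.finite(eff)] <- 0
  list(degree = deg, clustering = clus, efficiency = eff, betweenness = btw,
       global_efficiency = mean(eff))
}

# Best two-way split by exhaustive modularity maximization over all
# 2^(n-1) sign assignments (including the trivial single community, Q=0).
bruteBestTwoSplit <- function(A) {
  n <- nrow(A)
  k <- rowSums(A); m2 <- sum(k)
  B <- A - tcrossprod(k) / m2
  best <- list(Q = 0, s = rep(1, n))
  for (code in 0:(2^(n - 1) - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n - 1)]
    s <- c(1, ifelse(bits == 1, 1, -1))
    Q <- as.numeric(t(s) %*% B %*% s) / (2 * m2)
    if (Q > best$Q + 1e-12) best <- list(Q = Q, s = s)
  }
  best
}

# Two-sided correlation p-value by numeric integration of the t density.
integratedCorPvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  df <- n - 2
  tt <- abs(r) * sqrt(df) / sqrt(1 - r^2)
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, tt, Inf, rel.tol = 1e-10)$value
}

# Pearson correlation straight from the covariance formula.
covFormulaCor <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
           sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# All labeled connected graphs on n nodes, as edge-selection bit masks
# over the rows of t(combn(n, 2)).
connectedGraphMasks <- function(n) {
  pairs <- t(utils::combn(n, 2))
  np <- nrow(pairs)
  masks <- list()
  for (code in seq_len(2^np) - 1L) {
    bits <- as.logical(intToBits(code))[seq_len(np)]
    if (!any(bits)) next
    A <- matrix(0, n, n)
    sel <- pairs[bits, , drop = FALSE]
    A[sel] <- 1; A[sel[, 2:1, drop = FALSE]] <- 1
    # connectivity via reachability
    R <- diag(n) + A
    for (i in seq_len(ceiling(log2(n)))) R <- R %*% R
    if (all(R > 0)) masks[[length(masks) + 1L]] <- bits
  }
  list(pairs = pairs, masks = masks)
}
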