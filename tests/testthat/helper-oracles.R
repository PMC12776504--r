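# Independent brute-force oracles. These deliberately re-derive quantities
# through a different code path than the package implementation.

# Direct PDC evaluation from first principles: build Abar(f) element by
# element with explicit complex arithmetic loops.
oracle_pdc <- function(coefs, f, fs) {
  R <- dim(coefs)[1]; p <- dim(coefs)[3]
  Abar <- matrix(0 + 0i, R, R)
  for (i in seq_len(R)) for (j in seq_len(R)) {
    a <- if (i == j) 1 + 0i else 0 + 0i
    for (r in seq_len(p))
      a <- a - coefs[i, j, r] * complex(modulus = 1, argument = -2 * pi * f * r / fs)
    Abar[i, j] <- a
  }
  out <- matrix(NA_real_, R, R)
  for (j in seq_len(R)) {
    denom <- sqrt(sum(Mod(Abar[, j])^2))
    for (i in seq_len(R)) out[i, j] <- Mod(Abar[i, j]) / denom
  }
  out
}

# Normal-equations MVAR estimate for a single continuous series.
oracle_mvar_fit <- function(x, p) {
  R <- nrow(x); Tn <- ncol(x)
  Y <- t(x[, (p + 1):Tn, drop = FALSE])
  X <- NULL
  for (r in seq_len(p)) X <- cbind(X, t(x[, (p + 1 - r):(Tn - r), drop = FALSE]))
  B <- solve(t(X) %*% X, t(X) %*% Y)
  coefs <- array(0, c(R, R, p))
  for (r in seq_len(p)) coefs[, , r] <- t(B[((r - 1) * R + 1):(r * R), , drop = FALSE])
  coefs
}

# Floyd-Warshall all-pairs shortest paths on distances 1/w (directed,
# convention W[i, j] = flow j -> i).
oracle_distances <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && W[i, j] > 0) D[j, i] <- 1 / W[i, j]  # edge j -> i
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_local_efficiency <- function(W) {
  n <- nrow(W)
  eff <- numeric(n)
  for (v in seq_len(n)) {
    nbrs <- setdiff(union(which(W[v, ] > 0), which(W[, v] > 0)), v)
    if (length(nbrs) < 2) next
    D <- oracle_distances(W[nbrs, nbrs, drop = FALSE])
    acc <- 0
    for (s in seq_along(nbrs)) for (t in seq_along(nbrs)) if (s != t)
      acc <- acc + 1 / D[s, t]
    eff[v] <- acc / (length(nbrs) * (length(nbrs) - 1))
  }
  eff
}

oracle_strength <- function(W, direction) {
  n <- nrow(W)
  out <- numeric(n)
  for (v in seq_len(n)) {
    s_out <- 0; s_in <- 0
    for (i in seq_len(n)) { s_out <- s_out + W[i, v]; s_in <- s_in + W[v, i] }
    out[v] <- switch(direction, out = s_out, `in` = s_in, total = s_out + s_in)
  }
  out
}

oracle_degree <- function(adj) {
  n <- nrow(adj)
  deg <- integer(n)
  for (v in seq_len(n)) {
    d <- 0L
    for (i in seq_len(n)) { if (adj[i, v]) d <- d + 1L; if (adj[v, i]) d <- d + 1L }
    deg[v] <- d
  }
  deg
}

# Enumerate all spanning trees of a small undirected weighted graph and
# return the edge set minimizing total distance 1/w.
oracle_min_spanning_tree <- function(S) {
  n <- nrow(S)
  edges <- which(upper.tri(S) & S > 0, arr.ind = TRUE)
  m <- nrow(edges)
  best <- NULL; best_cost <- Inf
  for (mask in 0:(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (length(sel) != n - 1) next
    A <- matrix(0, n, n)
    for (k in sel) { A[edges[k, 1], edges[k, 2]] <- 1; A[edges[k, 2], edges[k, 1]] <- 1 }
    # connectivity via reachability
    reach <- (diag(n) + A) > 0
    for (it in seq_len(n)) reach <- (reach %*% reach) > 0
    if (!all(reach)) next
    cost <- sum(1 / S[edges[sel, , drop = FALSE]])
    if (cost < best_cost) { best_cost <- cost; best <- edges[sel, , drop = FALSE] }
  }
  list(edges = best, cost = best_cost)
}

# Plain double-loop ReliefF with k neighbours, range-normalized diffs.
oracle_relief <- function(x, y, k) {
  n <- nrow(x); d <- ncol(x)
  rng <- apply(x, 2, function(col) max(col) - min(col))
  rng[rng == 0] <- 1
  xn <- sweep(x, 2, rng, "/")
  w <- numeric(d)
  for (m in seq_len(n)) {
    dists <- apply(xn, 1, function(row) sqrt(sum((row - xn[m, ])^2)))
    dists[m] <- Inf
    hits <- order(ifelse(y == y[m], dists, Inf))[seq_len(k)]
    misses <- order(ifelse(y != y[m], dists, Inf))[seq_len(k)]
    for (f in seq_len(d)) {
      w[f] <- w[f] + mean(abs(xn[misses, f] - xn[m, f])) -
        mean(abs(xn[hits, f] - xn[m, f]))
    }
  }
  w / n
}

# random connected directed weight matrix with zero diagonal
random_connected_graph <- function(n, density = 0.6) {
  repeat {
    W <- matrix(stats::runif(n * n), n, n) * (matrix(stats::runif(n * n), n, n) < density)
    diag(W) <- 0
    S <- (W + t(W)) / 2
    g <- igraph::graph_from_adjacency_matrix(S > 0, mode = "undirected")
    if (igraph::components(g)$no == 1 && all(rowSums(S) > 0)) return(W)
  }
}
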