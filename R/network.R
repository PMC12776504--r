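conn_weights <- function(x) {
  W <- if (inherits(x, "connectivity_matrix")) x$weights else x
  if (any(W < 0)) stop("connectivity weights must be non-negative")
  if (any(diag(W) != 0)) stop("connectivity diagonal must be zero")
  W
}

# global efficiency of an undirected weighted matrix (all R vertices),
# distances 1/w, unreachable pairs contribute 0
global_efficiency_und <- function(S) {
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  iD <- 1 / D
  diag(iD) <- 0
  R <- nrow(S)
  sum(iD) / (R * (R - 1))
}

#' Binarize a connectivity matrix with orthogonal minimum spanning trees
#'
#' Data-driven thresholding: (1) directed weights are symmetrized by the
#' mean of the two directions; (2) weights map to distances `d = 1/w`;
#' (3) successive minimum spanning trees are extracted, each orthogonal to
#' (excluding the edges of) all previous trees; (4) after each round the
#' aggregated selection is scored by the global cost-efficiency
#' `J = E_glob / E_glob(full) - cost`, where cost is the selected fraction
#' of total weight; (5) the aggregation maximizing `J` is kept; (6) direction
#' is restored — a directed edge is selected iff its symmetrized edge was
#' selected and its directed weight is positive.
#'
#' @param connectivity a `connectivity_matrix` or non-negative matrix with
#'   zero diagonal
#' @param max_rounds cap on MST rounds (default: number of nodes minus 1)
#' @param stop_patience stop after this many consecutive declines of `J`
#' @return a `binary_network`: list with `adjacency` (logical R x R, same
#'   direction convention as the input), `selection_trace` (per-round
#'   data.frame of edge counts, cost, normalized efficiency and `J`),
#'   `rounds_kept`, `labels`
#' @export
omst_binarize <- function(connectivity, max_rounds = NULL, stop_patience = 3) {
  W <- conn_weights(connectivity)
  R <- nrow(W)
  labels <- rownames(W)
  if (is.null(max_rounds)) max_rounds <- R - 1L
  S <- (W + t(W)) / 2
  g0 <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  if (igraph::components(g0)$no > 1)
    stop("positive-weight support is disconnected; OMST cannot span all nodes")
  total_w <- sum(S) / 2
  eff_full <- global_efficiency_und(S)
  Srem <- S
  sel <- matrix(FALSE, R, R)
  trace <- list()
  round_edges <- list()
  decline <- 0L
  best_J <- -Inf
  J_prev <- -Inf
  for (rnd in seq_len(max_rounds)) {
    g <- igraph::graph_from_adjacency_matrix(Srem, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    if (igraph::components(g)$no > 1) break  # residual cannot span any more
    mt <- igraph::mst(g, weights = 1 / igraph::E(g)$weight)
    el <- igraph::as_edgelist(mt, names = FALSE)
    for (k in seq_len(nrow(el))) {
      i <- el[k, 1]; j <- el[k, 2]
      sel[i, j] <- sel[j, i] <- TRUE
      Srem[i, j] <- Srem[j, i] <- 0
    }
    cost <- sum(S[sel]) / 2 / total_w
    eff <- global_efficiency_und(S * sel) / eff_full
    J <- eff - cost
    trace[[rnd]] <- data.frame(round = rnd, n_edges = sum(sel) / 2,
                               cost = cost, efficiency = eff, J = J)
    round_edges[[rnd]] <- el
    if (J > best_J) best_J <- J
    decline <- if (J < J_prev) decline + 1L else 0L
    J_prev <- J
    if (decline >= stop_patience) break
  }
  trace <- do.call(rbind, trace)
  keep <- which.max(trace$J)
  sel_best <- matrix(FALSE, R, R)
  for (rnd in seq_len(keep)) {
    el <- round_edges[[rnd]]
    for (k in seq_len(nrow(el))) {
      sel_best[el[k, 1], el[k, 2]] <- TRUE
      sel_best[el[k, 2], el[k, 1]] <- TRUE
    }
  }
  adj <- sel_best & (W > 0)
  dimnames(adj) <- dimnames(W)
  bn <- list(adjacency = adj, selection_trace = trace, rounds_kept = keep,
             labels = labels)
  class(bn) <- "binary_network"
  bn
}

#' @export
print.binary_network <- function(x, ...) {
  cat("binary_network: ", nrow(x$adjacency), " nodes, ",
      sum(x$adjacency), " directed edges from ", x$rounds_kept,
      " MST round(s)\n", sep = "")
  invisible(x)
}

#' Node strength
#'
#' Sums of incident weights per node. With the package's direction
#' convention (entry `(i, j)` is flow from `j` to `i`), out-strength of node
#' `j` is the column sum and in-strength of node `i` the row sum. An
#' optional OMST mask restricts the sums to selected edges.
#'
#' @param connectivity a `connectivity_matrix` or weight matrix
#' @param direction `"out"`, `"in"` or `"total"`
#' @param mask optional `binary_network` (or logical matrix)
#' @return named numeric vector, one value per node
#' @export
node_strength <- function(connectivity, direction = c("out", "in", "total"),
                          mask = NULL) {
  direction <- match.arg(direction)
  W <- conn_weights(connectivity)
  if (!is.null(mask)) {
    adj <- if (inherits(mask, "binary_network")) mask$adjacency else mask
    W <- W * adj
  }
  out <- switch(direction,
                out = colSums(W),
                `in` = rowSums(W),
                total = colSums(W) + rowSums(W))
  names(out) <- rownames(W)
  out
}

#' Node degree
#'
#' Number of distinct selected directed edges incident to each node
#' (in-degree plus out-degree).
#'
#' @param binary_network a `binary_network` (or logical adjacency matrix)
#' @return named integer vector
#' @export
node_degree <- function(binary_network) {
  adj <- if (inherits(binary_network, "binary_network"))
    binary_network$adjacency else binary_network
  deg <- colSums(adj) + rowSums(adj)
  names(deg) <- rownames(adj)
  deg
}

#' Local efficiency
#'
#' For each node, the mean inverse weighted shortest-path length between the
#' members of its neighbourhood (the union of in- and out-neighbours,
#' excluding the node itself), computed on the subgraph those neighbours
#' induce in the masked weighted network, with edge distances `1/w`. Nodes
#' with fewer than two neighbours score 0; unreachable pairs contribute 0.
#'
#' @param connectivity a `connectivity_matrix` or weight matrix
#' @param mask optional `binary_network` restricting the edges considered
#' @return named numeric vector in `[0, 1]`
#' @export
local_efficiency <- function(connectivity, mask = NULL) {
  W <- conn_weights(connectivity)
  if (!is.null(mask)) {
    adj <- if (inherits(mask, "binary_network")) mask$adjacency else mask
    W <- W * adj
  }
  R <- nrow(W)
  eff <- numeric(R)
  for (v in seq_len(R)) {
    nbrs <- setdiff(union(which(W[v, ] > 0), which(W[, v] > 0)), v)
    if (length(nbrs) < 2) next
    sub <- W[nbrs, nbrs, drop = FALSE]
    # igraph adjacency convention is row -> column; ours is column -> row
    g <- igraph::graph_from_adjacency_matrix(t(sub), mode = "directed",
                                             weighted = TRUE, diag = FALSE)
    D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight, mode = "out")
    iD <- 1 / D
    diag(iD) <- 0
    k <- length(nbrs)
    eff[v] <- sum(iD) / (k * (k - 1))
  }
  names(eff) <- rownames(W)
  eff
}

#' Laterality index of outward connectivity
#'
#' For each homotopic base-region pair, with data in the canonical flipped
#' convention (affected hemisphere = left),
#' `LI = (U - A) / (U + A)` where `A` and `U` are the out-strengths of the
#' affected (left) and unaffected (right) homotopes. Positive values
#' indicate unaffected dominance; pairs with `U + A = 0` are undefined and
#' returned as `NA`.
#'
#' @param connectivity a `connectivity_matrix` or weight matrix with atlas
#'   labels
#' @param mask optional `binary_network` (out-strengths computed on the
#'   masked weighted matrix)
#' @param atlas a `region_atlas`
#' @return named numeric vector over the 14 base regions, in `[-1, 1]` or `NA`
#' @export
laterality_index <- function(connectivity, mask = NULL, atlas = region_atlas()) {
  s_out <- node_strength(connectivity, "out", mask = mask)
  if (is.null(names(s_out))) names(s_out) <- atlas$labels
  n_base <- length(atlas$base)
  li <- numeric(n_base)
  for (b in seq_len(n_base)) {
    A <- s_out[paste0(atlas$base[b], "_L")]
    U <- s_out[paste0(atlas$base[b], "_R")]
    if (is.na(A) || is.na(U)) stop("missing homotope for base region ", atlas$base[b])
    li[b] <- if (A + U == 0) NA_real_ else (U - A) / (U + A)
  }
  names(li) <- atlas$base
  li
}

#' Group-level test of laterality
#'
#' One-sample two-sided test of the mean laterality index against zero,
#' using a t-test when Shapiro-Wilk does not reject normality at 0.05 and a
#' Wilcoxon signed-rank test otherwise. A zero-variance sample is degenerate:
#' it is declared significant when its common value is non-zero (the
#' one-sided limit of the t statistic) and non-significant at exactly zero.
#'
#' @param li numeric vector of per-subject laterality indices (NAs dropped)
#' @param alpha significance threshold (default 0.05)
#' @return list with `mean`, `p_value`, `significant`, `test_used`, `n`
#' @export
li_group_test <- function(li, alpha = 0.05) {
  li <- li[!is.na(li)]
  if (length(li) < 3) stop("need at least 3 subjects")
  if (stats::sd(li) == 0) {
    p <- if (mean(li) == 0) 1 else 0
    return(list(mean = mean(li), p_value = p, significant = p < alpha,
                test_used = "degenerate", n = length(li)))
  }
  gate <- normality_gate(li)
  if (gate == "parametric") {
    tt <- stats::t.test(li, mu = 0)
    res <- list(mean = mean(li), p_value = tt$p.value, test_used = "t")
  } else {
    wt <- stats::wilcox.test(li, mu = 0, exact = FALSE)
    res <- list(mean = mean(li), p_value = wt$p.value, test_used = "wilcoxon")
  }
  res$significant <- res$p_value < alpha
  res$n <- length(li)
  res[c("mean", "p_value", "significant", "test_used", "n")]
}
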