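# Weighted graph metrics on fully weighted undirected networks whose
# weights are absolute Pearson correlations: node/graph strength, Onnela
# geometric-mean clustering, and Brandes betweenness centrality with edge
# lengths 1/w.

check_weight_matrix <- function(w, require_unit = FALSE, tol = 1e-10) {
  if (!is.matrix(w) || nrow(w) != ncol(w)) stop("weights must be square")
  if (anyNA(w)) stop("weights contain NaN")
  if (max(abs(w - t(w))) > tol) {
    stop("contract violation: weight matrix is not symmetric")
  }
  if (any(diag(w) != 0)) stop("contract violation: diagonal must be zero")
  if (min(w) < 0) stop("contract violation: negative weights")
  if (require_unit && max(w) > 1) {
    stop("contract violation: weights above 1 (weights are |PCC|)")
  }
  invisible(w)
}

#' Node strength and graph strength
#'
#' Strength of node i is the sum of the weights of all its connections
#' (the i-th row sum of the weight matrix); the graph strength is the
#' average of the N node strengths.
#'
#' @param weights symmetric non-negative N x N matrix with zero diagonal.
#' @return list with `node` (length-N vector) and `graph` (scalar mean).
#' @export
strength <- function(weights) {
  check_weight_matrix(weights)
  s <- rowSums(weights)
  names(s) <- rownames(weights)
  list(node = s, graph = mean(s))
}

#' Weighted clustering coefficient (Onnela geometric-mean form)
#'
#' \deqn{C_i^w = \frac{1}{k_i (k_i - 1)} \sum_{j \ne h}
#'   (w_{ij} w_{ih} w_{jh})^{1/3}}
#' with \eqn{k_i} the number of neighbours with non-zero weight, computed on
#' the raw |PCC| weights (no normalisation by the maximum weight, so that on
#' a near-uniform correlation network \eqn{C_i^w} stays on the scale of the
#' mean weight).  Nodes with fewer than two neighbours get \eqn{C_i^w = 0};
#' the graph coefficient is the average over all N nodes.
#'
#' @param weights symmetric N x N matrix, entries in [0, 1], zero diagonal.
#' @return list with `node` and `graph`.
#' @export
clustering_coefficient <- function(weights) {
  check_weight_matrix(weights, require_unit = TRUE)
  k <- rowSums(weights > 0)
  w3 <- weights^(1 / 3)
  num <- diag(w3 %*% w3 %*% w3)
  cc <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  names(cc) <- rownames(weights)
  list(node = cc, graph = mean(cc))
}

# Dijkstra from source s on length matrix L (Inf = no edge), with counting
# of all minimal paths; ties resolved within a relative tolerance so that
# equal-length parallel routes are counted fractionally downstream.
# Returns distances, path counts sigma, predecessor lists and the
# settled order (for Brandes' dependency accumulation).
dijkstra_count <- function(L, s, tol = 1e-10) {
  n <- nrow(L)
  d <- rep(Inf, n); d[s] <- 0
  sigma <- numeric(n); sigma[s] <- 1
  preds <- vector("list", n)
  visited <- logical(n)
  order <- integer(0)
  repeat {
    dd <- d; dd[visited] <- Inf
    u <- which.min(dd)
    if (!is.finite(dd[u])) break
    visited[u] <- TRUE
    order <- c(order, u)
    alt <- d[u] + L[u, ]
    eps <- tol * (1 + abs(alt))
    relax <- !visited & is.finite(alt)
    closer <- relax & (alt < d - eps)
    equal <- relax & !closer & (abs(alt - d) <= eps)
    if (any(closer)) {
      d[closer] <- alt[closer]
      sigma[closer] <- sigma[u]
      for (v in which(closer)) preds[[v]] <- u
    }
    if (any(equal)) {
      sigma[equal] <- sigma[equal] + sigma[u]
      for (v in which(equal)) preds[[v]] <- c(preds[[v]], u)
    }
    if (all(visited)) break
  }
  list(d = d, sigma = sigma, preds = preds, order = order)
}

#' All-pairs weighted shortest paths with path counts
#'
#' Edge length is the reciprocal weight 1/w (zero weight = absent edge);
#' disconnected pairs have infinite distance and zero path count.  Path
#' counts include all minimal-length routes, so downstream betweenness can
#' apportion ties fractionally.
#'
#' @param weights symmetric non-negative N x N matrix, zero diagonal.
#' @return list with `distance` and `sigma` (N x N matrices).
#' @export
shortest_paths <- function(weights) {
  check_weight_matrix(weights)
  n <- nrow(weights)
  L <- ifelse(weights > 0, 1 / weights, Inf)
  diag(L) <- Inf
  D <- matrix(Inf, n, n, dimnames = dimnames(weights))
  S <- matrix(0, n, n, dimnames = dimnames(weights))
  for (s in seq_len(n)) {
    r <- dijkstra_count(L, s)
    D[s, ] <- r$d
    S[s, ] <- r$sigma
  }
  diag(D) <- 0
  diag(S) <- 0
  list(distance = D, sigma = S)
}

#' Betweenness centrality of a weighted network
#'
#' Fraction of shortest paths between other node pairs passing through each
#' node, accumulated with Brandes' single-source dependency scheme on the
#' 1/w length graph, and normalised by (N-1)(N-2) ordered source-target
#' pairs so that \eqn{BC_i \in [0, 1]}.  The graph value is the average
#' over all N nodes.
#'
#' @param weights symmetric non-negative N x N matrix, zero diagonal,
#'   N >= 3.
#' @return list with `node` and `graph`.
#' @export
betweenness_centrality <- function(weights) {
  check_weight_matrix(weights)
  n <- nrow(weights)
  if (n < 3) stop("betweenness needs at least 3 nodes (normaliser vanishes)")
  L <- ifelse(weights > 0, 1 / weights, Inf)
  diag(L) <- Inf
  bc <- numeric(n)
  for (s in seq_len(n)) {
    r <- dijkstra_count(L, s)
    delta <- numeric(n)
    for (w in rev(r$order)) {
      coef <- (1 + delta[w]) / r$sigma[w]
      for (v in r$preds[[w]]) delta[v] <- delta[v] + r$sigma[v] * coef
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / ((n - 1) * (n - 2))
  names(bc) <- rownames(weights)
  list(node = bc, graph = mean(bc))
}

#' Summarise a connectivity matrix with all three network metrics
#'
#' @param cm a `connectivity_matrix`.
#' @param metrics subset of `c("clustering", "strength", "betweenness")` to
#'   compute (betweenness is the expensive one on whole-head networks).
#' @return a `network_summary`: list with `scope`, `n_nodes`, per-node
#'   vectors (`cc_node`, `strength_node`, `bc_node`) and graph averages
#'   (`cc_graph`, `strength_graph`, `bc_graph`); metrics not requested are
#'   `NULL`.
#' @export
summarize_network <- function(cm, metrics = c("clustering", "strength",
                                              "betweenness")) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  out <- list(scope = cm$scope, n_nodes = length(cm$labels),
              cc_node = NULL, cc_graph = NA_real_,
              strength_node = NULL, strength_graph = NA_real_,
              bc_node = NULL, bc_graph = NA_real_)
  if ("clustering" %in% metrics) {
    cc <- clustering_coefficient(cm$weights)
    out$cc_node <- cc$node; out$cc_graph <- cc$graph
  }
  if ("strength" %in% metrics) {
    s <- strength(cm$weights)
    out$strength_node <- s$node; out$strength_graph <- s$graph
  }
  if ("betweenness" %in% metrics) {
    b <- betweenness_centrality(cm$weights)
    out$bc_node <- b$node; out$bc_graph <- b$graph
  }
  structure(out, class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("<network_summary> scope=", x$scope, ", ", x$n_nodes, " nodes\n",
      sep = "")
  cat(sprintf("  clustering %.4f | strength %.3f | betweenness %.4f\n",
              x$cc_graph, x$strength_graph, x$bc_graph))
  invisible(x)
}
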