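# Independent brute-force oracles for the graph metrics and ROC analysis.
# These deliberately share no code with the implementation: triple loops,
# exhaustive simple-path enumeration, and direct pair counting.

random_weight_graph <- function(n, density = 0.8) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < density) w[i, j] <- w[j, i] <- runif(1, 0.05, 1)
    }
  }
  w
}

brute_strength <- function(w) {
  n <- nrow(w)
  s <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) s[i] <- s[i] + w[i, j]
  list(node = s, graph = mean(s))
}

brute_clustering <- function(w) {
  n <- nrow(w)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != h && j != i && h != i) {
          acc <- acc + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
        }
      }
    }
    cc[i] <- acc / (k * (k - 1))
  }
  list(node = cc, graph = mean(cc))
}

# all simple paths s -> t with their 1/w lengths (recursive DFS)
enumerate_paths <- function(w, s, t) {
  n <- nrow(w)
  L <- ifelse(w > 0, 1 / w, Inf)
  out <- list()
  rec <- function(v, visited, len, path) {
    if (v == t) {
      out[[length(out) + 1]] <<- list(len = len, path = path)
      return()
    }
    for (u in seq_len(n)) {
      if (!visited[u] && is.finite(L[v, u])) {
        visited[u] <- TRUE
        rec(u, visited, len + L[v, u], c(path, u))
        visited[u] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[s] <- TRUE
  rec(s, visited, 0, s)
  out
}

# minimal-length distance, path count, and per-vertex passage count for an
# ordered pair, with the same relative tie tolerance as the implementation
brute_pair <- function(w, s, t, tol = 1e-10) {
  paths <- enumerate_paths(w, s, t)
  if (length(paths) == 0) {
    return(list(d = Inf, sigma = 0, through = numeric(nrow(w))))
  }
  lens <- vapply(paths, `[[`, numeric(1), "len")
  dmin <- min(lens)
  sel <- which(lens <= dmin + tol * (1 + dmin))
  through <- numeric(nrow(w))
  for (k in sel) {
    interior <- setdiff(paths[[k]]$path, c(s, t))
    through[interior] <- through[interior] + 1
  }
  list(d = dmin, sigma = length(sel), through = through)
}

brute_shortest_paths <- function(w) {
  n <- nrow(w)
  D <- matrix(0, n, n)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      bp <- brute_pair(w, s, t)
      D[s, t] <- bp$d
      S[s, t] <- bp$sigma
    }
  }
  list(distance = D, sigma = S)
}

brute_betweenness <- function(w) {
  n <- nrow(w)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      bp <- brute_pair(w, s, t)
      if (bp$sigma > 0) bc <- bc + bp$through / bp$sigma
    }
  }
  bc <- bc / ((n - 1) * (n - 2))
  list(node = bc, graph = mean(bc))
}

# AUC by direct positive-negative pair counting, ties worth 1/2
brute_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  acc <- 0
  for (p in pos) for (q in neg) acc <- acc + (p > q) + 0.5 * (p == q)
  acc / (length(pos) * length(neg))
}

# trapezoidal integral of an ROC curve (ordered (0,0) -> (1,1))
trapezoid_auc <- function(curve) {
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
}

# tiny synthetic recording for preprocessing tests
toy_recording <- function(data, fs = 250, bad = character(),
                          id = "toy", group = "HC") {
  structure(list(subject_id = id, group = group, data = data, fs = fs,
                 montage_ref = "toy", bad_channels = bad),
            class = "eeg_recording")
}
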