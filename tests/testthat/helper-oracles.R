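# Independent brute-force oracles. These deliberately avoid igraph and the
# package's own code paths: centralities come from explicit enumeration of
# all simple paths, hypergeometric values from exact integer binomial
# coefficients, path sets from a hand-written DFS.

# All simple paths between two vertices of an adjacency matrix, as lists of
# vertex indices, with at most max_edges edges.
oracle_simple_paths <- function(A, from, to, max_edges = nrow(A)) {
  n <- nrow(A)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == to && length(path) > 1) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    if (length(path) - 1 >= max_edges) return(invisible())
    for (u in seq_len(n)) {
      if (A[v, u] == 1 && !(u %in% path)) {
        if (u == to || length(path) < max_edges) walk(c(path, u))
      }
    }
  }
  walk(from)
  out
}

# Degree, betweenness, closeness, clustering by exhaustive enumeration.
# Betweenness: fraction of shortest paths through each interior vertex,
# summed over unordered pairs, normalized by (n-1)(n-2)/2. Closeness:
# (r/sum_d) * (r/(n-1)). Clustering: closed wedges / possible wedges.
oracle_centralities <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  dmat <- matrix(Inf, n, n); diag(dmat) <- 0
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- oracle_simple_paths(A, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1)) - 1L
      dmin <- min(lens)
      dmat[s, t] <- dmat[t, s] <- dmin
      shortest <- paths[lens == dmin]
      sigma <- length(shortest)
      for (p in shortest) {
        interior <- p[-c(1, length(p))]
        for (v in interior) btw[v] <- btw[v] + 1 / sigma
      }
    }
  }
  denom <- (n - 1) * (n - 2) / 2
  btw <- if (denom > 0) btw / denom else rep(0, n)
  clo <- vapply(seq_len(n), function(i) {
    d <- dmat[i, -i]
    r <- sum(is.finite(d))
    if (r == 0) return(0)
    (r / sum(d[is.finite(d)])) * (r / (n - 1))
  }, double(1))
  clu <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, double(1))
  list(degree = deg, betweenness = btw, closeness = clo, clustering = clu)
}

# Exact hypergeometric values from integer binomial coefficients; choose()
# on integers this small is exact in doubles.
oracle_hyper_point <- function(a, b, c, d) {
  choose(b, a) * choose(d, c) / choose(b + d, a + c)
}

# Upper tail by explicit summation over all achievable overlap tables in
# the sampling orientation (population d, successes c, draws b).
oracle_hyper_tail <- function(a, b, c, d) {
  ks <- a:min(b, c)
  sum(vapply(ks, function(k) {
    choose(c, k) * choose(d - c, b - k) / choose(d, b)
  }, double(1)))
}

# Connected check by reachability.
oracle_connected <- function(A) {
  n <- nrow(A)
  seen <- c(1L); frontier <- c(1L)
  while (length(frontier) > 0) {
    nxt <- setdiff(which(colSums(A[frontier, , drop = FALSE]) > 0), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  length(seen) == n
}

# Random adjacency matrix (simple undirected), optionally forced connected
# by resampling.
random_adjacency <- function(n, p = 0.4, connected = TRUE) {
  repeat {
    A <- matrix(0L, n, n)
    up <- which(upper.tri(A))
    A[up] <- stats::rbinom(length(up), 1, p)
    A <- A + t(A)
    if (!connected || oracle_connected(A)) return(A)
  }
}
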