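# Brute-force oracles, independent of the package implementation (and of
# igraph, except where igraph itself is the stated cross-check). All are
# exhaustive-enumeration versions meant for N <= 8.

adj_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (e in edges) {
    a[e[1L], e[2L]] <- 1L
    a[e[2L], e[1L]] <- 1L
  }
  a
}

rand_adj <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  ut <- which(upper.tri(a))
  a[ut] <- rbinom(length(ut), 1L, p)
  a + t(a)
}

# All simple paths s -> t by depth-first enumeration; returns a list of
# integer vectors (each a node sequence).
bf_paths <- function(a, s, t) {
  n <- nrow(a)
  out <- list()
  walk <- function(path, visited) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (w in seq_len(n)) {
      if (a[v, w] == 1L && !visited[w]) {
        visited[w] <- TRUE
        walk(c(path, w), visited)
        visited[w] <- FALSE
      }
    }
  }
  vis <- rep(FALSE, n)
  vis[s] <- TRUE
  walk(s, vis)
  out
}

# Shortest-path matrix from exhaustive path enumeration (Inf when
# disconnected).
bf_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    paths <- bf_paths(a, s, t)
    if (length(paths)) {
      d[s, t] <- d[t, s] <- min(lengths(paths)) - 1L
    }
  }
  d
}

# Betweenness from enumerated geodesics: each pair contributes the
# fraction of its shortest paths passing through the node.
bf_betweenness <- function(a) {
  n <- nrow(a)
  b <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    paths <- bf_paths(a, s, t)
    if (!length(paths)) next
    len <- lengths(paths)
    geo <- paths[len == min(len)]
    for (g in geo) {
      inner <- setdiff(g, c(s, t))
      b[inner] <- b[inner] + 1 / length(geo)
    }
  }
  b
}

bf_clustering <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1L)
    k <- length(nb)
    if (k < 2L) return(0)
    t <- sum(a[nb, nb]) / 2
    2 * t / (k * (k - 1))
  }, 0.0)
}

bf_matching_pair <- function(a, i, j) {
  ni <- setdiff(which(a[i, ] == 1L), c(i, j))
  nj <- setdiff(which(a[j, ] == 1L), c(i, j))
  u <- union(ni, nj)
  if (!length(u)) return(0)
  length(intersect(ni, nj)) / length(u)
}

bf_matching <- function(a) {
  n <- nrow(a)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    m[i, j] <- m[j, i] <- bf_matching_pair(a, i, j)
  m
}

bf_efficiency <- function(a) {
  n <- nrow(a)
  if (n < 2L) return(0)
  d <- bf_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

bf_local_efficiency <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1L)
    if (length(nb) < 2L) return(0)
    bf_efficiency(a[nb, nb, drop = FALSE])
  }, 0.0)
}

bf_cpl <- function(a) {
  d <- bf_distances(a)
  off <- d[upper.tri(d)]
  fin <- off[is.finite(off) & off > 0]
  if (!length(fin)) return(NA_real_)
  mean(fin)
}

bf_rich_club_phi <- function(a) {
  deg <- colSums(a)
  kmax <- max(deg)
  if (kmax < 1) return(data.frame(k = integer(), phi = numeric()))
  ks <- 0:(kmax - 1)
  phi <- vapply(ks, function(k) {
    nodes <- which(deg > k)
    if (length(nodes) < 2L) return(NA_real_)
    sub <- a[nodes, nodes, drop = FALSE]
    (sum(sub) / 2) / (length(nodes) * (length(nodes) - 1) / 2)
  }, 0.0)
  data.frame(k = ks, phi = phi)
}

bf_modularity_q <- function(a, membership) {
  m <- sum(a) / 2
  if (m == 0) return(0)
  deg <- colSums(a)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    q <- q + sum(a[idx, idx]) / 2 / m - (sum(deg[idx]) / (2 * m))^2
  }
  q
}

bf_ks <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)
  fy <- stats::ecdf(y)
  max(abs(fx(grid) - fy(grid)))
}

# Does the package phi(k) curve equal the exhaustive subgraph oracle?
rich_club_curve_oracle_check <- function(a) {
  got <- wiregrow:::rich_club_curve(a)
  want <- bf_rich_club_phi(a)
  nrow(got) == nrow(want) && isTRUE(all.equal(got$phi, want$phi))
}
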