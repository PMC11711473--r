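#' Local (per-node) graph measures
#'
#' Standard binary-graph statistics: degree, local clustering coefficient,
#' betweenness centrality on unweighted shortest paths, nodal edge length
#' (sum of Euclidean lengths of the node's connections), local efficiency
#' (efficiency of the node's neighbourhood subgraph) and mean matching
#' index with all other nodes.
#'
#' @param network a `binary_network` or adjacency matrix.
#' @param distances Euclidean distance matrix; defaults to the network's
#'   geometry. Required only for `nodal_edge_length`.
#' @return data frame with one row per node: `degree`, `clustering`,
#'   `betweenness`, `nodal_edge_length`, `local_efficiency`, `matching`.
#' @export
local_measures <- function(network, distances = NULL) {
  a <- as_adjacency(network)
  n <- nrow(a)
  if (is.null(distances) && inherits(network, "binary_network") &&
      !is.null(network$geometry))
    distances <- network$geometry$dist
  g <- as_igraph(a)
  deg <- as.integer(colSums(a))
  clu <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  nel <- if (is.null(distances)) rep(NA_real_, n)
         else unname(rowSums(a * as.matrix(distances)))
  leff <- local_efficiency(a)
  m <- value_matrix_cpp(a, "matching")
  match_mean <- (rowSums(m)) / (n - 1)
  data.frame(node = seq_len(n), degree = deg, clustering = clu,
             betweenness = btw, nodal_edge_length = nel,
             local_efficiency = leff, matching = match_mean)
}

# Efficiency of each node's neighbourhood subgraph; 0 for degree < 2.
local_efficiency <- function(a) {
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1L)
    if (length(nb) < 2L) next
    sub <- a[nb, nb, drop = FALSE]
    out[i] <- graph_efficiency(sub)
  }
  out
}

# Mean inverse shortest path length over ordered node pairs; disconnected
# pairs contribute 0. Equals 1 on a complete graph.
graph_efficiency <- function(a) {
  n <- nrow(a)
  if (n < 2L) return(0)
  sp <- igraph::distances(as_igraph(a))
  inv <- 1 / sp
  diag(inv) <- 0
  inv[is.infinite(sp)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Global graph measures
#'
#' Density, maximum modularity (Newman spectral bisection with
#' Kernighan-Lin refinement), characteristic path length (mean over
#' connected pairs only) and global efficiency (mean inverse shortest
#' path; disconnected pairs contribute zero). When `rich_nodes` is
#' supplied, edge-class counts and mean lengths (rich / feeder / local)
#' are included.
#'
#' @inheritParams local_measures
#' @param rich_nodes optional integer vector of rich-club node indices.
#' @return Named list of scalars (and the modularity `membership`).
#' @export
global_measures <- function(network, distances = NULL, rich_nodes = NULL) {
  a <- as_adjacency(network)
  n <- nrow(a)
  if (is.null(distances) && inherits(network, "binary_network") &&
      !is.null(network$geometry))
    distances <- network$geometry$dist
  mod <- modularity_spectral(a)
  sp <- igraph::distances(as_igraph(a))
  off <- sp[upper.tri(sp)]
  finite <- off[is.finite(off) & off > 0]
  cpl <- if (length(finite)) mean(finite) else NA_real_
  out <- list(density = network_density(a),
              modularity_q = mod$q,
              membership = mod$membership,
              characteristic_path_length = cpl,
              global_efficiency = graph_efficiency(a))
  if (!is.null(rich_nodes)) {
    cls <- classify_edges(a, rich_nodes, distances)
    out$n_rich <- cls$summary$count[cls$summary$class == "rich"]
    out$n_feeder <- cls$summary$count[cls$summary$class == "feeder"]
    out$n_local <- cls$summary$count[cls$summary$class == "local"]
    out$mean_length_rich <- cls$summary$mean_length[cls$summary$class == "rich"]
    out$mean_length_feeder <- cls$summary$mean_length[cls$summary$class == "feeder"]
    out$mean_length_local <- cls$summary$mean_length[cls$summary$class == "local"]
  }
  out
}

#' Newman spectral modularity with Kernighan-Lin refinement
#'
#' Recursive spectral bisection on the (generalised) modularity matrix:
#' each candidate split takes the sign pattern of the leading eigenvector,
#' is refined by deterministic Kernighan-Lin single-node moves, and is
#' accepted only when it increases modularity. Fully deterministic for a
#' given adjacency.
#'
#' @param network a `binary_network` or adjacency matrix.
#' @return List with `membership` (integer community labels) and `q`
#'   (modularity of that partition).
#' @export
modularity_spectral <- function(network) {
  a <- as_adjacency(network)
  n <- nrow(a)
  m <- sum(a) / 2
  if (m == 0) return(list(membership = rep(1L, n), q = 0))
  k <- colSums(a)
  B <- a - outer(k, k) / (2 * m)

  membership <- rep(1L, n)
  next_label <- 2L
  queue <- list(seq_len(n))
  while (length(queue)) {
    g <- queue[[1L]]; queue <- queue[-1L]
    if (length(g) < 2L) next
    Bg <- B[g, g, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    ev <- eigen(Bg, symmetric = TRUE)
    v <- ev$vectors[, 1L]
    # deterministic sign convention
    nz <- which(abs(v) > 1e-12)
    if (length(nz) && v[nz[1L]] < 0) v <- -v
    s <- ifelse(v >= 0, 1, -1)
    s <- kl_refine(Bg, s)
    dq <- as.numeric(t(s) %*% Bg %*% s) / (4 * m)
    if (dq <= 1e-10 || all(s == s[1L])) next
    grp2 <- g[s < 0]
    membership[grp2] <- next_label
    next_label <- next_label + 1L
    queue <- c(queue, list(g[s > 0]), list(grp2))
  }
  membership <- as.integer(factor(membership))
  list(membership = membership, q = modularity_q(a, membership))
}

# Kernighan-Lin style refinement of a bisection vector s on modularity
# matrix Bg: repeatedly move the single vertex with the best gain (each
# vertex at most once per pass), keep the best configuration seen.
kl_refine <- function(Bg, s) {
  n <- length(s)
  repeat {
    moved <- rep(FALSE, n)
    s_try <- s
    Bs <- as.numeric(Bg %*% s_try)
    best_s <- s
    best_gain <- 0
    cum <- 0
    for (step in seq_len(n)) {
      gains <- diag(Bg) - s_try * Bs
      gains[moved] <- -Inf
      i <- which.max(gains)
      cum <- cum + gains[i]
      Bs <- Bs - 2 * s_try[i] * Bg[, i]
      s_try[i] <- -s_try[i]
      moved[i] <- TRUE
      if (cum > best_gain + 1e-12) {
        best_gain <- cum
        best_s <- s_try
      }
    }
    if (best_gain <= 1e-12) return(s)
    s <- best_s
  }
}

# Modularity Q of a given partition, from its definition.
modularity_q <- function(a, membership) {
  m <- sum(a) / 2
  if (m == 0) return(0)
  k <- colSums(a)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    e_c <- sum(a[idx, idx]) / 2
    d_c <- sum(k[idx])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}
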