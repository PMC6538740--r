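# Independent oracles used across the suite. These deliberately avoid the
# algorithms the package (or igraph) uses: distances come from Floyd-
# Warshall, shortest-path counts from powers of the adjacency matrix, and
# rank-sum p-values from full enumeration of group assignments.

# random simple undirected graph as an adjacency matrix with node names
random_graph_adj <- function(n, p_edge = 0.4) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) a[i, j] <- a[j, i] <- 1L
  }
  dimnames(a) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  a
}

adj_to_network <- function(a) {
  idx <- which(upper.tri(a) & a == 1L, arr.ind = TRUE)
  interaction_network(
    nodes = data.frame(id = rownames(a), kind = "protein",
                       stringsAsFactors = FALSE),
    edges = data.frame(from = rownames(a)[idx[, 1]],
                       to = colnames(a)[idx[, 2]],
                       stringsAsFactors = FALSE)
  )
}

oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1L] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# number of shortest s-t paths = walks of length dist(s,t), via A^d
oracle_path_counts <- function(a, d) {
  n <- nrow(a)
  maxd <- max(d[is.finite(d)])
  pows <- vector("list", max(maxd, 1))
  pows[[1]] <- a
  if (maxd >= 2) for (k in 2:maxd) pows[[k]] <- pows[[k - 1]] %*% a
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s != t && is.finite(d[s, t])) sigma[s, t] <- pows[[d[s, t]]][s, t]
  }
  sigma
}

oracle_betweenness <- function(a) {
  n <- nrow(a)
  if (n < 3) return(setNames(rep(0, n), rownames(a)))
  d <- oracle_distances(a)
  sigma <- oracle_path_counts(a, d)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(d[s, t])) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
    bc[v] <- tot / ((n - 1) * (n - 2) / 2)
  }
  setNames(bc, rownames(a))
}

oracle_closeness <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    reach <- is.finite(d[i, ])
    nc <- sum(reach)
    if (nc > 1) cc[i] <- ((nc - 1) / sum(d[i, reach])) * ((nc - 1) / (n - 1))
  }
  setNames(cc, rownames(a))
}

oracle_mean_neighbour_degree <- function(a) {
  deg <- rowSums(a)
  nc <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    nb <- which(a[i, ] == 1L)
    nc[i] <- if (length(nb)) mean(deg[nb]) else 0
  }
  setNames(nc, rownames(a))
}

# exact two-sided rank-sum p by enumerating all group assignments
oracle_wilcox_exact_p <- function(x, y) {
  all <- c(x, y)
  n1 <- length(x)
  r <- rank(all)
  mu <- n1 * length(y) / 2
  cmb <- combn(length(all), n1)
  w <- apply(cmb, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  w0 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mean(abs(w - mu) >= abs(w0 - mu))
}

# hypergeometric upper tail by direct summation of binomial products
oracle_hypergeom_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

default_spec <- function(seed = 1L) sim_spec(seed = seed)
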