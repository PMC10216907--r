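# Shared fixtures (built in code) and independent brute-force oracles.

path3 <- function() network_from_edges(c("a", "b"), c("b", "c"))

path_n <- function(n) network_from_edges(seq_len(n - 1), seq_len(n - 1) + 1)

star_n <- function(n) network_from_edges(rep("h", n - 1), paste0("l", seq_len(n - 1)))

triangle <- function() network_from_edges(c(1, 2, 3), c(2, 3, 1))

cycle_n <- function(n) network_from_edges(seq_len(n), c(seq_len(n)[-1], 1))

complete_n <- function(n) {
  cm <- utils::combn(n, 2)
  network_from_edges(cm[1, ], cm[2, ])
}

# Toy 5-node graph used to illustrate neighbourhood overlap:
# edges 1-2, 1-3, 1-5, 2-3, 2-4, 3-4.
toy_overlap <- function() {
  network_from_edges(c(1, 1, 1, 2, 2, 3), c(2, 3, 5, 3, 4, 4))
}

# Erdos-Renyi G(n, p); possibly disconnected.
random_er <- function(n, p, seed) {
  cm <- utils::combn(n, 2)
  keep <- rsgnn:::with_seed(seed, stats::runif(ncol(cm)) < p)
  if (!any(keep)) keep[1] <- TRUE
  # nodes absent from every kept edge are dropped; tests needing all n nodes
  # use random_connected instead
  network_from_edges(cm[1, keep], cm[2, keep])
}

# Connected random graph: random spanning tree plus ER extra edges.
random_connected <- function(n, p, seed) {
  rsgnn:::with_seed(seed, {
    tf <- seq.int(2, n)
    tt <- vapply(tf, function(v) sample.int(v - 1, 1), integer(1))
    cm <- utils::combn(n, 2)
    keep <- stats::runif(ncol(cm)) < p
    network_from_edges(c(tf, cm[1, keep]), c(tt, cm[2, keep]))
  })
}

dense_adjacency <- function(g) {
  A <- matrix(0L, g$n, g$n)
  for (r in seq_len(nrow(g$edges))) {
    i <- g$edges[r, 1]; j <- g$edges[r, 2]
    A[i, j] <- 1L; A[j, i] <- 1L
  }
  A
}

# Literal evaluation of the entropy-weight equations, summing node by node;
# independent of the vectorised implementation.
entropy_oracle <- function(g) {
  n <- g$n
  k <- as.numeric(g$deg)
  kbar <- vapply(seq_len(n), function(u) mean(k[g$adj[[u]]]), numeric(1))
  norm01 <- function(x) (x - min(x)) / (max(x) - min(x))
  ent <- function(x) {
    if (max(x) == min(x)) return(1)
    xs <- norm01(x)
    tot <- sum(xs)
    acc <- 0
    for (u in seq_len(n)) {
      p <- xs[u] / tot
      if (p > 0) acc <- acc + p * log(p)
    }
    -acc / log(n)
  }
  Hk <- ent(k); Hkb <- ent(kbar)
  if (abs(2 - Hk - Hkb) < 1e-12) c(Hk, Hkb, 0.5, 0.5)
  else c(Hk, Hkb, (1 - Hk) / (2 - Hk - Hkb), (1 - Hkb) / (2 - Hk - Hkb))
}

# O(n^2) pairwise Kendall tau-a.
kendall_brute <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      s <- s + sign(x[i] - x[j]) * sign(y[i] - y[j])
    }
  }
  s / (n * (n - 1) / 2)
}

# Brute-force betweenness: BFS shortest-path counts per source, then the
# pair-dependency definition applied literally over unordered pairs.
betweenness_brute <- function(g) {
  n <- g$n
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in g$adj[[v]]) {
          if (is.infinite(dist[s, w])) {
            dist[s, w] <- d
            nxt <- c(nxt, w)
          }
          if (dist[s, w] == d) sigma[s, w] <- sigma[s, w] + sigma[s, v]
        }
      }
      frontier <- unique(nxt)
    }
  }
  bc <- numeric(n)
  for (u in seq_len(n)) {
    for (m in seq_len(n - 1)) {
      for (v in seq.int(m + 1, n)) {
        if (m == u || v == u || is.infinite(dist[m, v])) next
        if (dist[m, u] + dist[u, v] == dist[m, v]) {
          bc[u] <- bc[u] + sigma[m, u] * sigma[u, v] / sigma[m, v]
        }
      }
    }
  }
  bc
}

# Mean local clustering (0 for degree < 2) and endpoint-degree Pearson,
# computed by explicit triangle counting / explicit correlation.
stats_brute <- function(g) {
  n <- g$n
  A <- dense_adjacency(g)
  lc <- vapply(seq_len(n), function(u) {
    nb <- g$adj[[u]]
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, numeric(1))
  d1 <- g$deg[g$edges[, 1]]
  d2 <- g$deg[g$edges[, 2]]
  x <- c(d1, d2); y <- c(d2, d1)
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  list(clustering = mean(lc), assortativity = r)
}
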