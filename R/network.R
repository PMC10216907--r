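#' Undirected simple network container
#'
#' An `rs_network` stores an undirected simple graph with a deterministic
#' internal indexing: original node labels are sorted (numerically when every
#' label is an integer string, lexicographically in the C locale otherwise)
#' and mapped to internal indices `1..n`. All matrices and per-node vectors
#' produced by the package follow this internal order, so results do not
#' depend on the order in which edges were supplied.
#'
#' @param from,to vectors of node labels (coerced to character), one edge per
#'   position. Self-loops and duplicate (or reversed-duplicate) edges are
#'   dropped silently; the number of dropped records is available as
#'   `attr(net, "dropped")`.
#' @return an object of class `rs_network` with components:
#'   \describe{
#'     \item{labels}{character vector of original labels in internal order}
#'     \item{n}{node count}
#'     \item{edges}{two-column integer matrix of internal indices, `i < j`}
#'     \item{adj}{adjacency list: sorted integer neighbour vectors}
#'     \item{deg}{integer degree vector}
#'   }
#' @export
network_from_edges <- function(from, to) {
  if (length(from) != length(to)) stopf("from/to length mismatch")
  from <- as.character(from)
  to <- as.character(to)
  labels <- sort_labels(unique(c(from, to)))
  n <- length(labels)
  if (n == 0) stopf("network has no nodes")
  i <- match(from, labels)
  j <- match(to, labels)
  keep <- i != j
  a <- pmin(i[keep], j[keep])
  b <- pmax(i[keep], j[keep])
  key <- (a - 1) * n + b
  dup <- duplicated(key)
  edges <- cbind(a[!dup], b[!dup])
  dropped <- length(from) - nrow(edges)
  net <- build_network(labels, edges)
  attr(net, "dropped") <- dropped
  net
}

sort_labels <- function(x) {
  if (all(grepl("^-?[0-9]+$", x))) {
    x[order(as.numeric(x), method = "radix")]
  } else {
    sort(x, method = "radix")
  }
}

build_network <- function(labels, edges) {
  n <- length(labels)
  storage.mode(edges) <- "integer"
  if (nrow(edges) > 1) edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  adj <- rep(list(integer(0)), n)
  if (nrow(edges) > 0) {
    nb <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
    idx <- as.integer(names(nb))
    adj[idx] <- lapply(nb, function(v) sort(as.integer(v)))
  }
  structure(
    list(labels = labels, n = n, edges = edges, adj = adj,
         deg = vapply(adj, length, integer(1))),
    class = "rs_network"
  )
}

#' @export
print.rs_network <- function(x, ...) {
  cat(sprintf("<rs_network> %d nodes, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}

#' Convert a network to an igraph object
#'
#' Vertices appear in internal index order and carry the original label as
#' the `name` attribute.
#'
#' @param g an `rs_network`
#' @return an [igraph::igraph] undirected graph
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "rs_network"))
  ig <- igraph::make_empty_graph(n = g$n, directed = FALSE)
  if (nrow(g$edges) > 0) ig <- igraph::add_edges(ig, t(g$edges))
  igraph::set_vertex_attr(ig, "name", value = g$labels)
}

#' Read an undirected edge list
#'
#' Lines starting with `#` are comments; blank lines are skipped. The
#' delimiter is auto-detected among space, tab and comma unless given. Each
#' data line must have at least two tokens (extra tokens, e.g. weights, are
#' ignored). Self-loops and duplicate edges are collapsed; the count of
#' dropped records is reported via `message()` and `attr(net, "dropped")`.
#'
#' @param path file path
#' @param delimiter optional single-character delimiter
#' @return an `rs_network`
#' @export
read_edgelist <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stopf("cannot read edge list: '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stopf("edge list '%s' contains no edges", path)
  split_re <- if (is.null(delimiter)) "[,\\s]+" else
    if (delimiter == ",") "," else "[\\s]+"
  toks <- strsplit(trimws(lines), split_re, perl = TRUE)
  bad <- which(vapply(toks, length, integer(1)) < 2)
  if (length(bad) > 0) {
    stopf("parse error in '%s' at line %d: fewer than 2 tokens", path, lineno[bad[1]])
  }
  from <- vapply(toks, `[[`, character(1), 1)
  to <- vapply(toks, `[[`, character(1), 2)
  net <- network_from_edges(from, to)
  if (attr(net, "dropped") > 0) {
    message(sprintf("read_edgelist: dropped %d self-loop/duplicate record(s)",
                    attr(net, "dropped")))
  }
  net
}

#' Write a network as a whitespace-delimited edge list
#'
#' @param g an `rs_network`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_edgelist <- function(g, path) {
  stopifnot(inherits(g, "rs_network"))
  lines <- sprintf("%s %s", g$labels[g$edges[, 1]], g$labels[g$edges[, 2]])
  writeLines(lines, path)
  invisible(path)
}

#' Largest connected component
#'
#' Returns the induced subgraph on the largest connected component, with
#' original labels preserved. Size ties are broken in favour of the component
#' containing the smallest original label (in internal sort order).
#'
#' @param g an `rs_network`
#' @return an `rs_network`
#' @export
largest_connected_component <- function(g) {
  stopifnot(inherits(g, "rs_network"))
  if (g$n == 0) stopf("empty graph")
  comp <- component_ids(g)
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))
  # internal indices are label-sorted, so the component whose first member
  # has the smallest index wins ties
  first <- vapply(best, function(cid) which(comp == cid)[1], integer(1))
  cid <- best[which.min(first)]
  keep <- comp == cid
  subset_network(g, which(keep))
}

component_ids <- function(g) {
  comp <- integer(g$n)
  cid <- 0L
  for (s in seq_len(g$n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      nb <- unique(unlist(g$adj[queue], use.names = FALSE))
      queue <- nb[comp[nb] == 0L]
      comp[queue] <- cid
    }
  }
  comp
}

subset_network <- function(g, idx) {
  idx <- sort(idx)
  labels <- g$labels[idx]
  remap <- integer(g$n)
  remap[idx] <- seq_along(idx)
  keep <- g$edges[, 1] %in% idx & g$edges[, 2] %in% idx
  edges <- cbind(remap[g$edges[keep, 1]], remap[g$edges[keep, 2]])
  if (!is.matrix(edges)) edges <- matrix(edges, ncol = 2)
  build_network(labels, edges)
}

#' Barabasi-Albert scale-free generator
#'
#' Preferential attachment starting from `m_attach` isolated seed nodes; each
#' subsequent node attaches `m_attach` edges to distinct existing nodes with
#' probability proportional to current degree (uniformly while all degrees
#' are zero). The result has exactly `m_attach * (n - m_attach)` edges.
#'
#' @param n node count
#' @param m_attach edges added per new node; must satisfy
#'   `1 <= m_attach < n`
#' @param seed integer seed; the same `(n, m_attach, seed)` always yields the
#'   same graph
#' @return an `rs_network` with labels `"1".."n"`
#' @export
generate_ba <- function(n, m_attach, seed = 1) {
  if (!is_count(n) || !is_count(m_attach) || m_attach < 1 || m_attach >= n) {
    stopf("require 1 <= m_attach < n")
  }
  n <- as.integer(n); m_attach <- as.integer(m_attach)
  with_seed(seed, {
    deg <- integer(n)
    ef <- integer(m_attach * (n - m_attach))
    et <- integer(length(ef))
    pos <- 0L
    for (v in seq.int(m_attach + 1L, n)) {
      existing <- seq_len(v - 1L)
      w <- deg[existing]
      if (sum(w) == 0) w <- rep(1, v - 1L)
      targets <- sample(existing, m_attach, replace = FALSE, prob = w)
      ix <- pos + seq_len(m_attach)
      ef[ix] <- v
      et[ix] <- targets
      pos <- pos + m_attach
      deg[targets] <- deg[targets] + 1L
      deg[v] <- deg[v] + m_attach
    }
    edges <- cbind(pmin(ef, et), pmax(ef, et))
    build_network(as.character(seq_len(n)), edges)
  })
}

#' LFR-style benchmark generator with planted communities
#'
#' Generates a community-structured benchmark in the spirit of the LFR
#' model: node degrees follow a truncated power law with exponent `tau1`,
#' community sizes follow a power law with exponent `tau2`, and each node
#' places a fraction `1 - mu` of its edges inside its own community
#' (configuration-model wiring, multi-edges and self-loops discarded). The
#' returned graph is the largest connected component; the planted community
#' of each surviving node is available as `attr(net, "community")` (named by
#' label).
#'
#' @param n node count before LCC reduction
#' @param tau1 degree power-law exponent (> 1)
#' @param tau2 community-size power-law exponent (> 1)
#' @param mu mixing parameter in (0, 1): target fraction of inter-community
#'   edge stubs per node
#' @param avg_deg target mean degree
#' @param max_deg maximum degree
#' @param seed integer seed
#' @return an `rs_network`
#' @export
generate_lfr <- function(n, tau1 = 3, tau2 = 1.5, mu = 0.1, avg_deg = 8,
                         max_deg = 50, seed = 1) {
  if (!is_count(n) || n < 20) stopf("n must be an integer >= 20")
  if (!(mu > 0 && mu < 1)) stopf("mu must lie in (0, 1)")
  if (tau1 <= 1 || tau2 <= 1) stopf("power-law exponents must exceed 1")
  if (avg_deg <= 1 || avg_deg >= max_deg) stopf("require 1 < avg_deg < max_deg")
  if (max_deg >= n) stopf("max_deg must be below n")
  with_seed(seed, {
    deg <- lfr_degrees(n, tau1, avg_deg, max_deg)
    memb <- lfr_assign(n, deg, tau2, mu, avg_deg)
    edges <- lfr_wire(deg, memb, mu)
    if (nrow(edges) == 0) stopf("LFR parameters produced an empty graph")
    net <- build_network(as.character(seq_len(n)), edges)
    lcc <- largest_connected_component(net)
    comm <- memb[as.integer(lcc$labels)]
    names(comm) <- lcc$labels
    attr(lcc, "community") <- comm
    lcc
  })
}

powerlaw_sample <- function(howmany, exponent, xmin, xmax) {
  support <- seq.int(xmin, xmax)
  sample(support, howmany, replace = TRUE, prob = support^(-exponent))
}

lfr_degrees <- function(n, tau1, avg_deg, max_deg) {
  # pick the smallest kmin whose truncated power-law mean reaches avg_deg
  means <- vapply(seq_len(max_deg - 1), function(kmin) {
    s <- seq.int(kmin, max_deg)
    sum(s * s^(-tau1)) / sum(s^(-tau1))
  }, numeric(1))
  kmin <- which.min(abs(means - avg_deg))
  deg <- powerlaw_sample(n, tau1, kmin, max_deg)
  if (sum(deg) %% 2 == 1) deg[which.min(deg)] <- deg[which.min(deg)] + 1L
  as.integer(deg)
}

lfr_assign <- function(n, deg, tau2, mu, avg_deg) {
  smin <- max(10L, ceiling(avg_deg))
  smax <- max(3L * smin, ceiling(n / 5))
  smax <- min(smax, n)
  sizes <- integer(0)
  while (sum(sizes) < n) {
    sizes <- c(sizes, powerlaw_sample(1, tau2, smin, smax))
  }
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
  if (sizes[length(sizes)] < smin && length(sizes) > 1) {
    sizes[length(sizes) - 1] <- sizes[length(sizes) - 1] + sizes[length(sizes)]
    sizes <- sizes[-length(sizes)]
  }
  cap <- sizes
  memb <- integer(n)
  for (u in order(deg, decreasing = TRUE)) {
    want <- round((1 - mu) * deg[u])
    ok <- which(cap > 0 & sizes - 1 >= want)
    if (length(ok) == 0) ok <- which(cap > 0)
    pick <- if (length(ok) == 1) ok else sample(ok, 1, prob = cap[ok])
    memb[u] <- pick
    cap[pick] <- cap[pick] - 1L
  }
  memb
}

lfr_wire <- function(deg, memb, mu) {
  n <- length(deg)
  d_int <- pmin(round((1 - mu) * deg), tabulate(memb)[memb] - 1L)
  d_ext <- deg - d_int
  ef <- integer(0); et <- integer(0)
  for (cid in sort(unique(memb))) {
    nodes <- which(memb == cid)
    stubs <- rep(nodes, d_int[nodes])
    if (length(stubs) %% 2 == 1) stubs <- stubs[-length(stubs)]
    if (length(stubs) < 2) next
    stubs <- sample(stubs)
    half <- length(stubs) / 2
    ef <- c(ef, stubs[seq_len(half)])
    et <- c(et, stubs[half + seq_len(half)])
  }
  stubs <- rep(seq_len(n), d_ext)
  if (length(stubs) %% 2 == 1) stubs <- stubs[-length(stubs)]
  if (length(stubs) >= 2) {
    stubs <- sample(stubs)
    half <- length(stubs) / 2
    a <- stubs[seq_len(half)]
    b <- stubs[half + seq_len(half)]
    # one reshuffle pass to reduce same-community external pairings
    same <- memb[a] == memb[b]
    if (any(same) && any(!same)) {
      b[same] <- sample(b[same])
    }
    ef <- c(ef, a); et <- c(et, b)
  }
  keep <- ef != et
  a <- pmin(ef[keep], et[keep]); b <- pmax(ef[keep], et[keep])
  dup <- duplicated((a - 1) * n + b)
  cbind(a[!dup], b[!dup])
}

#' Descriptive network statistics
#'
#' Computes the six catalogue-style statistics: node count, edge count, mean
#' degree, maximum degree, clustering coefficient (mean of local clustering
#' coefficients, 0 for nodes of degree < 2) and degree assortativity (degree
#' Pearson correlation over edge endpoints; `NA` when either endpoint degree
#' sequence is constant, e.g. regular graphs).
#'
#' @param g an `rs_network`
#' @return a list of class `network_stats` with fields `n`, `m_edges`,
#'   `avg_degree`, `max_degree`, `clustering`, `assortativity`
#' @export
network_stats <- function(g) {
  stopifnot(inherits(g, "rs_network"))
  m <- nrow(g$edges)
  clustering <- 0
  assort <- NA_real_
  if (m > 0) {
    ig <- as_igraph(g)
    lc <- igraph::transitivity(ig, type = "local", isolates = "zero")
    clustering <- mean(lc)
    assort <- igraph::assortativity_degree(ig, directed = FALSE)
    if (is.nan(assort)) assort <- NA_real_
  }
  structure(
    list(n = g$n, m_edges = m, avg_degree = 2 * m / g$n,
         max_degree = if (g$n > 0) max(g$deg) else 0L,
         clustering = clustering, assortativity = assort),
    class = "network_stats"
  )
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(
    "n=%d  |E|=%d  <k>=%.3f  max_deg=%d  C=%.3f  r=%s\n",
    x$n, x$m_edges, x$avg_degree, x$max_degree, x$clustering,
    if (is.na(x$assortativity)) "NA" else sprintf("%.3f", x$assortativity)))
  invisible(x)
}

stats_as_row <- function(name, st) {
  data.frame(network = name, n = st$n, edges = st$m_edges,
             avg_degree = st$avg_degree, max_degree = st$max_degree,
             clustering = st$clustering, assortativity = st$assortativity,
             stringsAsFactors = FALSE)
}
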