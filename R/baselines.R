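# Classical centrality baselines. Degree centrality and K-shell are
# implemented directly (the peeling procedure is simple and its oracle is
# igraph::coreness); exact betweenness and PageRank are delegated to igraph
# and cross-checked against brute-force oracles in the test suite.

centrality_result <- function(method, g, scores) {
  names(scores) <- g$labels
  ord <- order(-scores, seq_along(scores))
  structure(list(method = method, scores = scores,
                 ranking = g$labels[ord]),
            class = "centrality_result")
}

#' @export
print.centrality_result <- function(x, ...) {
  cat(sprintf("<centrality_result> %s, %d nodes, top: %s\n",
              x$method, length(x$scores),
              paste(utils::head(x$ranking, 5), collapse = " ")))
  invisible(x)
}

#' Degree centrality
#'
#' `DC(u) = k(u) / (n - 1)`.
#'
#' @param g an `rs_network` with `n >= 2`
#' @return a `centrality_result`
#' @export
degree_centrality <- function(g) {
  stopifnot(inherits(g, "rs_network"))
  if (g$n < 2) stopf("degree centrality needs n >= 2")
  centrality_result("DC", g, as.numeric(g$deg) / (g$n - 1))
}

#' K-shell decomposition
#'
#' Iterative peeling: all nodes of current degree at most `s` are removed
#' (cascading until none remain) and assigned shell index `s`, starting at
#' `s = 1`, then `s` is incremented.
#'
#' @param g an `rs_network`
#' @return a `centrality_result` with integer shell indices as scores
#' @export
k_shell <- function(g) {
  stopifnot(inherits(g, "rs_network"))
  deg <- as.integer(g$deg)
  shell <- integer(g$n)
  alive <- rep(TRUE, g$n)
  s <- 1L
  remaining <- g$n
  while (remaining > 0) {
    repeat {
      peel <- which(alive & deg <= s)
      if (length(peel) == 0) break
      shell[peel] <- s
      alive[peel] <- FALSE
      remaining <- remaining - length(peel)
      for (u in peel) {
        nb <- g$adj[[u]]
        nb <- nb[alive[nb]]
        deg[nb] <- deg[nb] - 1L
      }
    }
    s <- s + 1L
  }
  centrality_result("KS", g, as.numeric(shell))
}

#' Betweenness centrality
#'
#' Exact betweenness over unordered pairs, without the pair-count
#' normalisation: `BC(u) = sum_{m != n != u} g_mn(u) / g_mn`, the summed
#' fraction of shortest `m`-`n` paths passing through `u`. Only the rank
#' order matters downstream, so no normalisation is applied.
#'
#' @param g a connected `rs_network`
#' @return a `centrality_result`
#' @export
betweenness_centrality <- function(g) {
  stopifnot(inherits(g, "rs_network"))
  if (max(component_ids(g)) != 1) stopf("betweenness requires a connected graph")
  sc <- igraph::betweenness(as_igraph(g), directed = FALSE, normalized = FALSE)
  centrality_result("BC", g, as.numeric(sc))
}

#' PageRank centrality
#'
#' Power iteration on the undirected graph (each edge treated as two
#' directed edges); scores sum to 1.
#'
#' @param g a connected `rs_network`
#' @param damping damping factor (default 0.85)
#' @param tol convergence tolerance (default 1e-9)
#' @return a `centrality_result`
#' @export
pagerank_centrality <- function(g, damping = 0.85, tol = 1e-9) {
  stopifnot(inherits(g, "rs_network"))
  if (max(component_ids(g)) != 1) stopf("pagerank requires a connected graph")
  pr <- igraph::page_rank(as_igraph(g), damping = damping,
                          options = list(eps = tol))$vector
  centrality_result("PR", g, as.numeric(pr))
}

#' Export a centrality (or model) ranking as CSV
#'
#' Columns `node,score,rank`, the same format as [rsgnn_rank()] output.
#'
#' @param res a `centrality_result`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_ranking_csv <- function(res, path) {
  ord <- match(res$ranking, names(res$scores))
  df <- data.frame(node = res$ranking, score = unname(res$scores[ord]),
                   rank = seq_along(ord), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
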