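#' Epidemic threshold of a network
#'
#' `beta_th = <k> / <k^2>`: mean degree over mean squared degree, reported
#' to two decimal places (rounding half away from zero) and floored at 0.01
#' so extreme graphs never yield a zero infection probability.
#'
#' @param g an `rs_network` with at least one edge
#' @return the threshold probability
#' @export
epidemic_threshold <- function(g) {
  stopifnot(inherits(g, "rs_network"))
  if (nrow(g$edges) == 0) stopf("epidemic threshold undefined for edgeless graph")
  k <- as.numeric(g$deg)
  max(0.01, round_half_away(mean(k) / mean(k^2), 2))
}

# All sn runs for one seed node under its own derived RNG substream. The
# epidemic loop itself lives in src/sir_core.cpp.
sir_runs <- function(g, seed_node, beta, sn, seed) {
  with_seed(derive_seed(seed, seed_node), {
    sir_runs_cpp(g$adj, g$n, as.integer(seed_node), beta, as.integer(sn))
  })
}

#' Monte Carlo SIR influence of a single seed node
#'
#' Runs `sn` independent discrete-time SIR epidemics (recovery probability
#' fixed at 1: each node is infectious for exactly one synchronous
#' generation) seeded at `seed_node` and returns the mean infection ratio
#' `t = mean(N_r) / N`, the standard spreading-influence label. The per-run
#' recovered counts are attached as `attr(, "runs")`.
#'
#' Randomness comes from a substream derived from `(seed, seed_node)`, so
#' results are reproducible and independent of any outer iteration order.
#'
#' @param g an `rs_network`
#' @param seed_node internal node index
#' @param beta infection probability in `[0, 1]`
#' @param sn number of independent runs (default 500)
#' @param seed master integer seed
#' @return mean infection ratio in `[1/N, 1]`
#' @export
simulate_sir <- function(g, seed_node, beta, sn = 500, seed = 1) {
  stopifnot(inherits(g, "rs_network"))
  if (!is_count(seed_node) || seed_node < 1 || seed_node > g$n) {
    stopf("seed_node must be an internal index in 1..n")
  }
  if (beta < 0 || beta > 1) stopf("beta must lie in [0, 1]")
  if (!is_count(sn) || sn < 1) stopf("sn must be a positive integer")
  runs <- sir_runs(g, as.integer(seed_node), beta, sn, seed)
  structure(mean(runs) / g$n, runs = runs)
}

#' SIR influence labels for every node
#'
#' Runs [simulate_sir()] with each node as the sole initial spreader. Each
#' node uses its own RNG substream derived from `seed`, so the label vector
#' does not depend on iteration order.
#'
#' @param g an `rs_network`
#' @param beta infection probability; if `NULL`, resolved from `beta_ratio`
#'   times the network's [epidemic_threshold()]
#' @param beta_ratio multiplier of the epidemic threshold (used when `beta`
#'   is `NULL`; default 1)
#' @param sn runs per node (default 500)
#' @param seed master integer seed
#' @return a list of class `influence_labels`: `t` (named numeric vector of
#'   mean infection ratios, internal order), `beta`, `sn`, `seed`
#' @export
label_all_nodes <- function(g, beta = NULL, beta_ratio = 1, sn = 500, seed = 1) {
  stopifnot(inherits(g, "rs_network"))
  beta <- resolve_beta(g, beta, beta_ratio)
  t <- vapply(seq_len(g$n), function(u) {
    mean(sir_runs(g, u, beta, sn, seed)) / g$n
  }, numeric(1))
  names(t) <- g$labels
  structure(list(t = t, beta = beta, sn = sn, seed = seed),
            class = "influence_labels")
}

resolve_beta <- function(g, beta, beta_ratio) {
  if (is.null(beta)) beta <- beta_ratio * epidemic_threshold(g)
  if (beta > 1) {
    warning("infection probability clamped to 1")
    beta <- 1
  }
  beta
}

#' @export
print.influence_labels <- function(x, ...) {
  cat(sprintf("<influence_labels> %d nodes, beta=%.3g, sn=%d\n",
              length(x$t), x$beta, x$sn))
  invisible(x)
}

#' Exact expected infection ratio by enumeration
#'
#' Brute-force oracle for tiny graphs: with one-generation infectivity the
#' final recovered set equals the bond-percolation cluster of the seed with
#' edge retention probability `beta`, so the expectation is computed by
#' enumerating all `2^|E|` edge subsets. Intended for validation on graphs
#' with at most ~12 edges.
#'
#' @param g an `rs_network`
#' @param seed_node internal node index
#' @param beta infection probability
#' @return exact `E[N_r] / N`
#' @export
enumerate_sir_expectation <- function(g, seed_node, beta) {
  stopifnot(inherits(g, "rs_network"))
  m <- nrow(g$edges)
  if (m > 20) stopf("enumeration limited to <= 20 edges")
  total <- 0
  for (mask in 0:(2^m - 1)) {
    open <- as.logical(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) > 0)
    p <- prod(ifelse(open, beta, 1 - beta))
    sub <- g$edges[open, , drop = FALSE]
    reach <- reach_size(g$n, sub, seed_node)
    total <- total + p * reach
  }
  total / g$n
}

reach_size <- function(n, edges, s) {
  adj <- rep(list(integer(0)), n)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n)
  seen[s] <- TRUE
  queue <- s
  while (length(queue) > 0) {
    nb <- unique(unlist(adj[queue], use.names = FALSE))
    queue <- nb[!seen[nb]]
    seen[queue] <- TRUE
  }
  sum(seen)
}

#' Export influence labels as CSV
#'
#' Columns: `node,label,beta,sn`.
#'
#' @param labels an `influence_labels` object
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_labels_csv <- function(labels, path) {
  df <- data.frame(node = names(labels$t), label = unname(labels$t),
                   beta = labels$beta, sn = labels$sn,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
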