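#' Mean neighbour degree
#'
#' For node `u`, the arithmetic mean of the degrees of its first-order
#' neighbours. The degree and the mean neighbour degree are the two
#' indicators fused into the basic node feature.
#'
#' @param g an `rs_network`
#' @param u internal node index, or `NULL` for every node
#' @return numeric scalar (for one node) or vector in internal order
#' @export
neighbor_avg_degree <- function(g, u = NULL) {
  stopifnot(inherits(g, "rs_network"))
  one <- function(i) {
    nb <- g$adj[[i]]
    if (length(nb) == 0) stopf("node %s is isolated", g$labels[i])
    mean(g$deg[nb])
  }
  if (is.null(u)) vapply(seq_len(g$n), one, numeric(1)) else one(u)
}

#' Entropy weights for the two degree indicators
#'
#' Implements the entropy weight method over the node degree `k(u)` and the
#' mean neighbour degree `kbar(u)`: each indicator is min-max normalised
#' across nodes, turned into probability shares, and scored by its Shannon
#' entropy on the `log(n)` scale. The less uniform (lower-entropy) indicator
#' receives the larger weight:
#' `omega1 = (1 - H_k) / (2 - H_k - H_kbar)` and symmetrically for `omega2`,
#' so `omega1 + omega2 = 1`.
#'
#' Degenerate cases: an indicator that is constant across nodes (min = max)
#' carries no information and is assigned entropy 1, which drives its weight
#' to 0; if both indicators are constant (regular graphs) the weights fall
#' back to 1/2 each. The convention `0 * log(0) = 0` is used for zero
#' shares.
#'
#' @param g an `rs_network` with at least 3 nodes
#' @return a list of class `entropy_weights` with fields `H_k`, `H_kbar`,
#'   `omega1`, `omega2`
#' @export
entropy_weights <- function(g) {
  stopifnot(inherits(g, "rs_network"))
  if (g$n < 3) stopf("entropy weights need n >= 3")
  k <- as.numeric(g$deg)
  kbar <- neighbor_avg_degree(g)
  H_k <- share_entropy(k, g$n)
  H_kbar <- share_entropy(kbar, g$n)
  denom <- 2 - H_k - H_kbar
  if (abs(denom) < 1e-12) {
    omega1 <- 0.5; omega2 <- 0.5
  } else {
    omega1 <- (1 - H_k) / denom
    omega2 <- (1 - H_kbar) / denom
  }
  structure(list(H_k = H_k, H_kbar = H_kbar, omega1 = omega1, omega2 = omega2),
            class = "entropy_weights")
}

# Shannon entropy (log n base) of the min-max-normalised shares of x;
# a constant indicator is maximally uninformative -> entropy 1.
share_entropy <- function(x, n) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(1)
  xn <- (x - rng[1]) / (rng[2] - rng[1])
  p <- xn / sum(xn)
  p <- p[p > 0]
  -sum(p * log(p)) / log(n)
}

#' @export
print.entropy_weights <- function(x, ...) {
  cat(sprintf("H_k=%.4f  H_kbar=%.4f  omega1=%.4f  omega2=%.4f\n",
              x$H_k, x$H_kbar, x$omega1, x$omega2))
  invisible(x)
}

#' Basic node feature B(u)
#'
#' `B(u) = omega1 * k(u) + omega2 * kbar(u)` on the raw (unnormalised)
#' degree scale; min-max normalisation is used only inside the entropy
#' computation, and the model input is batch-normalised separately.
#'
#' @param g an `rs_network`
#' @param w an `entropy_weights` object (or any list with `omega1`,
#'   `omega2`)
#' @return numeric vector of basic features in internal order
#' @export
basic_feature <- function(g, w) {
  stopifnot(inherits(g, "rs_network"))
  if (abs(w$omega1 + w$omega2 - 1) > 1e-9 || w$omega1 < 0 || w$omega2 < 0) {
    stopf("invalid weights: omega1 + omega2 must be 1, both nonnegative")
  }
  w$omega1 * as.numeric(g$deg) + w$omega2 * neighbor_avg_degree(g)
}

#' Fixed-width input feature matrix
#'
#' Row `u` is `[B(u), B(u1), ..., B(u_{width-1})]` where `u1, u2, ...` are
#' the neighbours of `u` sorted by degree (descending, ties broken by
#' ascending internal index, so truncation keeps the best-connected
#' neighbours). Nodes with fewer than `width - 1` neighbours are
#' zero-padded; nodes with more keep only the first `width - 1`.
#'
#' @param g an `rs_network`
#' @param B per-node basic feature vector (internal order)
#' @param width feature dimension (default 24)
#' @return an `n x width` numeric matrix
#' @export
input_features <- function(g, B, width = 24) {
  stopifnot(inherits(g, "rs_network"))
  if (!is_count(width) || width < 2) stopf("width must be an integer >= 2")
  if (length(B) != g$n) stopf("B must have one value per node")
  F <- matrix(0, g$n, width)
  for (u in seq_len(g$n)) {
    nb <- g$adj[[u]]
    if (length(nb) > 0) {
      nb <- nb[order(-g$deg[nb], nb)]
      m <- min(length(nb), width - 1L)
      F[u, 1 + seq_len(m)] <- B[nb[seq_len(m)]]
    }
    F[u, 1] <- B[u]
  }
  F
}

#' Build the full feature bundle for a network
#'
#' Convenience wrapper: entropy weights, basic features and the input
#' feature matrix in one call. `rule` selects the basic-feature definition
#' used by the ablation variants: `"entropy"` is the entropy-weighted fusion
#' `B(u)`; `"degree"` uses the raw degree only (weights 1, 0); `"neighbor"`
#' uses the mean neighbour degree only (weights 0, 1).
#'
#' @param g an `rs_network`
#' @param width feature dimension
#' @param rule one of `"entropy"`, `"degree"`, `"neighbor"`
#' @return a list of class `feature_bundle` with fields `weights`, `basic`,
#'   `features`
#' @export
feature_bundle <- function(g, width = 24, rule = c("entropy", "degree", "neighbor")) {
  rule <- match.arg(rule)
  w <- switch(rule,
    entropy = entropy_weights(g),
    degree = structure(list(H_k = NA_real_, H_kbar = NA_real_,
                            omega1 = 1, omega2 = 0), class = "entropy_weights"),
    neighbor = structure(list(H_k = NA_real_, H_kbar = NA_real_,
                              omega1 = 0, omega2 = 1), class = "entropy_weights"))
  B <- basic_feature(g, w)
  structure(list(weights = w, basic = B, features = input_features(g, B, width)),
            class = "feature_bundle")
}

#' Export an input feature matrix as CSV
#'
#' One row per node: original label, then `f0..f{width-1}`.
#'
#' @param g an `rs_network`
#' @param F feature matrix from [input_features()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_features_csv <- function(g, F, path) {
  df <- data.frame(node = g$labels, F, stringsAsFactors = FALSE)
  names(df) <- c("node", paste0("f", seq_len(ncol(F)) - 1))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
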