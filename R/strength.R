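#' Number of common neighbours of two nodes
#'
#' @param g an `rs_network`
#' @param i,j distinct internal node indices
#' @return integer count `|N(i) intersect N(j)|`
#' @export
common_neighbors <- function(g, i, j) {
  stopifnot(inherits(g, "rs_network"))
  if (i == j) stopf("common_neighbors requires i != j")
  length(intersect(g$adj[[i]], g$adj[[j]]))
}

#' Relationship-strength matrix and normalised propagation operator
#'
#' The relationship strength between nodes is the degree of neighbourhood
#' overlap: `R = (A + I)^2`, so that `R_ii = k(i) + 1`, `R_ij = C_ij + 2`
#' for adjacent pairs and `R_ij = C_ij` for non-adjacent pairs, where
#' `C_ij` counts common neighbours. Adjacent nodes with no other shared
#' neighbour are thus still connected in `R`, and non-adjacent nodes that
#' share neighbours (2-hop pairs) exchange messages too.
#'
#' With `S_i = sum_j R_ij` and `D = diag(S)`, the symmetric propagation
#' operator is `L = D^{-1/2} R D^{-1/2}`, i.e.
#' `L_ij = R_ij / sqrt(S_i S_j)`. Only nonzero entries are materialised
#' (sparse storage); the fill is each node's closed 2-hop neighbourhood.
#'
#' @param g a connected `rs_network` with `n >= 2`
#' @return a list of class `strength_operator` with fields `R` (sparse
#'   integer-valued matrix), `S` (row sums), `L` (sparse operator), `n`,
#'   `labels`
#' @export
strength_matrix <- function(g) {
  stopifnot(inherits(g, "rs_network"))
  if (g$n < 2) stopf("strength_matrix needs n >= 2")
  A <- Matrix::sparseMatrix(
    i = c(g$edges[, 1], g$edges[, 2]),
    j = c(g$edges[, 2], g$edges[, 1]),
    x = 1, dims = c(g$n, g$n))
  M <- A + Matrix::Diagonal(g$n)
  R <- M %*% M
  S <- Matrix::rowSums(R)
  dinv <- Matrix::Diagonal(x = 1 / sqrt(S))
  L <- dinv %*% R %*% dinv
  structure(list(R = methods::as(R, "generalMatrix"), S = S,
                 L = methods::as(L, "generalMatrix"),
                 n = g$n, labels = g$labels),
            class = "strength_operator")
}

#' @export
print.strength_operator <- function(x, ...) {
  cat(sprintf("<strength_operator> n=%d, nnz(R)=%d\n",
              x$n, length(x$R@x)))
  invisible(x)
}

#' Export the relationship-strength matrix as sparse triplets
#'
#' Three-column text file `i j value` using original node labels; one line
#' per nonzero of the upper triangle including the diagonal.
#'
#' @param op a `strength_operator`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_strength_triplets <- function(op, path) {
  T <- methods::as(op$R, "TsparseMatrix")
  keep <- T@i <= T@j
  df <- data.frame(i = op$labels[T@i[keep] + 1], j = op$labels[T@j[keep] + 1],
                   value = T@x[keep])
  utils::write.table(df, path, row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}
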