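# Relationship-strength message-passing model.
#
# Architecture: input batch norm over the feature columns, two
# message-passing layers e' = BatchNorm(e W1 + L e W2) (no extra
# nonlinearity unless `relu = TRUE`), and a fully connected layer to one
# score per node. Training minimises the MSE against SIR influence labels
# with NAdam. Forward, backward and the optimiser are implemented directly
# on base matrices (the operator L stays sparse).

rowbc <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

bn_init <- function(d) {
  list(gamma = rep(1, d), beta = rep(0, d),
       mean = rep(0, d), var = rep(1, d))
}

bn_forward <- function(X, gamma, beta, rmean, rvar, training,
                       eps = 1e-5, momentum = 0.1) {
  n <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    cen <- X - rowbc(mu, n)
    va <- colMeans(cen^2)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * va
  } else {
    mu <- rmean
    va <- rvar
    cen <- X - rowbc(mu, n)
  }
  inv_s <- 1 / sqrt(va + eps)
  xhat <- cen * rowbc(inv_s, n)
  Y <- xhat * rowbc(gamma, n) + rowbc(beta, n)
  list(Y = Y, cache = list(xhat = xhat, inv_s = inv_s, gamma = gamma,
                           training = training),
       mean = rmean, var = rvar)
}

bn_backward <- function(cache, dY) {
  n <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rowbc(cache$gamma, n)
  if (cache$training) {
    dX <- (dxhat * n - rowbc(colSums(dxhat), n) -
             xhat * rowbc(colSums(dxhat * xhat), n)) *
      rowbc(cache$inv_s / n, n)
  } else {
    dX <- dxhat * rowbc(cache$inv_s, n)
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

#' Create an untrained relationship-strength model
#'
#' @param in_dim input feature width (default 24)
#' @param hidden hidden dimensions of the two message-passing layers
#' @param seed integer seed for weight initialisation (uniform fan-in
#'   scaling)
#' @param relu apply a ReLU after each message-passing layer's batch norm;
#'   off by default (the layer update uses batch normalisation only)
#' @param rule basic-feature rule the model expects its inputs to follow
#'   (see [feature_bundle()]); stored so that [rsgnn_rank()] can rebuild
#'   features for new networks
#' @return an object of class `rsgnn_model`
#' @export
rsgnn_model <- function(in_dim = 24, hidden = c(32, 32), seed = 1,
                        relu = FALSE, rule = "entropy") {
  stopifnot(length(hidden) == 2, all(hidden >= 1))
  d <- c(in_dim, as.integer(hidden))
  winit <- function(nin, nout) {
    matrix(stats::runif(nin * nout, -1 / sqrt(nin), 1 / sqrt(nin)), nin, nout)
  }
  params <- with_seed(seed, {
    b0 <- bn_init(d[1]); b1 <- bn_init(d[2]); b2 <- bn_init(d[3])
    list(
      bn0_gamma = b0$gamma, bn0_beta = b0$beta,
      l1_W1 = winit(d[1], d[2]), l1_W2 = winit(d[1], d[2]),
      l1_gamma = b1$gamma, l1_beta = b1$beta,
      l2_W1 = winit(d[2], d[3]), l2_W2 = winit(d[2], d[3]),
      l2_gamma = b2$gamma, l2_beta = b2$beta,
      fc_W = winit(d[3], 1), fc_b = 0
    )
  })
  structure(
    list(dims = d, relu = relu, rule = rule, params = params,
         state = list(bn0_mean = rep(0, d[1]), bn0_var = rep(1, d[1]),
                      l1_mean = rep(0, d[2]), l1_var = rep(1, d[2]),
                      l2_mean = rep(0, d[3]), l2_var = rep(1, d[3])),
         trained = FALSE, loss_history = numeric(0), seed = seed),
    class = "rsgnn_model"
  )
}

#' @export
print.rsgnn_model <- function(x, ...) {
  cat(sprintf("<rsgnn_model> dims %s -> 1, rule=%s, %s\n",
              paste(x$dims, collapse = " -> "), x$rule,
              if (x$trained) sprintf("trained (%d epochs)", length(x$loss_history))
              else "untrained"))
  invisible(x)
}

#' One message-passing layer
#'
#' Computes `BatchNorm(e W1 + L e W2)` where `L` is the normalised
#' relationship-strength operator: each node mixes its own transformed state
#' with overlap-weighted messages `m_{i<-j} = e_j R_ij / sqrt(S_i S_j)` from
#' its 1- and 2-hop neighbours.
#'
#' @param e `n x d` matrix of node states
#' @param op a `strength_operator` for the same graph
#' @param p layer parameters: a list with matrices `W1`, `W2` (both
#'   `d x d'`) and optionally `bn = list(gamma, beta, mean, var, eps)`;
#'   `bn = NULL` disables normalisation
#' @param training logical; with normalisation on, use batch statistics
#'   (`TRUE`) or the supplied running statistics (`FALSE`)
#' @return `n x d'` matrix of updated node states
#' @export
message_passing <- function(e, op, p, training = FALSE) {
  stopifnot(inherits(op, "strength_operator"))
  if (nrow(e) != op$n) stopf("state/operator size mismatch")
  if (nrow(p$W1) != ncol(e) || !identical(dim(p$W1), dim(p$W2))) {
    stopf("W1/W2 shape mismatch with input states")
  }
  Z <- e %*% p$W1 + as.matrix(op$L %*% e) %*% p$W2
  if (is.null(p$bn)) return(Z)
  bn <- p$bn
  bn_forward(Z, bn$gamma, bn$beta,
             bn$mean %||% rep(0, ncol(Z)), bn$var %||% rep(1, ncol(Z)),
             training = training, eps = bn$eps %||% 1e-5)$Y
}

# Full forward pass with caches for backprop. Returns scores (length n),
# caches and the (possibly updated) running-statistics state.
rsgnn_forward_full <- function(model, F, op, training = FALSE) {
  if (ncol(F) != model$dims[1]) {
    stopf("feature width %d does not match model input dim %d",
          ncol(F), model$dims[1])
  }
  p <- model$params; st <- model$state
  L <- op$L
  b0 <- bn_forward(F, p$bn0_gamma, p$bn0_beta, st$bn0_mean, st$bn0_var, training)
  X0 <- b0$Y
  LX0 <- as.matrix(L %*% X0)
  Z1 <- X0 %*% p$l1_W1 + LX0 %*% p$l1_W2
  b1 <- bn_forward(Z1, p$l1_gamma, p$l1_beta, st$l1_mean, st$l1_var, training)
  H1 <- b1$Y
  m1 <- NULL
  if (model$relu) { m1 <- H1 > 0; H1 <- H1 * m1 }
  LH1 <- as.matrix(L %*% H1)
  Z2 <- H1 %*% p$l2_W1 + LH1 %*% p$l2_W2
  b2 <- bn_forward(Z2, p$l2_gamma, p$l2_beta, st$l2_mean, st$l2_var, training)
  H2 <- b2$Y
  m2 <- NULL
  if (model$relu) { m2 <- H2 > 0; H2 <- H2 * m2 }
  scores <- drop(H2 %*% p$fc_W) + p$fc_b
  list(scores = scores,
       cache = list(X0 = X0, H1 = H1, H2 = H2, LX0 = LX0, LH1 = LH1,
                    b0 = b0$cache, b1 = b1$cache, b2 = b2$cache,
                    m1 = m1, m2 = m2, L = L),
       state = list(bn0_mean = b0$mean, bn0_var = b0$var,
                    l1_mean = b1$mean, l1_var = b1$var,
                    l2_mean = b2$mean, l2_var = b2$var))
}

#' Model scores for a feature matrix
#'
#' Evaluation-mode forward pass (running batch-norm statistics, no state
#' update).
#'
#' @param model an `rsgnn_model`
#' @param F `n x in_dim` feature matrix
#' @param op `strength_operator` of the same graph
#' @return numeric vector of `n` scores
#' @export
rsgnn_forward <- function(model, F, op) {
  stopifnot(inherits(model, "rsgnn_model"))
  rsgnn_forward_full(model, F, op, training = FALSE)$scores
}

# MSE loss and parameter gradients for one full-graph batch.
rsgnn_loss_grad <- function(model, F, op, target, training = TRUE) {
  fw <- rsgnn_forward_full(model, F, op, training = training)
  n <- length(target)
  resid <- fw$scores - target
  loss <- mean(resid^2)
  p <- model$params; cc <- fw$cache
  L <- cc$L
  ds <- matrix(2 * resid / n, n, 1)
  g <- list()
  g$fc_W <- t(cc$H2) %*% ds
  g$fc_b <- sum(ds)
  dH2 <- ds %*% t(p$fc_W)
  if (model$relu) dH2 <- dH2 * cc$m2
  bb2 <- bn_backward(cc$b2, dH2)
  g$l2_gamma <- bb2$dgamma; g$l2_beta <- bb2$dbeta
  dZ2 <- bb2$dX
  g$l2_W1 <- t(cc$H1) %*% dZ2
  g$l2_W2 <- t(cc$LH1) %*% dZ2
  dH1 <- dZ2 %*% t(p$l2_W1) + as.matrix(L %*% (dZ2 %*% t(p$l2_W2)))
  if (model$relu) dH1 <- dH1 * cc$m1
  bb1 <- bn_backward(cc$b1, dH1)
  g$l1_gamma <- bb1$dgamma; g$l1_beta <- bb1$dbeta
  dZ1 <- bb1$dX
  g$l1_W1 <- t(cc$X0) %*% dZ1
  g$l1_W2 <- t(cc$LX0) %*% dZ1
  dX0 <- dZ1 %*% t(p$l1_W1) + as.matrix(L %*% (dZ1 %*% t(p$l1_W2)))
  bb0 <- bn_backward(cc$b0, dX0)
  g$bn0_gamma <- bb0$dgamma; g$bn0_beta <- bb0$dbeta
  list(loss = loss, grads = g, state = fw$state, scores = fw$scores)
}

nadam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

nadam_step <- function(params, grads, opt, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - b1^opt$t
  c2 <- 1 - b2^opt$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * gr
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * gr^2
    upd <- (b1 * opt$m[[nm]] / c1 + (1 - b1) * gr / c1) /
      (sqrt(opt$v[[nm]] / c2) + eps)
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, opt = opt)
}

#' Train the relationship-strength model
#'
#' Supervised regression of SIR influence labels. Each training network is
#' presented as one full-graph batch; every epoch performs one NAdam step
#' per network, in the order supplied (e.g. alternately the scale-free and
#' the community-structured generator output). Features and the propagation
#' operator are precomputed per network with that network's own entropy
#' weights.
#'
#' Labels are standardised per network (zero mean, unit variance) before
#' regression: infection ratios live on network-specific scales (they depend
#' on each network's epidemic threshold and size), and forcing one readout
#' to reproduce conflicting raw scales destabilises training badly, while
#' the rank-based evaluation is unaffected by any monotone rescaling.
#'
#' @param train_data list of training cases, each a list with elements
#'   `network` (an `rs_network`) and `labels` (an `influence_labels` or a
#'   numeric vector in internal order)
#' @param epochs training epochs (default 1000; influence labels have tiny
#'   variance, so the fit needs well over a few hundred NAdam steps before
#'   the training MSE drops below the label variance)
#' @param lr learning rate (default 0.001)
#' @param hidden hidden dimensions (default `c(32, 32)`)
#' @param width input feature width (default 24)
#' @param rule basic-feature rule (see [feature_bundle()]); `"entropy"` is
#'   the full model, `"degree"`/`"neighbor"` are the ablation variants
#' @param relu optional ReLU after each layer (default off)
#' @param seed integer seed controlling weight initialisation
#' @return a trained `rsgnn_model` with `loss_history` (summed per-epoch
#'   MSE across networks)
#' @export
rsgnn_train <- function(train_data, epochs = 1000, lr = 0.001,
                        hidden = c(32, 32), width = 24,
                        rule = c("entropy", "degree", "neighbor"),
                        relu = FALSE, seed = 1) {
  rule <- match.arg(rule)
  if (length(train_data) == 0) stopf("no training networks supplied")
  if (!is_count(epochs) || epochs < 1) stopf("epochs must be >= 1")
  if (lr <= 0) stopf("learning rate must be positive")
  prep <- lapply(train_data, function(case) {
    g <- case$network
    stopifnot(inherits(g, "rs_network"))
    lab <- case$labels
    t <- if (inherits(lab, "influence_labels")) lab$t else lab
    if (length(t) != g$n) stopf("labels must cover every node")
    t <- as.numeric(t)
    s <- stats::sd(t)
    t <- if (s > 0) (t - mean(t)) / s else t - mean(t)
    fb <- feature_bundle(g, width = width, rule = rule)
    list(F = fb$features, op = strength_matrix(g), t = t)
  })
  model <- rsgnn_model(in_dim = width, hidden = hidden, seed = seed,
                       relu = relu, rule = rule)
  opt <- nadam_init(model$params)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    total <- 0
    for (case in prep) {
      lg <- rsgnn_loss_grad(model, case$F, case$op, case$t, training = TRUE)
      total <- total + lg$loss
      model$state <- lg$state
      step <- nadam_step(model$params, lg$grads, opt, lr)
      model$params <- step$params
      opt <- step$opt
    }
    history[ep] <- total
  }
  model$trained <- TRUE
  model$loss_history <- history
  model
}

#' Score and rank the nodes of a network with a trained model
#'
#' Rebuilds the network-specific inputs (entropy weights and features under
#' the model's basic-feature rule, and the relationship-strength operator),
#' runs an evaluation-mode forward pass and orders nodes by descending
#' score (ties broken by internal index).
#'
#' @param model a trained `rsgnn_model`
#' @param g an `rs_network`
#' @return a `data.frame` with columns `node`, `score`, `rank`, ordered by
#'   rank
#' @export
rsgnn_rank <- function(model, g) {
  scores <- rsgnn_scores(model, g)
  ord <- order(-scores, seq_along(scores))
  data.frame(node = g$labels[ord], score = unname(scores[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Per-node scores of a trained model on a network
#'
#' @param model a trained `rsgnn_model`
#' @param g an `rs_network`
#' @return named numeric vector of scores in internal order
#' @export
rsgnn_scores <- function(model, g) {
  stopifnot(inherits(model, "rsgnn_model"), inherits(g, "rs_network"))
  if (!model$trained) stopf("model has not been trained")
  fb <- feature_bundle(g, width = model$dims[1], rule = model$rule)
  scores <- rsgnn_forward(model, fb$features, strength_matrix(g))
  names(scores) <- g$labels
  scores
}

#' Serialise a model to a versioned JSON archive
#'
#' All parameter tensors, running statistics, dimensions and training
#' metadata are written as plain JSON, so models survive text-only storage.
#'
#' @param model an `rsgnn_model`
#' @param path output path
#' @return `path`, invisibly
#' @export
save_rsgnn <- function(model, path) {
  stopifnot(inherits(model, "rsgnn_model"))
  payload <- list(
    format = "rsgnn-model", version = 1L,
    dims = model$dims, relu = model$relu, rule = model$rule,
    seed = model$seed, trained = model$trained,
    loss_history = model$loss_history,
    params = model$params, state = model$state)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_rsgnn()]
#'
#' @param path JSON archive path
#' @return an `rsgnn_model`
#' @export
load_rsgnn <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "rsgnn-model")) stopf("'%s' is not a model archive", path)
  d <- as.integer(x$dims)
  shape <- function(p, nr) if (is.matrix(p)) p else matrix(p, nrow = nr)
  params <- x$params
  params$l1_W1 <- shape(params$l1_W1, d[1]); params$l1_W2 <- shape(params$l1_W2, d[1])
  params$l2_W1 <- shape(params$l2_W1, d[2]); params$l2_W2 <- shape(params$l2_W2, d[2])
  params$fc_W <- shape(params$fc_W, d[3])
  structure(
    list(dims = d, relu = isTRUE(x$relu), rule = x$rule, params = params,
         state = lapply(x$state, as.numeric), trained = isTRUE(x$trained),
         loss_history = as.numeric(x$loss_history), seed = x$seed),
    class = "rsgnn_model")
}
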