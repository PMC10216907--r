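test_that("message passing with identity weights returns its input", {
  g <- random_connected(8, 0.3, 1)
  op <- strength_matrix(g)
  e <- matrix(rnorm(8 * 3), 8, 3)
  W1 <- diag(3); W2 <- matrix(0, 3, 3)
  expect_equal(message_passing(e, op, list(W1 = W1, W2 = W2, bn = NULL)), e)
  # frozen unit-statistics batch norm (eps 0) is also the identity
  bn <- list(gamma = rep(1, 3), beta = rep(0, 3), mean = rep(0, 3),
             var = rep(1, 3), eps = 0)
  expect_equal(message_passing(e, op, list(W1 = W1, W2 = W2, bn = bn),
                               training = FALSE), e, tolerance = 1e-12)
})

test_that("matrix form equals the per-node message formulation", {
  for (seed in 1:10) {
    g <- random_connected(10, 0.25, seed)
    op <- strength_matrix(g)
    d_in <- 6; d_out <- 4
    ws <- rsgnn:::with_seed(seed, list(
      W1 = matrix(rnorm(d_in * d_out), d_in, d_out),
      W2 = matrix(rnorm(d_in * d_out), d_in, d_out),
      e = matrix(rnorm(10 * d_in), 10, d_in)))
    out <- message_passing(ws$e, op, list(W1 = ws$W1, W2 = ws$W2, bn = NULL))
    R <- as.matrix(op$R); S <- op$S
    node <- matrix(0, 10, d_out)
    for (i in 1:10) {
      acc <- t(ws$W1) %*% ws$e[i, ]
      for (j in which(R[i, ] != 0)) {
        m_ij <- ws$e[j, ] * R[i, j] / sqrt(S[i] * S[j])
        acc <- acc + t(ws$W2) %*% m_ij
      }
      node[i, ] <- acc
    }
    expect_equal(out, node, tolerance = 1e-6)
  }
})

test_that("forward pass shape, determinism and input validation", {
  g <- generate_ba(40, 3, seed = 2)
  fb <- feature_bundle(g)
  op <- strength_matrix(g)
  m <- rsgnn_model(seed = 4)
  s1 <- rsgnn_forward(m, fb$features, op)
  s2 <- rsgnn_forward(m, fb$features, op)
  expect_length(s1, g$n)
  expect_identical(s1, s2)
  expect_error(rsgnn_forward(m, fb$features[, 1:10], op), "width")
})

test_that("scores are equivariant under node relabelling", {
  # graphs whose neighbour orderings are label-independent (no meaningful
  # degree ties): scores must permute exactly with the labels
  for (g in list(path_n(4), star_n(9))) {
    ren <- setNames(sprintf("q%02d", rev(seq_len(g$n))), g$labels)
    g2 <- network_from_edges(ren[g$labels[g$edges[, 1]]],
                             ren[g$labels[g$edges[, 2]]])
    m <- rsgnn_model(seed = 8)
    s1 <- rsgnn_forward(m, feature_bundle(g)$features, strength_matrix(g))
    s2 <- rsgnn_forward(m, feature_bundle(g2)$features, strength_matrix(g2))
    idx <- match(ren[g$labels], g2$labels)
    expect_equal(s2[idx], s1, tolerance = 1e-9)
  }
})

test_that("autodiff gradients match finite differences", {
  g <- random_connected(6, 0.4, 5)
  fb <- feature_bundle(g, width = 5)
  op <- strength_matrix(g)
  target <- rsgnn:::with_seed(6, runif(6))
  m <- rsgnn_model(in_dim = 5, hidden = c(4, 3), seed = 7)
  lg <- rsgnn:::rsgnn_loss_grad(m, fb$features, op, target, training = TRUE)
  h <- 1e-6
  for (nm in names(lg$grads)) {
    for (idx in seq_len(min(4, length(lg$grads[[nm]])))) {
      mp <- m; mp$params[[nm]][idx] <- mp$params[[nm]][idx] + h
      mm <- m; mm$params[[nm]][idx] <- mm$params[[nm]][idx] - h
      num <- (rsgnn:::rsgnn_loss_grad(mp, fb$features, op, target)$loss -
                rsgnn:::rsgnn_loss_grad(mm, fb$features, op, target)$loss) / (2 * h)
      expect_equal(unname(as.numeric(lg$grads[[nm]])[idx]), num, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss and is seed-reproducible", {
  g <- generate_ba(200, 3, seed = 10)
  lab <- label_all_nodes(g, beta_ratio = 1, sn = 50, seed = 11)
  td <- list(list(network = g, labels = lab))
  m1 <- rsgnn_train(td, epochs = 100, seed = 12)
  expect_lt(utils::tail(m1$loss_history, 1), m1$loss_history[1])
  m2 <- rsgnn_train(td, epochs = 100, seed = 12)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params, m2$params)
  expect_error(rsgnn_train(list()), "no training networks")
})

test_that("ranking is complete, deterministic and label-stable", {
  g <- generate_ba(300, 3, seed = 10)
  lab <- label_all_nodes(g, beta_ratio = 1, sn = 200, seed = 11)
  model <- rsgnn_train(list(list(network = g, labels = lab)),
                       epochs = 1000, seed = 22)
  s <- star_n(12)
  rk <- rsgnn_rank(model, s)
  expect_equal(nrow(rk), s$n)
  expect_equal(sort(rk$node), sort(s$labels))
  expect_equal(rk$node[1], "h") # hub first on a star

  # same structure under permuted labels gives the same original-label order
  ren <- setNames(c("h", sample(paste0("l", 1:11))), s$labels)
  s2 <- network_from_edges(ren[s$labels[s$edges[, 1]]],
                           ren[s$labels[s$edges[, 2]]])
  rk2 <- rsgnn_rank(model, s2)
  expect_equal(rk2$node[1], "h")
  expect_error(rsgnn_rank(rsgnn_model(), s), "trained")
})

test_that("model JSON serialisation round-trips", {
  g <- generate_ba(80, 3, seed = 30)
  lab <- label_all_nodes(g, beta_ratio = 1, sn = 20, seed = 31)
  model <- rsgnn_train(list(list(network = g, labels = lab)),
                       epochs = 50, seed = 32)
  f <- tempfile(fileext = ".json")
  save_rsgnn(model, f)
  back <- load_rsgnn(f)
  unlink(f)
  expect_equal(rsgnn_scores(back, g), rsgnn_scores(model, g), tolerance = 1e-12)
  expect_equal(back$dims, model$dims)
})
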