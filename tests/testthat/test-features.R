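test_that("neighbor_avg_degree matches hand values", {
  s <- star_n(5) # internal order: h, l1..l4
  hub <- which(s$labels == "h")
  expect_equal(neighbor_avg_degree(s, hub), 1)
  expect_equal(neighbor_avg_degree(s, which(s$labels == "l1")), 4)
  p <- path3() # a, b, c
  expect_equal(neighbor_avg_degree(p), c(2, 1, 2))
  expect_error(neighbor_avg_degree(network_from_edges("a", "a"), 1), "isolated")
})

test_that("entropy weights reproduce hand-derived values", {
  w <- entropy_weights(path3())
  expect_equal(w$H_k, 0)
  expect_equal(w$H_kbar, log(2) / log(3), tolerance = 1e-12)
  expect_equal(w$omega1, 1 / (2 - log(2) / log(3)), tolerance = 1e-6)
  expect_equal(w$omega2, 1 - w$omega1, tolerance = 1e-12)

  w <- entropy_weights(star_n(5))
  expect_equal(w$H_k, 0)
  expect_equal(w$H_kbar, log(4) / log(5), tolerance = 1e-12)
  expect_equal(w$omega1, 0.8782354, tolerance = 1e-6)

  # regular graphs: both indicators constant -> equal fallback weights
  for (g in list(cycle_n(6), complete_n(5))) {
    w <- entropy_weights(g)
    expect_equal(w$omega1, 0.5)
    expect_equal(w$omega2, 0.5)
  }
})

test_that("entropy computation matches a literal brute-force oracle", {
  for (seed in 1:12) {
    g <- random_connected(10 + 3 * seed, 0.15, seed)
    w <- entropy_weights(g)
    or <- entropy_oracle(g)
    expect_equal(c(w$H_k, w$H_kbar, w$omega1, w$omega2), or, tolerance = 1e-10)
    expect_equal(w$omega1 + w$omega2, 1, tolerance = 1e-12)
    expect_gte(w$omega1, 0); expect_gte(w$omega2, 0)
  }
})

test_that("basic_feature combines raw degrees with the weights", {
  g <- path3()
  w <- list(omega1 = 0.5, omega2 = 0.5)
  expect_equal(basic_feature(g, w), c(1.5, 1.5, 1.5))
  expect_equal(basic_feature(g, list(omega1 = 1, omega2 = 0)), as.numeric(g$deg))
  wd <- entropy_weights(g)
  expect_equal(basic_feature(g, wd)[2], wd$omega1 * 2 + wd$omega2 * 1,
               tolerance = 1e-12)
  expect_error(basic_feature(g, list(omega1 = 0.7, omega2 = 0.7)), "weights")
})

test_that("adding an edge never decreases B when omega1 > 0", {
  g <- random_connected(15, 0.15, 3)
  w <- entropy_weights(g)
  B <- basic_feature(g, w)
  # add an edge between two non-adjacent nodes; recompute B with the SAME
  # weights and the old neighbour degrees held fixed means k(u) grows by 1
  nonadj <- which(outer(seq_len(g$n), seq_len(g$n), Vectorize(function(i, j) {
    i < j && !(j %in% g$adj[[i]])
  })), arr.ind = TRUE)
  pick <- nonadj[1, ]
  g2 <- network_from_edges(c(g$labels[g$edges[, 1]], g$labels[pick[1]]),
                           c(g$labels[g$edges[, 2]], g$labels[pick[2]]))
  B2 <- basic_feature(g2, w)
  expect_gt(B2[pick[1]], B[pick[1]])
})

test_that("input_features has fixed width, padding and truncation", {
  g <- star_n(31) # hub degree 30
  fb <- feature_bundle(g, width = 24)
  F <- fb$features
  expect_equal(dim(F), c(31, 24))
  hub <- which(g$labels == "h")
  leaf <- which(g$labels == "l1")
  # hub keeps the 23 highest-degree neighbours (all leaves, degree 1)
  expect_true(all(F[hub, -1] == fb$basic[leaf]))
  # each leaf has one neighbour -> 22 trailing zeros
  expect_equal(sum(F[leaf, ] == 0), 22)
  expect_equal(F[leaf, 1], fb$basic[leaf])
  expect_equal(F[leaf, 2], fb$basic[hub])
  expect_error(input_features(g, fb$basic, width = 1), "width")
})

test_that("neighbour ordering is degree-descending with index tie-break", {
  # node 1 adjacent to 2 (deg 3), 3 (deg 2), 4 (deg 2): expect order 2,3,4
  g <- network_from_edges(c(1, 1, 1, 2, 2, 3), c(2, 3, 4, 5, 6, 7))
  B <- seq_len(g$n) * 10
  F <- input_features(g, B, width = 4)
  u1 <- which(g$labels == "1")
  nb <- match(c("2", "3", "4"), g$labels)
  expect_equal(F[u1, ], c(B[u1], B[nb]))
})

test_that("relabelling nodes permutes feature rows identically", {
  relabel <- function(g) {
    ren <- setNames(sprintf("z%02d", rev(seq_len(g$n))), g$labels)
    list(g2 = network_from_edges(ren[g$labels[g$edges[, 1]]],
                                 ren[g$labels[g$edges[, 2]]]),
         ren = ren)
  }
  # exact row equality where neighbour ordering is unambiguous (tie-free
  # neighbour degrees on the 4-path; interchangeable tied leaves on stars)
  for (g in list(path_n(4), star_n(9))) {
    fb <- feature_bundle(g)
    rl <- relabel(g)
    fb2 <- feature_bundle(rl$g2)
    m <- match(rl$ren[g$labels], rl$g2$labels)
    expect_equal(fb2$features[m, ], fb$features, tolerance = 1e-12)
  }
  # in general, same-degree neighbours reorder under relabelling (the
  # tie-break is the internal index), so rows match as multisets and the
  # basic feature permutes exactly
  g <- random_connected(12, 0.2, 8)
  fb <- feature_bundle(g)
  rl <- relabel(g)
  fb2 <- feature_bundle(rl$g2)
  m <- match(rl$ren[g$labels], rl$g2$labels)
  expect_equal(fb2$basic[m], fb$basic, tolerance = 1e-12)
  for (u in seq_len(g$n)) {
    expect_equal(sort(fb2$features[m[u], ]), sort(fb$features[u, ]),
                 tolerance = 1e-12)
  }
})
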