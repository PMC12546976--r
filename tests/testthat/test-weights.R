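test_that("phi combines first- and second-order seed fractions for DE genes", {
  net <- make_network(c("a", "b", "c"), c("b", "c", "d"))
  # path a-b-c-d, seeds {a}, DE {c}: N(c)={b,d}, N2(c)={a}
  phi <- compute_phi(net, seeds = "a", de = "c")
  expect_equal(unname(phi["c"]), 1)
  expect_equal(unname(phi[c("a", "b", "d")]), c(0, 0, 0))
  # DE gene whose every neighbor at both orders is a seed
  star <- make_network(c("h", "h", "x"), c("x", "y", "z"))
  phi2 <- compute_phi(star, seeds = c("x", "y", "z"), de = "h")
  expect_equal(unname(phi2["h"]), 2)
})

test_that("phi matches a breadth-first-search oracle on random graphs", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(8:50, 1)
    net <- random_network(n, p = runif(1, 0.08, 0.3))
    seeds <- sample(net$nodes, sample(1:4, 1))
    de <- sample(net$nodes, sample(1:6, 1))
    expect_equal(compute_phi(net, seeds, de),
                 phi_bfs_oracle(net, seeds, de), tolerance = 1e-12)
  }
})

test_that("phi is invariant under node relabeling", {
  set.seed(37)
  net <- random_network(12, p = 0.3)
  seeds <- sample(net$nodes, 3)
  de <- sample(net$nodes, 4)
  phi <- compute_phi(net, seeds, de)
  relabel <- setNames(sprintf("RN%02d", sample(12)), net$nodes)
  net2 <- make_network(unname(relabel[net$edges$from]),
                       unname(relabel[net$edges$to]))
  phi2 <- compute_phi(net2, unname(relabel[seeds]), unname(relabel[de]))
  expect_equal(unname(phi2[relabel[names(phi)]]), unname(phi))
})

test_that("the personalization vector is a convex mix of normalized scores", {
  theta <- c(a = 4, b = 0, c = 1, d = 0)
  phi <- c(a = 0, b = 1, c = 1, d = 0)
  expect_equal(build_personalization(theta, phi, alpha = 1), theta / 5)
  expect_equal(build_personalization(theta, phi, alpha = 0), phi / 2)
  for (alpha in c(0.25, 0.5, 0.9)) {
    q <- build_personalization(theta, phi, alpha)
    expect_equal(sum(q), 1, tolerance = 1e-12)
    expect_gte(min(q), 0)
  }
  expect_error(build_personalization(c(a = 0, b = 0), c(a = 1, b = 0), 0.5),
               "all zero")
  expect_message(
    qz <- build_personalization(theta, phi * 0, 0.5), "uniform")
  expect_equal(unname(qz), unname(0.5 * theta / 5 + 0.5 * rep(0.25, 4)))
})

test_that("DSI counts shared significant annotations", {
  catalog <- make_catalog(list(s = list(t1 = c("i", "j"), t2 = c("i", "j"),
                                        t3 = c("i", "j", "k"))))
  all3 <- tid("s", c("t1", "t2", "t3"))
  expect_equal(dsi("i", "j", catalog, all3), 3)
  expect_equal(dsi("i", "j", catalog, character(0)), 0L)
  catalog2 <- make_catalog(list(s = list(t1 = "i", t2 = c("i", "j"),
                                         t3 = "j")))
  expect_equal(dsi("i", "j", catalog2, tid("s", c("t2", "t3"))), 1)
})

test_that("annotation edge weights floor at c and vanish off-support", {
  catalog <- make_catalog(list(s = list(t1 = c("a", "b", "x"),
                                        t2 = c("a", "b"), t3 = c("a", "b"))))
  net <- make_network(c("a", "b"), c("b", "x"))
  W1 <- compute_w1(net, catalog, tid("s", c("t1", "t2", "t3")), c = 0.1)
  expect_equal(W1["a", "b"], 3.1)       # three shared significant terms
  expect_equal(W1["b", "x"], 1.1)       # one shared term
  expect_equal(W1["a", "x"], 0)         # non-adjacent
  expect_equal(W1["a", "b"], W1["b", "a"])
  W1f <- compute_w1(net, catalog, character(0), c = 0.1)
  expect_equal(W1f["a", "b"], 0.1)      # floor when nothing shared
})

test_that("co-expression rows normalize, clip negatives, and fall back to uniform", {
  net <- make_network(c("h", "h", "a"), c("a", "b", "b"))
  e <- net$edges
  P <- numeric(nrow(e))
  P[e$from == "a" & e$to == "h"] <- 0.6
  P[e$from == "b" & e$to == "h"] <- 0.2
  P[e$from == "a" & e$to == "b"] <- -0.5
  W2 <- compute_w2(P, net)
  expect_equal(W2["h", "a"], 0.75)
  expect_equal(W2["h", "b"], 0.25)
  expect_equal(unname(Matrix::rowSums(W2)), rep(1, 3))
  # single-neighbor row normalizes to 1 regardless of magnitude
  net1 <- make_network("u", "v")
  expect_equal(compute_w2(0.9, net1)["u", "v"], 1)
  # all-negative neighborhood -> uniform over neighbors
  Wneg <- compute_w2(rep(-0.4, nrow(e)), net)
  expect_equal(Wneg["h", "a"], 0.5)
  expect_equal(Wneg["h", "b"], 0.5)
  # abs mode keeps magnitude instead of clipping
  Wabs <- compute_w2(P, net, negative_corr = "abs")
  expect_equal(Wabs["a", "b"], 0.5 / 1.1, tolerance = 1e-12)
})

test_that("combined edge weights are row-stochastic at every beta", {
  set.seed(41)
  net <- random_network(15, p = 0.3)
  catalog <- make_catalog(list(s = setNames(
    lapply(1:5, function(i) sample(net$nodes, 6)), paste0("t", 1:5))))
  F <- tid("s", paste0("t", 1:5))
  W1 <- compute_w1(net, catalog, F, c = 0.1)
  W2 <- compute_w2(runif(nrow(net$edges), -1, 1), net)
  A <- biorankr:::edge_matrix(net, rep(1, nrow(net$edges)))
  for (beta in c(0, 0.3, 1)) {
    W <- combine_edge_weights(W1, W2, beta)
    expect_equal(unname(Matrix::rowSums(W)), rep(1, 15), tolerance = 1e-12)
    expect_true(all((W != 0) * 1 <= A))  # support inside the edge set
    if (beta > 0) {
      # the c floor keeps every interaction traversable
      expect_true(all((W != 0) == (A != 0)))
    }
  }
  expect_equal(as.matrix(combine_edge_weights(W1, W2, 0)), as.matrix(W2),
               tolerance = 1e-15)
})
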