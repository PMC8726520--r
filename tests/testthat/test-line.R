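test_that("first-order probability matches the sigmoid oracle", {
  expect_equal(first_order_prob(c(1, 0), c(0, 1)), 0.5)
  u <- c(sqrt(log(3)), 0)
  expect_equal(first_order_prob(u, u), 0.75)
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8)
    expect_equal(first_order_prob(a, b), plogis(sum(a * b)),
                 tolerance = 1e-12)
    expect_identical(first_order_prob(a, b), first_order_prob(b, a))
  }
  # clamped, never 0 or 1 even for enormous dot products
  expect_lt(first_order_prob(rep(100, 4), rep(100, 4)), 1)
})

fake_embedding <- function(n, dim, seed = 1) {
  set.seed(seed)
  keys <- paste0("protein:P", seq_len(n))
  mk <- function() {
    m <- matrix(rnorm(n * dim), n, dim, dimnames = list(keys, NULL))
    m
  }
  structure(list(first = mk(), second = mk(), context = mk()),
            class = "line_embedding")
}

test_that("second-order probabilities form exact softmax rows", {
  emb <- fake_embedding(5, 6)
  # uniform when every context vector is zero
  emb0 <- emb; emb0$context[] <- 0
  expect_equal(second_order_prob(1, 3, emb0), 1 / 5)

  for (a in 1:5) {
    p <- vapply(1:5, function(b) second_order_prob(a, b, emb), numeric(1))
    expect_equal(sum(p), 1, tolerance = 1e-9)
    # log-sum-exp oracle
    sc <- drop(emb$context %*% emb$second[a, ])
    expect_equal(p, unname(exp(sc) / sum(exp(sc))), tolerance = 1e-12)
  }
})

test_that("empirical distributions follow edge weights and degrees", {
  tri <- man_graph(association_edges(c("P1", "P2", "P3"),
                                     c("P2", "P3", "P1"), "protein-protein"),
                   require_dd = FALSE)
  emp <- empirical_distributions(tri)
  expect_equal(emp$p1$p, rep(1 / 3, 3))
  expect_equal(emp$p2$p, rep(1 / 2, 6))

  st <- star_graph()
  emp2 <- empirical_distributions(st)
  p2 <- emp2$p2
  expect_equal(p2$p[p2$from == "protein:P1" & p2$to == "drug:D2"], 1 / 4)
  expect_equal(p2$p[p2$from == "drug:D2"], 1)

  g <- small_sim()$graph
  rows <- tapply(empirical_distributions(g)$p2$p,
                 empirical_distributions(g)$p2$from, sum)
  expect_equal(as.numeric(rows), rep(1, length(rows)), tolerance = 1e-9)
  expect_equal(sum(empirical_distributions(g)$p1$p), 1, tolerance = 1e-12)
})

test_that("exact objectives take known values at uninformative embeddings", {
  g <- triangle_graph()
  n <- nrow(g$nodes); m <- nrow(g$edges)
  zero <- list(
    first = matrix(0, n, 8, dimnames = list(g$nodes$key, NULL)),
    second = matrix(0, n, 8, dimnames = list(g$nodes$key, NULL)),
    context = matrix(0, n, 8, dimnames = list(g$nodes$key, NULL)))
  ls <- exact_line_losses(g, zero)
  expect_equal(unname(ls["L1"]), m * log(2))
  expect_equal(unname(ls["L2"]), 2 * m * log(n))

  # single-edge graph at the first-order optimum: p1 -> 1, L1 -> 0
  g1 <- man_graph(association_edges("D1", "dis1", "drug-disease"))
  big <- matrix(10, 2, 4, dimnames = list(g1$nodes$key, NULL))
  ls1 <- exact_line_losses(g1, list(first = big, second = big, context = big))
  expect_lt(unname(ls1["L1"]), 1e-10)
})

test_that("full-gradient descent monotonically reduces both objectives", {
  g <- man_graph(association_edges(c("P1", "P2", "P3", "P4"),
                                   c("P2", "P3", "P4", "P5"),
                                   "protein-protein"), require_dd = FALSE)
  ref <- line_descent_reference(g, dim = 4, steps = 20, lr = 0.05, seed = 3)
  expect_true(all(diff(ref$L1) < 0))
  expect_true(all(diff(ref$L2) < 0))
})

test_that("edge-sampling training is deterministic and reduces the objective", {
  g <- two_clique_graph()
  cfg <- line_config(dim = 16, seed = 11)
  e1 <- train_line(g, cfg)
  e2 <- train_line(g, cfg)
  expect_identical(e1$behavior, e2$behavior)
  e3 <- train_line(g, line_config(dim = 16, seed = 12))
  expect_false(identical(e1$behavior, e3$behavior))

  # trained first-order loss beats a random initialization of equal shape
  init <- fake_embedding(nrow(g$nodes), 8, seed = 5)
  rownames(init$first) <- rownames(init$second) <-
    rownames(init$context) <- g$nodes$key
  init$first <- init$first / 100   # same scale as the trainer's init
  expect_lt(exact_line_losses(g, e1)["L1"],
            exact_line_losses(g, init)["L1"])
})

test_that("trained embeddings separate planted communities", {
  g <- two_clique_graph()
  emb <- train_line(g, line_config(dim = 16, seed = 4))
  a <- paste0("protein:A", 1:10)
  b <- paste0("protein:B", 1:10)
  mean_p1 <- function(keys1, keys2) {
    v <- outer(seq_along(keys1), seq_along(keys2), Vectorize(function(i, j)
      first_order_prob(emb$first[keys1[i], ], emb$first[keys2[j], ])))
    mean(v[v < 1])  # drop self pairs (exactly 1 only if identical keys)
  }
  within <- mean(c(mean_p1(a, a), mean_p1(b, b)))
  between <- mean_p1(a, b)
  expect_gt(within, between + 0.05)

  cos_mat <- function(M) { Mn <- M / sqrt(rowSums(M^2)); Mn %*% t(Mn) }
  for (half in list(emb$first, emb$second)) {
    S <- cos_mat(half[c(a, b), ])
    same <- outer(rep(1:2, each = 10), rep(1:2, each = 10), "==")
    diag(S) <- NA
    expect_gt(mean(S[same], na.rm = TRUE), mean(S[!same]) + 0.05)
  }
})

test_that("training rejects graphs it cannot embed", {
  g <- triangle_graph()
  expect_error(train_line(g, line_config(dim = 15)), "even")
  expect_error(train_line(g, line_config(samples = 1)), "budget")
})
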