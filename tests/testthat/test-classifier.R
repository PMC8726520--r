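test_that("negative sampling is exact, disjoint and seeded", {
  ds <- small_sim()
  pos <- dd_pairs(ds$graph)
  neg <- sample_negatives(pos, ds$graph, seed = 3)
  expect_equal(nrow(neg), nrow(pos))
  expect_length(intersect(paste(neg$drug, neg$disease),
                          paste(pos$drug, pos$disease)), 0L)
  expect_identical(sample_negatives(pos, ds$graph, seed = 3), neg)
  expect_false(identical(sample_negatives(pos, ds$graph, seed = 4), neg))

  # pigeonhole: 2x2 universe with 3 positives cannot yield 3 negatives
  g <- man_graph(association_edges(c("D1", "D1", "D2"),
                                   c("dis1", "dis2", "dis1"), "drug-disease"))
  toomany <- dd_pairs(g)
  expect_error(sample_negatives(toomany, g, seed = 1), "unobserved")
})

test_that("feature fusion yields the documented widths and row order", {
  ds <- small_sim()
  att <- suppressMessages(node_attributes(ds$graph, mesh_table = ds$mesh_table,
    sequences = ds$sequences, drug_table = ds$drug_table, seed = 1))
  emb <- train_line(ds$graph, line_config(seed = 1, samples = 50 * nrow(ds$graph$edges)))
  pairs <- dd_pairs(ds$graph)[1:8, ]
  expect_equal(ncol(fuse_features(pairs, att, emb, "full")), 256L)
  expect_equal(ncol(fuse_features(pairs, att, emb, "attributes")), 128L)
  expect_equal(ncol(fuse_features(pairs, att, emb, "embeddings")), 128L)
  X <- fuse_features(pairs, att, emb, "full")
  expect_equal(nrow(X), 8L)
  # row i is the concatenation for pair i
  k1 <- paste0("drug:", pairs$drug[3])
  expect_equal(unname(X[3, 1:64]), unname(att$values[k1, ]))
  expect_equal(unname(X[3, 65:128]), unname(emb$behavior[k1, ]))

  bad <- data.frame(drug = "NOPE", disease = pairs$disease[1])
  expect_error(fuse_features(bad, att, emb, "full"), "NOPE")
})

test_that("every classifier kind exposes calibrated scores and a seed", {
  toy <- toy_features()
  for (kind in c("random_forest", "adaboost", "logistic", "naive_bayes")) {
    m <- train_classifier(toy$x, toy$y, classifier_spec(kind), seed = 5)
    s <- predict(m, toy$x)
    expect_length(s, nrow(toy$x))
    expect_true(all(s >= 0 & s <= 1))
  }
  # linearly separable data: random forest fits it perfectly
  m <- train_classifier(toy$x, toy$y, classifier_spec("random_forest"), seed = 5)
  expect_equal(as.integer(predict(m, toy$x) >= 0.5), toy$y)
  expect_identical(predict(m, toy$x),
    predict(train_classifier(toy$x, toy$y, classifier_spec(), seed = 5), toy$x))
  expect_error(train_classifier(toy$x, rep(1, nrow(toy$x)), classifier_spec()),
               "both classes")
})

test_that("permuted labels yield chance-level cross-validated AUC", {
  set.seed(21)
  n <- 2000
  x <- matrix(rnorm(n * 10), n, 10)
  y <- rbinom(n, 1, 0.5)   # labels independent of features
  fold <- make_folds(y, k = 5, seed = 22)
  aucs <- vapply(0:4, function(f) {
    m <- train_classifier(x[fold != f, ], y[fold != f],
                          classifier_spec("random_forest"), seed = f + 1)
    roc_auc(predict(m, x[fold == f, ]), y[fold == f])$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("ranking is score-sorted with documented tie-breaks", {
  toy <- toy_features()
  m <- train_classifier(toy$x, toy$y, classifier_spec(), seed = 1)
  one <- data.frame(drug = "DZ", disease = "dis")
  r1 <- predict_ranking(m, one, toy$x[1, , drop = FALSE])
  expect_equal(r1$rank, 1L)

  pairs <- data.frame(drug = c("DB", "DA", "DC"), disease = "dis")
  same_row <- toy$x[c(1, 1, 1), ]
  r <- predict_ranking(m, pairs, same_row)
  expect_equal(length(unique(r$score)), 1L)
  expect_equal(r$drug, c("DA", "DB", "DC"))   # lexicographic on ties

  mixed <- predict_ranking(m, data.frame(drug = paste0("D", 1:6),
                                         disease = "dis"), toy$x[1:6, ])
  expect_equal(mixed$score, sort(mixed$score, decreasing = TRUE))
  expect_equal(mixed$score, unname(predict(m, toy$x[1:6, ])[
    match(mixed$drug, paste0("D", 1:6))]))
})
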