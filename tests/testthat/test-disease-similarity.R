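chain_table <- data.frame(
  descriptor_id = c("A", "B", "C"),
  name = c("a", "b", "c"),
  tree_number = c("T01", "T01.100", "T01.100.200"))

test_that("disease DAGs collect self plus all tree-number ancestors", {
  root <- build_disease_dag("A", chain_table)
  expect_equal(root$members, "A")
  expect_equal(unname(root$depth["A"]), 0L)

  dag <- build_disease_dag("C", chain_table)
  expect_setequal(dag$members, c("A", "B", "C"))
  expect_equal(unname(dag$depth["A"]), 2L)

  # two tree numbers sharing an ancestor: ancestor appears once
  tab <- rbind(chain_table,
               data.frame(descriptor_id = c("D", "C"), name = c("d", "c"),
                          tree_number = c("T01.300", "T01.300.900")))
  dag2 <- build_disease_dag("C", tab)
  expect_setequal(dag2$members, c("A", "B", "C", "D"))
  expect_equal(sum(dag2$members == "A"), 1L)
  expect_equal(unname(dag2$depth["A"]), 2L)   # min over the two paths

  expect_error(build_disease_dag("ZZ", chain_table), "no DAG")
})

test_that("semantic contributions follow the decayed max rule", {
  dag1 <- build_disease_dag("A", chain_table)
  expect_equal(semantic_contribution(dag1, 0.4)$value, 1)

  dag <- build_disease_dag("B", chain_table)
  sc <- semantic_contribution(dag, 0.5)
  expect_equal(unname(sc$contribution["A"]), 0.5)
  expect_equal(sc$value, 1.5)

  # diamond: ancestor reachable at depth 1 and depth 2 takes the shorter
  diamond <- data.frame(
    descriptor_id = c("P", "M", "E", "E"),
    name = c("p", "m", "e", "e"),
    tree_number = c("T01", "T01.100", "T01.200", "T01.100.300"))
  dd <- build_disease_dag("E", diamond)
  sd <- semantic_contribution(dd, 0.5)
  expect_equal(unname(sd$contribution["P"]), 0.5)

  expect_error(semantic_contribution(dag, 1.5), "epsilon")
  expect_error(semantic_contribution(dag, 0), "epsilon")
})

test_that("recursive contributions equal brute-force path enumeration", {
  for (seed in 1:40) {
    tab <- random_mesh_table(n = sample(4:20, 1), seed = seed)
    target <- sample(unique(tab$descriptor_id), 1)
    dag <- build_disease_dag(target, tab)
    eps <- runif(1, 0.2, 0.9)
    got <- semantic_contribution(dag, eps)$contribution
    want <- brute_force_contribution(dag, eps)
    expect_equal(got[order(names(got))], want[order(names(want))],
                 tolerance = 1e-12)
  }
})

test_that("semantic similarity is symmetric, bounded and exact for known cases", {
  tab <- data.frame(descriptor_id = c("P", "E1", "E2"),
                    name = c("p", "e1", "e2"),
                    tree_number = c("T01", "T01.100", "T01.200"))
  c1 <- semantic_contribution(build_disease_dag("E1", tab), 0.5)
  c2 <- semantic_contribution(build_disease_dag("E2", tab), 0.5)
  expect_equal(semantic_similarity(c1, c2), 1 / 3)   # (0.5+0.5)/(1.5+1.5)
  expect_equal(semantic_similarity(c1, c2), semantic_similarity(c2, c1))
  expect_equal(semantic_similarity(c1, c1), 1)

  disjoint <- data.frame(descriptor_id = c("Q", "R"), name = c("q", "r"),
                         tree_number = c("T02", "T03"))
  d1 <- semantic_contribution(build_disease_dag("Q", disjoint), 0.5)
  expect_equal(semantic_similarity(d1,
    semantic_contribution(build_disease_dag("R", disjoint), 0.5)), 0)

  expect_error(semantic_similarity(c1, semantic_contribution(
    build_disease_dag("E2", tab), 0.7)), "epsilon")
})

test_that("similarity never decreases when both DAGs gain a shared ancestor", {
  # base: two root-level diseases (disjoint); extended: both placed under
  # a common parent
  base <- data.frame(descriptor_id = c("E1", "E2"), name = c("e1", "e2"),
                     tree_number = c("T01", "T02"))
  for (eps in c(0.3, 0.5, 0.8)) {
    b1 <- semantic_contribution(build_disease_dag("E1", base), eps)
    b2 <- semantic_contribution(build_disease_dag("E2", base), eps)
    s_before <- semantic_similarity(b1, b2)
    ext <- data.frame(descriptor_id = c("P", "E1", "E2"),
                      name = c("p", "e1", "e2"),
                      tree_number = c("T01", "T01.100", "T01.200"))
    a1 <- semantic_contribution(build_disease_dag("E1", ext), eps)
    a2 <- semantic_contribution(build_disease_dag("E2", ext), eps)
    expect_gte(semantic_similarity(a1, a2), s_before)
  }
})

test_that("the pairwise similarity matrix is symmetric with unit diagonal", {
  tab <- random_mesh_table(n = 15, seed = 3)
  ids <- unique(tab$descriptor_id)[1:8]
  S <- disease_similarity_matrix(ids, tab, 0.5)$similarity
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 8))
  expect_true(all(S >= 0 & S <= 1))

  # a disease listed twice contributes one row; similarity with itself is 1
  S2 <- disease_similarity_matrix(c("E1", "E1"), rbind(
    data.frame(descriptor_id = "R", name = "r", tree_number = "T01"),
    data.frame(descriptor_id = "E1", name = "x", tree_number = "T01.1")),
    0.5)$similarity
  expect_equal(unname(S2), matrix(1, 1, 1))
})

test_that("disease attribute vectors are uniformly 64-wide", {
  ds <- small_sim()
  att <- suppressMessages(node_attributes(ds$graph, mesh_table = ds$mesh_table,
                                          seed = 1))
  keys <- ds$graph$nodes$key[ds$graph$nodes$kind == "disease"]
  expect_equal(ncol(att$values), 64L)
  expect_true(all(is.finite(att$values[keys, ])))

  # > 64 diseases exercises the autoencoder compression path
  comm <- rep(1:4, length.out = 100)
  big <- generate_mesh_table(sprintf("d%03d", 1:100), comm, seed = 2)
  sim <- disease_similarity_matrix(sprintf("d%03d", 1:100), big, 0.5)
  model <- train_sae(sim$similarity, c(100L, 64L), epochs = 5, seed = 1)
  enc <- predict(model, sim$similarity)
  expect_equal(dim(enc), c(100L, 64L))
})
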