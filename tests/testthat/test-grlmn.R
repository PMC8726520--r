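# Shared small dataset for the pipeline tests: built once per file run.
ds <- small_sim(seed = 7)
att <- suppressMessages(node_attributes(ds$graph, mesh_table = ds$mesh_table,
  sequences = ds$sequences, drug_table = ds$drug_table, seed = 7))
fast_line <- line_config(seed = 1, samples = 100 * nrow(ds$graph$edges))

test_that("the fitted model scores pairs and prints sensibly", {
  fit <- suppressMessages(grlmn(ds$graph, att, line = fast_line, seed = 3))
  expect_s3_class(fit, "grlmn")
  sc <- predict(fit)
  expect_length(sc, nrow(fit$pairs))
  expect_true(all(sc >= 0 & sc <= 1))
  # training positives score above training negatives on average
  expect_gt(mean(sc[fit$labels == 1]), mean(sc[fit$labels == 0]))

  out <- capture.output(print(fit))
  expect_match(out[1], "GRLMN")
  s <- summary(fit)
  expect_true(s$training_auc > 0.5)
  expect_match(capture.output(print(s))[1], "GRLMN")

  new <- data.frame(drug = ds$graph$nodes$id[ds$graph$nodes$kind == "drug"][1:3],
                    disease = ds$graph$nodes$id[ds$graph$nodes$kind == "disease"][1])
  expect_length(predict(fit, new), 3L)
})

test_that("cross-validation produces k rows per variant sharing pairs and folds", {
  cv <- suppressMessages(grlmn_cv(ds$graph, att,
    variants = c("full", "attributes", "embeddings"),
    line = fast_line, k = 4, seed = 3))
  expect_equal(nrow(cv$folds), 12L)           # 4 folds x 3 variants
  expect_setequal(unique(cv$folds$fold), 0:3)
  expect_setequal(unique(cv$folds$model), c("GRLMN", "GRLMN_A", "GRLMN_M"))
  # ablations see exactly the same held-out pairs per fold
  sc <- cv$scores
  key <- function(v) paste(sc$fold[sc$variant == v], sc$drug[sc$variant == v],
                           sc$disease[sc$variant == v])
  expect_setequal(key("full"), key("attributes"))
  expect_setequal(key("full"), key("embeddings"))
  # metric columns complete and bounded
  expect_true(all(cv$folds$AUC >= 0 & cv$folds$AUC <= 1))
  expect_true(all(cv$summary$metric %in% c("SEN", "SPE", "PRE", "ACC", "MCC", "AUC")))
  expect_length(cv_mean(cv, "AUC", "full"), 1L)
})

test_that("cross-validation reports are reproducible under one master seed", {
  cv1 <- suppressMessages(grlmn_cv(ds$graph, att, line = fast_line, seed = 11))
  cv2 <- suppressMessages(grlmn_cv(ds$graph, att, line = fast_line, seed = 11))
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$scores, cv2$scores)
  cv3 <- suppressMessages(grlmn_cv(ds$graph, att, line = fast_line, seed = 12))
  expect_false(identical(cv1$folds, cv3$folds))
})

test_that("the single-embedding protocol is available and distinct", {
  cv_safe <- suppressMessages(grlmn_cv(ds$graph, att, line = fast_line,
                                       seed = 5, leakage_safe = TRUE))
  cv_paper <- suppressMessages(grlmn_cv(ds$graph, att, line = fast_line,
                                        seed = 5, leakage_safe = FALSE))
  expect_false(identical(cv_safe$folds$AUC, cv_paper$folds$AUC))
  expect_true(cv_paper$leakage_safe == FALSE)
})

test_that("cv reports serialize to the documented files", {
  cv <- suppressMessages(grlmn_cv(ds$graph, att, line = fast_line, seed = 2))
  dir <- withr::local_tempdir()
  write_cv_report(cv, dir)
  expect_true(all(file.exists(file.path(dir,
    c("folds.tsv", "summary.tsv", "roc_points.csv")))))
  back <- read.delim(file.path(dir, "folds.tsv"))
  expect_equal(nrow(back), nrow(cv$folds))
})

test_that("disease ranking deletes the query's edges and recovers planted partners", {
  # choose the disease with the most held-out true partners
  held <- small_sim(seed = 7)$heldout
  tab <- sort(table(held$disease), decreasing = TRUE)
  target <- names(tab)[1]
  expect_gte(tab[[1]], 1L)

  ranked <- suppressMessages(grlmn_rank(ds$graph, att, target,
    top_n = 100L, line = fast_line, seed = 9))
  expect_true(all(c("drug", "disease", "score", "rank") %in% names(ranked)))
  expect_equal(ranked$score, sort(ranked$score, decreasing = TRUE))
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
  # none of the query disease's former direct edges influenced the fit:
  # every drug is scorable, including its former partners
  expect_setequal(ranked$disease, target)

  expect_error(suppressMessages(grlmn_rank(ds$graph, att, "made-up-disease",
    line = fast_line)), "known ids")
})

test_that("ranking places held-out true partners well above random", {
  big <- simulate_man(man_sim_spec(), seed = 15)
  batt <- suppressMessages(node_attributes(big$graph,
    mesh_table = big$mesh_table, sequences = big$sequences,
    drug_table = big$drug_table, seed = 15))
  # query diseases with several held-out partners whose attribute
  # placement agrees with their community (the generator's attribute
  # noise deliberately breaks this agreement for a minority of nodes)
  tab <- sort(table(big$heldout$disease), decreasing = TRUE)
  branch_of <- function(d) as.integer(sub("^C0*(\\d+)\\..*$", "\\1",
    big$mesh_table$tree_number[big$mesh_table$descriptor_id == d][1]))
  clean <- Filter(function(d)
    branch_of(d) == big$community[paste0("disease:", d)], names(tab))
  targets <- utils::head(clean, 2)
  pct <- unlist(lapply(targets, function(target) {
    partners <- big$heldout$drug[big$heldout$disease == target]
    r <- suppressMessages(grlmn_rank(big$graph, batt, target,
                                     top_n = 1000L, seed = 15))
    r$rank[match(partners, r$drug)] / nrow(r)
  }))
  expect_lt(mean(pct), 0.35)
})
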