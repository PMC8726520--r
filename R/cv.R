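# Stratified five-fold cross-validation with leakage-safe per-fold
# re-embedding: each fold's held-out positive edges are removed from the
# MAN before LINE runs, so test signal cannot reach the features.

#' Cross-validate a drug-disease association model
#'
#' Builds the labeled pair set (known associations plus 1:1 sampled
#' negatives), assigns stratified folds, and for every fold removes the
#' held-out positive edges from the graph (leakage-safe default),
#' re-trains the embedding, fits the classifier on the remaining folds
#' and scores the held-out fold.  Several feature variants can be
#' evaluated in one call; they share pairs, folds, negatives and per-fold
#' embeddings, differing only in feature columns.
#'
#' @param g A `man_graph`.
#' @param attributes A [node_attributes()] object for `g`.
#' @param variants Character subset of `"full"`, `"attributes"`,
#'   `"embeddings"`.
#' @param classifier A [classifier_spec()] or classifier kind name.
#' @param line A [line_config()].
#' @param k Number of folds.
#' @param leakage_safe If `TRUE` (default), re-embed per fold without the
#'   held-out positive edges; if `FALSE`, embed the full graph once (the
#'   optimistic single-embedding protocol).
#' @param seed Master seed.
#' @return Object of class `grlmn_cv`: `folds` (per-variant per-fold
#'   metric rows), `summary` (per-variant mean and sd), `roc`
#'   (per-variant per-fold ROC points), `scores` (per-variant data frame
#'   of held-out scores and labels), plus the call configuration.
#' @export
grlmn_cv <- function(g, attributes, variants = "full",
                     classifier = classifier_spec(), line = line_config(),
                     k = 5L, leakage_safe = TRUE, seed = 1L) {
  stopifnot(inherits(g, "man_graph"))
  variants <- match.arg(variants, c("full", "attributes", "embeddings"),
                        several.ok = TRUE)
  if (is.character(classifier)) classifier <- classifier_spec(classifier)
  seeds <- stage_seeds(seed)

  positives <- drop_flagged_pairs(dd_pairs(g), attributes)
  negatives <- drop_flagged_pairs(
    sample_negatives(positives, g, seed = seeds$negatives), attributes)
  pairs <- rbind(positives, negatives)
  labels <- rep(c(1L, 0L), c(nrow(positives), nrow(negatives)))
  fold <- make_folds(labels, k = k, seed = seeds$folds)

  need_emb <- any(variants != "attributes")
  emb_full <- if (need_emb && !leakage_safe) {
    cfg <- line; cfg$seed <- seeds$line
    train_line(g, cfg)
  } else NULL

  fold_rows <- list(); roc_list <- list(); score_list <- list()
  for (f in sort(unique(fold))) {
    test <- fold == f
    held_pos <- pairs[test & labels == 1L, , drop = FALSE]
    emb <- if (!need_emb) NULL
           else if (leakage_safe) {
      gf <- drop_dd_edges(g, held_pos)
      # leakage guard: none of the held-out positives survives as an edge
      still <- dd_pairs(gf)
      if (any(paste(still$drug, still$disease) %in%
              paste(held_pos$drug, held_pos$disease)))
        stop(sprintf("leakage: held-out edge present in fold %d embedding graph", f))
      cfg <- line; cfg$seed <- seeds$line + 10L * f
      train_line(gf, cfg)
    } else emb_full

    # pairs whose endpoints dropped out of the fold graph cannot be scored
    usable <- rep(TRUE, nrow(pairs))
    if (need_emb) {
      dk <- node_key(normalize_id(pairs$drug, "drug"), "drug")
      sk <- node_key(normalize_id(pairs$disease, "disease"), "disease")
      usable <- dk %in% rownames(emb$behavior) & sk %in% rownames(emb$behavior)
      if (!all(usable))
        message(sprintf("fold %d: %d pair(s) unscorable (node isolated without held-out edges)",
                        f, sum(!usable)))
    }
    for (v in variants) {
      tr <- !test & usable
      te <- test & usable
      X_tr <- fuse_features(pairs[tr, ], attributes, emb, v)
      X_te <- fuse_features(pairs[te, ], attributes, emb, v)
      model <- train_classifier(X_tr, labels[tr], classifier,
                                seed = seeds$classifier + f)
      sc <- predict(model, X_te)
      cc <- confusion_counts(sc, labels[te])
      ra <- roc_auc(sc, labels[te])
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        variant = v, model = variant_label(v), fold = f,
        t(compute_metrics(cc["tp"], cc["fp"], cc["tn"], cc["fn"])),
        AUC = ra$auc, n_test = sum(te))
      roc_list[[paste(v, f)]] <- cbind(variant = v, fold = f, ra$roc)
      score_list[[length(score_list) + 1L]] <- data.frame(
        variant = v, fold = f, pairs[te, ], score = sc, label = labels[te])
    }
  }
  folds_df <- do.call(rbind, fold_rows)
  rownames(folds_df) <- NULL
  metric_cols <- c("SEN", "SPE", "PRE", "ACC", "MCC", "AUC")
  summ <- do.call(rbind, lapply(split(folds_df, folds_df$variant), function(d)
    data.frame(variant = d$variant[1], model = d$model[1],
               metric = metric_cols,
               mean = vapply(metric_cols, function(m) mean(d[[m]]), numeric(1)),
               sd = vapply(metric_cols, function(m) stats::sd(d[[m]]), numeric(1)))))
  rownames(summ) <- NULL
  structure(list(folds = folds_df, summary = summ,
                 roc = do.call(rbind, roc_list),
                 scores = do.call(rbind, score_list),
                 variants = variants, k = k, leakage_safe = leakage_safe,
                 classifier = classifier, line = line, seed = as.integer(seed)),
            class = "grlmn_cv")
}

#' Mean cross-validated value of one metric
#'
#' @param cv A `grlmn_cv`.
#' @param metric One of `SEN`, `SPE`, `PRE`, `ACC`, `MCC`, `AUC`.
#' @param variant Feature variant to read.
#' @return The across-fold mean.
#' @export
cv_mean <- function(cv, metric = "AUC", variant = "full") {
  s <- cv$summary
  s$mean[s$variant == variant & s$metric == metric]
}

#' @export
print.grlmn_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s, %s embedding protocol)\n",
              x$k, x$classifier$kind,
              if (x$leakage_safe) "leakage-safe" else "single"))
  s <- x$summary
  for (v in unique(s$variant)) {
    d <- s[s$variant == v, ]
    cat(sprintf("  %-8s %s\n", d$model[1],
                paste(sprintf("%s %.4f±%.4f", d$metric, d$mean, d$sd),
                      collapse = "  ")))
  }
  invisible(x)
}

#' @export
summary.grlmn_cv <- function(object, ...) object$summary

#' Plot cross-validated ROC curves
#'
#' One panel per variant, one curve per fold, mean AUC in the legend.
#'
#' @param x A `grlmn_cv`.
#' @param ... Passed to [plot()].
#' @export
plot.grlmn_cv <- function(x, ...) {
  vs <- unique(x$roc$variant)
  op <- graphics::par(mfrow = c(1, length(vs)))
  on.exit(graphics::par(op))
  for (v in vs) {
    d <- x$roc[x$roc$variant == v, ]
    plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "false positive rate",
         ylab = "true positive rate",
         main = sprintf("%s (mean AUC %.3f)", variant_label(v),
                        cv_mean(x, "AUC", v)), ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
    for (f in unique(d$fold))
      graphics::lines(d$fpr[d$fold == f], d$tpr[d$fold == f],
                      col = f + 2L)
  }
  invisible(x)
}

#' Write a cross-validation metrics report
#'
#' Emits a per-fold TSV, a summary TSV and per-fold ROC points.
#'
#' @param cv A `grlmn_cv`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cv_report <- function(cv, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cv$folds, file.path(dir, "folds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cv$summary, file.path(dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cv$roc, file.path(dir, "roc_points.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
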