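# The fitted model: LINE behavior vectors over the MAN plus 64-dim node
# attributes, fused per drug-disease pair and classified (random forest
# by default).

variant_label <- function(variant) {
  switch(variant, full = "GRLMN", attributes = "GRLMN_A",
         embeddings = "GRLMN_M")
}

# Derive per-stage seeds from one master seed (kept below 2^31).
stage_seeds <- function(seed) {
  base <- (as.integer(seed) %% 1000003L) * 1009L
  list(negatives = base + 1L, folds = base + 2L, line = base + 3L,
       classifier = base + 4L, attributes = base + 5L)
}

# Drop pairs whose drug or disease carries a flagged (missing) attribute.
drop_flagged_pairs <- function(pairs, attributes) {
  if (!length(attributes$flagged)) return(pairs)
  bad <- names(attributes$flagged)
  dk <- node_key(normalize_id(pairs$drug, "drug"), "drug")
  sk <- node_key(normalize_id(pairs$disease, "disease"), "disease")
  keep <- !(dk %in% bad | sk %in% bad)
  if (!all(keep))
    message(sprintf("excluded %d pair(s) with flagged attributes", sum(!keep)))
  pairs[keep, , drop = FALSE]
}

#' Fit a drug-disease association model
#'
#' Trains LINE behavior vectors on the full MAN, samples unobserved
#' drug-disease pairs as negatives (1:1), fuses attribute and behavior
#' features per pair and fits the classifier.
#'
#' @param g A `man_graph`.
#' @param attributes A [node_attributes()] object for `g`.
#' @param variant `"full"` (attributes + embeddings), `"attributes"`
#'   (GRLMN_A ablation) or `"embeddings"` (GRLMN_M ablation).
#' @param classifier A [classifier_spec()] or the name of a classifier
#'   kind.
#' @param line A [line_config()]; its seed is overridden by the derived
#'   stage seed.
#' @param seed Master seed; derives every stage seed.
#' @param exclude_negatives Optional data frame `drug`, `disease` of
#'   pairs to keep out of the sampled negative set (see
#'   [sample_negatives()]).
#' @return Object of class `grlmn`: the fitted classifier, the
#'   embedding, the training pairs and labels, plus configuration.
#' @export
grlmn <- function(g, attributes, variant = c("full", "attributes", "embeddings"),
                  classifier = classifier_spec(), line = line_config(),
                  seed = 1L, exclude_negatives = NULL) {
  variant <- match.arg(variant)
  if (is.character(classifier)) classifier <- classifier_spec(classifier)
  seeds <- stage_seeds(seed)
  positives <- drop_flagged_pairs(dd_pairs(g), attributes)
  if (!nrow(positives)) stop("no usable positive drug-disease pairs")
  negatives <- sample_negatives(positives, g, seed = seeds$negatives,
                                exclude = exclude_negatives)
  negatives <- drop_flagged_pairs(negatives, attributes)
  pairs <- rbind(positives, negatives)
  labels <- rep(c(1L, 0L), c(nrow(positives), nrow(negatives)))

  line$seed <- seeds$line
  embedding <- if (variant == "attributes") NULL else train_line(g, line)
  X <- fuse_features(pairs, attributes, embedding, variant)
  model <- train_classifier(X, labels, classifier, seed = seeds$classifier)

  structure(list(classifier = model, embedding = embedding,
                 attributes = attributes, graph = g,
                 pairs = pairs, labels = labels, variant = variant,
                 spec = classifier, line = line, seed = as.integer(seed)),
            class = "grlmn")
}

#' @export
print.grlmn <- function(x, ...) {
  cat(sprintf("%s drug-disease association model (%s classifier)\n",
              variant_label(x$variant), x$spec$kind))
  cat(sprintf("  trained on %d pairs (%d positive) over %d nodes / %d edges\n",
              nrow(x$pairs), sum(x$labels), nrow(x$graph$nodes),
              nrow(x$graph$edges)))
  invisible(x)
}

#' Score drug-disease pairs with a fitted model
#'
#' @param object A `grlmn` model.
#' @param pairs Data frame `drug`, `disease`; defaults to the training
#'   pairs.
#' @param ... Unused.
#' @return Numeric association scores in \[0, 1\].
#' @export
predict.grlmn <- function(object, pairs = NULL, ...) {
  if (is.null(pairs)) pairs <- object$pairs
  X <- fuse_features(pairs, object$attributes, object$embedding,
                     object$variant)
  predict(object$classifier, X)
}

#' @export
summary.grlmn <- function(object, ...) {
  sc <- predict(object)
  cc <- confusion_counts(sc, object$labels)
  out <- list(variant = variant_label(object$variant),
              classifier = object$spec$kind,
              n_pairs = nrow(object$pairs),
              training_metrics = compute_metrics(cc["tp"], cc["fp"],
                                                 cc["tn"], cc["fn"]),
              training_auc = roc_auc(sc, object$labels)$auc)
  class(out) <- "summary.grlmn"
  out
}

#' @export
print.summary.grlmn <- function(x, ...) {
  cat(sprintf("%s (%s): %d training pairs\n", x$variant, x$classifier,
              x$n_pairs))
  cat("  apparent (training) metrics:\n")
  print(round(c(x$training_metrics, AUC = x$training_auc), 4))
  invisible(x)
}

#' Rank candidate drugs for one disease
#'
#' Case-study-style query: removes every known drug association of the
#' disease from the MAN, re-embeds, trains on the remaining associations
#' and scores all drugs against the disease; the removed edges are
#' asserted absent from the embedding graph.
#'
#' @param g A `man_graph`.
#' @param attributes A [node_attributes()] object.
#' @param disease Disease id (normalized internally).
#' @param top_n Rows to return.
#' @param variant,classifier,line,seed As in [grlmn()].
#' @return Data frame `drug`, `disease`, `score`, `rank` (descending
#'   score; ties broken by drug id).
#' @export
grlmn_rank <- function(g, attributes, disease, top_n = 20L,
                       variant = "full", classifier = classifier_spec(),
                       line = line_config(), seed = 1L) {
  disease <- normalize_id(disease, "disease")
  key <- node_key(disease, "disease")
  if (!key %in% g$nodes$key) {
    near <- utils::head(g$nodes$id[g$nodes$kind == "disease"], 5)
    stop(sprintf("unknown disease '%s'; known ids include: %s", disease,
                 paste(near, collapse = ", ")))
  }
  known <- dd_pairs(g)
  held <- known[known$disease == disease, , drop = FALSE]
  g2 <- drop_dd_edges(g, held)
  still <- dd_pairs(g2)
  stopifnot(!any(still$disease == disease))
  # the query's candidate pairs are the prediction targets: none of them
  # may enter training as a sampled negative
  all_cand <- data.frame(drug = g$nodes$id[g$nodes$kind == "drug"],
                         disease = disease, stringsAsFactors = FALSE)
  fit <- grlmn(g2, attributes, variant = variant, classifier = classifier,
               line = line, seed = seed, exclude_negatives = all_cand)
  drugs <- sort(g2$nodes$id[g2$nodes$kind == "drug"])
  flagged <- names(attributes$flagged)
  drugs <- drugs[!node_key(drugs, "drug") %in% flagged]
  cand <- data.frame(drug = drugs, disease = disease,
                     stringsAsFactors = FALSE)
  X <- fuse_features(cand, attributes, fit$embedding, fit$variant)
  ranked <- predict_ranking(fit$classifier, cand, X)
  utils::head(ranked, top_n)
}
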