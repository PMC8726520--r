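# Labeled drug-disease pair assembly: negative sampling, feature fusion,
# stratified folds.

#' Sample negative drug-disease pairs
#'
#' Draws unobserved (drug, disease) pairs uniformly without replacement
#' until the negative set matches the positive set 1:1; negatives never
#' collide with a known positive.
#'
#' @param positives Data frame with columns `drug`, `disease`.
#' @param g A `man_graph` supplying the drug and disease universes.
#' @param seed Integer seed.
#' @param ratio Negatives per positive (default 1).
#' @param exclude Optional data frame `drug`, `disease` of additional
#'   pairs kept out of the negative pool (e.g. the candidate pairs of a
#'   ranking query, which must not be trained on as negatives).
#' @return Data frame `drug`, `disease` of sampled negatives.
#' @export
sample_negatives <- function(positives, g, seed = 1L, ratio = 1,
                             exclude = NULL) {
  stopifnot(nrow(positives) >= 1L)
  drugs <- g$nodes$id[g$nodes$kind == "drug"]
  diseases <- g$nodes$id[g$nodes$kind == "disease"]
  if (length(drugs) < 2L || length(diseases) < 2L)
    stop("need at least 2 drugs and 2 diseases")
  n_need <- round(nrow(positives) * ratio)
  pos_key <- paste(positives$drug, positives$disease)
  if (!is.null(exclude) && nrow(exclude))
    pos_key <- c(pos_key, paste(exclude$drug, exclude$disease))
  all_pairs <- expand.grid(drug = drugs, disease = diseases,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cand <- all_pairs[!paste(all_pairs$drug, all_pairs$disease) %in% pos_key, ,
                    drop = FALSE]
  if (nrow(cand) < n_need)
    stop(sprintf("only %d unobserved pairs available; %d negatives requested",
                 nrow(cand), n_need))
  pick <- with_local_seed(seed, sample.int(nrow(cand), n_need))
  out <- cand[pick, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified cross-validation folds
#'
#' @param labels 0/1 integer vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold ids in `0:(k-1)`, stratified by label (per-class
#'   fold sizes differ by at most 1).
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.integer(labels)
  if (any(table(labels) < k))
    stop(sprintf("each class needs at least %d members for %d folds", k, k))
  fold <- integer(length(labels))
  with_local_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(0:(k - 1L), length(idx)))
    }
  })
  fold
}

#' Fuse attribute and embedding features for drug-disease pairs
#'
#' Full rows are `drug attribute (64) | drug behavior (64) | disease
#' attribute (64) | disease behavior (64)` (width 256); the
#' attributes-only and embeddings-only ablations keep the corresponding
#' 128 columns.
#'
#' @param pairs Data frame `drug`, `disease`.
#' @param attributes A `node_attributes` object (see [node_attributes()]).
#' @param embedding A `line_embedding`.
#' @param variant `"full"`, `"attributes"` or `"embeddings"`.
#' @return Numeric feature matrix, one row per pair.
#' @export
fuse_features <- function(pairs, attributes, embedding,
                          variant = c("full", "attributes", "embeddings")) {
  variant <- match.arg(variant)
  dk <- node_key(normalize_id(pairs$drug, "drug"), "drug")
  sk <- node_key(normalize_id(pairs$disease, "disease"), "disease")
  grab <- function(mat, keys, what) {
    miss <- setdiff(keys, rownames(mat))
    if (length(miss))
      stop(sprintf("no %s for node '%s'", what, miss[1]))
    mat[keys, , drop = FALSE]
  }
  blocks <- list()
  if (variant %in% c("full", "attributes")) {
    A <- attributes$values
    blocks$drug_attr <- grab(A, dk, "attribute")
    blocks$dis_attr <- grab(A, sk, "attribute")
  }
  if (variant %in% c("full", "embeddings")) {
    E <- embedding$behavior
    blocks$drug_emb <- grab(E, dk, "embedding")
    blocks$dis_emb <- grab(E, sk, "embedding")
  }
  ord <- switch(variant,
    full = c("drug_attr", "drug_emb", "dis_attr", "dis_emb"),
    attributes = c("drug_attr", "dis_attr"),
    embeddings = c("drug_emb", "dis_emb"))
  X <- do.call(cbind, blocks[ord])
  colnames(X) <- unlist(lapply(ord, function(b)
    paste0(b, "_", seq_len(ncol(blocks[[b]])))))
  rownames(X) <- NULL
  X
}
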