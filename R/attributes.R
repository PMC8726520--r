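# Per-node 64-dim attribute vectors: disease semantic-similarity profiles
# (autoencoder-compressed, or zero-padded when there are at most 64
# diseases), grouped 3-mer composition for protein/miRNA/lncRNA
# sequences, and autoencoder-compressed circular fingerprints for drugs.

ATTR_DIM <- 64L

#' Compute attribute vectors for every node of a MAN
#'
#' Nodes whose raw attribute is unavailable (disease without a MeSH DAG,
#' sequence shorter than 3 usable residues, unparseable SMILES, or simply
#' absent from the input tables) keep a zero vector and are flagged;
#' flagged drugs and diseases are excluded from classifier training by
#' the pipeline.  Ids present in the attribute inputs but not in the
#' graph are kept out of the graph (a warning reports them) since an
#' isolated node cannot be embedded.
#'
#' @param g A `man_graph`.
#' @param mesh_table MeSH descriptor table (see [read_mesh_table()]), or
#'   `NULL`.
#' @param sequences Named character vector of protein/ncRNA sequences
#'   (names = node ids), or `NULL`.
#' @param drug_table Data frame `drug_id`, `smiles`, or `NULL`.
#' @param epsilon Semantic-contribution decay, see
#'   [semantic_contribution()].
#' @param sae A [sae_config()] for the two compression steps.
#' @param seed Integer seed (drives autoencoder training).
#' @return Object of class `node_attributes`: `values` (matrix nodes x
#'   64, rownames = node keys), `flagged` (keys without a usable
#'   attribute, with reasons), `epsilon`.
#' @export
node_attributes <- function(g, mesh_table = NULL, sequences = NULL,
                            drug_table = NULL, epsilon = 0.5,
                            sae = sae_config(), seed = 1L) {
  stopifnot(inherits(g, "man_graph"))
  nodes <- g$nodes
  V <- matrix(0, nrow(nodes), ATTR_DIM,
              dimnames = list(nodes$key, paste0("a", seq_len(ATTR_DIM))))
  flagged <- character(0)
  flag <- function(key, why) {
    flagged[key] <<- why
  }

  # --- diseases: pairwise semantic similarity -> 64-wide rows ----------
  dis <- nodes$id[nodes$kind == "disease"]
  if (length(dis) && !is.null(mesh_table)) {
    mesh_table$descriptor_id <- normalize_id(mesh_table$descriptor_id, "disease")
    sim <- disease_similarity_matrix(dis, mesh_table, epsilon)
    for (d in sim$missing) flag(node_key(d, "disease"), "no MeSH DAG")
    S <- sim$similarity
    n <- ncol(S)
    if (n <= ATTR_DIM) {
      rows <- cbind(S, matrix(0, n, ATTR_DIM - n))
    } else {
      widths <- if (n >= 4L * ATTR_DIM) c(n, 4L * ATTR_DIM, ATTR_DIM)
                else c(n, ATTR_DIM)
      model <- train_sae(S, widths, epochs = sae$epochs, lr = sae$lr,
                         batch_size = sae$batch_size, seed = seed + 101L)
      rows <- predict(model, S)
    }
    V[node_key(rownames(S), "disease"), ] <- rows
  } else if (length(dis)) {
    for (d in dis) flag(node_key(d, "disease"), "no MeSH table supplied")
  }

  # --- sequence nodes: grouped 3-mer frequencies -----------------------
  for (kind in c("protein", "mirna", "lncrna")) {
    ids <- nodes$id[nodes$kind == kind]
    if (!length(ids)) next
    alpha <- if (kind == "protein") "protein" else "rna"
    for (id in ids) {
      s <- if (is.null(sequences) || !(id %in% names(sequences))) NULL
           else sequences[[id]]
      if (is.null(s) || is.na(s)) {
        flag(node_key(id, kind), "no sequence")
        next
      }
      v <- tryCatch(suppressMessages(kmer_vector(s, alpha)),
                    error = function(e) NULL)
      if (is.null(v)) flag(node_key(id, kind), "sequence too short")
      else V[node_key(id, kind), ] <- v
    }
  }

  # --- drugs: circular fingerprints -> autoencoder code ----------------
  drugs <- nodes$id[nodes$kind == "drug"]
  if (length(drugs) && !is.null(drug_table)) {
    dt <- drug_table[drug_table$drug_id %in% drugs, , drop = FALSE]
    absent <- setdiff(drugs, dt$drug_id)
    for (d in absent) flag(node_key(d, "drug"), "no SMILES")
    if (nrow(dt)) {
      fpr <- drug_fingerprint_matrix(dt)
      for (d in fpr$missing) flag(node_key(d, "drug"), "unparseable SMILES")
      fp <- fpr$fingerprints
      nb <- ncol(fp)
      model <- train_sae(fp, c(nb, nb %/% 4L, ATTR_DIM),
                         epochs = sae$epochs, lr = sae$lr,
                         batch_size = sae$batch_size, seed = seed + 202L)
      V[node_key(rownames(fp), "drug"), ] <- predict(model, fp)
    }
  } else if (length(drugs)) {
    for (d in drugs) flag(node_key(d, "drug"), "no drug table supplied")
  }

  extra <- character(0)
  if (!is.null(sequences))
    extra <- c(extra, setdiff(names(sequences),
                              nodes$id[nodes$kind %in% c("protein", "mirna", "lncrna")]))
  if (!is.null(drug_table))
    extra <- c(extra, setdiff(drug_table$drug_id, drugs))
  if (length(extra))
    warning(sprintf("%d attribute-only id(s) not in the graph (e.g. '%s'); retained in inputs but not embedded",
                    length(extra), extra[1]))

  structure(list(values = V, flagged = flagged, epsilon = epsilon),
            class = "node_attributes")
}

#' @export
print.node_attributes <- function(x, ...) {
  cat(sprintf("node attributes: %d nodes x %d dims; %d flagged\n",
              nrow(x$values), ncol(x$values), length(x$flagged)))
  invisible(x)
}
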