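#' @useDynLib grlmn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict
"_PACKAGE"

# Canonical association kinds and their endpoint node kinds.  The first
# element of the endpoint pair is the kind stored in the `u` column.
.edge_kinds <- list(
  "drug-disease"    = c("drug",    "disease"),
  "drug-protein"    = c("drug",    "protein"),
  "protein-protein" = c("protein", "protein"),
  "protein-disease" = c("protein", "disease"),
  "lncrna-protein"  = c("lncrna",  "protein"),
  "lncrna-disease"  = c("lncrna",  "disease"),
  "mirna-protein"   = c("mirna",   "protein"),
  "mirna-disease"   = c("mirna",   "disease"),
  "mirna-lncrna"    = c("mirna",   "lncrna")
)

.node_kinds <- c("drug", "disease", "protein", "mirna", "lncrna")

#' Association kinds of the molecular association network
#'
#' @return Character vector of the nine recognised association kinds.
#' @export
man_edge_kinds <- function() names(.edge_kinds)

# Normalize an identifier per node-kind convention: whitespace trimmed for
# every kind; disease names additionally case-folded (MeSH headings are
# case-insensitive); drug/protein/RNA ids kept verbatim.
normalize_id <- function(id, kind) {
  id <- trimws(as.character(id))
  if (kind == "disease") id <- tolower(id)
  id
}

node_key <- function(id, kind) paste(kind, id, sep = ":")

#' Read an association edge list from a TSV file
#'
#' Each line holds `source_id<TAB>target_id`; lines starting with `#` are
#' comments.  Identifiers are normalized (trimmed; disease names
#' case-folded), self-loops are skipped with a warning and duplicate rows
#' are collapsed.
#'
#' @param path Path to the TSV file.
#' @param edge_kind One of [man_edge_kinds()]; determines the node kinds
#'   of the two columns.
#' @return A data frame of edges with columns `u_id`, `u_kind`, `v_id`,
#'   `v_kind`, `kind`, `weight`, suitable for [man_graph()].
#' @export
load_edge_list <- function(path, edge_kind) {
  edge_kind <- match.arg(edge_kind, names(.edge_kinds))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) return(association_edges(character(), character(), edge_kind))
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 2L || !nzchar(trimws(p[1])) ||
                  !nzchar(trimws(p[2])), logical(1))
  if (any(bad)) {
    stop(sprintf("malformed edge row at line %d of '%s' (need 2 tab-separated ids)",
                 rows[which(bad)[1]], path))
  }
  u <- vapply(parts, `[`, character(1), 1L)
  v <- vapply(parts, `[`, character(1), 2L)
  association_edges(u, v, edge_kind)
}

#' Build a normalized edge table for one association kind
#'
#' @param u,v Character vectors of source and target identifiers.
#' @param edge_kind One of [man_edge_kinds()].
#' @return Edge data frame (see [load_edge_list()]).
#' @export
association_edges <- function(u, v, edge_kind) {
  edge_kind <- match.arg(edge_kind, names(.edge_kinds))
  kinds <- .edge_kinds[[edge_kind]]
  u <- vapply(as.character(u), normalize_id, character(1), kind = kinds[1],
              USE.NAMES = FALSE)
  v <- vapply(as.character(v), normalize_id, character(1), kind = kinds[2],
              USE.NAMES = FALSE)
  df <- data.frame(u_id = u, u_kind = kinds[1], v_id = v, v_kind = kinds[2],
                   kind = edge_kind, weight = 1, stringsAsFactors = FALSE)
  loops <- df$u_id == df$v_id & df$u_kind == df$v_kind
  if (any(loops)) {
    warning(sprintf("skipped %d self-loop row(s) in %s edge list",
                    sum(loops), edge_kind))
    df <- df[!loops, , drop = FALSE]
  }
  # undirected dedup: canonical endpoint order within unipartite kinds
  if (kinds[1] == kinds[2]) {
    flip <- df$u_id > df$v_id
    tmp <- df$u_id[flip]; df$u_id[flip] <- df$v_id[flip]; df$v_id[flip] <- tmp
  }
  dup <- duplicated(df[c("u_id", "v_id", "kind")])
  if (any(dup)) {
    message(sprintf("collapsed %d duplicate %s edge(s)", sum(dup), edge_kind))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Construct a molecular association network
#'
#' Takes one or more edge tables (from [load_edge_list()] or
#' [association_edges()]) and forms their undirected union graph over the
#' five node kinds (drug, disease, protein, miRNA, lncRNA).  All edges
#' carry unit weight; duplicates across tables collapse to a single edge.
#'
#' @param ... Edge data frames, or a single list of them.
#' @param require_dd Require at least one drug-disease edge (default);
#'   internal rebuilds (e.g. after edge deletion) may relax this.
#' @return An object of class `man_graph` with elements `nodes` (data
#'   frame `id`, `kind`, `key`), `edges` (deduplicated edge data frame
#'   with `u`/`v` integer node indices appended) and `degree` (named
#'   weighted degree vector, by node key).
#' @export
man_graph <- function(..., require_dd = TRUE) {
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1]]) && !is.data.frame(dots[[1]]))
    dots <- dots[[1]]
  edges <- do.call(rbind, dots)
  if (is.null(edges) || !nrow(edges)) stop("empty edge union: no edges supplied")
  if (require_dd && !"drug-disease" %in% edges$kind)
    stop("a drug-disease edge table is required")
  dup <- duplicated(edges[c("u_id", "u_kind", "v_id", "v_kind", "kind")])
  edges <- edges[!dup, , drop = FALSE]

  keys <- c(node_key(edges$u_id, edges$u_kind), node_key(edges$v_id, edges$v_kind))
  ids <- c(edges$u_id, edges$v_id)
  kinds <- c(edges$u_kind, edges$v_kind)
  first <- !duplicated(keys)
  nodes <- data.frame(id = ids[first], kind = kinds[first], key = keys[first],
                      stringsAsFactors = FALSE)
  o <- order(nodes$kind, nodes$id)
  nodes <- nodes[o, , drop = FALSE]
  rownames(nodes) <- NULL

  edges$u <- match(node_key(edges$u_id, edges$u_kind), nodes$key)
  edges$v <- match(node_key(edges$v_id, edges$v_kind), nodes$key)
  rownames(edges) <- NULL

  g <- structure(list(nodes = nodes, edges = edges), class = "man_graph")
  g$degree <- man_degree(g)
  g
}

#' Weighted node degrees of a MAN
#'
#' @param g A `man_graph`.
#' @return Named numeric vector (by node key) of weighted degrees; for the
#'   unit-weight MAN this is the edge count at each node.
#' @export
man_degree <- function(g) {
  stopifnot(inherits(g, "man_graph"))
  d <- numeric(nrow(g$nodes))
  names(d) <- g$nodes$key
  tu <- tapply(g$edges$weight, g$edges$u, sum)
  tv <- tapply(g$edges$weight, g$edges$v, sum)
  d[as.integer(names(tu))] <- d[as.integer(names(tu))] + tu
  d[as.integer(names(tv))] <- d[as.integer(names(tv))] + tv
  names(d) <- g$nodes$key
  d
}

#' Total edge weight of a MAN
#'
#' @param g A `man_graph`.
#' @return Sum of edge weights (the symbol W of the first-order empirical
#'   distribution).
#' @export
man_total_weight <- function(g) sum(g$edges$weight)

#' @export
print.man_graph <- function(x, ...) {
  cat("Molecular association network\n")
  cat(sprintf("  %d nodes: %s\n", nrow(x$nodes),
              paste(sprintf("%s=%d", names(table(x$nodes$kind)),
                            table(x$nodes$kind)), collapse = ", ")))
  tk <- table(x$edges$kind)
  cat(sprintf("  %d edges over %d association kind(s)\n", nrow(x$edges), length(tk)))
  for (k in names(tk)) cat(sprintf("    %-16s %6d\n", k, tk[[k]]))
  invisible(x)
}

#' @export
summary.man_graph <- function(object, ...) {
  list(n_nodes = table(object$nodes$kind),
       n_edges = table(object$edges$kind),
       total_weight = man_total_weight(object),
       degree = summary(object$degree))
}

#' Serialize a MAN to a TSV edge dump
#'
#' Columns: `u_id u_kind v_id v_kind edge_kind weight`.  The dump
#' round-trips through [read_man()].
#'
#' @param g A `man_graph`.
#' @param path Output file path.
#' @export
write_man <- function(g, path) {
  stopifnot(inherits(g, "man_graph"))
  df <- g$edges[c("u_id", "u_kind", "v_id", "v_kind", "kind", "weight")]
  names(df)[5] <- "edge_kind"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MAN edge dump written by [write_man()]
#'
#' @param path Path to the TSV dump.
#' @return A `man_graph`.
#' @export
read_man <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  tabs <- lapply(split(df, df$edge_kind), function(d)
    association_edges(d$u_id, d$v_id, d$edge_kind[1]))
  man_graph(tabs)
}

#' Remove a set of drug-disease edges from a MAN
#'
#' Used by leakage-safe cross-validation and by case-study ranking, where
#' held-out association edges must not be visible to the embedding.
#'
#' @param g A `man_graph`.
#' @param pairs Data frame with columns `drug` and `disease` (raw ids).
#' @return A `man_graph` without those drug-disease edges.
#' @export
drop_dd_edges <- function(g, pairs) {
  stopifnot(inherits(g, "man_graph"))
  if (!nrow(pairs)) return(g)
  tgt <- paste(normalize_id(pairs$drug, "drug"),
               normalize_id(pairs$disease, "disease"))
  e <- g$edges
  isdd <- e$kind == "drug-disease"
  hit <- isdd & paste(e$u_id, e$v_id) %in% tgt
  tabs <- split(e[!hit, , drop = FALSE],
                e$kind[!hit])
  man_graph(lapply(tabs, function(d)
    d[c("u_id", "u_kind", "v_id", "v_kind", "kind", "weight")]),
    require_dd = FALSE)
}

#' Drug-disease association pairs present in a MAN
#'
#' @param g A `man_graph`.
#' @return Data frame with columns `drug`, `disease` (normalized ids).
#' @export
dd_pairs <- function(g) {
  e <- g$edges[g$edges$kind == "drug-disease", , drop = FALSE]
  data.frame(drug = e$u_id, disease = e$v_id, stringsAsFactors = FALSE)
}
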