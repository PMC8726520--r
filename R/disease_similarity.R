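# Disease semantic similarity from MeSH tree numbers.
#
# A disease descriptor's tree numbers (e.g. "C04.557.337") place it in the
# MeSH hierarchy; every prefix of a tree number is an ancestor descriptor.
# The per-disease DAG of ancestors carries a semantic contribution that
# decays geometrically with distance, and two diseases are compared through
# the contributions of their shared ancestors.

#' Read a flattened MeSH descriptor table
#'
#' TSV with columns `descriptor_id<TAB>name<TAB>tree_number`, one row per
#' tree number (a descriptor with several tree numbers spans several rows).
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `descriptor_id`, `name`, `tree_number`.
#' @export
read_mesh_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")
  need <- c("descriptor_id", "name", "tree_number")
  if (!all(need %in% names(df)))
    stop("MeSH table must have columns descriptor_id, name, tree_number")
  df
}

# Internal index: tree number -> descriptor id, and descriptor -> tree numbers.
mesh_index <- function(mesh_table) {
  list(by_tn = stats::setNames(mesh_table$descriptor_id, mesh_table$tree_number),
       by_id = split(mesh_table$tree_number, mesh_table$descriptor_id))
}

tn_parent <- function(tn) {
  parts <- strsplit(tn, ".", fixed = TRUE)[[1]]
  if (length(parts) <= 1L) return(NA_character_)
  paste(parts[-length(parts)], collapse = ".")
}

#' Build the ancestor DAG of one disease
#'
#' Collects the disease descriptor itself plus every descriptor reachable
#' by stripping tree-number segments (all ancestors, across all of the
#' disease's tree numbers), with parent-to-child links and shortest hop
#' counts from the disease up.
#'
#' @param disease_id Descriptor id of the disease (must appear in
#'   `mesh_table`).
#' @param mesh_table Data frame from [read_mesh_table()].
#' @return An object of class `disease_dag`: list with `disease`,
#'   `members` (descriptor ids, self included), `depth` (named integer,
#'   0 for the disease itself), `children` (named list: member -> its
#'   child members within the DAG).
#' @export
build_disease_dag <- function(disease_id, mesh_table) {
  idx <- mesh_index(mesh_table)
  tns <- idx$by_id[[disease_id]]
  if (is.null(tns) || !length(tns))
    stop(sprintf("disease '%s' has no DAG: absent from the MeSH table", disease_id))

  # walk every tree number up to its root, recording descriptor hops
  depth <- c(stats::setNames(0L, disease_id))
  children <- list()
  for (tn in tns) {
    cur <- tn; cur_id <- disease_id; d <- 0L
    repeat {
      par <- tn_parent(cur)
      if (is.na(par)) break
      par_id <- idx$by_tn[[par]]
      if (is.null(par_id))
        stop(sprintf("tree number '%s' has no descriptor in the MeSH table", par))
      d <- d + 1L
      old <- depth[par_id]
      if (is.na(old) || d < old) depth[par_id] <- d
      kids <- children[[par_id]]
      if (!cur_id %in% kids) children[[par_id]] <- c(kids, cur_id)
      cur <- par; cur_id <- par_id
    }
  }
  structure(list(disease = disease_id,
                 members = names(depth),
                 depth = depth,
                 children = children),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("disease DAG of '%s': %d member(s), max depth %d\n",
              x$disease, length(x$members), max(x$depth)))
  invisible(x)
}

#' Semantic contributions and semantic value of a disease DAG
#'
#' The disease itself contributes 1; every ancestor contributes the best
#' (maximal) value obtainable by decaying a child's contribution by the
#' factor `epsilon`, so a member reachable along several paths takes the
#' contribution of its shortest path.  The semantic value is the sum of
#' all member contributions.
#'
#' @param dag A `disease_dag`.
#' @param epsilon Decay factor per hierarchy step, in (0, 1).
#' @return Object of class `semantic_contribution`: list with
#'   `contribution` (named numeric over members), `value` (the summed
#'   semantic value, >= 1) and `epsilon`.
#' @export
semantic_contribution <- function(dag, epsilon = 0.5) {
  stopifnot(inherits(dag, "disease_dag"))
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon >= 1)
    stop("epsilon must be a single value in (0, 1)")
  contrib <- stats::setNames(rep(NA_real_, length(dag$members)), dag$members)
  contrib[dag$disease] <- 1
  # members in increasing depth have children already resolved only if the
  # recursion follows child depths; use memoized recursion over child links.
  visiting <- character()
  resolve <- function(d) {
    if (!is.na(contrib[d])) return(contrib[d])
    kids <- dag$children[[d]]
    vals <- vapply(kids, resolve, numeric(1))
    contrib[d] <<- max(epsilon * vals)
    contrib[d]
  }
  for (d in dag$members) resolve(d)
  structure(list(contribution = contrib, value = sum(contrib),
                 epsilon = epsilon, disease = dag$disease),
            class = "semantic_contribution")
}

#' Semantic similarity between two diseases
#'
#' Shared ancestors contribute from both sides; the similarity is the
#' shared contribution mass over the two semantic values, symmetric and
#' in \[0, 1\], with value 1 for identical DAGs.
#'
#' @param ci,cj `semantic_contribution` objects built with the same
#'   `epsilon`.
#' @return Similarity in \[0, 1\].
#' @export
semantic_similarity <- function(ci, cj) {
  stopifnot(inherits(ci, "semantic_contribution"),
            inherits(cj, "semantic_contribution"))
  if (!isTRUE(all.equal(ci$epsilon, cj$epsilon)))
    stop("semantic contributions built with different epsilon")
  shared <- intersect(names(ci$contribution), names(cj$contribution))
  if (!length(shared)) return(0)
  sum(ci$contribution[shared] + cj$contribution[shared]) / (ci$value + cj$value)
}

#' Pairwise disease semantic-similarity matrix
#'
#' @param disease_ids Character vector of descriptor ids.
#' @param mesh_table Data frame from [read_mesh_table()].
#' @param epsilon Decay factor, see [semantic_contribution()].
#' @return List with `similarity` (symmetric matrix, unit diagonal, over
#'   the diseases that have DAGs) and `missing` (ids without a DAG).
#' @export
disease_similarity_matrix <- function(disease_ids, mesh_table, epsilon = 0.5) {
  disease_ids <- unique(disease_ids)
  have <- disease_ids %in% mesh_table$descriptor_id
  missing <- disease_ids[!have]
  ids <- disease_ids[have]
  if (length(ids) < 1L) stop("no disease has a MeSH DAG")
  contribs <- lapply(ids, function(d)
    semantic_contribution(build_disease_dag(d, mesh_table), epsilon))
  n <- length(ids)
  S <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      S[i, j] <- S[j, i] <- semantic_similarity(contribs[[i]], contribs[[j]])
    }
  }
  dimnames(S) <- list(ids, ids)
  list(similarity = S, missing = missing)
}
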