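# Small in-code fixtures shared across the suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

# A triangle of proteins plus one drug-disease edge to satisfy the
# drug-disease requirement where needed.
triangle_graph <- function() {
  man_graph(association_edges(c("P1", "P2", "P3"), c("P2", "P3", "P1"),
                              "protein-protein"),
            association_edges("D1", "dis1", "drug-disease"))
}

# Star: one protein hub with 4 drug leaves (plus a drug-disease edge).
star_graph <- function() {
  man_graph(association_edges(paste0("D", 1:4), rep("P1", 4), "drug-protein"),
            association_edges("D1", "dis1", "drug-disease"))
}

# Two 10-cliques of proteins bridged by a single edge; a drug-disease
# edge keeps the constructor happy without touching the cliques.
two_clique_graph <- function() {
  clique <- function(ids) {
    p <- t(utils::combn(ids, 2))
    association_edges(p[, 1], p[, 2], "protein-protein")
  }
  a <- paste0("A", 1:10)
  b <- paste0("B", 1:10)
  man_graph(clique(a), clique(b),
            association_edges("A1", "B1", "protein-protein"),
            association_edges("DRX", "disx", "drug-disease"))
}

# Random MeSH-style table: a random tree of `n` descriptors (ids X1..Xn,
# X1 the root); a few descriptors get a second tree number (grafted under
# another node) so the per-disease DAGs contain genuine diamonds.
random_mesh_table <- function(n = 12L, seed = 1L, multi = TRUE) {
  set.seed(seed)
  ids <- paste0("X", seq_len(n))
  tn <- character(n)
  tn[1] <- "T01"
  rows <- data.frame(descriptor_id = ids[1], name = "root", tree_number = tn[1])
  for (i in seq_len(n)[-1]) {
    parent <- sample.int(i - 1L, 1L)
    tn[i] <- paste0(tn[parent], sprintf(".%03d", i))
    rows <- rbind(rows, data.frame(descriptor_id = ids[i], name = ids[i],
                                   tree_number = tn[i]))
  }
  if (multi && n >= 4L) {
    extra <- sample(2:n, max(1L, n %/% 4L))
    for (i in extra) {
      # graft only under a node that is not i itself nor a descendant of
      # i, so tree numbers stay acyclic as in real MeSH
      ok <- setdiff(which(!startsWith(tn, tn[i])), i)
      if (!length(ok)) next
      host <- if (length(ok) == 1L) ok else sample(ok, 1L)
      rows <- rbind(rows, data.frame(descriptor_id = ids[i], name = ids[i],
                                     tree_number = paste0(tn[host],
                                                          sprintf(".%03d", 500L + i))))
    }
  }
  rows
}

# Brute-force semantic contribution: enumerate every ancestor path from
# the disease up through the DAG and take the best geometric decay.
brute_force_contribution <- function(dag, epsilon) {
  # invert child links: member -> parents
  parents <- list()
  for (p in names(dag$children))
    for (ch in dag$children[[p]])
      parents[[ch]] <- c(parents[[ch]], p)
  best <- stats::setNames(rep(-Inf, length(dag$members)), dag$members)
  walk <- function(node, len) {
    val <- epsilon^len
    if (val > best[node]) best[node] <<- val
    for (p in parents[[node]]) walk(p, len + 1L)
  }
  walk(dag$disease, 0L)
  best
}

# Feature matrix for classifier tests: two gaussian blobs.
toy_features <- function(n = 60L, p = 6L, sep = 3, seed = 1L) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * p), n, p)
  x[y == 1, 1] <- x[y == 1, 1] + sep
  list(x = x, y = y)
}

# A small simulated dataset reused by pipeline tests (cheap settings).
small_sim <- function(seed = 7L) {
  spec <- man_sim_spec(n_drug = 15L, n_disease = 20L, n_protein = 40L,
                       n_mirna = 20L, n_lncrna = 10L, n_community = 2L,
                       seq_len = c(40L, 80L))
  simulate_man(spec, seed = seed)
}
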