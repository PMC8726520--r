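# Synthetic molecular association network with planted drug-disease
# signal, plus matching sequences, SMILES and a MeSH-style descriptor
# tree, so the whole pipeline is testable without any external download.
#
# Every node gets a community; each of the nine association kinds is
# drawn as a block model whose within-community probability exceeds the
# between-community one.  The drug-disease block contrast is governed by
# `signal`, the approximate fraction of drug-disease edges explained by
# shared community membership; signal 0 collapses the contrast to a null
# model.

#' Settings for the synthetic MAN generator
#'
#' Node counts default to the five-kind composition of a realistic
#' association compendium at small scale (drugs 40, diseases 60,
#' proteins 120, miRNAs 60, lncRNAs 30, about 310 nodes).
#'
#' @param n_drug,n_disease,n_protein,n_mirna,n_lncrna Node counts.
#' @param n_community Number of planted communities.
#' @param signal In \[0, 1\]: strength of the planted block contrast
#'   (0 = null model: every kind's within-community probability equals
#'   its between-community probability).
#' @param dd_base Base drug-disease edge probability; the realized
#'   within/between probabilities are `dd_base * (1 + 3 * signal)` and
#'   `dd_base * (1 - signal)`.
#' @param within,between Full-signal within-community and (constant)
#'   between-community edge probabilities for the eight auxiliary
#'   association kinds; the realized within probability interpolates
#'   from `between` (signal 0) to `within` (signal 1).
#' @param attr_noise Fraction of nodes whose attribute profile (sequence
#'   composition, MeSH placement, SMILES scaffold family) is drawn from
#'   a random community instead of their own — attributes track
#'   interaction communities only imperfectly in real data.
#' @param heldout_frac Fraction of true drug-disease edges reserved
#'   (kept out of the graph) as held-out positives.
#' @param seq_len Length-2 integer range of generated sequence lengths.
#' @return A list of settings of class `man_sim_spec`.
#' @export
man_sim_spec <- function(n_drug = 40L, n_disease = 60L, n_protein = 120L,
                         n_mirna = 60L, n_lncrna = 30L, n_community = 4L,
                         signal = 0.8, dd_base = 0.25,
                         within = 0.34, between = 0.02,
                         attr_noise = 0.10,
                         heldout_frac = 0.1, seq_len = c(80L, 200L)) {
  stopifnot(signal >= 0, signal <= 1, dd_base > 0, dd_base <= 1,
            within >= 0, within <= 1, between >= 0, between <= 1,
            attr_noise >= 0, attr_noise <= 1,
            heldout_frac >= 0, heldout_frac < 1)
  if (signal > 0 && within <= between)
    stop("within-community probability must exceed between when signal > 0")
  structure(list(n = c(drug = as.integer(n_drug), disease = as.integer(n_disease),
                       protein = as.integer(n_protein), mirna = as.integer(n_mirna),
                       lncrna = as.integer(n_lncrna)),
                 n_community = as.integer(n_community), signal = signal,
                 dd_base = dd_base, within = within, between = between,
                 attr_noise = attr_noise,
                 heldout_frac = heldout_frac, seq_len = as.integer(seq_len)),
            class = "man_sim_spec")
}

sim_node_ids <- function(spec) {
  list(drug = sprintf("DR%04d", seq_len(spec$n["drug"])),
       disease = sprintf("dis%04d", seq_len(spec$n["disease"])),
       protein = sprintf("P%04d", seq_len(spec$n["protein"])),
       mirna = sprintf("mir%04d", seq_len(spec$n["mirna"])),
       lncrna = sprintf("lnc%04d", seq_len(spec$n["lncrna"])))
}

# Draw a block-model edge table between two id vectors.
sim_block_edges <- function(ids_u, comm_u, ids_v, comm_v, kind,
                            p_within, p_between, unipartite = FALSE) {
  grid <- expand.grid(i = seq_along(ids_u), j = seq_along(ids_v),
                      KEEP.OUT.ATTRS = FALSE)
  if (unipartite) grid <- grid[grid$i < grid$j, , drop = FALSE]
  p <- ifelse(comm_u[grid$i] == comm_v[grid$j], p_within, p_between)
  hit <- stats::runif(nrow(grid)) < p
  association_edges(ids_u[grid$i[hit]], ids_v[grid$j[hit]], kind)
}

#' Generate a synthetic MAN with planted structure
#'
#' @param spec A [man_sim_spec()].
#' @param seed Integer seed; the same seed reproduces the same graph.
#' @return List with `graph` (a `man_graph`), `community` (named integer
#'   vector over node keys), `heldout` (data frame `drug`, `disease` of
#'   reserved true associations) and `ids` (per-kind id lists).
#' @export
generate_man <- function(spec = man_sim_spec(), seed = 1L) {
  stopifnot(inherits(spec, "man_sim_spec"))
  ids <- sim_node_ids(spec)
  with_local_seed(seed, {
    comm <- lapply(ids, function(v)
      sample(rep_len(seq_len(spec$n_community), length(v))))
    s <- spec$signal
    p_dd_w <- min(1, spec$dd_base * (1 + 3 * s))
    p_dd_b <- spec$dd_base * (1 - s)
    p_aux_w <- spec$between + (spec$within - spec$between) * s
    p_aux_b <- spec$between
    tabs <- list(
      sim_block_edges(ids$drug, comm$drug, ids$disease, comm$disease,
                      "drug-disease", p_dd_w, p_dd_b),
      sim_block_edges(ids$drug, comm$drug, ids$protein, comm$protein,
                      "drug-protein", p_aux_w, p_aux_b),
      sim_block_edges(ids$protein, comm$protein, ids$protein, comm$protein,
                      "protein-protein", p_aux_w, p_aux_b,
                      unipartite = TRUE),
      sim_block_edges(ids$protein, comm$protein, ids$disease, comm$disease,
                      "protein-disease", p_aux_w, p_aux_b),
      sim_block_edges(ids$lncrna, comm$lncrna, ids$protein, comm$protein,
                      "lncrna-protein", p_aux_w, p_aux_b),
      sim_block_edges(ids$lncrna, comm$lncrna, ids$disease, comm$disease,
                      "lncrna-disease", p_aux_w, p_aux_b),
      sim_block_edges(ids$mirna, comm$mirna, ids$protein, comm$protein,
                      "mirna-protein", p_aux_w, p_aux_b),
      sim_block_edges(ids$mirna, comm$mirna, ids$disease, comm$disease,
                      "mirna-disease", p_aux_w, p_aux_b),
      sim_block_edges(ids$mirna, comm$mirna, ids$lncrna, comm$lncrna,
                      "mirna-lncrna", p_aux_w, p_aux_b))
    empty <- vapply(tabs, nrow, integer(1)) == 0L
    if (any(empty))
      stop(sprintf("generated zero edges for kind '%s'; increase probabilities",
                   man_edge_kinds()[which(empty)[1]]))

    # reserve a fraction of true drug-disease edges as held-out positives
    dd <- tabs[[1]]
    n_hold <- floor(nrow(dd) * spec$heldout_frac)
    hold_idx <- if (n_hold > 0) sample.int(nrow(dd), n_hold) else integer(0)
    heldout <- data.frame(drug = dd$u_id[hold_idx],
                          disease = dd$v_id[hold_idx],
                          stringsAsFactors = FALSE)
    tabs[[1]] <- dd[setdiff(seq_len(nrow(dd)), hold_idx), , drop = FALSE]

    # connectivity guarantee: attach isolated nodes through a protein hub
    # of their community (a disease via protein-disease, a drug via
    # drug-protein, etc.), so embedding never sees an isolated node
    seen <- unique(c(paste(unlist(lapply(tabs, `[[`, "u_kind")),
                           unlist(lapply(tabs, `[[`, "u_id"))),
                     paste(unlist(lapply(tabs, `[[`, "v_kind")),
                           unlist(lapply(tabs, `[[`, "v_id")))))
    for (kind in names(ids)) {
      missing <- ids[[kind]][!paste(kind, ids[[kind]]) %in% seen]
      for (id in missing) {
        cm <- comm[[kind]][match(id, ids[[kind]])]
        partner_pool <- if (kind == "protein") setdiff(ids$protein, id) else ids$protein
        partner_comm <- comm$protein[match(partner_pool, ids$protein)]
        pool <- partner_pool[partner_comm == cm]
        if (!length(pool)) pool <- partner_pool
        partner <- pool[sample.int(length(pool), 1L)]
        ek <- switch(kind, drug = "drug-protein", disease = "protein-disease",
                     protein = "protein-protein", mirna = "mirna-protein",
                     lncrna = "lncrna-protein")
        new_edge <- if (kind == "disease") association_edges(partner, id, ek)
                    else association_edges(id, partner, ek)
        ki <- match(ek, vapply(tabs, function(t) t$kind[1], character(1)))
        tabs[[ki]] <- rbind(tabs[[ki]], new_edge)
      }
    }
    g <- man_graph(tabs)
    community <- integer(nrow(g$nodes))
    names(community) <- g$nodes$key
    for (kind in names(ids)) {
      keys <- node_key(normalize_id(ids[[kind]], kind), kind)
      hit <- match(keys, names(community))
      ok <- !is.na(hit)
      community[hit[ok]] <- comm[[kind]][ok]
    }
    list(graph = g, community = community, heldout = heldout, ids = ids)
  })
}

#' Generate community-biased synthetic sequences
#'
#' Nodes in the same community share a Dirichlet-drawn composition
#' profile over the reduced 4-letter alphabet, so grouped 3-mer vectors
#' carry community signal.
#'
#' @param ids Character node ids.
#' @param communities Integer community per id.
#' @param kind `"protein"` or `"rna"`.
#' @param len_range Length-2 integer sequence-length range.
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration of the community
#'   profiles (smaller = stronger bias).
#' @return Named character vector of sequences.
#' @export
generate_sequences <- function(ids, communities, kind = c("protein", "rna"),
                               len_range = c(80L, 200L), seed = 1L,
                               concentration = 1.5) {
  kind <- match.arg(kind)
  with_local_seed(seed + 7L * (kind == "rna"), {
    profiles <- lapply(sort(unique(communities)), function(c) {
      x <- stats::rgamma(4, concentration)
      x / sum(x)
    })
    names(profiles) <- sort(unique(communities))
    seqs <- vapply(seq_along(ids), function(i) {
      prof <- profiles[[as.character(communities[i])]]
      len <- sample(len_range[1]:len_range[2], 1L)
      groups <- sample.int(4L, len, replace = TRUE, prob = prof)
      if (kind == "rna") {
        paste(c("A", "C", "G", "U")[groups], collapse = "")
      } else {
        letters4 <- lapply(groups, function(gi) {
          pool <- .aa_groups[[gi]]
          pool[sample.int(length(pool), 1L)]
        })
        paste(unlist(letters4), collapse = "")
      }
    }, character(1))
    names(seqs) <- ids
    seqs
  })
}

# Community-specific SMILES scaffold families: a shared backbone per
# community with randomized chain length and terminal group, all valid
# linear/aromatic SMILES.
.smiles_scaffolds <- list(
  `1` = list(prefix = "C",          tails = c("O", "N", "OC", "NC")),
  `2` = list(prefix = "c1ccccc1",   tails = c("O", "N", "C(=O)O", "CO")),
  `3` = list(prefix = "C1CCCCC1",   tails = c("O", "N", "OC", "S")),
  `4` = list(prefix = "CC(=O)",     tails = c("OC", "NC", "OCC", "NCC")),
  `5` = list(prefix = "c1ccncc1",   tails = c("O", "N", "OC", "CO")),
  `6` = list(prefix = "C1CCOC1",    tails = c("O", "N", "C", "CC"))
)

#' Generate a synthetic drug SMILES table
#'
#' Each drug's SMILES is drawn from its community's scaffold family with
#' a randomized linker length and terminal group; all strings parse.
#'
#' @param ids Drug ids.
#' @param communities Integer community per drug.
#' @param seed Integer seed.
#' @return Data frame `drug_id`, `smiles`.
#' @export
generate_drug_table <- function(ids, communities, seed = 1L) {
  with_local_seed(seed + 13L, {
    smiles <- vapply(seq_along(ids), function(i) {
      fam <- .smiles_scaffolds[[1L + (communities[i] - 1L) %% length(.smiles_scaffolds)]]
      linker <- strrep("C", sample.int(4L, 1L))
      tail <- fam$tails[sample.int(length(fam$tails), 1L)]
      paste0(fam$prefix, linker, tail)
    }, character(1))
    data.frame(drug_id = ids, smiles = smiles, stringsAsFactors = FALSE)
  })
}

#' Generate a MeSH-style descriptor table for synthetic diseases
#'
#' Builds one hierarchy branch per community (a root plus a random chain
#' tree of internal descriptors) and attaches each disease beneath its
#' community's branch, so semantic similarity correlates with community
#' co-membership.
#'
#' @param ids Disease ids.
#' @param communities Integer community per disease.
#' @param seed Integer seed.
#' @param n_internal Internal descriptors per community branch.
#' @return Data frame `descriptor_id`, `name`, `tree_number` (one row
#'   per tree number; every disease has at least one).
#' @export
generate_mesh_table <- function(ids, communities, seed = 1L,
                                n_internal = 6L) {
  with_local_seed(seed + 29L, {
    rows <- list()
    tn_of <- list()   # community -> character vector of attachable tree numbers
    for (c in sort(unique(communities))) {
      root_id <- sprintf("mroot%02d", c)
      root_tn <- sprintf("C%02d", c)
      rows[[length(rows) + 1L]] <-
        data.frame(descriptor_id = root_id, name = sprintf("branch %d root", c),
                   tree_number = root_tn, stringsAsFactors = FALSE)
      tns <- root_tn
      for (i in seq_len(n_internal)) {
        parent <- tns[sample.int(length(tns), 1L)]
        tn <- paste0(parent, sprintf(".%03d", sample.int(999L, 1L)))
        while (tn %in% tns) tn <- paste0(parent, sprintf(".%03d", sample.int(999L, 1L)))
        did <- sprintf("mint%02d_%02d", c, i)
        rows[[length(rows) + 1L]] <-
          data.frame(descriptor_id = did, name = sprintf("internal %d.%d", c, i),
                     tree_number = tn, stringsAsFactors = FALSE)
        tns <- c(tns, tn)
      }
      tn_of[[as.character(c)]] <- tns
    }
    for (i in seq_along(ids)) {
      tns <- tn_of[[as.character(communities[i])]]
      parent <- tns[sample.int(length(tns), 1L)]
      tn <- paste0(parent, sprintf(".%03d", sample.int(999L, 1L)))
      rows[[length(rows) + 1L]] <-
        data.frame(descriptor_id = ids[i], name = paste("disease", ids[i]),
                   tree_number = tn, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Generate a complete synthetic dataset
#'
#' Orchestrates [generate_man()], [generate_sequences()],
#' [generate_drug_table()] and [generate_mesh_table()] into one
#' self-consistent bundle.
#'
#' @param spec A [man_sim_spec()].
#' @param seed Integer master seed.
#' @return List of class `man_dataset`: `graph`, `community`, `heldout`,
#'   `sequences` (named vector over proteins, miRNAs and lncRNAs),
#'   `drug_table`, `mesh_table`, `spec`, `seed`.
#' @export
simulate_man <- function(spec = man_sim_spec(), seed = 1L) {
  gm <- generate_man(spec, seed)
  ids <- gm$ids
  comm_of <- function(kind) {
    keys <- node_key(normalize_id(ids[[kind]], kind), kind)
    cm <- gm$community[keys]
    # nodes guaranteed present (connectivity pass); default community 1
    cm[is.na(cm)] <- 1L
    # attribute-noise: some nodes carry another community's profile
    with_local_seed(seed + 997L + match(kind, names(ids)), {
      flip <- stats::runif(length(cm)) < spec$attr_noise
      cm[flip] <- sample.int(spec$n_community, sum(flip), replace = TRUE)
    })
    cm
  }
  seqs <- c(generate_sequences(ids$protein, comm_of("protein"), "protein",
                               spec$seq_len, seed),
            generate_sequences(ids$mirna, comm_of("mirna"), "rna",
                               c(20L, 26L), seed + 1L),
            generate_sequences(ids$lncrna, comm_of("lncrna"), "rna",
                               spec$seq_len * 2L, seed + 2L))
  structure(list(graph = gm$graph, community = gm$community,
                 heldout = gm$heldout,
                 sequences = seqs,
                 drug_table = generate_drug_table(ids$drug, comm_of("drug"), seed),
                 mesh_table = generate_mesh_table(ids$disease, comm_of("disease"), seed),
                 spec = spec, seed = as.integer(seed)),
            class = "man_dataset")
}

#' @export
print.man_dataset <- function(x, ...) {
  cat(sprintf("synthetic MAN dataset (seed %d, signal %.2f)\n",
              x$seed, x$spec$signal))
  print(x$graph)
  cat(sprintf("  %d held-out true associations\n", nrow(x$heldout)))
  invisible(x)
}

#' Write a synthetic dataset to a directory of standard files
#'
#' Emits one edge-list TSV per association kind, FASTA files for protein
#' and ncRNA sequences, the drug SMILES TSV, the MeSH-style TSV, and a
#' ground-truth JSON-like TSV of held-out pairs and communities.  The
#' files load back through the package's regular readers.
#'
#' @param dataset A `man_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_man_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "man_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  e <- dataset$graph$edges
  for (k in unique(e$kind)) {
    d <- e[e$kind == k, c("u_id", "v_id")]
    utils::write.table(d, file.path(dir, paste0(k, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  write_fasta <- function(seqs, path) {
    con <- file(path, "w"); on.exit(close(con))
    for (nm in names(seqs)) writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  }
  kinds <- dataset$graph$nodes$kind[match(names(dataset$sequences),
                                          dataset$graph$nodes$id)]
  write_fasta(dataset$sequences[kinds == "protein"],
              file.path(dir, "proteins.fasta"))
  write_fasta(dataset$sequences[kinds != "protein"],
              file.path(dir, "ncrna.fasta"))
  utils::write.table(dataset$drug_table, file.path(dir, "drugs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$mesh_table, file.path(dir, "mesh.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$heldout, file.path(dir, "heldout_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  comm <- data.frame(key = names(dataset$community),
                     community = dataset$community)
  utils::write.table(comm, file.path(dir, "communities.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a FASTA file into a named character vector
#'
#' @param path Path to an uncompressed FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  id <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  stats::setNames(unname(seqs), id)
}

#' Load a dataset directory written by [write_man_dataset()]
#'
#' @param dir Dataset directory.
#' @return A list with `graph`, `sequences`, `drug_table`, `mesh_table`
#'   (and `heldout` if present).
#' @export
read_man_dataset <- function(dir) {
  tabs <- list()
  for (k in man_edge_kinds()) {
    f <- file.path(dir, paste0(k, ".tsv"))
    if (file.exists(f)) tabs[[k]] <- load_edge_list(f, k)
  }
  out <- list(graph = man_graph(tabs),
              sequences = c(read_fasta(file.path(dir, "proteins.fasta")),
                            read_fasta(file.path(dir, "ncrna.fasta"))),
              drug_table = read_drug_table(file.path(dir, "drugs.tsv")),
              mesh_table = read_mesh_table(file.path(dir, "mesh.tsv")))
  hof <- file.path(dir, "heldout_pairs.tsv")
  if (file.exists(hof))
    out$heldout <- utils::read.table(hof, sep = "\t", header = TRUE,
                                     stringsAsFactors = FALSE)
  out
}
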