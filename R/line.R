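# LINE graph embedding: first-order (direct-edge) and second-order
# (shared-neighborhood) proximity, trained by edge sampling with negative
# sampling; exact softmax objectives kept for small-graph diagnostics.

#' LINE training settings
#'
#' @param dim Total behavior-vector width (first-order half plus
#'   second-order half); must be even.
#' @param negatives Negative samples per positive edge draw.
#' @param lr Initial learning rate (decays linearly to `lr/100`).
#' @param samples Edge-sample budget per order; default `500 * |E|`.
#' @param seed Integer seed for initialization and sampling.
#' @return A list of settings of class `line_config`.
#' @export
line_config <- function(dim = 64L, negatives = 5L, lr = 0.025,
                        samples = NULL, seed = 1L) {
  dim <- as.integer(dim)
  if (dim %% 2L != 0L) stop("dim must be even (two equal-order halves)")
  if (negatives < 1L) stop("need at least 1 negative sample")
  structure(list(dim = dim, negatives = as.integer(negatives), lr = lr,
                 samples = samples, seed = as.integer(seed)),
            class = "line_config")
}

#' First-order proximity probability
#'
#' Sigmoid of the inner product of two vertex vectors; the model
#' probability that the two vertices are direct neighbors.
#'
#' @param u_a,u_b Embedding vectors of equal width.
#' @return Probability in (0, 1); symmetric in its arguments.
#' @export
first_order_prob <- function(u_a, u_b) {
  stopifnot(length(u_a) == length(u_b))
  dot <- sum(u_a * u_b)
  1 / (1 + exp(-pmin(pmax(dot, -35), 35)))
}

#' Second-order proximity probability
#'
#' Softmax, over all context vectors, of the inner product between the
#' source vertex vector and the target's context vector: the model
#' probability that `b` is generated as a "context" of `a`.
#'
#' @param a,b Node keys (or indices) into the embedding.
#' @param embedding A `line_embedding` (see [train_line()]).
#' @return Probability in (0, 1); rows sum to 1 over all `b`.
#' @export
second_order_prob <- function(a, b, embedding) {
  stopifnot(inherits(embedding, "line_embedding"))
  U <- embedding$second
  C <- embedding$context
  ia <- if (is.character(a)) match(a, rownames(U)) else a
  ib <- if (is.character(b)) match(b, rownames(C)) else b
  scores <- drop(C %*% U[ia, ])
  scores <- scores - max(scores)          # log-sum-exp stabilization
  unname(exp(scores[ib]) / sum(exp(scores)))
}

#' Empirical proximity distributions of a graph
#'
#' First order: each undirected edge's share of the total edge weight.
#' Second order: each directed edge's share of its source's weighted
#' degree (for unit weights, 1/degree).
#'
#' @param g A `man_graph`.
#' @return List with `p1` (data frame `u`, `v`, `p` per undirected edge)
#'   and `p2` (data frame `from`, `to`, `p` per directed edge, both
#'   directions of every undirected edge).
#' @export
empirical_distributions <- function(g) {
  stopifnot(inherits(g, "man_graph"))
  deg <- g$degree
  if (any(deg == 0))
    stop(sprintf("isolated node(s) in graph (e.g. '%s'): second-order empirical distribution undefined",
                 names(deg)[deg == 0][1]))
  W <- man_total_weight(g)
  e <- g$edges
  p1 <- data.frame(u = g$nodes$key[e$u], v = g$nodes$key[e$v],
                   p = e$weight / W, stringsAsFactors = FALSE)
  p2 <- data.frame(from = c(g$nodes$key[e$u], g$nodes$key[e$v]),
                   to   = c(g$nodes$key[e$v], g$nodes$key[e$u]),
                   stringsAsFactors = FALSE)
  p2$p <- c(e$weight, e$weight) / deg[p2$from]
  rownames(p2) <- NULL
  list(p1 = p1, p2 = p2)
}

#' Train LINE embeddings over a MAN
#'
#' Trains the first-order and second-order models independently at half
#' the total width each by edge-sampling SGD with negative sampling
#' (noise proportional to degree^0.75), then concatenates them
#' (first-order half first) into the per-node behavior vector.
#'
#' @param g A `man_graph` without isolated nodes.
#' @param config A [line_config()].
#' @return Object of class `line_embedding`: matrices `first`, `second`,
#'   `context` (rows = nodes, rownames = node keys), `behavior`
#'   (first/second concatenation, width `config$dim`), loss traces
#'   `trace1`, `trace2`, and the `config`.
#' @export
train_line <- function(g, config = line_config()) {
  stopifnot(inherits(g, "man_graph"), inherits(config, "line_config"))
  if (any(g$degree == 0)) stop("graph has isolated nodes; cannot embed")
  n <- nrow(g$nodes)
  half <- config$dim %/% 2L
  m <- nrow(g$edges)
  samples <- if (is.null(config$samples)) 500 * m else config$samples
  if (samples < m) stop("sample budget below the edge count")

  init <- function(seed_off) {
    with_local_seed(config$seed + seed_off,
      matrix(stats::runif(half * n, -0.5 / half, 0.5 / half), half, n))
  }
  u0 <- g$edges$u - 1L
  v0 <- g$edges$v - 1L
  w <- g$edges$weight

  r1 <- .line_sgd(u0, v0, w, n, half, samples, config$negatives, config$lr,
                  order = 1L, neg_power = 0.75, seed = config$seed,
                  init_vertex = init(0L), init_context = matrix(0, 0, 0))
  # second order: expand each undirected edge into both directions
  r2 <- .line_sgd(c(u0, v0), c(v0, u0), c(w, w), n, half, samples,
                  config$negatives, config$lr, order = 2L, neg_power = 0.75,
                  seed = config$seed + 1L,
                  init_vertex = init(1L), init_context = init(2L))

  first <- t(r1$vertex); second <- t(r2$vertex); ctx <- t(r2$context)
  rownames(first) <- rownames(second) <- rownames(ctx) <- g$nodes$key
  behavior <- cbind(first, second)
  colnames(behavior) <- paste0("e", seq_len(config$dim))
  structure(list(first = first, second = second, context = ctx,
                 behavior = behavior, trace1 = r1$trace, trace2 = r2$trace,
                 config = config, nodes = g$nodes),
            class = "line_embedding")
}

#' @export
print.line_embedding <- function(x, ...) {
  cat(sprintf("LINE embedding: %d nodes x %d dims (%d per order)\n",
              nrow(x$behavior), ncol(x$behavior), ncol(x$first)))
  invisible(x)
}

#' Exact first- and second-order objectives
#'
#' Evaluates the untruncated objectives: the weighted negative
#' log-likelihood of each edge under the sigmoid first-order model, and
#' under the full-softmax second-order model over both directions of each
#' edge.  Intended as a small-graph training diagnostic and test oracle.
#'
#' @param g A `man_graph` with at most 2000 nodes.
#' @param embedding A `line_embedding`, or a list with matrices `first`,
#'   `second`, `context` (rownames = node keys).
#' @return Named numeric vector `c(L1, L2)`.
#' @export
exact_line_losses <- function(g, embedding) {
  n <- nrow(g$nodes)
  if (n > 2000L)
    stop("graph too large for the exact softmax; use the sampled trace instead")
  e <- g$edges
  U1 <- embedding$first[g$nodes$key, , drop = FALSE]
  L1 <- -sum(e$weight * log(vapply(seq_len(nrow(e)), function(i)
    first_order_prob(U1[e$u[i], ], U1[e$v[i], ]), numeric(1))))

  U2 <- embedding$second[g$nodes$key, , drop = FALSE]
  C <- embedding$context[g$nodes$key, , drop = FALSE]
  S <- U2 %*% t(C)                        # scores[a, k]
  lse <- apply(S, 1, function(r) { mx <- max(r); mx + log(sum(exp(r - mx))) })
  logp <- S - lse                         # log p2(k | a)
  from <- c(e$u, e$v); to <- c(e$v, e$u); w2 <- c(e$weight, e$weight)
  L2 <- -sum(w2 * logp[cbind(from, to)])
  c(L1 = L1, L2 = L2)
}

#' Full-gradient descent on the exact LINE objectives
#'
#' Reference optimizer for small graphs: plain gradient descent on the
#' exact first-order objective (vertex vectors) and the exact
#' second-order objective (vertex and context vectors), recording the
#' objective value at every step.  Complements the sampled trainer as an
#' independent check that both objectives are correctly specified.
#'
#' @param g A small `man_graph`.
#' @param dim Width per order.
#' @param steps Gradient steps.
#' @param lr Step size.
#' @param seed Seed for initialization.
#' @return List with `embedding` (a `line_embedding`-shaped list) and
#'   `L1`, `L2` (objective values, length `steps + 1`).
#' @export
line_descent_reference <- function(g, dim = 8L, steps = 25L, lr = 0.05,
                                   seed = 1L) {
  n <- nrow(g$nodes)
  if (n > 200L) stop("reference optimizer is for small graphs")
  e <- g$edges
  init <- function(off) with_local_seed(seed + off,
    matrix(stats::runif(n * dim, -0.5 / dim, 0.5 / dim), n, dim))
  U1 <- init(0L); U2 <- init(1L); C <- init(2L)
  rn <- g$nodes$key
  mk <- function() {
    rownames(U1) <- rownames(U2) <- rownames(C) <- rn
    list(first = U1, second = U2, context = C)
  }
  L1 <- numeric(steps + 1L); L2 <- numeric(steps + 1L)
  ls <- exact_line_losses(g, mk()); L1[1] <- ls["L1"]; L2[1] <- ls["L2"]
  from <- c(e$u, e$v); to <- c(e$v, e$u); w2 <- c(e$weight, e$weight)
  for (s in seq_len(steps)) {
    # first order: dL1/du_a = -sum_b w_ab (1 - sigma(ua.ub)) u_b (and sym.)
    G1 <- matrix(0, n, dim)
    for (i in seq_len(nrow(e))) {
      a <- e$u[i]; b <- e$v[i]
      gcoef <- e$weight[i] * (1 - first_order_prob(U1[a, ], U1[b, ]))
      G1[a, ] <- G1[a, ] - gcoef * U1[b, ]
      G1[b, ] <- G1[b, ] - gcoef * U1[a, ]
    }
    U1 <- U1 - lr * G1
    # second order: softmax cross-entropy over contexts
    S <- U2 %*% t(C)
    P <- exp(S - apply(S, 1, max)); P <- P / rowSums(P)
    out_w <- tapply(w2, from, sum)
    Wrow <- numeric(n); Wrow[as.integer(names(out_w))] <- out_w
    T <- matrix(0, n, n)
    T[cbind(from, to)] <- T[cbind(from, to)] + w2
    D <- Wrow * P - T                     # d L2 / d S
    GU <- D %*% C
    GC <- t(D) %*% U2
    U2 <- U2 - lr * GU
    C <- C - lr * GC
    ls <- exact_line_losses(g, mk()); L1[s + 1L] <- ls["L1"]; L2[s + 1L] <- ls["L2"]
  }
  list(embedding = mk(), L1 = L1, L2 = L2)
}

#' Write an embedding to TSV
#'
#' Columns `node_id`, `node_kind`, then `v1..v<dim>`; a `#` header line
#' records the width and order layout.
#'
#' @param embedding A `line_embedding`.
#' @param path Output path.
#' @export
write_embedding <- function(embedding, path) {
  stopifnot(inherits(embedding, "line_embedding"))
  dim <- ncol(embedding$behavior)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dim=%d order=first:%d+second:%d", dim,
                     ncol(embedding$first), ncol(embedding$second)), con)
  df <- data.frame(node_id = embedding$nodes$id,
                   node_kind = embedding$nodes$kind,
                   embedding$behavior, check.names = FALSE)
  names(df)[-(1:2)] <- paste0("v", seq_len(dim))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
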