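# Node2vec-style station embedding: biased second-order random walks over
# edge affinities feeding a skip-gram model with negative sampling (SGNS).
# Edge weights in the transit graph are stop distances, so walks use the
# affinity 1/weight: an express edge (weight 1) gets maximal affinity.

# Generate biased second-order walks. return_p and inout_q follow the usual
# roles: 1/p weight for returning to the previous node, 1 for moving to a
# common neighbour of the previous node, 1/q for moving outward.
node2vec_walks <- function(graph, num_walks, walk_length, return_p, inout_q) {
  nodes <- igraph::V(graph)$name
  nbrs <- lapply(nodes, function(v) {
    nb <- igraph::neighbors(graph, v)
    eids <- igraph::incident(graph, v)
    w <- igraph::edge_attr(graph, "weight", eids)
    if (is.null(w)) w <- rep(1, length(nb))
    list(ids = nb$name, aff = 1 / w)
  })
  names(nbrs) <- nodes
  walks <- list()
  for (iter in seq_len(num_walks)) {
    for (start in nodes) {
      if (length(nbrs[[start]]$ids) == 0) next   # isolated node: no walks
      walk <- character(walk_length)
      walk[1] <- start
      prev <- NA_character_
      for (step in 2:walk_length) {
        cur <- walk[step - 1]
        nb <- nbrs[[cur]]
        w <- nb$aff
        if (!is.na(prev)) {
          prev_nb <- nbrs[[prev]]$ids
          bias <- ifelse(nb$ids == prev, 1 / return_p,
                         ifelse(nb$ids %in% prev_nb, 1, 1 / inout_q))
          w <- w * bias
        }
        nxt <- if (length(nb$ids) == 1) nb$ids else
          sample(nb$ids, 1, prob = w)
        walk[step] <- nxt
        prev <- cur
      }
      walks[[length(walks) + 1L]] <- walk
    }
  }
  walks
}

# Skip-gram with negative sampling over the walk corpus. Returns the input
# (center) vectors. Unigram^(3/4) negative-sampling distribution.
sgns_embed <- function(walks, nodes, d, window, negative, epochs, lr) {
  vocab <- nodes
  nv <- length(vocab)
  counts <- table(factor(unlist(walks), levels = vocab))
  neg_prob <- as.numeric(counts)^0.75
  if (sum(neg_prob) == 0) neg_prob <- rep(1, nv)
  neg_prob <- neg_prob / sum(neg_prob)
  Win <- matrix(runif(nv * d, -0.5 / d, 0.5 / d), nv, d,
                dimnames = list(vocab, NULL))
  Wout <- matrix(0, nv, d, dimnames = list(vocab, NULL))
  iwalks <- lapply(walks, function(w) match(w, vocab))
  for (ep in seq_len(epochs)) {
    for (w in iwalks) {
      lw <- length(w)
      for (pos in seq_len(lw)) {
        ctx <- setdiff(max(1, pos - window):min(lw, pos + window), pos)
        ci <- w[pos]
        for (cj in w[ctx]) {
          neg <- sample.int(nv, negative, replace = TRUE, prob = neg_prob)
          targets <- c(cj, neg)
          labels <- c(1, numeric(negative))
          vin <- Win[ci, ]
          outs <- Wout[targets, , drop = FALSE]
          p <- sigmoid(drop(outs %*% vin))
          gscale <- (p - labels) * lr            # length negative+1
          gin <- drop(crossprod(outs, gscale))
          Wout[targets, ] <- outs - gscale %o% vin
          Win[ci, ] <- vin - gin
        }
      }
    }
  }
  Win
}

#' Embed stations with biased random walks + skip-gram
#'
#' Second-order (node2vec-style) random walks over the transit graph, with
#' transition affinities `1 / edge-weight` (weights are stop distances), fed
#' to a skip-gram model with negative sampling. Deterministic given `seed`.
#' Isolated nodes receive a zero vector with a warning.
#'
#' @param tg a `transit_graph` (or an igraph with a `weight` attribute).
#' @param d embedding dimension (default 16).
#' @param num_walks walks started per node (default 10).
#' @param walk_length nodes per walk (default 20).
#' @param window skip-gram context window (default 5).
#' @param return_p,inout_q walk bias parameters (default 1, 1).
#' @param negative negative samples per context pair (default 5).
#' @param epochs SGNS passes over the walk corpus (default 5).
#' @param learning_rate SGNS step size (default 0.025).
#' @param seed RNG seed.
#' @return matrix of station embeddings (rownames = station ids).
#' @export
embed_stations <- function(tg, d = 16, num_walks = 10, walk_length = 20,
                           window = 5, return_p = 1, inout_q = 1,
                           negative = 5, epochs = 5, learning_rate = 0.025,
                           seed = 1) {
  graph <- if (inherits(tg, "transit_graph")) tg$graph else tg
  nodes <- igraph::V(graph)$name
  set.seed(seed)
  walks <- node2vec_walks(graph, num_walks, walk_length, return_p, inout_q)
  deg <- igraph::degree(graph)
  isolated <- nodes[deg == 0]
  if (length(isolated))
    warning(length(isolated), " isolated station(s) get zero embeddings")
  dims <- paste0("dim", seq_len(d))
  if (length(walks) == 0) {
    return(matrix(0, length(nodes), d, dimnames = list(nodes, dims)))
  }
  emb <- sgns_embed(walks, nodes, d, window, negative, epochs, learning_rate)
  emb[isolated, ] <- 0
  colnames(emb) <- dims
  emb
}

#' Write / read a station embedding cache as TSV
#' @param embedding matrix from [embed_stations()].
#' @param path TSV path.
#' @export
write_embedding_tsv <- function(embedding, path) {
  write_matrix_tsv(embedding, path, id_col = "station_id")
}

#' @rdname write_embedding_tsv
#' @export
read_embedding_tsv <- function(path) read_matrix_tsv(path)
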