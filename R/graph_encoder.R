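# Hybrid molecular graph encoder: multi-head neighbourhood-restricted
# scaled dot-product attention, three multi-scale message-passing branches
# (1-layer GCN, 2-layer GCN, 3-layer mean-aggregator SAGE), linear scale
# fusion, dual global pooling and a two-layer projection to a 128-d
# molecule embedding.

init_graph_encoder <- function(cfg, variant) {
  g <- cfg$graph
  d <- g$input_dim
  A <- if (variant$attention) g$heads * g$head_dim else d
  p <- list()
  if (variant$attention) {
    p$attn <- lapply(seq_len(g$heads), function(k) list(
      q = init_linear(d, g$head_dim, "linear"),
      k = init_linear(d, g$head_dim, "linear"),
      v = init_linear(d, g$head_dim, "linear")))
  }
  if (variant$multiscale_graph) {
    p$gcn0 <- init_linear(A, g$branch_width, "relu")
    p$gcn1 <- init_linear(A, g$branch_width, "relu")
    p$gcn2 <- init_linear(g$branch_width, g$branch_width, "relu")
    p$sage1 <- init_linear(2L * A, g$branch_width, "relu")
    p$sage2 <- init_linear(2L * g$branch_width, g$branch_width, "relu")
    p$sage3 <- init_linear(2L * g$branch_width, g$branch_width, "relu")
    p$fuse <- init_linear(3L * g$branch_width, g$fused_width, "linear")
  } else {
    # simplified backbone: a single GCN stage feeding the same pooling
    p$gcn_single <- init_linear(A, g$fused_width, "relu")
  }
  p$proj1 <- init_linear(2L * g$fused_width, g$proj_hidden, "relu")
  p$proj2 <- init_linear(g$proj_hidden, g$embed_dim, "linear")
  p
}

# Stack a list of mol_graphs into one disjoint-union batch.
batch_graphs <- function(graphs) {
  ns <- vapply(graphs, function(g) g$heavy_atom_count, 1L)
  off <- cumsum(c(0L, ns[-length(ns)]))
  N <- sum(ns)
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  A <- matrix(0, N, N)
  for (i in seq_along(graphs)) {
    e <- graphs[[i]]$edges
    if (nrow(e)) A[cbind(e[, 1L] + off[i], e[, 2L] + off[i])] <- 1
  }
  list(X = X, A = A, groups = rep(seq_along(graphs), ns), n = N)
}

# Symmetric-normalised adjacency with self loops: D^-1/2 (A + I) D^-1/2.
gcn_norm_adj <- function(A) {
  Ah <- A + diag(nrow(A))
  d <- 1 / sqrt(rowSums(Ah))
  Ah * outer(d, d)
}

# Row-normalised neighbourhood (incl. self) for mean aggregation.
mean_adj <- function(A) {
  Ah <- A + diag(nrow(A))
  Ah / rowSums(Ah)
}

# Forward pass on the tape. pn: parameter nodes (or plain matrices for a
# frozen evaluation); bat: from batch_graphs(). Returns list of nodes.
graph_encoder_fwd <- function(tape, pn, bat, cfg, variant, training) {
  g <- cfg$graph
  X <- ad_const(tape, bat$X)
  mask <- bat$A + diag(bat$n) # self-loop policy
  if (!g$self_loops) {
    if (any(rowSums(bat$A) == 0))
      stop("isolated node with empty neighbourhood; enable graph$self_loops")
    mask <- bat$A
  }
  attn_maps <- NULL
  if (variant$attention) {
    masked_out <- mask == 0 # shared across heads
    heads <- vector("list", g$heads)
    attn_maps <- vector("list", g$heads)
    for (k in seq_len(g$heads)) {
      hp <- pn$attn[[k]]
      Q <- ly_linear(tape, X, hp$q)
      K <- ly_linear(tape, X, hp$k)
      V <- ly_linear(tape, X, hp$v)
      S <- ad_scale(tape, ad_mm(tape, Q, ad_transpose(tape, K)), 1 / sqrt(g$head_dim))
      Attn <- ad_masked_softmax(tape, S, masked_out)
      attn_maps[[k]] <- Attn
      heads[[k]] <- ad_mm(tape, Attn, V)
    }
    H0 <- ad_cbind(tape, heads)
  } else {
    H0 <- X
  }
  An <- ad_const(tape, gcn_norm_adj(bat$A))
  if (variant$multiscale_graph) {
    Hshort <- ad_relu(tape, ly_linear(tape, ad_mm(tape, An, H0), pn$gcn0))
    Hmid1 <- ad_relu(tape, ly_linear(tape, ad_mm(tape, An, H0), pn$gcn1))
    Hmid <- ad_relu(tape, ly_linear(tape, ad_mm(tape, An, Hmid1), pn$gcn2))
    Mn <- ad_const(tape, mean_adj(bat$A))
    sage_layer <- function(H, p) {
      ad_relu(tape, ly_linear(tape, ad_cbind(tape, list(H, ad_mm(tape, Mn, H))), p))
    }
    Hlong <- sage_layer(sage_layer(sage_layer(H0, pn$sage1), pn$sage2), pn$sage3)
    Hout <- ly_linear(tape, ad_cbind(tape, list(Hshort, Hmid, Hlong)), pn$fuse)
  } else {
    Hout <- ad_relu(tape, ly_linear(tape, ad_mm(tape, An, H0), pn$gcn_single))
    Hshort <- Hmid <- Hlong <- NULL
  }
  fmol <- ad_cbind(tape, list(ad_group_max(tape, Hout, bat$groups),
                              ad_group_mean(tape, Hout, bat$groups)))
  h1 <- ad_dropout(tape, ad_relu(tape, ly_linear(tape, fmol, pn$proj1)),
                   g$dropout, training)
  ffinal <- ly_linear(tape, h1, pn$proj2)
  list(H0 = H0, attn = attn_maps, Hshort = Hshort, Hmid = Hmid, Hlong = Hlong,
       Hout = Hout, fmol = fmol, ffinal = ffinal)
}

#' Multi-head neighbourhood-restricted graph attention
#'
#' Per head, node features are projected to query/key/value spaces, raw
#' scaled dot-product scores are softmax-normalised over each node's
#' neighbourhood (self loops included by default), and values are aggregated
#' with the resulting weights; heads are concatenated channel-wise.
#'
#' @param graph A `mol_graph`.
#' @param model A model from [build_model()] (must use attention).
#' @return List with `H0` (|V| x heads*head_dim matrix) and `attn` (list of
#'   per-head |V| x |V| attention matrices, zero outside the neighbourhood).
#' @export
multihead_graph_attention <- function(graph, model) {
  if (!model$variant$attention) stop("variant has no attention stage")
  tape <- ad_tape()
  bat <- batch_graphs(list(graph))
  out <- graph_encoder_fwd(tape, model$params$graph, bat, model$config,
                           model$variant, training = FALSE)
  list(H0 = out$H0$val, attn = lapply(out$attn, function(a) a$val))
}

#' Encode molecules into fixed-length embeddings
#'
#' Full graph-branch forward pass in evaluation mode.
#'
#' @param model A model from [build_model()].
#' @param graphs A `mol_graph` or list of them.
#' @return Matrix with one row per molecule (`embed_dim` columns).
#' @export
encode_molecules <- function(model, graphs) {
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  tape <- ad_tape()
  bat <- batch_graphs(graphs)
  out <- graph_encoder_fwd(tape, model$params$graph, bat, model$config,
                           model$variant, training = FALSE)
  out$ffinal$val
}
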