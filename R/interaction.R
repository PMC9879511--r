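# Multi-GNN substructure stacks and drug-drug co-attention.
#
# L independent SA-DMPNN blocks are stacked; block l consumes block l-1's
# node features (raw 42-dim atom features for l = 1) while the original
# bond features are reused at every block's bond-state initialization.
# Each layer is pooled into a substructure vector g^(l) with node
# importances beta_i (softmax of a graph-convolution scorer over the
# molecule's atoms -- scores only, no top-k truncation). The two drugs'
# stacks are coupled by the co-attention map
# gamma_ij = b' tanh(W_x g_x^(i) + W_y g_y^(j)), left unnormalized as the
# model defines it (an optional per-tuple softmax is available behind
# `gamma_norm`). The reweighted layers sum to the final graph-level
# representations g_x, g_y.

#' Create Multi-GNN + co-attention parameters
#'
#' @param L number of stacked encoder blocks.
#' @param h hidden dimension.
#' @param T message passing steps per block.
#' @param d_in input atom-feature dimension of the first block.
#' @return named list: `blocks` (L encoder parameter sets),
#'   `theta_node`/`b_node` (per-layer node scorers), `Wx`, `Wy`, `b_co`
#'   (co-attention), and `meta`.
#' @export
multignn_params <- function(L = 3L, h = 64L, T = 3L, d_in = 42L) {
  stopifnot(L >= 1L)
  list(
    blocks = lapply(seq_len(L), function(l)
      encoder_params(d_in = if (l == 1L) d_in else h, h = h, T = T)),
    theta_node = lapply(seq_len(L), function(l) .glorot(h, 1L)),
    b_node = lapply(seq_len(L), function(l) .zeros(1L, 1L)),
    Wx = .glorot(h, h), Wy = .glorot(h, h), b_co = .glorot(h, 1L),
    meta = list(L = L, h = h, T = T, d_in = d_in))
}

# tape forward of the full stack over a batch; returns per-layer handles
.stack_forward <- function(tape, wp, batch, beta_mode = "recompute",
                           alpha_mode = "softmax") {
  L <- wp$meta$L
  X <- td_node(tape, batch$X)
  g <- vector("list", L)
  beta_node <- vector("list", L)
  node_features <- vector("list", L)
  enc <- vector("list", L)
  for (l in seq_len(L)) {
    fw <- .encoder_forward(tape, wp$blocks[[l]], batch, X,
                           beta_mode = beta_mode, alpha_mode = alpha_mode)
    Hn <- fw$H_nodes
    s <- td_add(td_matmul(td_spmm(batch$A_atom_norm, Hn), wp$theta_node[[l]]),
                wp$b_node[[l]])
    bn <- td_group_softmax(s, batch$atom_graph)
    g[[l]] <- td_spmm(batch$P_atom, td_scale_rows(Hn, bn))   # ng x h
    beta_node[[l]] <- bn
    node_features[[l]] <- Hn
    enc[[l]] <- fw
    X <- Hn
  }
  list(g = g, beta_node = beta_node, node_features = node_features,
       encoder = enc)
}

#' Per-layer substructure representations of one drug
#'
#' Runs the L stacked encoder blocks on a single molecule and pools each
#' layer: `g^(l) = sum_i beta_i h_i^(l)` with `beta_i` the softmax of the
#' node scorer over the molecule's atoms.
#'
#' @param graph a `molecular_graph`.
#' @param params Multi-GNN parameters ([multignn_params()]).
#' @inheritParams encode
#' @return list with `g` (L x h matrix, one row per layer),
#'   `node_importance` (list of per-layer beta vectors, each summing
#'   to 1) and `node_features` (list of per-layer atoms x h matrices).
#' @export
layer_representations <- function(graph, params, beta_mode = "recompute",
                                  alpha_mode = "softmax") {
  tape <- new_tape()
  wp <- td_wrap_params(tape, params, track = FALSE)
  bt <- batch_graphs(list(graph))
  fw <- .stack_forward(tape, wp, bt, beta_mode, alpha_mode)
  list(g = do.call(rbind, lapply(fw$g, td_value)),
       node_importance = lapply(fw$beta_node,
                                function(b) as.vector(td_value(b))),
       node_features = lapply(fw$node_features, td_value))
}

#' Co-attention map between two substructure stacks
#'
#' `gamma_ij = b' tanh(W_x g_x^(i) + W_y g_y^(j))` for layer pairs
#' i, j = 1..L. No normalization is applied by default.
#'
#' @param stack_x,stack_y L x h matrices of per-layer substructure
#'   vectors (rows `g^(l)`), e.g. the `g` component of
#'   [layer_representations()].
#' @param params Multi-GNN parameters.
#' @param gamma_norm `"none"` (default) or `"softmax"` (softmax over all
#'   L^2 entries).
#' @return L x L matrix gamma.
#' @export
co_attention <- function(stack_x, stack_y, params, gamma_norm = "none") {
  L <- nrow(stack_x)
  stopifnot(nrow(stack_y) == L)
  Zx <- stack_x %*% params$Wx
  Zy <- stack_y %*% params$Wy
  gamma <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L))
    gamma[i, j] <- sum(tanh(Zx[i, ] + Zy[j, ]) * params$b_co)
  if (gamma_norm == "softmax") {
    ex <- exp(gamma - max(gamma))
    gamma <- ex / sum(ex)
  }
  gamma
}

#' Reweight substructure stacks by the co-attention map and pool
#'
#' `g_hat_x^(i) = sum_j gamma_ij g_x^(i)` (row sums of gamma scale drug
#' x's layers), `g_hat_y^(j) = sum_i gamma_ij g_y^(j)` (column sums scale
#' drug y's), and the final graph-level representations are the sums over
#' layers.
#'
#' @inheritParams co_attention
#' @param gamma L x L co-attention matrix.
#' @return list with `g_x`, `g_y` (length-h vectors), `g_hat_x`,
#'   `g_hat_y` (L x h matrices) and `gamma`.
#' @export
reweight_and_pool <- function(stack_x, stack_y, gamma) {
  g_hat_x <- stack_x * rowSums(gamma)
  g_hat_y <- stack_y * colSums(gamma)
  list(g_x = colSums(g_hat_x), g_y = colSums(g_hat_y),
       g_hat_x = g_hat_x, g_hat_y = g_hat_y, gamma = gamma)
}

# ---- batched tape versions used in training -----------------------------

# gathered stacks: for tuples with graph indices xi, yi (into the batch),
# returns co-attention pooled representations as tape nodes.
# sx, sy: lists (length L) of ng x h nodes; xi, yi integer vectors.
.coattention_forward <- function(tape, wp, stacks, xi, yi,
                                 gamma_norm = "none") {
  L <- wp$meta$L
  Sx <- lapply(stacks, function(gl) td_rows(gl, xi))      # n_t x h
  Sy <- lapply(stacks, function(gl) td_rows(gl, yi))
  Zx <- lapply(Sx, function(s) td_matmul(s, wp$Wx))
  Zy <- lapply(Sy, function(s) td_matmul(s, wp$Wy))
  gamma <- vector("list", L)
  for (i in seq_len(L)) {
    gamma[[i]] <- vector("list", L)
    for (j in seq_len(L))
      gamma[[i]][[j]] <- td_matmul(td_tanh(td_add(Zx[[i]], Zy[[j]])),
                                   wp$b_co)               # n_t x 1
  }
  if (gamma_norm == "softmax") {
    nt <- length(xi)
    flat <- td_vconcat(unlist(gamma, recursive = FALSE))
    sm <- td_group_softmax(flat, rep(seq_len(nt), L * L))
    k <- 0L
    for (i in seq_len(L)) for (j in seq_len(L)) {
      k <- k + 1L
      gamma[[i]][[j]] <- td_rows(sm, ((k - 1L) * nt + 1L):(k * nt))
    }
  }
  gx <- NULL; gy <- NULL
  for (i in seq_len(L)) {
    rs <- Reduce(td_add, gamma[[i]])                      # sum over j
    term <- td_scale_rows(Sx[[i]], rs)
    gx <- if (is.null(gx)) term else td_add(gx, term)
  }
  for (j in seq_len(L)) {
    cs <- Reduce(td_add, lapply(gamma, `[[`, j))          # sum over i
    term <- td_scale_rows(Sy[[j]], cs)
    gy <- if (is.null(gy)) term else td_add(gy, term)
  }
  list(g_x = gx, g_y = gy, gamma = gamma, Sx = Sx, Sy = Sy)
}
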