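# Substructure-attentive directed message passing encoder (SA-DMPNN).
#
# Bond states are initialized from both endpoint atoms and the bond
# features, then updated for T steps with the directed-MPNN rule that
# excludes the reverse bond. At every step a self-attention graph-pooling
# scorer (one graph convolution on the bond line graph) assigns each
# directed bond an importance beta, normalized by softmax over the
# incoming bonds of its target atom so node messages are convex
# combinations. Per-step graph summaries compete through a softmax
# attention over steps (alpha), and the alpha-weighted bond states are
# finally aggregated into node-level features through a one-hidden-layer
# MLP. Each step's summary spans substructures of radius t, so alpha is
# interpretable as a distribution over substructure sizes.

#' Create SA-DMPNN encoder parameters
#'
#' Weights are Glorot-uniform, biases zero; draws from the current RNG
#' stream (seed control belongs to the caller, see [ddi_model()]).
#'
#' @param d_in input atom-feature dimension (42 for raw molecular graphs,
#'   the hidden size for stacked blocks).
#' @param h hidden dimension.
#' @param T number of message passing steps (>= 1).
#' @return named list of parameter matrices plus a `meta` entry.
#' @export
encoder_params <- function(d_in = 42L, h = 64L, T = 3L) {
  stopifnot(T >= 1L, h >= 1L, d_in >= 1L)
  list(
    Wi = .glorot(d_in, h), Wj = .glorot(d_in, h), Wij = .glorot(6L, h),
    Wm = .glorot(h, h),
    theta_bond = .glorot(h, 1L), b_bond = .zeros(1L, 1L),
    w_att = lapply(seq_len(T), function(t) .glorot(h, 1L)),
    W_att = .glorot(h, h), b_att = .zeros(1L, h),
    W0 = .glorot(d_in, h),
    W1 = .glorot(h, h), b1 = .zeros(1L, h),
    W2 = .glorot(h, h), b2 = .zeros(1L, h),
    meta = list(d_in = d_in, h = h, T = T))
}

# uniform beta over the incoming bonds of each target atom (constant)
.uniform_beta <- function(batch) {
  if (batch$n_bonds == 0L) return(matrix(numeric(0), 0L, 1L))
  indeg <- tabulate(batch$dst, nbins = batch$n_atoms)
  matrix(1 / indeg[batch$dst], ncol = 1L)
}

# full tape forward of one encoder block over a graph batch.
# wp: wrapped params; X: tracked node (N x d_in).
# beta_mode: "recompute" (each step), "once" (step 1 scores reused),
# "uniform"; alpha_mode: "softmax" or "uniform".
.encoder_forward <- function(tape, wp, batch, X,
                             beta_mode = "recompute",
                             alpha_mode = "softmax") {
  T <- wp$meta$T
  ng <- batch$n_graphs
  Xb <- td_node(tape, batch$Xb)
  Xs <- td_spmm(batch$S_src, X)
  Xd <- td_spmm(batch$S_dst, X)
  H0 <- td_add(td_add(td_matmul(Xs, wp$Wi), td_matmul(Xd, wp$Wj)),
               td_matmul(Xb, wp$Wij))
  H <- vector("list", T)
  beta <- vector("list", T)
  g_step <- vector("list", T)
  e_step <- vector("list", T)
  Hprev <- H0
  beta_once <- NULL
  for (t in seq_len(T)) {
    P <- td_spmm(batch$B_msg, Hprev)
    Ht <- td_relu(td_add(H0, td_matmul(P, wp$Wm)))
    bt <- switch(beta_mode,
      uniform = td_node(tape, .uniform_beta(batch)),
      once = {
        if (is.null(beta_once)) {
          s <- td_add(td_matmul(td_spmm(batch$A_line_norm, Ht),
                                wp$theta_bond), wp$b_bond)
          beta_once <- td_group_softmax(s, batch$dst)
        }
        beta_once
      },
      recompute = {
        s <- td_add(td_matmul(td_spmm(batch$A_line_norm, Ht),
                              wp$theta_bond), wp$b_bond)
        td_group_softmax(s, batch$dst)
      },
      stop("unknown beta_mode: ", beta_mode))
    Wb <- td_scale_rows(Ht, bt)
    gt <- td_spmm(batch$P_bond, Wb)                      # ng x h
    et <- td_matmul(td_tanh(td_add(td_matmul(gt, wp$W_att), wp$b_att)),
                    wp$w_att[[t]])                       # ng x 1
    H[[t]] <- Ht; beta[[t]] <- bt; g_step[[t]] <- gt; e_step[[t]] <- et
    Hprev <- Ht
  }
  if (alpha_mode == "uniform") {
    alpha <- lapply(seq_len(T), function(t)
      td_node(tape, matrix(1 / T, ng, 1L)))
  } else {
    all_e <- td_vconcat(e_step)
    al <- td_group_softmax(all_e, rep(seq_len(ng), T))
    alpha <- lapply(seq_len(T), function(t)
      td_rows(al, ((t - 1L) * ng + 1L):(t * ng)))
  }
  H_final <- NULL
  for (t in seq_len(T)) {
    ab <- td_spmm(batch$E_bond, alpha[[t]])              # per-bond alpha
    term <- td_scale_rows(H[[t]], ab)
    H_final <- if (is.null(H_final)) term else td_add(H_final, term)
  }
  Z <- td_add(td_matmul(X, wp$W0), td_spmm(batch$G_in, H_final))
  hidden <- td_relu(td_add(td_matmul(Z, wp$W1), wp$b1))
  H_nodes <- td_add(td_matmul(hidden, wp$W2), wp$b2)
  list(H0 = H0, H = H, beta = beta, g_step = g_step, e_step = e_step,
       alpha = alpha, H_final = H_final, H_nodes = H_nodes)
}

# ---- single-graph numeric surface ---------------------------------------

#' Initialize bond-level hidden states
#'
#' For each directed bond i->j the initial state is
#' `W_i x_i + W_j x_j + W_ij x_ij`.
#'
#' @param graph a `molecular_graph`.
#' @param params encoder parameters ([encoder_params()]).
#' @return matrix (directed bonds x h).
#' @export
init_bond_states <- function(graph, params) {
  X <- graph$atom_features
  if (ncol(X) != nrow(params$Wi))
    stop("atom feature size ", ncol(X), " does not match encoder d_in ",
         nrow(params$Wi), call. = FALSE)
  X[graph$src, , drop = FALSE] %*% params$Wi +
    X[graph$dst, , drop = FALSE] %*% params$Wj +
    graph$bond_features %*% params$Wij
}

#' Bond importance scores (self-attention graph pooling)
#'
#' One graph-convolution layer over the bond line graph (two directed
#' bonds are adjacent iff they share an atom) produces a raw score per
#' bond; scores are softmax-normalized over the incoming-bond set of each
#' target atom, so the per-node weights of the message sum are a convex
#' combination.
#'
#' @param graph a `molecular_graph`.
#' @param bond_states current bond-state matrix (directed bonds x h).
#' @param params encoder parameters.
#' @return column vector of importances beta (one per directed bond);
#'   `sum(beta[dst == i]) == 1` for every atom i with incoming bonds.
#' @export
compute_bond_importance <- function(graph, bond_states, params) {
  bt <- batch_graphs(list(graph))
  s <- as.vector(as.matrix(bt$A_line_norm %*% bond_states) %*%
                   params$theta_bond) + params$b_bond[1L]
  .group_softmax_num(s, graph$dst)
}

.group_softmax_num <- function(s, groups) {
  if (length(s) == 0L) return(matrix(numeric(0), 0L, 1L))
  gi <- as.integer(groups)
  mx <- tapply(s, gi, max)[as.character(gi)]
  ex <- exp(s - mx)
  den <- rowsum(ex, gi)[as.character(gi), 1L]
  matrix(ex / den, ncol = 1L)
}

#' One message passing step
#'
#' Updates bond states with the directed-MPNN rule
#' `h_ij^(t) = ReLU(h_ij^(0) + W_m * sum_{k in N(i) \\ j} h_ki^(t-1))`
#' (the reverse bond is excluded from the neighbor sum), then forms node
#' messages `m_i = sum_j beta_ji h_ji^(t)` and the graph summary
#' `g^(t) = sum_i m_i`.
#'
#' @param graph a `molecular_graph`.
#' @param h0 initial bond states ([init_bond_states()]).
#' @param h_prev bond states after step t-1 (equal to `h0` for t = 1).
#' @param params encoder parameters.
#' @param beta optional importance column; recomputed from the updated
#'   states when `NULL` (the default behavior of [encode()]).
#' @return list with `h_bond` (updated states), `beta`, `m_node`
#'   (atoms x h) and `g_step` (1 x h).
#' @export
message_step <- function(graph, h0, h_prev, params, beta = NULL) {
  bt <- batch_graphs(list(graph))
  h_t <- pmax(h0 + as.matrix(bt$B_msg %*% h_prev) %*% params$Wm, 0)
  if (is.null(beta)) beta <- compute_bond_importance(graph, h_t, params)
  m_node <- as.matrix(bt$G_in %*% (h_t * as.vector(beta)))
  g_step <- matrix(colSums(h_t * as.vector(beta)), 1L)
  list(h_bond = h_t, beta = beta, m_node = m_node, g_step = g_step)
}

#' Substructure attention over message passing steps
#'
#' Computes the per-step logit `e^(t) = <w^(t), tanh(W g^(t) + b)>` and
#' its softmax normalization alpha over steps.
#'
#' @param g_steps matrix of per-step graph summaries (T x h, one row per
#'   step) or list of 1 x h rows.
#' @param params encoder parameters.
#' @return list with `e` and `alpha` (numeric vectors of length T).
#' @export
substructure_attention <- function(g_steps, params) {
  if (is.list(g_steps)) g_steps <- do.call(rbind, g_steps)
  T <- nrow(g_steps)
  z <- tanh(sweep(g_steps %*% params$W_att, 2L, as.vector(params$b_att), "+"))
  e <- vapply(seq_len(T), function(t)
    sum(z[t, ] * params$w_att[[t]]), numeric(1))
  a <- exp(e - max(e))
  list(e = e, alpha = a / sum(a))
}

#' Aggregate bond states across steps
#'
#' `h_ji = sum_t alpha^(t) h_ji^(t)`.
#'
#' @param states list of per-step bond-state matrices.
#' @param alpha step weights (length T, summing to 1).
#' @return matrix (directed bonds x h).
#' @export
aggregate_bond_states <- function(states, alpha) {
  stopifnot(length(states) == length(alpha))
  Reduce(`+`, Map(function(H, a) H * a, states, alpha))
}

#' Node features from aggregated bond states
#'
#' `h_i = f(W_0 x_i + sum_{j in N(i)} h_ji)` with f a one-hidden-layer
#' MLP. The learned input projection `W_0` lifts the raw atom features
#' into the hidden space before adding the incoming-bond sum.
#'
#' @param graph a `molecular_graph`.
#' @param h_final aggregated bond states ([aggregate_bond_states()]).
#' @param params encoder parameters.
#' @return matrix (atoms x h).
#' @export
finalize_node_features <- function(graph, h_final, params) {
  bt <- batch_graphs(list(graph))
  Z <- graph$atom_features %*% params$W0 + as.matrix(bt$G_in %*% h_final)
  hidden <- pmax(sweep(Z %*% params$W1, 2L, as.vector(params$b1), "+"), 0)
  sweep(hidden %*% params$W2, 2L, as.vector(params$b2), "+")
}

#' Encode one molecular graph with the SA-DMPNN
#'
#' Full composition: bond-state initialization, T message passing steps
#' with bond importances, step attention, bond aggregation and the final
#' node MLP. Deterministic given parameters.
#'
#' @param graph a `molecular_graph`.
#' @param params encoder parameters ([encoder_params()]).
#' @param beta_mode `"recompute"` (importances from the freshest states at
#'   every step, default), `"once"` (computed at step 1, reused) or
#'   `"uniform"`.
#' @param alpha_mode `"softmax"` (default) or `"uniform"` (frozen 1/T).
#' @param detail return all intermediates instead of node features only.
#' @return matrix of node features (atoms x h), or (with `detail = TRUE`)
#'   a list with `node_features`, `bond_states` (per step), `beta` (per
#'   step), `g_step`, `e`, `alpha`, `h0` and `h_final`.
#' @export
encode <- function(graph, params, beta_mode = "recompute",
                   alpha_mode = "softmax", detail = FALSE) {
  tape <- new_tape()
  wp <- td_wrap_params(tape, params, track = FALSE)
  bt <- batch_graphs(list(graph))
  X <- td_node(tape, bt$X)
  fw <- .encoder_forward(tape, wp, bt, X, beta_mode = beta_mode,
                         alpha_mode = alpha_mode)
  if (!detail) return(td_value(fw$H_nodes))
  list(node_features = td_value(fw$H_nodes),
       h0 = td_value(fw$H0),
       bond_states = lapply(fw$H, td_value),
       beta = lapply(fw$beta, function(b) as.vector(td_value(b))),
       g_step = lapply(fw$g_step, td_value),
       e = vapply(fw$e_step, function(e) td_value(e)[1L, 1L], numeric(1)),
       alpha = vapply(fw$alpha, function(a) td_value(a)[1L, 1L], numeric(1)),
       h_final = td_value(fw$H_final))
}
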