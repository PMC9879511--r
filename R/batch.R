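# Disjoint-union batching of molecular graphs.
#
# All graphs of a mini-batch are concatenated into one block-diagonal
# structure; every aggregation the encoder needs (source/target gather,
# incoming-bond scatter, neighbor sums excluding the reverse bond, the
# line-graph and atom-graph convolution supports, per-graph pooling) is
# precomputed once as a constant sparse matrix, so the forward pass is a
# chain of (sparse) matrix products.

.sym_norm_adj <- function(A) {
  # add self-loops and apply D^-1/2 (A + I) D^-1/2 (GCN normalization)
  n <- nrow(A)
  if (n == 0L) return(A)
  A <- A + Matrix::Diagonal(n)
  d <- Matrix::rowSums(A)
  Dm <- Matrix::Diagonal(n, 1 / sqrt(pmax(d, 1e-12)))
  Dm %*% A %*% Dm
}

.sparse01 <- function(i, j, nr, nc) {
  Matrix::sparseMatrix(i = i, j = j, x = rep(1, length(i)),
                       dims = c(nr, nc))
}

#' Batch molecular graphs into one block-diagonal structure
#'
#' @param graphs list of `molecular_graph` objects.
#' @return A `graph_batch`: concatenated feature matrices `X` (atoms x 42)
#'   and `Xb` (directed bonds x 6), global index vectors (`src`, `dst`,
#'   `rev`, `atom_graph`, `bond_graph`) and the constant sparse operators
#'   used by the encoder (`S_src`, `S_dst`, `G_in`, `B_msg`,
#'   `A_line_norm`, `A_atom_norm`, `P_atom`, `P_bond`, `E_bond`).
#' @export
batch_graphs <- function(graphs) {
  ng <- length(graphs)
  stopifnot(ng >= 1L)
  n_atoms <- vapply(graphs, function(g) g$n_atoms, integer(1))
  n_bonds <- vapply(graphs, function(g) g$n_directed_bonds, integer(1))
  atom_off <- cumsum(c(0L, n_atoms))[seq_len(ng)]
  bond_off <- cumsum(c(0L, n_bonds))[seq_len(ng)]
  N <- sum(n_atoms); M <- sum(n_bonds)

  X <- do.call(rbind, lapply(graphs, function(g) g$atom_features))
  Xb <- if (M > 0) do.call(rbind, lapply(graphs, function(g) g$bond_features))
        else matrix(numeric(0), 0L, 6L)
  src <- unlist(lapply(seq_len(ng), function(k)
    graphs[[k]]$src + atom_off[k]), use.names = FALSE)
  dst <- unlist(lapply(seq_len(ng), function(k)
    graphs[[k]]$dst + atom_off[k]), use.names = FALSE)
  rev <- unlist(lapply(seq_len(ng), function(k)
    graphs[[k]]$reverse_index + bond_off[k]), use.names = FALSE)
  if (is.null(src)) src <- dst <- rev <- integer(0)
  atom_graph <- rep(seq_len(ng), n_atoms)
  bond_graph <- rep(seq_len(ng), n_bonds)

  S_src <- .sparse01(seq_len(M), src, M, N)
  S_dst <- .sparse01(seq_len(M), dst, M, N)
  G_in <- .sparse01(dst, seq_len(M), N, M)

  # B_msg[k, k'] = 1 iff bond k' ends at the source of bond k and k' is
  # not the reverse of k (directed-MPNN neighbor sum)
  if (M > 0) {
    in_by_node <- split(seq_len(M), factor(dst, levels = seq_len(N)))
    lens <- lengths(in_by_node)
    bi <- rep(seq_len(M), lens[src])
    bj <- unlist(in_by_node[src], use.names = FALSE)
    keep <- bj != rev[bi]
    B_msg <- .sparse01(bi[keep], bj[keep], M, M)
    # line graph: two directed bonds are adjacent iff they share an atom
    U <- .sparse01(c(seq_len(M), seq_len(M)), c(src, dst), M, N)
    A_line <- Matrix::tcrossprod(U)
    A_line <- 1 * (A_line > 0)
    Matrix::diag(A_line) <- 0
    A_line_norm <- .sym_norm_adj(A_line)
  } else {
    B_msg <- .sparse01(integer(0), integer(0), 0L, 0L)
    A_line_norm <- B_msg
  }

  A_atom <- .sparse01(c(src, dst), c(dst, src), N, N)
  A_atom <- 1 * (A_atom > 0)
  A_atom_norm <- .sym_norm_adj(A_atom)

  P_atom <- .sparse01(atom_graph, seq_len(N), ng, N)
  P_bond <- if (M > 0) .sparse01(bond_graph, seq_len(M), ng, M)
            else .sparse01(integer(0), integer(0), ng, 0L)
  E_bond <- Matrix::t(P_bond)

  structure(list(
    n_graphs = ng, n_atoms = N, n_bonds = M,
    atom_offsets = atom_off, bond_offsets = bond_off,
    X = X, Xb = Xb, src = src, dst = dst, rev = rev,
    atom_graph = atom_graph, bond_graph = bond_graph,
    S_src = S_src, S_dst = S_dst, G_in = G_in, B_msg = B_msg,
    A_line_norm = A_line_norm, A_atom_norm = A_atom_norm,
    P_atom = P_atom, P_bond = P_bond, E_bond = E_bond),
    class = "graph_batch")
}
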