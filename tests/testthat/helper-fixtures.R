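# Shared fixtures: toy graphs with fabricated features and small parsed
# molecules. Parsing is done once per test run.

quiet_parse <- function(s) suppressWarnings(parse_smiles(s))

# build a molecular-graph-shaped object directly from feature matrices
# (bypasses featurization; for encoder-level tests with arbitrary dims)
toy_graph <- function(atom_features, edges, bond_features = NULL) {
  n <- nrow(atom_features)
  m <- nrow(edges)
  if (is.null(bond_features)) bond_features <- matrix(1, m, 6L)
  if (m > 0) {
    src <- as.vector(rbind(edges[, 1], edges[, 2]))
    dst <- as.vector(rbind(edges[, 2], edges[, 1]))
    bf <- bond_features[rep(seq_len(m), each = 2L), , drop = FALSE]
    rev <- as.vector(rbind(seq_len(m) * 2L, seq_len(m) * 2L - 1L))
  } else {
    src <- dst <- rev <- integer(0)
    bf <- matrix(numeric(0), 0L, ncol(bond_features))
  }
  structure(list(n_atoms = n, n_directed_bonds = 2L * m,
                 atom_features = atom_features, bond_features = bf,
                 src = src, dst = dst, reverse_index = rev,
                 element = rep("C", n),
                 atoms = NULL, bonds = NULL, smiles = NA_character_),
            class = "molecular_graph")
}

# random toy graph: path or ring over n atoms, d-dimensional features
random_toy_graph <- function(n, d = 6L, ring = FALSE) {
  edges <- cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  if (ring && n > 2L) edges <- rbind(edges, c(n, 1L))
  toy_graph(matrix(rnorm(n * d), n, d),
            edges, matrix(rnorm(nrow(edges) * 6L), nrow(edges), 6L))
}

# relabel the atoms of a graph by permutation `perm` (new index of old
# atom i is perm[i]); bond order is preserved
permute_graph <- function(g, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  g2 <- g
  g2$atom_features <- g$atom_features[inv, , drop = FALSE]
  g2$src <- perm[g$src]
  g2$dst <- perm[g$dst]
  g2$element <- g$element[inv]
  g2
}

small_encoder_params <- function(d_in, h, T, seed = 1) {
  withr::with_seed(seed, encoder_params(d_in = d_in, h = h, T = T))
}
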