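# Independent dense brute-force implementations used as oracles. These
# deliberately share no code with the package: everything is explicit
# per-bond / per-atom loops on base matrices.

oracle_relu <- function(x) pmax(x, 0)

oracle_line_graph_norm <- function(g) {
  m <- g$n_directed_bonds
  A <- matrix(0, m, m)
  for (k in seq_len(m)) for (l in seq_len(m)) {
    if (k == l) next
    if (length(intersect(c(g$src[k], g$dst[k]),
                         c(g$src[l], g$dst[l]))) > 0) A[k, l] <- 1
  }
  A <- A + diag(m)
  d <- rowSums(A)
  diag(1 / sqrt(d)) %*% A %*% diag(1 / sqrt(d))
}

oracle_atom_graph_norm <- function(g) {
  n <- g$n_atoms
  A <- matrix(0, n, n)
  for (k in seq_len(g$n_directed_bonds)) A[g$src[k], g$dst[k]] <- 1
  A <- 1 * ((A + t(A)) > 0) + diag(n)
  d <- rowSums(A)
  diag(1 / sqrt(d)) %*% A %*% diag(1 / sqrt(d))
}

oracle_group_softmax <- function(s, groups) {
  p <- numeric(length(s))
  for (gr in unique(groups)) {
    i <- which(groups == gr)
    e <- exp(s[i] - max(s[i]))
    p[i] <- e / sum(e)
  }
  p
}

# full SA-DMPNN forward on one graph, explicit loops
oracle_encode <- function(g, params, beta_mode = "recompute",
                          alpha_mode = "softmax") {
  T <- params$meta$T
  h <- params$meta$h
  n <- g$n_atoms
  m <- g$n_directed_bonds
  X <- g$atom_features
  H0 <- matrix(0, m, h)
  for (k in seq_len(m))
    H0[k, ] <- X[g$src[k], ] %*% params$Wi + X[g$dst[k], ] %*% params$Wj +
      g$bond_features[k, ] %*% params$Wij
  Aln <- if (m > 0) oracle_line_graph_norm(g) else matrix(0, 0, 0)
  H <- list(); beta <- list(); gs <- list(); e <- numeric(T)
  Hprev <- H0
  beta_once <- NULL
  for (t in seq_len(T)) {
    Ht <- matrix(0, m, h)
    for (k in seq_len(m)) {
      acc <- rep(0, h)
      for (l in seq_len(m)) {
        if (g$dst[l] == g$src[k] && l != g$reverse_index[k])
          acc <- acc + Hprev[l, ]
      }
      Ht[k, ] <- oracle_relu(H0[k, ] + acc %*% params$Wm)
    }
    bt <- switch(beta_mode,
      uniform = {
        b <- numeric(m)
        for (k in seq_len(m)) b[k] <- 1 / sum(g$dst == g$dst[k])
        b
      },
      once = {
        if (is.null(beta_once)) {
          s <- as.vector(Aln %*% Ht %*% params$theta_bond) +
            params$b_bond[1]
          beta_once <- oracle_group_softmax(s, g$dst)
        }
        beta_once
      },
      recompute = {
        s <- as.vector(Aln %*% Ht %*% params$theta_bond) + params$b_bond[1]
        oracle_group_softmax(s, g$dst)
      })
    mi <- matrix(0, n, h)
    for (k in seq_len(m)) mi[g$dst[k], ] <- mi[g$dst[k], ] + bt[k] * Ht[k, ]
    gt <- colSums(mi)
    z <- tanh(as.vector(gt %*% params$W_att) + as.vector(params$b_att))
    e[t] <- sum(z * params$w_att[[t]])
    H[[t]] <- Ht; beta[[t]] <- bt; gs[[t]] <- gt
    Hprev <- Ht
  }
  alpha <- if (alpha_mode == "uniform") rep(1 / T, T)
           else { a <- exp(e - max(e)); a / sum(a) }
  Hfin <- matrix(0, m, h)
  for (t in seq_len(T)) Hfin <- Hfin + alpha[t] * H[[t]]
  Hn <- matrix(0, n, h)
  for (i in seq_len(n)) {
    acc <- as.vector(X[i, ] %*% params$W0)
    for (k in seq_len(m)) if (g$dst[k] == i) acc <- acc + Hfin[k, ]
    hid <- oracle_relu(as.vector(acc %*% params$W1) + as.vector(params$b1))
    Hn[i, ] <- as.vector(hid %*% params$W2) + as.vector(params$b2)
  }
  list(h0 = H0, bond_states = H, beta = beta, g_step = gs, e = e,
       alpha = alpha, h_final = Hfin, node_features = Hn)
}

# layer pooling oracle: beta_i softmax of atom-graph conv scores
oracle_layer_pool <- function(g, Hn, theta, b) {
  An <- oracle_atom_graph_norm(g)
  s <- as.vector(An %*% Hn %*% theta) + b[1]
  bi <- oracle_group_softmax(s, rep(1L, g$n_atoms))
  list(beta = bi, g = as.vector(t(bi) %*% Hn))
}

# co-attention + reweighting oracle (explicit double loops)
oracle_coattention <- function(gx, gy, Wx, Wy, b) {
  L <- nrow(gx)
  gamma <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L))
    gamma[i, j] <- sum(b * tanh(as.vector(gx[i, ] %*% Wx) +
                                as.vector(gy[j, ] %*% Wy)))
  ghx <- matrix(0, L, ncol(gx)); ghy <- matrix(0, L, ncol(gy))
  for (i in seq_len(L)) {
    s <- 0
    for (j in seq_len(L)) s <- s + gamma[i, j]
    ghx[i, ] <- s * gx[i, ]
  }
  for (j in seq_len(L)) {
    s <- 0
    for (i in seq_len(L)) s <- s + gamma[i, j]
    ghy[j, ] <- s * gy[j, ]
  }
  list(gamma = gamma, g_hat_x = ghx, g_hat_y = ghy,
       g_x = colSums(ghx), g_y = colSums(ghy))
}

# BFS expansion oracle over an edge list
oracle_bfs_members <- function(n, edges, centers, radius) {
  nbrs <- lapply(seq_len(n), function(i)
    unique(c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1])))
  members <- centers
  frontier <- centers
  for (r in seq_len(radius)) {
    if (length(frontier) == 0) break
    nxt <- setdiff(unique(unlist(nbrs[frontier])), members)
    members <- c(members, nxt)
    frontier <- nxt
  }
  sort(members)
}
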