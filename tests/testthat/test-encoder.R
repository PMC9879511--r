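# SA-DMPNN encoder: analytic examples on toy graphs, then full
# equivalence with the brute-force oracle.

test_that("bond-state initialization follows the three-term formula", {
  # identity weights on a 6-dim toy problem: h0 = x_i + x_j + x_ij
  p <- small_encoder_params(6L, 6L, 1L)
  p$Wi <- diag(6); p$Wj <- diag(6); p$Wij <- diag(6)
  X <- matrix(seq_len(18) / 10, 3, 6)
  B <- matrix(seq_len(12) / 5, 2, 6)
  g <- toy_graph(X, cbind(1:2, 2:3), B)
  H0 <- init_bond_states(g, p)
  expect_equal(H0[1, ], X[1, ] + X[2, ] + B[1, ])  # bond 1->2
  expect_equal(H0[2, ], X[2, ] + X[1, ] + B[1, ])  # reverse 2->1
  expect_equal(H0[3, ], X[2, ] + X[3, ] + B[2, ])

  p$Wi[] <- 0; p$Wj[] <- 0; p$Wij[] <- 0
  expect_true(all(init_bond_states(g, p) == 0))

  expect_error(init_bond_states(quiet_parse("CC"), p), "does not match")
})

test_that("bond importances are per-target-atom convex weights", {
  p <- small_encoder_params(6L, 4L, 1L)
  # 2-atom graph: each atom has exactly one incoming bond -> beta = 1
  g2 <- toy_graph(matrix(1, 2, 6), cbind(1L, 2L))
  H <- matrix(rnorm(8), 2, 4)
  expect_equal(as.vector(compute_bond_importance(g2, H, p)), c(1, 1))

  # symmetric path: the middle atom's two incoming bonds tie at 1/2
  g3 <- toy_graph(matrix(1, 3, 6), cbind(1:2, 2:3))
  H <- matrix(1, 4, 4)
  beta <- as.vector(compute_bond_importance(g3, H, p))
  mid <- which(g3$dst == 2L)
  expect_equal(beta[mid], c(0.5, 0.5))
  # every atom's incoming importances sum to one
  for (i in 1:3) expect_equal(sum(beta[g3$dst == i]), 1)
})

test_that("the reverse bond is excluded from the message sum", {
  # 2-atom molecule: N(i)\{j} is empty, so h^(t) = relu(h^(0)) forever
  p <- small_encoder_params(6L, 5L, 3L)
  g <- toy_graph(matrix(rnorm(12), 2, 6), cbind(1L, 2L))
  h0 <- init_bond_states(g, p)
  st <- message_step(g, h0, h0, p)
  expect_equal(st$h_bond, pmax(h0, 0))
  st2 <- message_step(g, h0, st$h_bond, p)
  expect_equal(st2$h_bond, pmax(h0, 0))
})

test_that("single-atom graphs yield zero messages and summaries", {
  p <- small_encoder_params(42L, 8L, 2L)
  g <- quiet_parse("C")
  d <- encode(g, p, detail = TRUE)
  for (t in 1:2) expect_equal(d$g_step[[t]], matrix(0, 1, 8))
  expect_equal(sum(d$alpha), 1)
  # node features reduce to the MLP of the projected atom features
  expect_equal(d$node_features,
               finalize_node_features(g, matrix(numeric(0), 0, 8), p))
})

test_that("step attention is a softmax with the dot-product logits", {
  h <- 4L
  p <- small_encoder_params(6L, h, 1L)
  expect_equal(substructure_attention(matrix(rnorm(h), 1, h), p)$alpha, 1)

  # equal logits -> uniform weights
  p3 <- small_encoder_params(6L, h, 3L)
  p3$w_att <- rep(list(matrix(1, h, 1)), 3L)
  g_same <- matrix(rep(rnorm(h), each = 3), 3, h)
  expect_equal(substructure_attention(g_same, p3)$alpha, rep(1 / 3, 3))

  # crafted logits (0, log 3) -> alpha = (1/4, 3/4)
  p2 <- small_encoder_params(6L, h, 2L)
  p2$W_att <- matrix(0, h, h)
  p2$b_att <- matrix(c(atanh(0.5), rep(0, h - 1)), 1, h)
  p2$w_att <- list(matrix(0, h, 1),
                   matrix(c(log(3) / 0.5, rep(0, h - 1)), h, 1))
  at <- substructure_attention(matrix(0, 2, h), p2)
  expect_equal(at$e, c(0, log(3)))
  expect_equal(at$alpha, c(0.25, 0.75))
})

test_that("bond aggregation is the alpha-weighted sum of step states", {
  A <- matrix(rnorm(12), 4, 3)
  B <- matrix(rnorm(12), 4, 3)
  expect_equal(aggregate_bond_states(list(A, B), c(1, 0)), A)
  expect_equal(aggregate_bond_states(list(A, -A), c(0.5, 0.5)),
               matrix(0, 4, 3))
  al <- c(0.3, 0.7)
  expect_equal(aggregate_bond_states(list(A, B), al), 0.3 * A + 0.7 * B)
})

test_that("node finalization reduces to the plain sum under identity MLP", {
  h <- 6L
  p <- small_encoder_params(6L, h, 1L)
  p$W1 <- diag(h); p$b1 <- matrix(0, 1, h)
  p$W2 <- diag(h); p$b2 <- matrix(0, 1, h)
  X <- matrix(abs(rnorm(12)), 2, 6)
  g0 <- toy_graph(X, matrix(integer(0), 0, 2),
                  matrix(numeric(0), 0, 6))
  p$W0 <- matrix(0, 6, h)
  expect_equal(finalize_node_features(g0, matrix(numeric(0), 0, h), p),
               matrix(0, 2, h))
  p$W0 <- diag(6)
  expect_equal(finalize_node_features(g0, matrix(numeric(0), 0, h), p), X)
})

test_that("all encoder intermediates match the brute-force oracle", {
  mols <- list(quiet_parse("CC"), quiet_parse("CCO"), quiet_parse("C=C"),
               quiet_parse("CC=O"), quiet_parse("C"))
  for (seed in 1:3) {
    p <- small_encoder_params(42L, 7L, 3L, seed = seed)
    for (g in mols) {
      for (bm in c("recompute", "once", "uniform")) {
        for (am in c("softmax", "uniform")) {
          got <- encode(g, p, beta_mode = bm, alpha_mode = am,
                        detail = TRUE)
          want <- oracle_encode(g, p, beta_mode = bm, alpha_mode = am)
          expect_equal(got$h0, want$h0, tolerance = 1e-6)
          for (t in 1:3) {
            expect_equal(got$bond_states[[t]], want$bond_states[[t]],
                         tolerance = 1e-6)
            expect_equal(got$beta[[t]], want$beta[[t]], tolerance = 1e-6)
            expect_equal(as.vector(got$g_step[[t]]), want$g_step[[t]],
                         tolerance = 1e-6)
          }
          expect_equal(got$alpha, want$alpha, tolerance = 1e-6)
          expect_equal(got$h_final, want$h_final, tolerance = 1e-6)
          expect_equal(got$node_features, want$node_features,
                       tolerance = 1e-6)
        }
      }
    }
  }
})

test_that("encoding is equivariant under atom relabeling", {
  p <- small_encoder_params(42L, 8L, 2L, seed = 4)
  g <- quiet_parse("CC(=O)Oc1ccccc1C")
  H <- encode(g, p)
  for (seed in 1:4) {
    perm <- withr::with_seed(seed, sample(g$n_atoms))
    Hp <- encode(permute_graph(g, perm), p)
    inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
    expect_equal(Hp, H[inv, , drop = FALSE], tolerance = 1e-8)
  }
})

test_that("bond states are local: distant mutations cannot reach a node", {
  # chain of 9 atoms; with frozen uniform attention weights the node
  # features of atom 1 depend only on atoms within T + 1 hops
  T <- 2L
  p <- small_encoder_params(6L, 5L, T, seed = 9)
  X <- matrix(rnorm(9 * 6), 9, 6)
  edges <- cbind(1:8, 2:9)
  g1 <- toy_graph(X, edges)
  X2 <- X; X2[9, ] <- X2[9, ] + 10  # atom 9 is 8 bonds from atom 1
  g2 <- toy_graph(X2, edges)
  H1 <- encode(g1, p, beta_mode = "uniform", alpha_mode = "uniform")
  H2 <- encode(g2, p, beta_mode = "uniform", alpha_mode = "uniform")
  expect_equal(H1[1:(9 - T - 2), ], H2[1:(9 - T - 2), ], tolerance = 1e-8)
  expect_gt(max(abs(H1[9, ] - H2[9, ])), 1e-3)
})
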