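# Multi-GNN layer pooling, co-attention and reweighting.

test_that("layer pooling weights are per-molecule softmax weights", {
  p <- withr::with_seed(2, multignn_params(L = 2L, h = 6L, T = 2L))
  r1 <- layer_representations(quiet_parse("C"), p)
  for (l in 1:2) {
    expect_equal(r1$node_importance[[l]], 1)
    expect_equal(r1$g[l, ], r1$node_features[[l]][1, ])
  }
  # ethane: the two atoms are symmetric, importances tie at 1/2
  r2 <- layer_representations(quiet_parse("CC"), p)
  for (l in 1:2) {
    expect_equal(r2$node_importance[[l]], c(0.5, 0.5))
    expect_equal(sum(r2$node_importance[[l]]), 1)
    expect_equal(r2$g[l, ], colMeans(r2$node_features[[l]]))
  }
})

test_that("co-attention map equals the direct formula", {
  h <- 5L
  p <- withr::with_seed(3, multignn_params(L = 2L, h = h, T = 1L))
  gx <- matrix(rnorm(2 * h), 2, h)
  gy <- matrix(rnorm(2 * h), 2, h)

  p0 <- p; p0$b_co <- matrix(0, h, 1)
  expect_equal(co_attention(gx, gy, p0), matrix(0, 2, 2))
  pooled <- reweight_and_pool(gx, gy, co_attention(gx, gy, p0))
  expect_equal(pooled$g_x, rep(0, h))

  pz <- p; pz$Wx <- matrix(0, h, h); pz$Wy <- matrix(0, h, h)
  expect_equal(co_attention(gx, gy, pz), matrix(0, 2, 2))

  want <- oracle_coattention(gx, gy, p$Wx, p$Wy, as.vector(p$b_co))
  expect_equal(co_attention(gx, gy, p), want$gamma, tolerance = 1e-10)

  sm <- co_attention(gx, gy, p, gamma_norm = "softmax")
  expect_equal(sum(sm), 1)
})

test_that("reweighting obeys the row-sum algebra", {
  h <- 4L
  gx <- matrix(rnorm(8), 2, h)
  gy <- matrix(rnorm(8), 2, h)
  out <- reweight_and_pool(gx, gy, diag(2))
  expect_equal(out$g_hat_x, gx)
  expect_equal(out$g_x, colSums(gx))

  gamma <- rbind(c(1.5, 0.5), c(0, 0))  # row sums (2, 0)
  out <- reweight_and_pool(gx, gy, gamma)
  expect_equal(out$g_hat_x[1, ], 2 * gx[1, ])
  expect_equal(out$g_hat_x[2, ], 0 * gx[2, ])

  for (seed in 1:5) {
    L <- 3L
    gx <- withr::with_seed(seed, matrix(rnorm(L * h), L, h))
    gy <- withr::with_seed(seed + 50, matrix(rnorm(L * h), L, h))
    p <- withr::with_seed(seed, multignn_params(L = L, h = h, T = 1L))
    gamma <- co_attention(gx, gy, p)
    got <- reweight_and_pool(gx, gy, gamma)
    want <- oracle_coattention(gx, gy, p$Wx, p$Wy, as.vector(p$b_co))
    expect_equal(got$g_x, want$g_x, tolerance = 1e-8)
    expect_equal(got$g_y, want$g_y, tolerance = 1e-8)
    # identity: g_hat_x^(i) = rowsum_i(gamma) * g_x^(i)
    for (i in seq_len(L))
      expect_equal(got$g_hat_x[i, ], sum(gamma[i, ]) * gx[i, ],
                   tolerance = 1e-6)
  }
})

test_that("a single layer degenerates to gamma_11 * g", {
  h <- 4L
  gx <- matrix(rnorm(h), 1, h)
  gy <- matrix(rnorm(h), 1, h)
  p <- withr::with_seed(6, multignn_params(L = 1L, h = h, T = 1L))
  gamma <- co_attention(gx, gy, p)
  out <- reweight_and_pool(gx, gy, gamma)
  expect_equal(out$g_x, gamma[1, 1] * gx[1, ])
})

test_that("batched pair coupling equals the single-pair computation", {
  p <- withr::with_seed(8, multignn_params(L = 2L, h = 6L, T = 2L))
  ga <- quiet_parse("CC(=O)N")
  gb <- quiet_parse("c1ccccc1")
  gc <- quiet_parse("CCO")
  graphs <- list(a = ga, b = gb, c = gc)
  batch <- batch_graphs(graphs)
  tape <- ddinet:::new_tape()
  wp <- ddinet:::td_wrap_params(tape, p, track = FALSE)
  sf <- ddinet:::.stack_forward(tape, wp, batch)
  co <- ddinet:::.coattention_forward(tape, wp, sf$g,
                                      xi = c(1L, 2L), yi = c(2L, 3L))
  for (k in 1:2) {
    gx_single <- layer_representations(graphs[[c(1, 2)[k]]], p)$g
    gy_single <- layer_representations(graphs[[c(2, 3)[k]]], p)$g
    pooled <- reweight_and_pool(gx_single, gy_single,
                                co_attention(gx_single, gy_single, p))
    expect_equal(as.vector(ddinet:::td_value(co$g_x)[k, ]), pooled$g_x,
                 tolerance = 1e-8)
    expect_equal(as.vector(ddinet:::td_value(co$g_y)[k, ]), pooled$g_y,
                 tolerance = 1e-8)
  }
})

test_that("graph-level representations are permutation invariant", {
  p <- withr::with_seed(10, multignn_params(L = 2L, h = 8L, T = 2L))
  g <- quiet_parse("CC(=O)Oc1ccccc1C")
  base <- layer_representations(g, p)$g
  for (seed in 1:3) {
    perm <- withr::with_seed(seed, sample(g$n_atoms))
    permuted <- layer_representations(permute_graph(g, perm), p)$g
    expect_equal(permuted, base, tolerance = 1e-6)
  }
})
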