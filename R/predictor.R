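# Per-relation bilinear scoring of DDI tuples.

#' Create per-relation bilinear matrices
#'
#' One learnable h x h matrix per interaction type; Glorot-uniform scaled
#' down by 1/h (a bilinear form multiplies two h-dimensional activations,
#' so unscaled Glorot saturates the sigmoid at initialization), no
#' symmetry constraint (so P(x, y, r) != P(y, x, r) in general —
#' `symmetrize` folds each matrix to (M + M')/2 if order-invariant scores
#' are wanted).
#'
#' @param n_relations number of interaction types (dense ids 0..K-1).
#' @param h hidden dimension.
#' @param symmetrize force symmetric matrices.
#' @return list of h x h matrices, element r+1 holding type r.
#' @export
relation_matrices <- function(n_relations, h = 64L, symmetrize = FALSE) {
  stopifnot(n_relations >= 1L)
  lapply(seq_len(n_relations), function(r) {
    M <- .glorot(h, h) / h
    if (symmetrize) (M + t(M)) / 2 else M
  })
}

#' Score a DDI tuple
#'
#' `P(d_x, d_y, r) = sigmoid(g_x' M_r g_y)`.
#'
#' @param g_x,g_y graph-level representations (length-h vectors).
#' @param r interaction type id (0-based).
#' @param M list of relation matrices ([relation_matrices()]).
#' @return list with `logit` and `probability`.
#' @export
score_tuple <- function(g_x, g_y, r, M) {
  if (r < 0L || r >= length(M))
    stop("unknown relation id ", r, " (have 0..", length(M) - 1L, ")",
         call. = FALSE)
  z <- as.numeric(t(g_x) %*% M[[r + 1L]] %*% g_y)
  list(logit = z, probability = .sigmoid(z))
}

#' Mean binary cross-entropy loss
#'
#' `-(1/M) sum y log p + (1-y) log(1-p)`, with probabilities clamped to
#' `[eps, 1-eps]` (the loss is undefined at p in {0, 1}).
#'
#' @param p predicted probabilities in (0,1).
#' @param y binary labels.
#' @param eps clamp width.
#' @return scalar loss.
#' @export
bce_loss <- function(p, y, eps = 1e-7) {
  if (length(p) == 0L) stop("empty batch", call. = FALSE)
  stopifnot(length(p) == length(y), all(y %in% c(0, 1)))
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Pairwise substructure interaction scores
#'
#' `S[i, j] = g_hat_x^(i)' M_r g_hat_y^(j)`; summing all entries
#' reproduces the tuple logit `g_x' M_r g_y`.
#'
#' @param g_hat_x,g_hat_y reweighted stacks (L x h), see
#'   [reweight_and_pool()].
#' @param r interaction type id (0-based).
#' @param M relation matrices.
#' @return L x L matrix of pairwise scores.
#' @export
pairwise_scores <- function(g_hat_x, g_hat_y, r, M) {
  g_hat_x %*% M[[r + 1L]] %*% t(g_hat_y)
}

#' Key substructure layer indices
#'
#' Indices (h, t) of the top-k entries of the pairwise interaction score
#' matrix; h indexes drug x's encoder layer (receptive-field radius) and
#' t drug y's. Ties break toward the smallest (i, j) lexicographically.
#'
#' @param scores L x L pairwise score matrix ([pairwise_scores()]).
#' @param k number of index pairs (1 by default, the headline
#'   explanation).
#' @return k x 2 integer matrix with columns `h`, `t`.
#' @export
key_substructure_indices <- function(scores, k = 1L) {
  L <- nrow(scores)
  if (k > L * L) stop("k = ", k, " exceeds L^2 = ", L * L, call. = FALSE)
  idx <- expand.grid(h = seq_len(L), t = seq_len(L))
  idx <- idx[order(idx$h, idx$t), ]
  s <- scores[cbind(idx$h, idx$t)]
  ord <- order(-s, idx$h, idx$t)
  out <- as.matrix(idx[ord[seq_len(k)], c("h", "t")])
  rownames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}
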