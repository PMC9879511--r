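# Full DDI model: Multi-GNN stacks + co-attention + bilinear scorer.

#' Create a DDI prediction model
#'
#' Bundles the dual-encoder parameters (shared between the two drugs of a
#' tuple — the same molecular encoder embeds either side) and the
#' per-relation bilinear matrices. All weights derive from `seed`.
#'
#' @param n_relations number of interaction types.
#' @param h hidden dimension.
#' @param T message passing steps per encoder block.
#' @param L number of stacked encoder blocks.
#' @param d_in atom feature dimension (42).
#' @param seed integer seed fixing the Glorot initialization.
#' @param beta_mode,alpha_mode,gamma_norm forward-pass conventions, see
#'   [encode()] and [co_attention()].
#' @param symmetrize_relations use symmetric relation matrices.
#' @return object of class `ddi_model`.
#' @export
ddi_model <- function(n_relations, h = 64L, T = 3L, L = 3L, d_in = 42L,
                      seed = 1L, beta_mode = "recompute",
                      alpha_mode = "softmax", gamma_norm = "none",
                      symmetrize_relations = FALSE) {
  params <- .with_seed(seed, list(
    multignn = multignn_params(L = L, h = h, T = T, d_in = d_in),
    M = relation_matrices(n_relations, h = h,
                          symmetrize = symmetrize_relations)))
  structure(list(
    params = params, n_relations = n_relations, seed = seed,
    h = h, T = T, L = L, d_in = d_in,
    beta_mode = beta_mode, alpha_mode = alpha_mode,
    gamma_norm = gamma_norm), class = "ddi_model")
}

#' @export
print.ddi_model <- function(x, ...) {
  cat("<ddi_model> h =", x$h, " T =", x$T, " L =", x$L,
      " relations =", x$n_relations, "\n")
  invisible(x)
}

# full tape forward over a set of tuples referencing graphs in `batch`.
# xi, yi: graph indices per tuple; r: 0-based relation ids; y: labels or
# NULL (no loss). Returns handles + per-tuple logits in input order.
.model_forward <- function(tape, model, wp, batch, xi, yi, r, y = NULL) {
  sf <- .stack_forward(tape, wp$multignn, batch,
                       beta_mode = model$beta_mode,
                       alpha_mode = model$alpha_mode)
  co <- .coattention_forward(tape, wp$multignn, sf$g, xi, yi,
                             gamma_norm = model$gamma_norm)
  nt <- length(xi)
  logits <- numeric(nt)
  loss <- NULL
  ones <- matrix(1, model$h, 1L)
  for (rr in sort(unique(r))) {
    idx <- which(r == rr)
    Gx <- td_rows(co$g_x, idx)
    Gy <- td_rows(co$g_y, idx)
    z <- td_matmul(td_mul(td_matmul(Gx, wp$M[[rr + 1L]]), Gy), ones)
    logits[idx] <- as.vector(td_value(z))
    if (!is.null(y)) {
      lr <- td_cmul(td_bce_mean(z, y[idx]), length(idx) / nt)
      loss <- if (is.null(loss)) lr else td_add(loss, lr)
    }
  }
  list(loss = loss, logits = logits, stacks = sf, coattention = co)
}

# numeric convenience: probabilities for labeled/unlabeled tuples.
# graphs: named list of molecular_graph; tuples: data frame with
# drug_x, drug_y, type.
.predict_probs <- function(model, graphs, tuples) {
  ids <- unique(c(tuples$drug_x, tuples$drug_y))
  missing <- setdiff(ids, names(graphs))
  if (length(missing) > 0)
    stop("no molecular graph for drug id(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  batch <- batch_graphs(graphs[ids])
  tape <- new_tape()
  wp <- td_wrap_params(tape, model$params, track = FALSE)
  fw <- .model_forward(tape, model, wp, batch,
                       xi = match(tuples$drug_x, ids),
                       yi = match(tuples$drug_y, ids),
                       r = tuples$type)
  .sigmoid(fw$logits)
}

#' Score DDI tuples with a (trained) model
#'
#' @param model a `ddi_model` (typically the `model` element of a
#'   [train_ddi()] checkpoint).
#' @param graphs named list of `molecular_graph` objects (names = drug
#'   ids), e.g. from [parse_drug_table()].
#' @param tuples data frame with `drug_x`, `drug_y`, `type`.
#' @param explain also extract the key substructure layer pair (h, t) per
#'   tuple.
#' @return `tuples` with an added `probability` column (and `h`, `t` when
#'   `explain = TRUE`).
#' @export
predict_ddi <- function(model, graphs, tuples, explain = FALSE) {
  tuples$probability <- .predict_probs(model, graphs, tuples)
  if (explain) {
    ht <- t(vapply(seq_len(nrow(tuples)), function(i) {
      ex <- explain_ddi(model, graphs[[tuples$drug_x[i]]],
                        graphs[[tuples$drug_y[i]]], tuples$type[i])
      ex$key_indices[1L, ]
    }, integer(2)))
    tuples$h <- ht[, 1L]
    tuples$t <- ht[, 2L]
  }
  tuples
}
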