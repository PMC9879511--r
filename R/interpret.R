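# Post-hoc explanations: atom-similarity matrices, key substructure
# extraction, and explanation-recovery experiments on planted motifs.

#' Pearson atom-similarity matrix
#'
#' Pairwise Pearson correlation of the atoms' node feature vectors
#' (conventionally the final encoder layer's). A constant (zero-variance)
#' feature vector has undefined correlation; such atoms get similarity 0
#' against every other atom and 1 on the diagonal.
#'
#' @param node_features atoms x h matrix.
#' @return n x n symmetric matrix with unit diagonal, values in [-1, 1].
#' @export
atom_similarity <- function(node_features) {
  n <- nrow(node_features)
  if (n < 2L) stop("need at least 2 atoms", call. = FALSE)
  if (ncol(node_features) < 2L)
    stop("need feature dimension >= 2", call. = FALSE)
  degenerate <- apply(node_features, 1L, stats::sd) == 0
  sim <- suppressWarnings(stats::cor(t(node_features)))
  if (any(degenerate)) {
    message(sum(degenerate), " atom(s) with constant features; ",
            "their similarities are set to 0 by convention")
    sim[degenerate, ] <- 0
    sim[, degenerate] <- 0
  }
  diag(sim) <- 1
  sim
}

#' Annotate the key substructure of one drug
#'
#' Centers are the `n_centers` atoms with the largest node importance
#' beta of the selected encoder layer; the member set expands each center
#' by breadth-first search up to the layer index interpreted as
#' receptive-field radius (graph distance in bonds).
#'
#' @param graph a `molecular_graph`.
#' @param beta per-atom importance vector of the selected layer.
#' @param radius expansion radius (the layer index).
#' @param n_centers number of center atoms (top-3 by default).
#' @return list with `center_atoms`, `radius` and `member_atoms` (sorted,
#'   contains the centers).
#' @export
annotate_substructure <- function(graph, beta, radius, n_centers = 3L) {
  n <- graph$n_atoms
  stopifnot(length(beta) == n, n >= 1L)
  centers <- order(-beta, seq_len(n))[seq_len(min(n_centers, n))]
  if (graph$n_directed_bonds > 0) {
    ig <- igraph::graph_from_data_frame(
      data.frame(from = graph$src, to = graph$dst), directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    D <- igraph::distances(ig)
    members <- which(apply(D[, as.character(centers), drop = FALSE], 1L,
                           min) <= radius)
    members <- as.integer(rownames(D))[members]
  } else {
    members <- centers
  }
  list(center_atoms = centers, radius = radius,
       member_atoms = sort(unique(c(centers, members))))
}

#' Explain one DDI tuple
#'
#' Runs both drugs through the trained stack, computes the co-attention
#' map and the reweighted substructure stacks, picks the key layer pair
#' (h, t) by the highest pairwise interaction score, and annotates the
#' key substructures (top-3 importance atoms of the selected layer,
#' expanded to the layer's receptive-field radius). Atom-similarity
#' matrices use the final layer's node features.
#'
#' @param model a `ddi_model`.
#' @param graph_x,graph_y the two drugs' molecular graphs.
#' @param r interaction type id (0-based).
#' @param k number of key layer pairs.
#' @return list with `probability`, `logit`, `gamma`, `pairwise_scores`,
#'   `key_indices`, `annotation_x`, `annotation_y`, `similarity_x`,
#'   `similarity_y`, `beta_x`, `beta_y`, `alpha` traces.
#' @export
explain_ddi <- function(model, graph_x, graph_y, r, k = 1L) {
  p <- model$params$multignn
  rep_x <- layer_representations(graph_x, p, beta_mode = model$beta_mode,
                                 alpha_mode = model$alpha_mode)
  rep_y <- layer_representations(graph_y, p, beta_mode = model$beta_mode,
                                 alpha_mode = model$alpha_mode)
  gamma <- co_attention(rep_x$g, rep_y$g, p, gamma_norm = model$gamma_norm)
  pooled <- reweight_and_pool(rep_x$g, rep_y$g, gamma)
  sc <- score_tuple(pooled$g_x, pooled$g_y, r, model$params$M)
  ps <- pairwise_scores(pooled$g_hat_x, pooled$g_hat_y, r, model$params$M)
  key <- key_substructure_indices(ps, k = k)
  h <- key[1L, "h"]; t <- key[1L, "t"]
  list(probability = sc$probability, logit = sc$logit,
       gamma = gamma, pairwise_scores = ps, key_indices = key,
       annotation_x = annotate_substructure(graph_x,
                                            rep_x$node_importance[[h]], h),
       annotation_y = annotate_substructure(graph_y,
                                            rep_y$node_importance[[t]], t),
       similarity_x = atom_similarity(
         rep_x$node_features[[length(rep_x$node_features)]]),
       similarity_y = atom_similarity(
         rep_y$node_features[[length(rep_y$node_features)]]),
       beta_x = rep_x$node_importance, beta_y = rep_y$node_importance)
}

#' Explanation-recovery experiment on planted motifs
#'
#' For each explained positive tuple, both drugs contribute one trial:
#' a hit when any of the top-3 center atoms of the selected key layer
#' lies in the planted motif. The null probability of a hit by uniformly
#' random center choice is computed per trial from the molecule and
#' motif sizes; the observed hit count is compared against the mean null
#' rate with a one-sided binomial test.
#'
#' @param checkpoint trained `ddi_checkpoint` (or `ddi_model`).
#' @param dataset the `synthetic_ddi_dataset` the tuples came from.
#' @param tuples subset of `dataset$tuples` rows to explain (default all
#'   positives).
#' @param n_centers centers per drug.
#' @return list with `hits`, `trials`, `hit_rate`, `baseline_rate`,
#'   `p_value` and the per-trial data frame.
#' @export
motif_recovery <- function(checkpoint, dataset, tuples = NULL,
                           n_centers = 3L) {
  model <- if (inherits(checkpoint, "ddi_checkpoint")) checkpoint$model
           else checkpoint
  has_truth <- vapply(dataset$truth, function(t)
    !is.null(t$atoms_x), logical(1))
  if (is.null(tuples)) {
    keep <- dataset$tuples$label == 1
  } else {
    keep <- seq_len(nrow(dataset$tuples)) %in% tuples
  }
  idx <- which(keep & has_truth)
  graphs <- dataset$graphs
  rows <- list()
  for (i in idx) {
    tp <- dataset$tuples[i, ]
    tr <- dataset$truth[[i]]
    ex <- explain_ddi(model, graphs[[tp$drug_x]], graphs[[tp$drug_y]],
                      tp$type)
    null_p <- function(n, m, c) {
      c <- min(c, n)
      if (m >= n) return(1)
      1 - prod((n - m - seq_len(c) + 1) / (n - seq_len(c) + 1))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      tuple = i, side = c("x", "y"),
      hit = c(any(ex$annotation_x$center_atoms %in% tr$atoms_x),
              any(ex$annotation_y$center_atoms %in% tr$atoms_y)),
      p_null = c(null_p(graphs[[tp$drug_x]]$n_atoms, length(tr$atoms_x),
                        n_centers),
                 null_p(graphs[[tp$drug_y]]$n_atoms, length(tr$atoms_y),
                        n_centers)))
  }
  trials <- do.call(rbind, rows)
  hits <- sum(trials$hit)
  p0 <- mean(trials$p_null)
  test <- stats::binom.test(hits, nrow(trials), p = p0,
                            alternative = "greater")
  list(hits = hits, trials = nrow(trials), hit_rate = hits / nrow(trials),
       baseline_rate = p0, p_value = test$p.value, detail = trials)
}
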