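# Evaluation metrics: ACC, AUC, F1, precision, recall, AUPR; overall and
# per interaction type.

#' Classification metrics for scored DDI tuples
#'
#' Threshold 0.5 for the confusion-matrix metrics; AUC (ROC, via pROC)
#' and AUPR (average precision with step interpolation) from the ranking.
#' Metrics undefined for the input (single-class labels for AUC/AUPR, no
#' predicted positives for precision) are reported as `NA`.
#'
#' @param probability predicted probabilities.
#' @param label binary labels.
#' @param threshold decision threshold for ACC/F1/Prec/Rec.
#' @return one-row data frame with columns `ACC`, `AUC`, `F1`, `Prec`,
#'   `Rec`, `AUPR`, `n`.
#' @export
ddi_metrics <- function(probability, label, threshold = 0.5) {
  stopifnot(length(probability) == length(label))
  pred <- as.integer(probability >= threshold)
  tp <- sum(pred == 1 & label == 1)
  fp <- sum(pred == 1 & label == 0)
  fn <- sum(pred == 0 & label == 1)
  acc <- mean(pred == label)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  both <- length(unique(label)) == 2L
  auc <- if (both)
    as.numeric(pROC::auc(pROC::roc(response = label, predictor = probability,
                                   levels = c(0, 1), direction = "<",
                                   quiet = TRUE)))
  else NA_real_
  aupr <- if (both) average_precision(probability, label) else NA_real_
  data.frame(ACC = acc, AUC = auc, F1 = f1, Prec = prec, Rec = rec,
             AUPR = aupr, n = length(label))
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-interpolated: `AP = sum_k (R_k - R_{k-1}) P_k` over the ranking
#' by decreasing score.
#'
#' @param probability scores.
#' @param label binary labels.
#' @return scalar in [0, 1].
#' @export
average_precision <- function(probability, label) {
  ord <- order(-probability)
  y <- label[ord]
  npos <- sum(y == 1)
  if (npos == 0) return(NA_real_)
  prec_k <- cumsum(y == 1) / seq_along(y)
  sum(prec_k[y == 1]) / npos
}

#' Evaluate a checkpoint on labeled tuples
#'
#' @param checkpoint a `ddi_checkpoint` (or bare `ddi_model`).
#' @param graphs named list of molecular graphs.
#' @param tuples labeled tuples.
#' @return one-row data frame of metrics ([ddi_metrics()]).
#' @export
evaluate_ddi <- function(checkpoint, graphs, tuples) {
  model <- if (inherits(checkpoint, "ddi_checkpoint")) checkpoint$model
           else checkpoint
  p <- .predict_probs(model, graphs, tuples)
  ddi_metrics(p, tuples$label)
}

#' @rdname evaluate_ddi
#' @export
per_type_metrics <- function(checkpoint, graphs, tuples) {
  model <- if (inherits(checkpoint, "ddi_checkpoint")) checkpoint$model
           else checkpoint
  p <- .predict_probs(model, graphs, tuples)
  types <- sort(unique(tuples$type))
  out <- do.call(rbind, lapply(types, function(r) {
    i <- tuples$type == r
    cbind(type = r, ddi_metrics(p[i], tuples$label[i]))
  }))
  rownames(out) <- NULL
  out
}
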