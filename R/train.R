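# Dataset splitting, negative sampling, Adam optimization.

#' Training configuration
#'
#' Defaults follow the model's reference setting: T = L = 3, hidden 64,
#' Adam with learning rate 1e-4 decayed by 0.96 per epoch, batch size
#' 256, 50 epochs, weight decay 5e-4, 60/20/20 split.
#'
#' @param T message passing steps.
#' @param L encoder blocks.
#' @param hidden hidden dimension h.
#' @param lr initial learning rate.
#' @param batch_size mini-batch size (tuples).
#' @param epochs training epochs.
#' @param weight_decay L2 weight decay coupled into the Adam gradient.
#' @param lr_decay per-epoch exponential decay factor.
#' @param split train/validation/test fractions (sum to 1).
#' @param seed master seed for initialization, shuffling and sampling.
#' @param beta_mode,alpha_mode,gamma_norm forward conventions.
#' @return list of class `train_config`.
#' @export
train_config <- function(T = 3L, L = 3L, hidden = 64L, lr = 1e-4,
                         batch_size = 256L, epochs = 50L,
                         weight_decay = 5e-4, lr_decay = 0.96,
                         split = c(0.6, 0.2, 0.2), seed = 1L,
                         beta_mode = "recompute", alpha_mode = "softmax",
                         gamma_norm = "none") {
  stopifnot(T >= 1, L >= 1, hidden >= 1, lr > 0, batch_size >= 1,
            epochs >= 0, weight_decay >= 0, lr_decay > 0,
            length(split) == 3, abs(sum(split) - 1) < 1e-8)
  structure(as.list(environment()), class = "train_config")
}

#' Learning rate schedule
#'
#' `lr_e = lr * decay^e` with epochs counted from 0.
#'
#' @param lr initial learning rate.
#' @param epoch epoch index (0-based).
#' @param decay exponential factor per epoch.
#' @return learning rate at `epoch`.
#' @export
lr_schedule <- function(lr, epoch, decay = 0.96) lr * decay^epoch

#' Split tuples into train/validation/test
#'
#' Disjoint random partition; validation and test receive
#' `floor(fraction * n)` tuples each, the remainder goes to train.
#'
#' @param tuples data frame of DDI tuples.
#' @param fractions train/valid/test fractions (sum to 1).
#' @param seed RNG seed (partition is reproducible).
#' @return list with `train`, `valid`, `test` data frames.
#' @export
split_dataset <- function(tuples, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  n <- nrow(tuples)
  stopifnot(n >= 5, length(fractions) == 3)
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("split fractions must sum to 1", call. = FALSE)
  n_valid <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  perm <- .with_seed(seed, sample.int(n))
  valid_i <- perm[seq_len(n_valid)]
  test_i <- perm[n_valid + seq_len(n_test)]
  train_i <- perm[-seq_len(n_valid + n_test)]
  list(train = tuples[sort(train_i), , drop = FALSE],
       valid = tuples[sort(valid_i), , drop = FALSE],
       test = tuples[sort(test_i), , drop = FALSE])
}

#' Negative sampling by drug corruption
#'
#' For every input tuple (x, y, r) one negative is emitted by replacing x
#' or y (fair coin) with a uniformly sampled drug such that the corrupted
#' tuple does not occur among the input tuples; negatives carry label 0.
#' The result interleaves nothing: input tuples first (their labels kept),
#' then the negatives, giving a 1:1 ratio.
#'
#' @param positives data frame of observed tuples (`drug_x`, `drug_y`,
#'   `type`, optionally `label`; missing labels default to 1).
#' @param drug_ids character vector of candidate drugs (>= 2 required
#'   beyond each tuple's own drugs).
#' @param seed RNG seed.
#' @param max_tries resampling bound per tuple.
#' @return data frame of 2n labeled tuples.
#' @export
negative_sampling <- function(positives, drug_ids, seed = 1L,
                              max_tries = 1000L) {
  if (length(drug_ids) < 3L)
    stop("drug set too small for corruption sampling", call. = FALSE)
  if (is.null(positives$label)) positives$label <- 1L
  key <- function(x, y, r) paste(x, y, r, sep = "\r")
  pos_keys <- key(positives$drug_x, positives$drug_y, positives$type)
  neg <- positives
  neg$label <- 0L
  .with_seed(seed, {
    for (i in seq_len(nrow(positives))) {
      side <- if (stats::runif(1) < 0.5) "drug_x" else "drug_y"
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- neg[i, ]
        cand[[side]] <- sample(drug_ids, 1L)
        if (cand[[side]] != positives[i, side] &&
            !(key(cand$drug_x, cand$drug_y, cand$type) %in% pos_keys)) {
          neg[i, ] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not corrupt tuple ", i, " within ", max_tries,
                    " tries", call. = FALSE)
    }
  })
  out <- rbind(positives, neg)
  rownames(out) <- NULL
  out
}

# ---- Adam ---------------------------------------------------------------

.adam_init <- function(params) {
  if (is.matrix(params))
    return(list(m = params * 0, v = params * 0))
  if (is.list(params)) return(lapply(params, .adam_init))
  NULL
}

.adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  if (is.matrix(params)) {
    g <- grads + weight_decay * params
    m <- beta1 * state$m + (1 - beta1) * g
    v <- beta2 * state$v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    return(list(params = params - lr * mh / (sqrt(vh) + eps),
                state = list(m = m, v = v)))
  }
  if (is.list(params)) {
    out <- Map(.adam_step, params, grads, state,
               MoreArgs = list(lr = lr, t = t, beta1 = beta1, beta2 = beta2,
                               eps = eps, weight_decay = weight_decay))
    return(list(params = lapply(out, `[[`, "params"),
                state = lapply(out, `[[`, "state")))
  }
  list(params = params, state = state)
}

# ---- training loop ------------------------------------------------------

#' Train a DDI model
#'
#' Mini-batch Adam with per-epoch exponential learning-rate decay; the
#' checkpoint keeps the parameters of the epoch with the lowest
#' validation loss (or the final epoch when no validation set is given).
#' All randomness (initialization, shuffling) derives from `config$seed`.
#'
#' @param graphs named list of `molecular_graph` objects covering every
#'   drug id referenced by the tuples.
#' @param train_tuples labeled tuples (`drug_x`, `drug_y`, `type`,
#'   `label`), e.g. after [negative_sampling()].
#' @param valid_tuples optional labeled validation tuples.
#' @param config a [train_config()].
#' @param n_relations number of interaction types (inferred when NULL).
#' @param verbose print per-epoch progress.
#' @return list of class `ddi_checkpoint` with `model`, `config`, `log`
#'   (epoch, lr, train_loss, valid_loss), `best_epoch` and `seed`.
#' @export
train_ddi <- function(graphs, train_tuples, valid_tuples = NULL,
                      config = train_config(), n_relations = NULL,
                      verbose = FALSE) {
  if (is.null(train_tuples$label))
    stop("train_tuples must carry a label column", call. = FALSE)
  if (is.null(n_relations))
    n_relations <- max(c(train_tuples$type,
                         if (!is.null(valid_tuples)) valid_tuples$type)) + 1L
  model <- ddi_model(n_relations, h = config$hidden, T = config$T,
                     L = config$L, seed = config$seed,
                     beta_mode = config$beta_mode,
                     alpha_mode = config$alpha_mode,
                     gamma_norm = config$gamma_norm)
  state <- .adam_init(model$params)
  n <- nrow(train_tuples)
  log <- data.frame(epoch = integer(0), lr = numeric(0),
                    train_loss = numeric(0), valid_loss = numeric(0))
  best <- list(params = model$params, valid_loss = Inf, epoch = -1L)
  step <- 0L
  if (config$epochs > 0) .with_seed(config$seed + 1L, {
    for (e in seq_len(config$epochs) - 1L) {
      lr_e <- lr_schedule(config$lr, e, config$lr_decay)
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        rows <- ord[s:min(s + config$batch_size - 1L, n)]
        bt <- train_tuples[rows, , drop = FALSE]
        ids <- unique(c(bt$drug_x, bt$drug_y))
        batch <- batch_graphs(graphs[ids])
        tape <- new_tape()
        wp <- td_wrap_params(tape, model$params, track = TRUE)
        fw <- .model_forward(tape, model, wp, batch,
                             xi = match(bt$drug_x, ids),
                             yi = match(bt$drug_y, ids),
                             r = bt$type, y = bt$label)
        lval <- td_value(fw$loss)[1L, 1L]
        if (!is.finite(lval))
          stop("training diverged (loss = ", lval, ") at epoch ", e,
               "; lower the learning rate", call. = FALSE)
        td_backward(fw$loss)
        grads <- td_param_grads(wp)
        step <- step + 1L
        upd <- .adam_step(model$params, grads, state, lr = lr_e, t = step,
                          weight_decay = config$weight_decay)
        model$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + lval * length(rows)
      }
      ep_loss <- ep_loss / n
      vloss <- NA_real_
      if (!is.null(valid_tuples) && nrow(valid_tuples) > 0) {
        vp <- .predict_probs(model, graphs, valid_tuples)
        vloss <- bce_loss(vp, valid_tuples$label)
        if (vloss < best$valid_loss)
          best <- list(params = model$params, valid_loss = vloss, epoch = e)
      }
      log[nrow(log) + 1L, ] <- list(e, lr_e, ep_loss, vloss)
      if (verbose)
        message(sprintf("epoch %3d  lr %.3e  train %.4f  valid %s",
                        e, lr_e, ep_loss,
                        if (is.na(vloss)) "-" else sprintf("%.4f", vloss)))
    }
  })
  if (is.finite(best$valid_loss)) model$params <- best$params
  structure(list(model = model, config = config, log = log,
                 best_epoch = if (is.finite(best$valid_loss)) best$epoch
                              else max(c(-1L, log$epoch)),
                 n_relations = n_relations, seed = config$seed),
            class = "ddi_checkpoint")
}

#' Save / load a training checkpoint
#'
#' Checkpoints bundle the model (weights), configuration and seed.
#'
#' @param checkpoint a `ddi_checkpoint`.
#' @param path file path (RDS).
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "ddi_checkpoint"))
    stop(path, " is not a ddi_checkpoint", call. = FALSE)
  ck
}
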