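# Splitting, negative sampling, schedule, optimization, metrics.

make_tuple_frame <- function(n, ids = sprintf("D%02d", 1:8)) {
  withr::with_seed(99, data.frame(
    drug_x = sample(ids, n, replace = TRUE),
    drug_y = sample(ids, n, replace = TRUE),
    type = sample(0:1, n, replace = TRUE),
    label = 1L))
}

test_that("splits use floor allocation with the remainder in train", {
  tp <- make_tuple_frame(100)
  sp <- split_dataset(tp, c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 60L, valid = 20L, test = 20L))
  sp5 <- split_dataset(make_tuple_frame(5), seed = 2)
  expect_equal(vapply(sp5, nrow, integer(1)),
               c(train = 3L, valid = 1L, test = 1L))
  # partition: disjoint, union = input, reproducible
  sp2 <- split_dataset(tp, c(0.6, 0.2, 0.2), seed = 1)
  expect_identical(sp, sp2)
  all_rows <- rbind(sp$train, sp$valid, sp$test)
  expect_equal(nrow(all_rows), 100L)
  expect_equal(sort(as.integer(rownames(all_rows))), 1:100)
  expect_error(split_dataset(tp, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("negative sampling corrupts one side per positive", {
  ids <- sprintf("D%02d", 1:10)
  pos <- make_tuple_frame(30, ids)
  pos <- pos[pos$drug_x != pos$drug_y, ]
  lab <- negative_sampling(pos, ids, seed = 4)
  expect_equal(nrow(lab), 2L * nrow(pos))
  neg <- lab[lab$label == 0, ]
  expect_equal(nrow(neg), nrow(pos))
  key <- function(d) paste(d$drug_x, d$drug_y, d$type)
  expect_false(any(key(neg) %in% key(pos)))
  # exactly one drug replaced per negative
  changed <- (neg$drug_x != pos$drug_x) + (neg$drug_y != pos$drug_y)
  expect_true(all(changed == 1))
  expect_identical(lab, negative_sampling(pos, ids, seed = 4))
  expect_error(negative_sampling(pos, ids[1:2], seed = 1), "too small")
})

test_that("the learning-rate schedule is exponential in the epoch", {
  expect_equal(lr_schedule(1e-4, 0), 1e-4)
  expect_equal(lr_schedule(1e-4, 2), 1e-4 * 0.96^2)
  expect_equal(lr_schedule(1e-4, 2), 9.216e-5)
  expect_equal(lr_schedule(0.01, 5, decay = 0.5), 0.01 * 0.5^5)
})

test_that("training with zero epochs returns a usable initial checkpoint", {
  drugs <- data.frame(id = c("a", "b", "c", "d"),
                      smiles = c("CC", "CCO", "c1ccccc1", "CC(=O)N"))
  graphs <- suppressWarnings(parse_drug_table(drugs))
  pos <- data.frame(drug_x = c("a", "b", "c", "a", "d"),
                    drug_y = c("b", "c", "d", "c", "b"),
                    type = c(0L, 1L, 0L, 1L, 0L), label = 1L)
  lab <- negative_sampling(pos, drugs$id, seed = 1)
  cfg <- train_config(T = 1L, L = 1L, hidden = 8L, epochs = 0L, seed = 2L)
  ck <- train_ddi(graphs, lab, config = cfg)
  expect_s3_class(ck, "ddi_checkpoint")
  expect_equal(nrow(ck$log), 0L)
  m <- evaluate_ddi(ck, graphs, lab)
  expect_true(is.finite(m$ACC))
  # checkpoints round-trip through disk
  f <- tempfile(fileext = ".rds")
  save_checkpoint(ck, f)
  ck2 <- load_checkpoint(f)
  expect_equal(ck2$model$params, ck$model$params)
})

test_that("the model can overfit a small labeled set", {
  drugs <- suppressWarnings(generate_drugs(6, seed = 31))
  graphs <- suppressWarnings(parse_drug_table(drugs))
  pos <- random_ddi_tuples(drugs, 12L, n_relations = 2L, seed = 32)
  lab <- negative_sampling(pos, drugs$id, seed = 33)
  cfg <- train_config(T = 1L, L = 1L, hidden = 16L, lr = 1e-2,
                      batch_size = 8L, epochs = 60L, weight_decay = 0,
                      seed = 34L)
  ck <- train_ddi(graphs, lab, config = cfg)
  losses <- ck$log$train_loss
  expect_lt(tail(losses, 1), 0.2)
  # on average non-increasing over 10-epoch windows
  w <- sapply(seq(1, 51, by = 10), function(s) mean(losses[s:(s + 9)]))
  expect_true(all(diff(w) < 0.05))
  # rerunning with the same seed reproduces the trajectory exactly
  ck2 <- train_ddi(graphs, lab, config = cfg)
  expect_equal(ck2$log$train_loss, losses)
})

test_that("metrics match a hand-worked confusion matrix", {
  p <- c(0.9, 0.8, 0.3, 0.2)
  y <- c(1, 0, 1, 0)
  m <- ddi_metrics(p, y)
  expect_equal(m$ACC, 0.5)
  expect_equal(m$Prec, 0.5)
  expect_equal(m$Rec, 0.5)
  expect_equal(m$F1, 0.5)
  expect_equal(m$AUC, 0.75)
  expect_equal(m$AUPR, (1 + 2 / 3) / 2)

  perfect <- ddi_metrics(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0))
  expect_true(all(perfect[c("ACC", "AUC", "F1", "Prec", "Rec",
                            "AUPR")] == 1))
  flipped <- ddi_metrics(c(0.1, 0.1, 0.9, 0.9), c(1, 1, 0, 0))
  expect_equal(flipped$ACC, 0)
  expect_equal(flipped$AUC, 0)
})

test_that("a random scorer sits near AUC 0.5 on balanced labels", {
  withr::with_seed(7, {
    p <- runif(1000)
    y <- rep(c(0, 1), 500)
  })
  m <- ddi_metrics(p, y)
  expect_gt(m$AUC, 0.4)
  expect_lt(m$AUC, 0.6)
})

test_that("per-type metrics restrict to each relation", {
  drugs <- data.frame(id = c("a", "b", "c"),
                      smiles = c("CC", "CCO", "c1ccccc1"))
  graphs <- suppressWarnings(parse_drug_table(drugs))
  model <- ddi_model(2L, h = 8L, T = 1L, L = 1L, seed = 5L)
  tuples <- data.frame(drug_x = c("a", "b", "a", "c"),
                       drug_y = c("b", "c", "c", "a"),
                       type = c(0L, 0L, 1L, 1L),
                       label = c(1L, 0L, 1L, 1L))
  pt <- per_type_metrics(model, graphs, tuples)
  expect_equal(pt$type, c(0L, 1L))
  expect_equal(pt$n, c(2L, 2L))
  # type 1 has a single class: ranking metrics undefined
  expect_true(is.na(pt$AUC[2]))
  expect_true(is.na(pt$AUPR[2]))
})
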