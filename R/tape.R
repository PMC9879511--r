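# Reverse-mode automatic differentiation over matrices.
#
# A tape records every operation applied to tracked nodes; td_backward()
# replays it in reverse, accumulating gradients. Values are base matrices;
# graph aggregations enter as constant sparse matrices (Matrix::dgCMatrix)
# via td_spmm(), so the whole encoder forward pass is expressible with a
# dozen primitives. Only nodes on a path from a parameter are revisited
# during the backward sweep.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp$grads <- NULL
  class(tp) <- "ddi_tape"
  tp
}

.td_push <- function(tape, val, parents, bw, requires) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- list(val = val, parents = parents, bw = bw,
                          requires = requires)
  tape$n <- n
  structure(list(tape = tape, id = n), class = "td_node")
}

#' @noRd
td_node <- function(tape, value, requires_grad = FALSE) {
  v <- if (is.matrix(value)) value else matrix(value, ncol = 1L)
  .td_push(tape, v, integer(0), NULL, requires_grad)
}

td_value <- function(x) x$tape$nodes[[x$id]]$val

.as_node <- function(tape, x) {
  if (inherits(x, "td_node")) x else td_node(tape, x)
}

.req <- function(tape, ...) {
  ids <- c(...)
  any(vapply(ids, function(i) tape$nodes[[i]]$requires, logical(1)))
}

td_matmul <- function(a, b) {
  tp <- a$tape
  b <- .as_node(tp, b)
  A <- td_value(a); B <- td_value(b)
  .td_push(tp, A %*% B, c(a$id, b$id),
           function(g) list(g %*% t(B), crossprod(A, g)),
           .req(tp, a$id, b$id))
}

# constant sparse S times tracked dense b
td_spmm <- function(S, b) {
  tp <- b$tape
  B <- td_value(b)
  .td_push(tp, as.matrix(S %*% B), b$id,
           function(g) list(as.matrix(Matrix::crossprod(S, g))),
           .req(tp, b$id))
}

# a + b; b may be a 1 x k bias row (broadcast over rows) or 1 x 1 scalar
td_add <- function(a, b) {
  tp <- a$tape
  b <- .as_node(tp, b)
  A <- td_value(a); B <- td_value(b)
  if (identical(dim(A), dim(B))) {
    val <- A + B
    bw <- function(g) list(g, g)
  } else if (nrow(B) == 1L && ncol(B) == ncol(A)) {
    val <- sweep(A, 2L, as.vector(B), "+")
    bw <- function(g) list(g, matrix(colSums(g), nrow = 1L))
  } else if (length(B) == 1L) {
    val <- A + B[1L]
    bw <- function(g) list(g, matrix(sum(g), 1L, 1L))
  } else stop("td_add: incompatible shapes")
  .td_push(tp, val, c(a$id, b$id), bw, .req(tp, a$id, b$id))
}

td_sub <- function(a, b) td_add(a, td_cmul(b, -1))

td_mul <- function(a, b) {
  tp <- a$tape
  b <- .as_node(tp, b)
  A <- td_value(a); B <- td_value(b)
  if (!identical(dim(A), dim(B))) stop("td_mul: incompatible shapes")
  .td_push(tp, A * B, c(a$id, b$id),
           function(g) list(g * B, g * A),
           .req(tp, a$id, b$id))
}

# multiply by a constant scalar
td_cmul <- function(a, c) {
  tp <- a$tape
  A <- td_value(a)
  .td_push(tp, A * c, a$id, function(g) list(g * c), .req(tp, a$id))
}

# scale each row i of a (n x k) by scalar v[i] (v is n x 1)
td_scale_rows <- function(a, v) {
  tp <- a$tape
  A <- td_value(a); V <- as.vector(td_value(v))
  .td_push(tp, A * V, c(a$id, v$id),
           function(g) list(g * V, matrix(rowSums(g * A), ncol = 1L)),
           .req(tp, a$id, v$id))
}

td_relu <- function(a) {
  tp <- a$tape
  A <- td_value(a)
  M <- A > 0
  .td_push(tp, A * M, a$id, function(g) list(g * M), .req(tp, a$id))
}

td_tanh <- function(a) {
  tp <- a$tape
  V <- tanh(td_value(a))
  .td_push(tp, V, a$id, function(g) list(g * (1 - V^2)), .req(tp, a$id))
}

td_sigmoid <- function(a) {
  tp <- a$tape
  V <- 1 / (1 + exp(-td_value(a)))
  .td_push(tp, V, a$id, function(g) list(g * V * (1 - V)), .req(tp, a$id))
}

td_sum <- function(a) {
  tp <- a$tape
  A <- td_value(a)
  d <- dim(A)
  .td_push(tp, matrix(sum(A), 1L, 1L), a$id,
           function(g) list(matrix(g[1L], d[1L], d[2L])),
           .req(tp, a$id))
}

# softmax of a scores column within integer groups (1..G); rows with a
# group of their own get probability 1
td_group_softmax <- function(s, groups) {
  tp <- s$tape
  sv <- as.vector(td_value(s))
  gi <- as.integer(groups)
  if (length(sv) == 0L)
    return(.td_push(tp, matrix(numeric(0), 0L, 1L), s$id,
                    function(g) list(g), .req(tp, s$id)))
  mx <- tapply(sv, gi, max)[as.character(gi)]
  ex <- exp(sv - mx)
  den <- rowsum(ex, gi)[as.character(gi), 1L]
  p <- ex / den
  .td_push(tp, matrix(p, ncol = 1L), s$id,
           function(g) {
             gv <- as.vector(g)
             inner <- rowsum(p * gv, gi)[as.character(gi), 1L]
             list(matrix(p * (gv - inner), ncol = 1L))
           },
           .req(tp, s$id))
}

# stack column blocks of equal width vertically
td_vconcat <- function(nodes) {
  tp <- nodes[[1L]]$tape
  vals <- lapply(nodes, td_value)
  rows <- vapply(vals, nrow, integer(1))
  ends <- cumsum(rows)
  starts <- ends - rows + 1L
  .td_push(tp, do.call(rbind, vals), vapply(nodes, function(x) x$id, integer(1)),
           function(g) lapply(seq_along(rows), function(i)
             g[starts[i]:ends[i], , drop = FALSE]),
           .req(tp, vapply(nodes, function(x) x$id, integer(1))))
}

# gather rows by index (duplicates allowed); backward scatter-adds
td_rows <- function(a, idx) {
  tp <- a$tape
  A <- td_value(a)
  n <- nrow(A)
  .td_push(tp, A[idx, , drop = FALSE], a$id,
           function(g) {
             out <- matrix(0, n, ncol(A))
             agg <- rowsum(g, idx)
             out[as.integer(rownames(agg)), ] <- agg
             list(out)
           },
           .req(tp, a$id))
}

# numerically stable mean binary cross-entropy on logits; y is constant
td_bce_mean <- function(logits, y) {
  tp <- logits$tape
  z <- as.vector(td_value(logits))
  yv <- as.vector(y)
  m <- length(z)
  val <- mean(pmax(z, 0) - z * yv + log1p(exp(-abs(z))))
  .td_push(tp, matrix(val, 1L, 1L), logits$id,
           function(g) list(matrix(g[1L] * (1 / (1 + exp(-z)) - yv) / m,
                                   ncol = 1L)),
           .req(tp, logits$id))
}

#' @noRd
td_backward <- function(loss) {
  tp <- loss$tape
  grads <- vector("list", tp$n)
  lv <- td_value(loss)
  grads[[loss$id]] <- matrix(1, nrow(lv), ncol(lv))
  for (id in seq(loss$id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tp$nodes[[id]]
    if (!node$requires || is.null(node$bw)) next
    pg <- node$bw(g)
    for (k in seq_along(node$parents)) {
      p <- node$parents[k]
      if (!tp$nodes[[p]]$requires) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  tp$grads <- grads
  invisible(grads)
}

td_grad <- function(x) {
  g <- x$tape$grads[[x$id]]
  if (is.null(g)) {
    v <- td_value(x)
    g <- matrix(0, nrow(v), ncol(v))
  }
  g
}

# ---- parameter trees ----------------------------------------------------

# wrap a nested list of matrices as tracked nodes (same structure);
# non-matrix leaves (metadata) pass through untouched
td_wrap_params <- function(tape, params, track = TRUE) {
  if (is.matrix(params)) return(td_node(tape, params, requires_grad = track))
  if (is.list(params) && !inherits(params, "td_node"))
    return(lapply(params, td_wrap_params, tape = tape, track = track))
  params
}

# extract gradients from a wrapped tree after td_backward()
td_param_grads <- function(wrapped) {
  if (inherits(wrapped, "td_node")) return(td_grad(wrapped))
  if (is.list(wrapped)) return(lapply(wrapped, td_param_grads))
  wrapped
}
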