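## Minimal reverse-mode automatic differentiation over dense matrices.
##
## Nodes are environments holding a value, an accumulated gradient, parent
## links and a backward closure. Only nodes on a path from a parameter are
## taped; constant subgraphs cost nothing at backward time. Every primitive
## has a hand-written vector-Jacobian product, checked against numerical
## gradients in the test suite.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

ad_node <- function(val, req = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$req <- req
  nd
}

## Constant: never taped; a plain list suffices.
ad_const <- function(x) {
  if (is.environment(x) || (is.list(x) && !is.null(x$val))) return(x)
  list(val = as_mat(x), req = FALSE)
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

## Parameter leaf: taped targets of differentiation.
ad_param <- function(x, tape) {
  nd <- ad_node(as_mat(x), req = TRUE)
  nd
}

ad_push <- function(tape, nd) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", n))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

## Build an op node; `bw` is function(g) -> list of parent gradients (same
## order as `parents`), entries may be NULL for constant parents. Nodes off
## every parameter path are plain lists (no tape, no gradient slot).
ad_op <- function(tape, val, parents, bw) {
  req <- FALSE
  for (p in parents) if (isTRUE(p$req)) { req <- TRUE; break }
  if (!req) return(list(val = val, req = FALSE))
  nd <- ad_node(val, req = TRUE)
  nd$parents <- parents
  nd$bw <- bw
  ad_push(tape, nd)
  nd
}

ad_accum <- function(p, g) {
  if (!isTRUE(p$req) || is.null(g)) return(invisible(NULL))
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

## Reverse pass from a scalar (1x1) loss node.
ad_backward <- function(tape, loss) {
  loss$grad <- matrix(1, 1, 1)
  if (tape$n == 0L) return(invisible(NULL))
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad)) next
    gs <- nd$bw(nd$grad)
    for (k in seq_along(nd$parents)) ad_accum(nd$parents[[k]], gs[[k]])
  }
  invisible(NULL)
}

## ---- primitives -----------------------------------------------------------

ad_mm <- function(tape, a, b) {
  ad_op(tape, a$val %*% b$val, list(a, b), function(g)
    list(g %*% t(b$val), t(a$val) %*% g))
}

ad_add <- function(tape, a, b) {
  ad_op(tape, a$val + b$val, list(a, b), function(g) list(g, g))
}

ad_sub <- function(tape, a, b) {
  ad_op(tape, a$val - b$val, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(tape, a, b) {
  ad_op(tape, a$val * b$val, list(a, b), function(g)
    list(g * b$val, g * a$val))
}

## Add a 1 x k row vector (node) to every row of a.
ad_add_rowvec <- function(tape, a, v) {
  nr <- nrow(a$val)
  val <- a$val + matrix(v$val, nr, ncol(a$val), byrow = TRUE)
  ad_op(tape, val, list(a, v), function(g)
    list(g, matrix(colSums(g), 1L)))
}

## Multiply every row of a by a 1 x k row vector (node).
ad_mul_rowvec <- function(tape, a, v) {
  nr <- nrow(a$val)
  V <- matrix(v$val, nr, ncol(a$val), byrow = TRUE)
  ad_op(tape, a$val * V, list(a, v), function(g)
    list(g * V, matrix(colSums(g * a$val), 1L)))
}

ad_smul <- function(tape, a, s) {          # s plain scalar
  ad_op(tape, a$val * s, list(a), function(g) list(g * s))
}

ad_sadd <- function(tape, a, s) {          # s plain scalar or const matrix
  ad_op(tape, a$val + s, list(a), function(g) list(g))
}

ad_sigmoid <- function(tape, a) {
  y <- 1 / (1 + exp(-a$val))
  ad_op(tape, y, list(a), function(g) list(g * y * (1 - y)))
}

ad_tanh <- function(tape, a) {
  y <- tanh(a$val)
  ad_op(tape, y, list(a), function(g) list(g * (1 - y^2)))
}

ad_lrelu <- function(tape, a, slope = 0.2) {
  f <- (a$val > 0) + slope * (a$val <= 0)
  ad_op(tape, a$val * f, list(a), function(g) list(g * f))
}

ad_exp <- function(tape, a) {
  y <- exp(a$val)
  ad_op(tape, y, list(a), function(g) list(g * y))
}

ad_log <- function(tape, a) {
  ad_op(tape, log(a$val), list(a), function(g) list(g / a$val))
}

## Row-wise softmax with optional additive constant mask (e.g. -1e9 holes).
ad_row_softmax <- function(tape, a, mask = NULL) {
  z <- a$val
  if (!is.null(mask)) z <- z + mask
  z <- z - z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z)
  y <- e / rowSums(e)
  ad_op(tape, y, list(a), function(g)
    list(y * (g - rowSums(g * y))))
}

ad_rowsum <- function(tape, a) {
  ad_op(tape, matrix(rowSums(a$val), ncol = 1L), list(a), function(g)
    list(matrix(g, nrow(a$val), ncol(a$val))))
}

ad_colsum <- function(tape, a) {
  ad_op(tape, matrix(colSums(a$val), nrow = 1L), list(a), function(g)
    list(matrix(g, nrow(a$val), ncol(a$val), byrow = TRUE)))
}

ad_sum <- function(tape, a) {
  ad_op(tape, matrix(sum(a$val), 1L, 1L), list(a), function(g)
    list(matrix(g[1L], nrow(a$val), ncol(a$val))))
}

## Row gather: out[r, ] = a[idx[r], ]; backward scatter-adds.
ad_gather <- function(tape, a, idx) {
  nr <- nrow(a$val)
  ad_op(tape, a$val[idx, , drop = FALSE], list(a), function(g) {
    acc <- rowsum(g, group = idx)
    out <- matrix(0, nr, ncol(a$val))
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

ad_cbind2 <- function(tape, a, b) {
  ka <- ncol(a$val)
  ad_op(tape, cbind(a$val, b$val), list(a, b), function(g)
    list(g[, seq_len(ka), drop = FALSE],
         g[, -seq_len(ka), drop = FALSE]))
}

ad_t <- function(tape, a) {
  ad_op(tape, t(a$val), list(a), function(g) list(t(g)))
}

## Row-wise dot product of two equally shaped matrices -> n x 1.
ad_rowdot <- function(tape, a, b) {
  ad_op(tape, matrix(rowSums(a$val * b$val), ncol = 1L), list(a, b),
        function(g) {
          G <- matrix(g, nrow(a$val), ncol(a$val))
          list(G * b$val, G * a$val)
        })
}

## Row-wise layer normalization with gain/bias (1 x k parameter nodes).
ad_layernorm <- function(tape, a, gain, bias, eps = 1e-5) {
  x <- a$val
  k <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  nr <- nrow(x)
  G <- matrix(gain$val, nr, k, byrow = TRUE)
  y <- xhat * G + matrix(bias$val, nr, k, byrow = TRUE)
  ad_op(tape, y, list(a, gain, bias), function(g) {
    dxhat <- g * G
    gx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    list(gx,
         matrix(colSums(g * xhat), 1L),
         matrix(colSums(g), 1L))
  })
}

## Column-major reshape (R's native vectorization order).
ad_reshape <- function(tape, a, nr, nc) {
  onr <- nrow(a$val); onc <- ncol(a$val)
  ad_op(tape, matrix(a$val, nr, nc), list(a), function(g)
    list(matrix(g, onr, onc)))
}

ad_slice_cols <- function(tape, a, cols) {
  nc <- ncol(a$val)
  ad_op(tape, a$val[, cols, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$val), nc)
    out[, cols] <- g
    list(out)
  })
}

## Multiply each row of a by the scalar in the matching row of c (n x 1).
ad_mul_colvec <- function(tape, a, c) {
  cv <- as.vector(c$val)
  ad_op(tape, a$val * cv, list(a, c), function(g)
    list(g * cv, matrix(rowSums(g * a$val), ncol = 1L)))
}

## Affine helper: X %*% W + b (b a 1 x k parameter node).
ad_linear <- function(tape, x, W, b = NULL) {
  out <- ad_mm(tape, x, W)
  if (!is.null(b)) out <- ad_add_rowvec(tape, out, b)
  out
}
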