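# Reverse-mode automatic differentiation on a flat tape of matrix operations.
# Just enough machinery for the graph-attention network: dense matmul,
# elementwise nonlinearities, row gather/scatter through a constant sparse
# matrix, per-neighborhood softmax, and the micro-to-macro pKa pooling.
# Gradients are verified against central differences in the test suite.
# Every op force()s its node-id arguments before touching tp$vals: the ids
# are often promises that themselves push onto the tape, and must run before
# the tape's value list is captured.

#' @importFrom Matrix sparseMatrix t crossprod
NULL

tp_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- vector("list", 256L)
  tp$backs <- vector("list", 256L)
  tp$parents <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tp_push <- function(tp, val, parents = integer(0), back = NULL) {
  n <- tp$n + 1L
  if (n > length(tp$vals)) {
    length(tp$vals) <- 2L * n
    length(tp$backs) <- 2L * n
    length(tp$parents) <- 2L * n
  }
  tp$vals[[n]] <- val
  tp$backs[[n]] <- back
  tp$parents[[n]] <- parents
  tp$n <- n
  n
}

tp_leaf <- function(tp, val) tp_push(tp, val)

tp_val <- function(tp, id) {
  force(id)
  tp$vals[[id]]
}

tp_matmul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  tp_push(tp, A %*% B, c(a, b), function(g)
    list(g %*% t(B), crossprod(A, g)))
}

tp_add <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp$vals[[a]] + tp$vals[[b]], c(a, b), function(g) list(g, g))
}

tp_sub <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp$vals[[a]] - tp$vals[[b]], c(a, b), function(g) list(g, -g))
}

# add a 1 x k bias row to every row of an n x k matrix
tp_bias <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]
  B <- as.vector(tp$vals[[b]])
  tp_push(tp, A + rep(B, each = nrow(A)), c(a, b),
          function(g) list(g, matrix(colSums(g), 1L)))
}

tp_mul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  tp_push(tp, A * B, c(a, b), function(g) list(g * B, g * A))
}

tp_sigmoid <- function(tp, a) {
  force(a)
  s <- 1 / (1 + exp(-tp$vals[[a]]))
  tp_push(tp, s, a, function(g) list(g * s * (1 - s)))
}

tp_tanh <- function(tp, a) {
  force(a)
  s <- tanh(tp$vals[[a]])
  tp_push(tp, s, a, function(g) list(g * (1 - s^2)))
}

tp_leakyrelu <- function(tp, a, alpha = 0.01) {
  force(a)
  A <- tp$vals[[a]]
  d <- 1 + (alpha - 1) * (A <= 0)
  tp_push(tp, A * d, a, function(g) list(g * d))
}

tp_elu <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  pos <- A > 0
  em1 <- expm1(pmin(A, 0))
  val <- pmax(A, 0) + em1
  d <- pos + (!pos) * (em1 + 1)
  tp_push(tp, val, a, function(g) list(g * d))
}

# contiguous column slice; backward pads the complement with zeros
tp_cols <- function(tp, a, from, to) {
  force(a)
  A <- tp$vals[[a]]
  nc <- ncol(A)
  tp_push(tp, A[, from:to, drop = FALSE], a, function(g) {
    ga <- matrix(0, nrow(g), nc)
    ga[, from:to] <- g
    list(ga)
  })
}

tp_cbind <- function(tp, ...) {
  ids <- c(...)
  mats <- lapply(ids, function(i) tp$vals[[i]])
  widths <- vapply(mats, ncol, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  tp_push(tp, do.call(cbind, mats), ids, function(g)
    lapply(seq_along(ids), function(k) g[, starts[k]:ends[k], drop = FALSE]))
}

# gather rows: out[i, ] = A[idx[i], ]
tp_rows <- function(tp, a, idx) {
  force(a)
  A <- tp$vals[[a]]
  nr <- nrow(A)
  tp_push(tp, A[idx, , drop = FALSE], a, function(g) {
    ga <- matrix(0, nr, ncol(g))
    # scatter-add via rowsum on the gathered index
    rs <- rowsum(g, idx, reorder = FALSE)
    ga[as.integer(rownames(rs)), ] <- rs
    list(ga)
  })
}

# constant sparse matrix times node: out = S %*% A (aggregation/scatter).
# St is the cached transpose (computed once per batch).
tp_spmm <- function(tp, S, a, St = Matrix::t(S)) {
  force(a); force(St)
  tp_push(tp, as.matrix(S %*% tp$vals[[a]]), a, function(g)
    list(as.matrix(St %*% g)))
}

# multiply each row i of A by scalar w[i] (attention weighting)
tp_rowscale <- function(tp, a, w) {
  force(a); force(w)
  A <- tp$vals[[a]]; W <- as.vector(tp$vals[[w]])
  tp_push(tp, A * W, c(a, w), function(g)
    list(g * W, matrix(rowSums(g * A), ncol = 1L)))
}

# softmax of a column vector within segments (neighborhoods).
# seg: list(grp = integer index per row, S = |groups| x n sparse indicator,
#           idx = split(seq_len(n), grp))
tp_segsoftmax <- function(tp, a, seg) {
  force(a)
  x <- as.vector(tp$vals[[a]])
  m <- vapply(seg$idx, function(ii) if (length(ii)) max(x[ii]) else 0, 0)
  e <- exp(x - m[seg$grp])
  denom <- as.vector(seg$S %*% e)
  w <- e / denom[seg$grp]
  tp_push(tp, matrix(w, ncol = 1L), a, function(g) {
    gv <- as.vector(g)
    dot <- as.vector(seg$S %*% (w * gv))
    list(matrix(w * (gv - dot[seg$grp]), ncol = 1L))
  })
}

# micro-to-macro pooling: for a column vector of site micro-pKa values and a
# molecule index per site, returns one macro value per molecule.
# sign = -1: most-acidic (softmin); sign = +1: most-basic (softmax).
tp_pool <- function(tp, a, seg, sign) {
  force(a)
  x <- as.vector(tp$vals[[a]])
  m <- vapply(seg$idx, function(ii) {
    if (!length(ii)) return(0)
    if (sign < 0) min(x[ii]) else max(x[ii])
  }, 0)
  e <- 10^(sign * (x - m[seg$grp]))
  tot <- as.vector(seg$S %*% e)
  val <- m + sign * log10(tot)
  w <- e / tot[seg$grp] # softmin/softmax weights: d val / d x
  tp_push(tp, matrix(val, ncol = 1L), a, function(g)
    list(matrix(w * as.vector(g)[seg$grp], ncol = 1L)))
}

tp_mse <- function(tp, a, target) {
  force(a)
  A <- tp$vals[[a]]
  d <- as.vector(A) - as.vector(target)
  n <- length(d)
  nr <- nrow(A); nc <- ncol(A)
  tp_push(tp, matrix(sum(d^2) / n, 1L, 1L), a, function(g)
    list(matrix(2 * d * as.vector(g) / n, nr, nc)))
}

# segment structure shared by tp_segsoftmax / tp_spmm / tp_pool
make_segments <- function(grp, ngroups) {
  n <- length(grp)
  S <- Matrix::sparseMatrix(i = grp, j = seq_len(n), x = 1,
                            dims = c(ngroups, n))
  list(
    grp = grp, S = S, St = Matrix::t(S),
    idx = split(seq_len(n), factor(grp, levels = seq_len(ngroups)))
  )
}

tp_backward <- function(tp, id) {
  n <- tp$n
  grads <- vector("list", n)
  v <- tp$vals[[id]]
  grads[[id]] <- matrix(1, nrow(v), ncol(v))
  for (k in seq(id, 1L)) {
    g <- grads[[k]]
    if (is.null(g)) next
    back <- tp$backs[[k]]
    if (is.null(back)) next
    pg <- back(g)
    ps <- tp$parents[[k]]
    for (j in seq_along(ps)) {
      p <- ps[j]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}
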