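# Central-difference verification of the reverse-mode gradients, on random
# small problems. The analytic path is the one training uses; the numeric
# oracle is plain finite differencing of the forward value.

numgrad <- function(f, x, h = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

test_that("elementwise and linear op gradients match finite differences", {
  set.seed(101)
  A0 <- matrix(rnorm(12), 3, 4)
  W0 <- matrix(rnorm(8), 4, 2)
  b0 <- matrix(rnorm(2), 1, 2)

  make_loss <- function(op) {
    function(Avec) {
      tp <- tp_new()
      a <- tp_leaf(tp, matrix(Avec, 3, 4))
      w <- tp_leaf(tp, W0); b <- tp_leaf(tp, b0)
      out <- op(tp, a, w, b)
      sum(tp_val(tp, out)^2)
    }
  }
  ops <- list(
    linear = function(tp, a, w, b) tp_bias(tp, tp_matmul(tp, a, w), b),
    sigmoid = function(tp, a, w, b) tp_sigmoid(tp, tp_matmul(tp, a, w)),
    tanh = function(tp, a, w, b) tp_tanh(tp, tp_matmul(tp, a, w)),
    lrelu = function(tp, a, w, b) tp_leakyrelu(tp, tp_matmul(tp, a, w)),
    elu = function(tp, a, w, b) tp_elu(tp, tp_matmul(tp, a, w)),
    cols = function(tp, a, w, b) tp_cols(tp, a, 2L, 3L),
    rows = function(tp, a, w, b) tp_rows(tp, a, c(1L, 3L, 3L, 2L)),
    mul = function(tp, a, w, b) tp_mul(tp, a, a)
  )
  for (nm in names(ops)) {
    f <- make_loss(ops[[nm]])
    # analytic: differentiate sum(out^2) by chaining through tp
    tp <- tp_new()
    a <- tp_leaf(tp, A0)
    w <- tp_leaf(tp, W0); b <- tp_leaf(tp, b0)
    out <- ops[[nm]](tp, a, w, b)
    sq <- tp_mul(tp, out, out)
    # reduce via mse against zero (n * mse = sum of squares)
    loss <- tp_mse(tp, out, tp_val(tp, out) * 0)
    grads <- tp_backward(tp, loss)
    n <- length(tp_val(tp, out))
    ana <- as.vector(grads[[a]]) * n # undo the 1/n of the mse
    num <- numgrad(function(v) {
      tp2 <- tp_new()
      a2 <- tp_leaf(tp2, matrix(v, 3, 4))
      w2 <- tp_leaf(tp2, W0); b2 <- tp_leaf(tp2, b0)
      sum(tp_val(tp2, ops[[nm]](tp2, a2, w2, b2))^2)
    }, as.vector(A0))
    expect_equal(ana, num, tolerance = 1e-5, label = paste("grad", nm))
  }
})

test_that("segment softmax and pooling gradients match finite differences", {
  set.seed(102)
  grp <- c(1L, 1L, 2L, 2L, 2L, 3L)
  seg <- make_segments(grp, 3L)
  x0 <- rnorm(6)
  w0 <- rnorm(6)

  # segsoftmax: loss = sum(w * softmax(x))^2-ish via mse
  f_soft <- function(x) {
    tp <- tp_new()
    a <- tp_leaf(tp, matrix(x, ncol = 1))
    s <- tp_segsoftmax(tp, a, seg)
    sum((as.vector(tp_val(tp, s)) * w0 - 0.3)^2)
  }
  tp <- tp_new()
  a <- tp_leaf(tp, matrix(x0, ncol = 1))
  s <- tp_segsoftmax(tp, a, seg)
  sw <- tp_mul(tp, s, tp_leaf(tp, matrix(w0, ncol = 1)))
  loss <- tp_mse(tp, sw, rep(0.3, 6))
  grads <- tp_backward(tp, loss)
  ana <- as.vector(grads[[a]]) * 6 / 1 # mse 1/n with n=6; loss f is sum
  expect_equal(ana, numgrad(f_soft, x0), tolerance = 1e-5)

  # attention weights are non-negative and sum to 1 in each neighborhood
  w <- as.vector(tp_val(tp, s))
  expect_true(all(w >= 0))
  expect_equal(as.vector(seg$S %*% w), rep(1, 3), tolerance = 1e-12)

  # pooling gradient equals the softmin/softmax weights
  for (sgn in c(-1, +1)) {
    tp <- tp_new()
    a <- tp_leaf(tp, matrix(x0, ncol = 1))
    pooled <- tp_pool(tp, a, seg, sgn)
    loss <- tp_mse(tp, pooled, c(0, 0, 0))
    grads <- tp_backward(tp, loss)
    f_pool <- function(x) {
      tp2 <- tp_new()
      a2 <- tp_leaf(tp2, matrix(x, ncol = 1))
      p <- as.vector(tp_val(tp2, tp_pool(tp2, a2, seg, sgn)))
      mean(p^2)
    }
    expect_equal(as.vector(grads[[a]]), numgrad(f_pool, x0),
                 tolerance = 1e-5, label = paste("pool sign", sgn))
    # forward value agrees with the reference pooling
    p <- as.vector(tp_val(tp, tp_pool(tp, tp_leaf(tp, matrix(x0, ncol = 1)),
                                      seg, sgn)))
    mode <- if (sgn < 0) "acidic" else "basic"
    expect_equal(p, vapply(seg$idx, function(ii) pool_sites(x0[ii], mode), 0),
                 ignore_attr = TRUE)
  }
})

test_that("whole-model gradients match finite differences", {
  set.seed(103)
  cfg <- model_config(mode = "basic", n_layers = 2L, hidden_dim = 5L,
                      dropout_rate = 0, head_hidden_dims = 4L, seed = 11L)
  st <- init_model(cfg)
  graphs <- list(build_graph("NCC(N)CN"), build_graph("c1ccncc1"))
  batch <- pkamil:::prepare_pool_batch(graphs, c(9.5, 5.0), "basic")
  lossval <- function(params) {
    tp <- tp_new()
    fw <- pkamil:::forward_macro(tp, params, batch, cfg)
    as.numeric(tp_val(tp, tp_mse(tp, fw$macro, batch$labels)))
  }
  tp <- tp_new()
  fw <- pkamil:::forward_macro(tp, st$params, batch, cfg)
  loss <- tp_mse(tp, fw$macro, batch$labels)
  grads <- tp_backward(tp, loss)
  h <- 1e-5
  set.seed(7)
  for (nm in names(st$params)) {
    gP <- grads[[fw$pid[[nm]]]]
    if (is.null(gP)) gP <- st$params[[nm]] * 0
    for (rep in 1:2) {
      i <- sample(length(st$params[[nm]]), 1)
      p2 <- st$params; p2[[nm]][i] <- p2[[nm]][i] + h; lp <- lossval(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * h; lm <- lossval(p2)
      expect_equal(as.matrix(gP)[i], (lp - lm) / (2 * h), tolerance = 1e-4,
                   label = sprintf("d loss / d %s[%d]", nm, i))
    }
  }
})
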