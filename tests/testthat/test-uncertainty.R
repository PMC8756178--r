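test_that("MC-dropout intervals behave at the edges", {
  g <- build_graph("OC(=O)c1ccccc1")

  # dropout 0: all samples identical, degenerate interval, warning
  st0 <- init_model(tiny_config(dropout = 0, seed = 3))
  expect_warning(u0 <- mc_dropout_predict(st0, g, n_samples = 20),
                 "degenerate")
  expect_equal(u0$ci_low, u0$macro_mean)
  expect_equal(u0$ci_high, u0$macro_mean)

  st <- init_model(tiny_config(dropout = 0.3, seed = 3))
  # n_samples = 1 collapses to the single sample
  u1 <- mc_dropout_predict(st, g, n_samples = 1, seed = 5)
  expect_equal(u1$ci_low, u1$macro_mean)
  expect_equal(u1$ci_high, u1$macro_mean)

  # seeded sampling reproduces the interval exactly
  u <- mc_dropout_predict(st, g, n_samples = 50, seed = 11)
  u2 <- mc_dropout_predict(st, g, n_samples = 50, seed = 11)
  expect_identical(u[c("macro_mean", "ci_low", "ci_high")],
                   u2[c("macro_mean", "ci_low", "ci_high")])
  u3 <- mc_dropout_predict(st, g, n_samples = 50, seed = 12)
  expect_false(identical(u$macro_mean, u3$macro_mean))
  expect_lte(u$ci_low, u$macro_mean)
  expect_gte(u$ci_high, u$macro_mean)
  expect_gt(u$ci_high - u$ci_low, 0)
})

test_that("interval width grows with the dropout rate on average", {
  g <- build_graph("OC(=O)CCN")
  widths <- vapply(c(0.05, 0.35), function(rate) {
    mean(vapply(1:10, function(s) {
      st <- init_model(tiny_config(dropout = rate, seed = 3))
      u <- mc_dropout_predict(st, g, n_samples = 30, seed = s)
      u$ci_high - u$ci_low
    }, 0))
  }, 0)
  expect_lt(widths[1], widths[2])
})

make_index_set <- function(n = 8, seed = 29) {
  s <- generate_set(n, mode = "acidic", noise_sigma = 0, seed = seed)
  s$records
}

test_that("embedding index stores one dominant-site entry per record", {
  st <- init_model(tiny_config(seed = 7))
  recs <- make_index_set()
  idx <- build_embedding_index(st, recs)
  expect_equal(nrow(idx$entries), nrow(recs))
  expect_equal(nrow(idx$embeddings), nrow(recs))
  expect_equal(ncol(idx$embeddings), st$config$hidden_dim)
  expect_identical(idx$mode, "acidic")
  expect_false(anyNA(idx$entries$experimental_pka))

  # records without a site of the mode are skipped with a warning
  recs2 <- recs
  recs2$standardized_smiles[1] <- as.character(standardize_structure("CCCC"))
  expect_warning(idx2 <- build_embedding_index(st, recs2), "skipped")
  expect_equal(nrow(idx2$entries), nrow(recs) - 1L)

  # serialization round-trip is bit-identical
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "ref.idx")
  save_index(idx, p)
  idx3 <- load_index(p)
  expect_identical(idx3$embeddings, idx$embeddings)
  expect_identical(idx3$entries, idx$entries)
})

test_that("similarity search equals a brute-force distance scan", {
  st <- init_model(tiny_config(seed = 7))
  recs <- make_index_set(n = 12)
  idx <- build_embedding_index(st, recs)

  # query identical to an indexed molecule: distance 0, returned first
  gq <- build_graph(recs$standardized_smiles[4])
  hits <- similar_molecules(idx, st, gq, threshold = 0.05)
  expect_gte(nrow(hits), 1L)
  expect_equal(hits$distance[1], 0, tolerance = 1e-12)
  expect_true(recs$record_id[4] %in% hits$record_id)

  # brute-force oracle at a loose threshold (untrained embeddings are far
  # apart, so widen the radius to exercise ordering and truncation)
  de <- pkamil:::dominant_embedding(st, gq)
  d <- sqrt(colSums((t(idx$embeddings) - de$embedding)^2))
  for (thr in c(0.05, 0.5, 5, 50)) {
    want <- order(d)[d[order(d)] < thr]
    want <- head(want, 4L)
    got <- similar_molecules(idx, st, gq, threshold = thr)
    expect_identical(got$record_id, idx$entries$record_id[want],
                     label = paste("threshold", thr))
    expect_equal(got$distance, unname(d[want]), tolerance = 1e-12)
    expect_lte(nrow(got), 4L)
  }

  # all distances beyond threshold: empty result, not an error
  far <- similar_molecules(idx, st, build_graph("SC(S)(S)S"),
                           threshold = 1e-12)
  expect_equal(nrow(far), 0L)

  # stale index: different model fingerprint
  st2 <- init_model(tiny_config(seed = 8))
  expect_error(similar_molecules(idx, st2, gq), "stale")
})

test_that("embedding projection matches an eigendecomposition oracle", {
  set.seed(31)
  X <- matrix(rnorm(50), 10, 5)
  pr <- project_embeddings(X)
  expect_equal(dim(pr$coords), c(10L, 2L))
  expect_true(all(pr$var_explained >= 0))
  expect_lte(sum(pr$var_explained), 1 + 1e-12)

  # oracle: eigendecomposition of the covariance of centered data
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(cov(Xc))
  coords_oracle <- Xc %*% ev$vectors[, 1:2]
  for (j in 1:2) {
    expect_equal(abs(pr$coords[, j]), abs(coords_oracle[, j]),
                 tolerance = 1e-8)
    # sign convention: the largest-magnitude loading is positive
    i <- which.max(abs(pr$loadings[, j]))
    expect_gt(pr$loadings[i, j], 0)
    expect_equal(pr$var_explained[j], ev$values[j] / sum(ev$values),
                 tolerance = 1e-8)
  }

  # collinear points: second component explains nothing
  line <- outer(seq_len(6), c(1, 2, -1))
  pr2 <- project_embeddings(line + 0)
  expect_equal(pr2$var_explained[2], 0, tolerance = 1e-12)
  expect_error(project_embeddings(X[1, , drop = FALSE]), "at least 2")
})

test_that("prediction tables mirror the masking in their micro rows", {
  st <- init_model(tiny_config(seed = 37))
  s <- generate_set(5, mode = "acidic", noise_sigma = 0, seed = 41)
  pred <- predict_records(st, s$records)
  expect_equal(nrow(pred$macro), 5L)
  expect_false(any(pred$macro$no_site))
  for (i in 1:5) {
    g <- build_graph(s$records$standardized_smiles[i])
    sites <- enumerate_acidic_sites(g)
    rows <- pred$micro[pred$micro$record_id == s$records$record_id[i], ]
    expect_setequal(rows$atom_index, sites)
    raw <- predict_atom_pka(st, g)
    expect_equal(pool_sites(raw[sites], "acidic"),
                 pred$macro$macro_pka[i])
  }
  # a record with no site yields a no-site macro row and no micro rows
  recs <- s$records[1, ]
  recs$standardized_smiles <- as.character(standardize_structure("CCC"))
  pred2 <- predict_records(st, recs)
  expect_true(pred2$macro$no_site)
  expect_null(pred2$micro)
})
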