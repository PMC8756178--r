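# Graph-attention message-passing network with a per-atom pKa head.
# Each of the stacked layers computes, for every atom, attention
# coefficients over its incoming neighborhood (non-negative, summing to 1),
# aggregates neighbor messages weighted by those coefficients, and updates
# the atom state through a gated recurrent (GRU) cell. There is deliberately
# no molecule-level readout: the final atom states go straight into a fully
# connected head that emits one raw pKa per atom, and molecule-level values
# arise only through the multi-instance pooling.

#' Model configuration
#'
#' @param mode `"acidic"` or `"basic"`; separate models are trained per mode
#'   and the mode decides the masking sign downstream.
#' @param n_layers number of stacked graph attention layers (default 6).
#' @param hidden_dim atom state width (default 200).
#' @param dropout_rate dropout fraction in `[0, 1)` applied to atom states
#'   between layers (training and Monte-Carlo sampling only).
#' @param head_hidden_dims integer vector of hidden widths of the fully
#'   connected per-atom head (the final scalar output layer is implicit).
#' @param seed integer seed controlling parameter initialization.
#' @param feature_config featurization schema the model is built for.
#' @return a `model_config` object.
#' @export
model_config <- function(mode = c("acidic", "basic"), n_layers = 6L,
                         hidden_dim = 200L, dropout_rate = 0.1,
                         head_hidden_dims = c(128L),
                         seed = 1L,
                         feature_config = default_feature_config()) {
  mode <- match.arg(mode)
  n_layers <- as.integer(n_layers)
  hidden_dim <- as.integer(hidden_dim)
  head_hidden_dims <- as.integer(head_hidden_dims)
  if (is.na(n_layers) || n_layers < 1L) stop("n_layers must be >= 1")
  if (hidden_dim < 1L) stop("hidden_dim must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (any(head_hidden_dims < 1L)) stop("head_hidden_dims must be positive")
  structure(
    list(mode = mode, n_layers = n_layers, hidden_dim = hidden_dim,
         dropout_rate = dropout_rate, head_hidden_dims = head_hidden_dims,
         seed = as.integer(seed), feature_config = feature_config),
    class = "model_config"
  )
}

glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -r, r), nin, nout)
}

#' Initialize a model state
#'
#' Parameters are drawn from a Glorot-uniform distribution seeded by
#' `config$seed`, so two states built from the same configuration are
#' numerically identical.
#'
#' @param config a [model_config()].
#' @return a `model_state` object: list with `params` (named list of
#'   matrices), `config`, and `training_meta`.
#' @export
init_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  H <- config$hidden_dim
  Da <- config$feature_config$atom_dim
  Db <- config$feature_config$bond_dim
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  p <- list(W0 = glorot(Da, H), b0 = matrix(0, 1, H))
  for (l in seq_len(config$n_layers)) {
    # attention logit, decomposed into node query/key and bond terms:
    # e_uv = leakyrelu(q[v] + k[u] + Wab' bf_uv + ba)
    p[[paste0("att_q", l)]] <- glorot(H, 1L)
    p[[paste0("att_k", l)]] <- glorot(H, 1L)
    p[[paste0("att_b", l)]] <- glorot(Db, 1L)
    p[[paste0("att_bias", l)]] <- matrix(0, 1, 1)
    # neighbor message: elu((h_u W_m + b_m) + bf_uv W_mb)
    p[[paste0("msg_W", l)]] <- glorot(H, H)
    p[[paste0("msg_b", l)]] <- matrix(0, 1, H)
    p[[paste0("msg_bf", l)]] <- glorot(Db, H)
    # fused GRU gates: columns [z | r | n]
    p[[paste0("gru_Wx", l)]] <- glorot(H, 3L * H)
    p[[paste0("gru_bx", l)]] <- matrix(0, 1, 3L * H)
    p[[paste0("gru_Wh", l)]] <- glorot(H, 3L * H)
    p[[paste0("gru_bn", l)]] <- matrix(0, 1, H)
  }
  dims <- c(H, config$head_hidden_dims, 1L)
  for (k in seq_len(length(dims) - 1L)) {
    p[[paste0("head_W", k)]] <- glorot(dims[k], dims[k + 1L])
    p[[paste0("head_b", k)]] <- matrix(0, 1, dims[k + 1L])
  }
  structure(
    list(params = p, config = config,
         training_meta = list(epochs = 0L, best_val = NA_real_)),
    class = "model_state"
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.model_state <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<model_state %s: %d layers, hidden %d, %s parameters>\n",
              cfg$mode, cfg$n_layers, cfg$hidden_dim,
              format(np, big.mark = ",")))
  invisible(x)
}

# --- Batched graph structure --------------------------------------------------

# Merge molecule graphs into one block-diagonal batch. Each undirected bond
# becomes two directed edges so every atom attends over its in-neighbors.
batch_graphs <- function(graphs) {
  n_atoms <- vapply(graphs, function(g) g$n, 0L)
  offsets <- cumsum(c(0L, n_atoms[-length(n_atoms)]))
  N <- sum(n_atoms)
  X <- do.call(rbind, lapply(graphs, function(g) g$atom_features))
  src <- integer(0); dst <- integer(0)
  BF <- vector("list", length(graphs))
  for (k in seq_along(graphs)) {
    g <- graphs[[k]]
    if (nrow(g$bonds)) {
      src <- c(src, g$bonds[, 1] + offsets[k], g$bonds[, 2] + offsets[k])
      dst <- c(dst, g$bonds[, 2] + offsets[k], g$bonds[, 1] + offsets[k])
      BF[[k]] <- rbind(g$bond_features, g$bond_features)
    }
  }
  Db <- ncol(graphs[[1]]$bond_features)
  BF <- do.call(rbind, c(BF, list(matrix(0, 0, Db))))
  seg <- make_segments_safe(dst, N)
  mol_index <- rep(seq_along(graphs), n_atoms)
  list(graphs = graphs, N = N, X = X, src = src, dst = dst, BF = BF,
       seg = seg, n_atoms = n_atoms, offsets = offsets,
       mol_index = mol_index)
}

# segments where some groups (isolated atoms) receive no edges
make_segments_safe <- function(grp, ngroups) {
  if (length(grp) == 0L) {
    return(list(grp = grp,
                S = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                         x = numeric(0), dims = c(ngroups, 0L)),
                idx = rep(list(integer(0)), ngroups)))
  }
  make_segments(grp, ngroups)
}

# --- Forward pass -------------------------------------------------------------

# The tape forward producing per-atom embeddings. `dropmasks` is NULL
# (deterministic) or a list of per-layer inverted-dropout mask matrices.
forward_embeddings <- function(tp, params, bg, config, dropmasks = NULL) {
  pid <- lapply(params, function(m) tp_leaf(tp, m))
  H <- config$hidden_dim
  has_edges <- length(bg$src) > 0L
  if (has_edges) bf <- tp_leaf(tp, bg$BF)

  h <- tp_leakyrelu(tp, tp_bias(tp, tp_matmul(tp, tp_leaf(tp, bg$X),
                                              pid$W0), pid$b0))
  for (l in seq_len(config$n_layers)) {
    if (has_edges) {
      # attention over in-neighbors: node-level query/key projections are
      # gathered per edge (equivalent to one linear form on [h_v, h_u, bf])
      q <- tp_matmul(tp, h, pid[[paste0("att_q", l)]])
      k <- tp_matmul(tp, h, pid[[paste0("att_k", l)]])
      logit <- tp_leakyrelu(tp, tp_bias(tp,
        tp_add(tp, tp_add(tp, tp_rows(tp, q, bg$dst),
                          tp_rows(tp, k, bg$src)),
               tp_matmul(tp, bf, pid[[paste0("att_b", l)]])),
        pid[[paste0("att_bias", l)]]), alpha = 0.2)
      att <- tp_segsoftmax(tp, logit, bg$seg)
      m <- tp_bias(tp, tp_matmul(tp, h, pid[[paste0("msg_W", l)]]),
                   pid[[paste0("msg_b", l)]])
      msg <- tp_elu(tp, tp_add(tp, tp_rows(tp, m, bg$src),
                               tp_matmul(tp, bf, pid[[paste0("msg_bf", l)]])))
      ctx <- tp_spmm(tp, bg$seg$S, tp_rowscale(tp, msg, att), bg$seg$St)
    } else {
      ctx <- tp_leaf(tp, matrix(0, bg$N, H))
    }
    # gated recurrent update of the atom state (fused gate projections)
    U <- tp_bias(tp, tp_matmul(tp, ctx, pid[[paste0("gru_Wx", l)]]),
                 pid[[paste0("gru_bx", l)]])
    V <- tp_matmul(tp, h, pid[[paste0("gru_Wh", l)]])
    z <- tp_sigmoid(tp, tp_add(tp, tp_cols(tp, U, 1L, H),
                               tp_cols(tp, V, 1L, H)))
    r <- tp_sigmoid(tp, tp_add(tp, tp_cols(tp, U, H + 1L, 2L * H),
                               tp_cols(tp, V, H + 1L, 2L * H)))
    nn <- tp_tanh(tp, tp_add(tp, tp_cols(tp, U, 2L * H + 1L, 3L * H),
      tp_mul(tp, r, tp_bias(tp, tp_cols(tp, V, 2L * H + 1L, 3L * H),
                            pid[[paste0("gru_bn", l)]]))))
    one <- tp_leaf(tp, matrix(1, bg$N, H))
    h <- tp_add(tp, tp_mul(tp, tp_sub(tp, one, z), nn), tp_mul(tp, z, h))
    if (!is.null(dropmasks)) h <- tp_mul(tp, h, tp_leaf(tp, dropmasks[[l]]))
  }
  list(h = h, pid = pid)
}

forward_head <- function(tp, pid, h, config) {
  nk <- length(config$head_hidden_dims) + 1L
  for (k in seq_len(nk)) {
    h <- tp_bias(tp, tp_matmul(tp, h, pid[[paste0("head_W", k)]]),
                 pid[[paste0("head_b", k)]])
    if (k < nk) h <- tp_leakyrelu(tp, h)
  }
  h
}

make_dropmasks <- function(config, N) {
  p <- config$dropout_rate
  if (p <= 0) return(NULL)
  lapply(seq_len(config$n_layers), function(l)
    matrix(rbinom(N * config$hidden_dim, 1L, 1 - p) / (1 - p),
           N, config$hidden_dim))
}

# --- Public inference surface -------------------------------------------------

#' Per-atom embeddings from the stacked attention layers
#'
#' Returns the atom states after the last graph attention layer (the
#' "last hidden layer" embeddings used for similarity search and
#' projection). With `dropout_active = FALSE` the result is deterministic.
#'
#' @param state a `model_state`.
#' @param graph a `molecule_graph` (or list of graphs, processed as a batch).
#' @param dropout_active if `TRUE`, applies inverted dropout between layers
#'   using the current RNG stream (used by Monte-Carlo sampling).
#' @return a numeric matrix with one row per atom (`last_hidden = TRUE`
#'   attribute marks the provenance); for a list input, a list of matrices.
#' @export
atom_embeddings <- function(state, graph, dropout_active = FALSE) {
  stopifnot(inherits(state, "model_state"))
  single <- inherits(graph, "molecule_graph")
  graphs <- if (single) list(graph) else graph
  check_feature_dims(state, graphs[[1]])
  bg <- batch_graphs(graphs)
  tp <- tp_new()
  masks <- if (dropout_active) make_dropmasks(state$config, bg$N) else NULL
  fw <- forward_embeddings(tp, state$params, bg, state$config, masks)
  E <- tp_val(tp, fw$h)
  attr(E, "last_hidden") <- TRUE
  if (single) return(E)
  lapply(seq_along(graphs), function(k)
    E[bg$mol_index == k, , drop = FALSE])
}

check_feature_dims <- function(state, graph) {
  want <- state$config$feature_config$atom_dim
  if (ncol(graph$atom_features) != want)
    stop("feature-length mismatch: graph has ", ncol(graph$atom_features),
         " atom features, model expects ", want)
}

#' Raw per-atom pKa from the fully connected head
#'
#' Maps each atom embedding to a scalar raw pKa (no masking applied).
#'
#' @param state a `model_state`.
#' @param embeddings matrix from [atom_embeddings()] (same state).
#' @return numeric vector, one raw pKa per atom.
#' @export
atom_pka_head <- function(state, embeddings) {
  stopifnot(inherits(state, "model_state"))
  if (ncol(embeddings) != state$config$hidden_dim)
    stop("embedding width does not match the model's hidden_dim")
  tp <- tp_new()
  pid <- lapply(state$params, function(m) tp_leaf(tp, m))
  out <- forward_head(tp, pid, tp_leaf(tp, embeddings), state$config)
  as.vector(tp_val(tp, out))
}

#' Predict raw per-atom pKa for one molecule
#'
#' Convenience composition of [atom_embeddings()] and [atom_pka_head()].
#'
#' @inheritParams atom_embeddings
#' @return numeric vector of length `graph$n`.
#' @export
predict_atom_pka <- function(state, graph, dropout_active = FALSE) {
  atom_pka_head(state, atom_embeddings(state, graph, dropout_active))
}

#' Predict the macro-pKa of a molecule
#'
#' Runs the per-atom model, masks non-ionizable atoms for the model's mode,
#' and pools the site micro-pKa values into the molecule's most-acidic or
#' most-basic macro-pKa.
#'
#' @param state a `model_state`.
#' @param graph a `molecule_graph`.
#' @return list with `macro` (a `macro_pka`), `micro` (a `micro_pka`), and
#'   `sites` (1-based site indices for the model's mode).
#' @export
predict_macro_pka <- function(state, graph) {
  mode <- state$config$mode
  sites <- sites_for_mode(graph, mode)
  raw <- predict_atom_pka(state, graph)
  masked <- apply_mask(raw, sites, mode)
  macro <- if (mode == "acidic") pool_acidic(masked) else pool_basic(masked)
  list(macro = macro, micro = masked, sites = sites)
}

# --- Checkpointing ------------------------------------------------------------

# order-insensitive content hash used to detect stale indexes/checkpoints
config_fingerprint <- function(state) {
  s <- paste(
    state$config$mode, state$config$n_layers, state$config$hidden_dim,
    paste(state$config$head_hidden_dims, collapse = ","),
    paste(unlist(state$config$feature_config$atom_schema), collapse = ","),
    paste(unlist(state$config$feature_config$bond_schema), collapse = ","),
    paste(sprintf("%.6e", unlist(state$params)[seq(1, length(unlist(state$params)), by = 97L)]),
          collapse = ","),
    sep = "|"
  )
  fnv1a(s)
}

fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles the parameters, the full model configuration and
#' the featurization schema, plus a format version and content fingerprint.
#' Loading verifies the schema: a checkpoint whose feature configuration
#' does not match the requested one is an error, never a silent re-encode.
#'
#' @param state a `model_state`.
#' @param path file path (RDS format).
#' @export
save_model <- function(state, path) {
  stopifnot(inherits(state, "model_state"))
  saveRDS(list(format = "pkamil-checkpoint", version = 1L,
               fingerprint = config_fingerprint(state), state = state),
          path)
  invisible(path)
}

#' @rdname save_model
#' @param feature_config if non-NULL, the schema the caller intends to use;
#'   mismatches with the stored schema raise an error.
#' @return `load_model()` returns the `model_state`.
#' @export
load_model <- function(path, feature_config = NULL) {
  x <- readRDS(path)
  if (!identical(x$format, "pkamil-checkpoint"))
    stop("not a model checkpoint: ", path)
  st <- x$state
  if (!identical(config_fingerprint(st), x$fingerprint))
    stop("checkpoint fingerprint mismatch (corrupted file?)")
  if (!is.null(feature_config) &&
      !identical(feature_config, st$config$feature_config))
    stop("feature configuration mismatch between checkpoint and caller")
  st
}
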