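# Dataset splitting, MSE training of the per-atom model against macro
# labels, and regression metrics. The model never sees a micro label:
# the only learning signal reaches atoms through the pooling algebra,
# whose gradient distributes the molecule-level error over sites in
# proportion to their dominance.

#' Split records into train/validation/test sets
#'
#' Uniform random partition, reproducible from `seed`. Set sizes follow the
#' largest-remainder rule: each set gets `floor(n * ratio)` records, and the
#' leftovers go to the sets with the largest fractional remainders (earlier
#' set wins ties), so a 10-record 70:15:15 split is 7/2/1.
#'
#' @param records a records data.frame.
#' @param ratios numeric length-3 vector summing to 1 (default 70:15:15).
#' @param seed integer seed.
#' @return a `dataset_split`: list with `train`, `validation`, `test`
#'   (disjoint row subsets of `records`), `ratios`, `seed`.
#' @export
split_dataset <- function(records, ratios = c(0.70, 0.15, 0.15), seed = 1L) {
  n <- nrow(records)
  if (n < 3L) stop("need at least 3 records to split")
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8)
    stop("ratios must be 3 numbers summing to 1")
  sizes <- floor(n * ratios)
  rem <- n * ratios - sizes
  left <- n - sum(sizes)
  if (left > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(left)]
    sizes[give] <- sizes[give] + 1L
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample.int(n)
  idx <- list(
    train = perm[seq_len(sizes[1])],
    validation = perm[sizes[1] + seq_len(sizes[2])],
    test = perm[sizes[1] + sizes[2] + seq_len(sizes[3])]
  )
  structure(
    list(train = records[sort(idx$train), , drop = FALSE],
         validation = records[sort(idx$validation), , drop = FALSE],
         test = records[sort(idx$test), , drop = FALSE],
         ratios = ratios, seed = as.integer(seed)),
    class = "dataset_split"
  )
}

#' Training hyperparameters
#'
#' @param lr Adam learning rate.
#' @param max_epochs epoch budget.
#' @param patience early-stopping patience on validation MAE, in epochs.
#' @param batch_size molecules per minibatch.
#' @param min_delta smallest validation-MAE improvement that resets the
#'   early-stopping counter (pKa units).
#' @param seed seed for batching and any training-time stochasticity
#'   (dropout masks); `NULL` uses the model's own seed.
#' @param verbose print per-epoch loss lines.
#' @return a list of class `train_config`.
#' @export
train_config <- function(lr = 1e-2, max_epochs = 500L, patience = 30L,
                         batch_size = 128L, min_delta = 1e-3, seed = NULL,
                         verbose = FALSE) {
  structure(list(lr = lr, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 min_delta = min_delta,
                 seed = seed, verbose = isTRUE(verbose)),
            class = "train_config")
}

# Precompute everything the loss needs for a fixed set of molecules.
prepare_pool_batch <- function(graphs, labels, mode) {
  bg <- batch_graphs(graphs)
  sites <- lapply(graphs, sites_for_mode, mode = mode)
  stopifnot(all(lengths(sites) > 0L))
  site_atoms <- unlist(mapply(function(s, o) s + o, sites, bg$offsets,
                              SIMPLIFY = FALSE), use.names = FALSE)
  site_mol <- rep(seq_along(graphs), lengths(sites))
  list(bg = bg, site_atoms = site_atoms,
       pool_seg = make_segments(site_mol, length(graphs)),
       labels = labels, n_mol = length(graphs))
}

# forward to per-molecule macro values; returns tape ids for backward
forward_macro <- function(tp, params, batch, config, dropmasks = NULL) {
  fw <- forward_embeddings(tp, params, batch$bg, config, dropmasks)
  out <- forward_head(tp, fw$pid, fw$h, config)
  p <- tp_rows(tp, out, batch$site_atoms)
  sign <- if (config$mode == "acidic") -1 else +1
  mac <- tp_pool(tp, p, batch$pool_seg, sign)
  list(macro = mac, pid = fw$pid, h = fw$h, raw = out)
}

predict_macro_batch_prepared <- function(state, batch) {
  tp <- tp_new()
  fw <- forward_macro(tp, state$params, batch, state$config)
  as.vector(tp_val(tp, fw$macro))
}

#' Batched macro-pKa prediction
#'
#' @param state a trained or initialized `model_state`.
#' @param graphs list of `molecule_graph` objects, each with at least one
#'   site of the model's mode.
#' @return numeric vector of macro-pKa values.
#' @export
predict_macro_batch <- function(state, graphs) {
  batch <- prepare_pool_batch(graphs, labels = NULL, state$config$mode)
  predict_macro_batch_prepared(state, batch)
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(params = params, opt = opt)
}

# records usable for a mode: finite label and >= 1 site
usable_for_mode <- function(records, graphs, mode) {
  lab <- if (mode == "acidic") records$acidic_label else records$basic_label
  has_site <- vapply(graphs, function(g) length(sites_for_mode(g, mode)) > 0L,
                     TRUE)
  ok <- is.finite(lab) & has_site
  dropped <- which(is.finite(lab) & !has_site)
  if (length(dropped))
    warning(sprintf("%d record(s) have no %s site and were excluded: %s",
                    length(dropped), mode,
                    paste(utils::head(records$record_id[dropped], 5L),
                          collapse = ", ")),
            call. = FALSE)
  ok
}

#' Train the model on macro labels
#'
#' Minimizes the mean squared error between the pooled macro prediction and
#' the macro label with Adam, early-stopping on validation MAE and returning
#' the best-validation parameters. Records lacking a finite label or any
#' ionizable site of the model's mode are excluded (with a warning for the
#' site-less ones). Reproducible: the same state, split and configuration
#' give identical loss histories.
#'
#' @param state an initialized `model_state` (decides the mode).
#' @param split a `dataset_split` of standardized records.
#' @param run_config a [train_config()].
#' @return the trained `model_state`; `training_meta` carries the epoch
#'   count, best validation MAE and the per-epoch `history` data.frame.
#' @export
train <- function(state, split, run_config = train_config()) {
  stopifnot(inherits(state, "model_state"), inherits(split, "dataset_split"))
  config <- state$config
  mode <- config$mode
  fc <- config$feature_config

  build_all <- function(recs) lapply(recs$standardized_smiles, build_graph,
                                     config = fc)
  tr_graphs <- build_all(split$train)
  va_graphs <- build_all(split$validation)
  tr_ok <- usable_for_mode(split$train, tr_graphs, mode)
  va_ok <- usable_for_mode(split$validation, va_graphs, mode)
  if (!any(tr_ok)) stop("no usable training records for mode ", mode)
  lab_col <- if (mode == "acidic") "acidic_label" else "basic_label"
  tr_labels <- split$train[[lab_col]][tr_ok]
  va_labels <- split$validation[[lab_col]][va_ok]
  tr_graphs <- tr_graphs[tr_ok]
  va_graphs <- va_graphs[va_ok]

  seed <- if (is.null(run_config$seed)) config$seed else run_config$seed
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # fixed seeded batch assignment, precomputed once
  n <- length(tr_graphs)
  perm <- sample.int(n)
  nb <- max(1L, ceiling(n / run_config$batch_size))
  assignment <- sort(rep(seq_len(nb), length.out = n))
  batches <- lapply(seq_len(nb), function(b) {
    ii <- perm[assignment == b]
    prepare_pool_batch(tr_graphs[ii], tr_labels[ii], mode)
  })
  va_batch <- if (length(va_graphs))
    prepare_pool_batch(va_graphs, va_labels, mode) else NULL

  params <- state$params
  opt <- adam_new(params)
  use_dropout <- config$dropout_rate > 0
  best <- list(val = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_mae = numeric(0))
  wait <- 0L

  for (epoch in seq_len(run_config$max_epochs)) {
    ep_loss <- 0
    for (b in seq_len(nb)) {
      batch <- batches[[b]]
      masks <- if (use_dropout) make_dropmasks(config, batch$bg$N) else NULL
      tp <- tp_new()
      fw <- forward_macro(tp, params, batch, config, masks)
      loss <- tp_mse(tp, fw$macro, batch$labels)
      ep_loss <- ep_loss + as.numeric(tp_val(tp, loss)) * batch$n_mol
      grads <- tp_backward(tp, loss)
      gnamed <- setNames(lapply(names(params), function(nm)
        grads[[fw$pid[[nm]]]]), names(params))
      upd <- adam_step(params, gnamed, opt, run_config$lr)
      params <- upd$params
      opt <- upd$opt
    }
    ep_loss <- ep_loss / n

    val_mae <- NA_real_
    if (!is.null(va_batch)) {
      vp <- predict_macro_batch_prepared(
        structure(list(params = params, config = config),
                  class = "model_state"), va_batch)
      val_mae <- mean(abs(vp - va_batch$labels))
    }
    history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                         val_mae = val_mae))
    if (run_config$verbose)
      message(sprintf("epoch %3d  train MSE %.4f  val MAE %.4f",
                      epoch, ep_loss, val_mae))

    track <- if (is.na(val_mae)) ep_loss else val_mae
    if (track < best$val - run_config$min_delta) {
      best <- list(val = track, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= run_config$patience) break
    }
  }

  state$params <- best$params
  state$training_meta <- list(epochs = epoch, best_epoch = best$epoch,
                              best_val = best$val, history = history)
  state
}

#' Regression metrics for macro-pKa prediction
#'
#' MAE, RMSE and the coefficient of determination
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}. `r2` is `NA` (with
#' `r2_undefined = TRUE`) when fewer than two observations are given or the
#' truths are constant.
#'
#' @param predictions,truths equal-length finite numeric vectors.
#' @return an `eval_report`: list with `mae`, `rmse`, `r2`, `r2_undefined`,
#'   `n`.
#' @export
compute_regression_metrics <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths))
  keep <- is.finite(predictions) & is.finite(truths)
  p <- predictions[keep]; t <- truths[keep]
  n <- length(p)
  if (n == 0L) stop("no finite prediction/truth pairs")
  mae <- mean(abs(p - t))
  rmse <- sqrt(mean((p - t)^2))
  ss_tot <- sum((t - mean(t))^2)
  undefined <- n < 2L || ss_tot == 0
  r2 <- if (undefined) NA_real_ else 1 - sum((p - t)^2) / ss_tot
  structure(list(mae = mae, rmse = rmse, r2 = r2, r2_undefined = undefined,
                 n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report n=%d: MAE %.4f, RMSE %.4f, R2 %s>\n", x$n,
              x$mae, x$rmse,
              if (x$r2_undefined) "undefined" else sprintf("%.4f", x$r2)))
  invisible(x)
}

#' Repeat training across independent runs
#'
#' Re-seeds both the split and the initialization per run and reports the
#' per-run test metrics with their mean and sample standard deviation.
#'
#' @param records standardized records.
#' @param base_config a `model_config` (its seed is offset per run).
#' @param run_config a [train_config()].
#' @param n_runs number of independent runs.
#' @param ratios split ratios.
#' @return list with `runs` (per-run `eval_report`s), `mean`, `sd` (named
#'   vectors over mae/rmse/r2).
#' @export
train_runs <- function(records, base_config, run_config = train_config(),
                       n_runs = 3L, ratios = c(0.70, 0.15, 0.15)) {
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- base_config
    cfg$seed <- base_config$seed + r - 1L
    sp <- split_dataset(records, ratios, seed = cfg$seed)
    st <- train(init_model(cfg), sp,
                modifyList(run_config, list(seed = cfg$seed)))
    graphs <- lapply(sp$test$standardized_smiles, build_graph,
                     config = cfg$feature_config)
    ok <- usable_for_mode(sp$test, graphs, cfg$mode)
    lab <- if (cfg$mode == "acidic") sp$test$acidic_label else
      sp$test$basic_label
    pred <- predict_macro_batch(st, graphs[ok])
    runs[[r]] <- compute_regression_metrics(pred, lab[ok])
  }
  pick <- function(f) vapply(runs, function(x) x[[f]], 0)
  mat <- rbind(mae = pick("mae"), rmse = pick("rmse"), r2 = pick("r2"))
  list(runs = runs, mean = rowMeans(mat), sd = apply(mat, 1L, stats::sd))
}
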