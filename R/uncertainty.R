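# Monte-Carlo-dropout uncertainty, atomic-embedding similarity search over
# a reference set, and 2-D projection of embeddings.

#' Monte-Carlo-dropout macro-pKa prediction with a 95% interval
#'
#' Runs `n_samples` stochastic forward passes with dropout active and
#' summarizes the macro-pKa samples by their mean and the empirical
#' 2.5/97.5 percentiles (robust to skew; no normality assumed). With
#' `dropout_rate = 0` every sample is identical and a degenerate-interval
#' warning is raised. Seeded: the same seed reproduces the interval.
#'
#' @param state a `model_state`.
#' @param graph a `molecule_graph` with at least one site of the mode.
#' @param n_samples number of stochastic passes (default 100).
#' @param seed integer seed for the dropout masks.
#' @param keep_samples retain the per-sample macro values.
#' @return an `uncertain_prediction`: list with `macro_mean`, `ci_low`,
#'   `ci_high`, `n_samples`, and optionally `samples`.
#' @export
mc_dropout_predict <- function(state, graph, n_samples = 100L, seed = 1L,
                               keep_samples = FALSE) {
  stopifnot(inherits(state, "model_state"), n_samples >= 1L)
  mode <- state$config$mode
  sites <- sites_for_mode(graph, mode)
  if (length(sites) == 0L) stop("molecule has no ", mode, " site")
  if (state$config$dropout_rate <= 0)
    warning("dropout_rate is 0: all samples are identical, ",
            "the interval is degenerate", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  samples <- vapply(seq_len(n_samples), function(s) {
    raw <- predict_atom_pka(state, graph, dropout_active = TRUE)
    pool_sites(raw[sites], mode)
  }, 0)
  ci <- unname(stats::quantile(samples, c(0.025, 0.975), type = 7))
  m <- mean(samples)
  structure(
    list(macro_mean = m, ci_low = min(ci[1], m), ci_high = max(ci[2], m),
         n_samples = as.integer(n_samples),
         samples = if (keep_samples) samples else NULL),
    class = "uncertain_prediction"
  )
}

#' @export
print.uncertain_prediction <- function(x, ...) {
  cat(sprintf("<uncertain_prediction: %.3f [%.3f, %.3f] (n=%d)>\n",
              x$macro_mean, x$ci_low, x$ci_high, x$n_samples))
  invisible(x)
}

dominant_embedding <- function(state, graph, epsilon = 0.1) {
  mode <- state$config$mode
  sites <- sites_for_mode(graph, mode)
  if (length(sites) == 0L) return(NULL)
  emb <- atom_embeddings(state, graph)
  raw <- atom_pka_head(state, emb)
  dom <- dominant_from_values(setNames(raw[sites], sites), mode, epsilon)
  site <- min(dom$G) # first of G under atom-index order
  list(site = site, embedding = emb[site, ],
       micro = unname(dom$micro[as.character(site)]))
}

#' Build an atomic-embedding reference index
#'
#' For each labelled reference record, predicts the dominant ionization
#' site (first of the dominant set in atom-index order under ties),
#' extracts that atom's last-hidden-layer embedding and stores it with the
#' record's experimental macro-pKa. Records without a site of the mode are
#' skipped with a warning.
#'
#' @param state a `model_state`.
#' @param records standardized records with a finite label for the mode.
#' @return an `embedding_index`: list with `entries` (data.frame:
#'   record_id, atom_index, experimental_pka), `embeddings` (matrix, one
#'   row per entry), `mode`, `fingerprint` (model/config hash used to
#'   detect stale indexes).
#' @export
build_embedding_index <- function(state, records) {
  mode <- state$config$mode
  lab <- if (mode == "acidic") records$acidic_label else records$basic_label
  entries <- list(); embs <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(records))) {
    g <- build_graph(records$standardized_smiles[i],
                     state$config$feature_config)
    de <- dominant_embedding(state, g)
    if (is.null(de)) {
      skipped <- c(skipped, records$record_id[i])
      next
    }
    entries[[length(entries) + 1L]] <- data.frame(
      record_id = records$record_id[i], atom_index = de$site,
      experimental_pka = lab[i], stringsAsFactors = FALSE)
    embs[[length(embs) + 1L]] <- de$embedding
  }
  if (length(skipped))
    warning(length(skipped), " record(s) without a ", mode,
            " site were skipped: ",
            paste(utils::head(skipped, 5L), collapse = ", "), call. = FALSE)
  structure(
    list(entries = do.call(rbind, entries),
         embeddings = do.call(rbind, embs),
         mode = mode, fingerprint = config_fingerprint(state)),
    class = "embedding_index"
  )
}

#' Save / load an embedding index
#'
#' @param index an `embedding_index`.
#' @param path file path (RDS format, versioned, fingerprinted).
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "embedding_index"))
  saveRDS(list(format = "pkamil-index", version = 1L, index = index), path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "pkamil-index")) stop("not an embedding index: ", path)
  x$index
}

#' Similar reference molecules by dominant-atom embedding distance
#'
#' Computes the Euclidean distance between the query's dominant-site
#' embedding and every index entry; entries with distance below the
#' threshold are returned nearest-first, truncated to `k`, each carrying
#' its experimental pKa. An empty result means nothing in the reference
#' set is close enough — not an error.
#'
#' @param index an `embedding_index` built with the same model.
#' @param state the `model_state` the index was built with.
#' @param graph the query `molecule_graph`.
#' @param threshold maximum Euclidean distance (default 0.05).
#' @param k maximum number of neighbors (default 4).
#' @return data.frame with `record_id`, `distance`, `experimental_pka`.
#' @export
similar_molecules <- function(index, state, graph, threshold = 0.05, k = 4L) {
  stopifnot(inherits(index, "embedding_index"))
  if (!identical(index$fingerprint, config_fingerprint(state)))
    stop("stale index: it was built with a different model or configuration")
  de <- dominant_embedding(state, graph)
  if (is.null(de)) stop("query molecule has no ", index$mode, " site")
  d <- sqrt(rowSums(sweep(index$embeddings, 2L, de$embedding)^2))
  hit <- which(d < threshold)
  hit <- hit[order(d[hit])]
  hit <- utils::head(hit, k)
  data.frame(record_id = index$entries$record_id[hit],
             distance = d[hit],
             experimental_pka = index$entries$experimental_pka[hit],
             stringsAsFactors = FALSE)
}

#' Project embeddings to their top-2 principal components
#'
#' Mean-centered PCA with a deterministic sign convention: within each
#' component the loading of largest magnitude is made positive.
#'
#' @param embeddings numeric matrix (rows are atoms/entries).
#' @return list with `coords` (n x 2), `var_explained` (fractions for the
#'   two components), `loadings`.
#' @export
project_embeddings <- function(embeddings) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) < 2L) stop("need at least 2 embeddings")
  pc <- stats::prcomp(embeddings, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sc <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sc[, j] <- -sc[, j]
    }
  }
  if (k < 2L) { # rank-1 input: second component is identically zero
    rot <- cbind(rot, 0)
    sc <- cbind(sc, 0)
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = sc, var_explained = c(ve, 0)[1:2], loadings = rot)
}
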