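# Tabular prediction output: one macro row per record and mode, one micro
# row per ionizable site (micro values are only reported for atoms in the
# site set, mirroring the masking).

#' Predict a set of records and tabulate the results
#'
#' @param state a `model_state`.
#' @param records standardized records data.frame.
#' @param uncertainty if `TRUE`, adds a Monte-Carlo-dropout 95% interval
#'   per record (requires `dropout_rate > 0`).
#' @param n_samples dropout samples when `uncertainty` is on.
#' @param seed seed for the dropout sampling.
#' @return list with `macro` (record_id, mode, macro_pka, no_site, and
#'   ci_low/ci_high when requested) and `micro` (record_id, atom_index,
#'   element, micro_pka).
#' @export
predict_records <- function(state, records, uncertainty = FALSE,
                            n_samples = 100L, seed = 1L) {
  mode <- state$config$mode
  macro_rows <- list(); micro_rows <- list()
  for (i in seq_len(nrow(records))) {
    g <- build_graph(records$standardized_smiles[i],
                     state$config$feature_config)
    sites <- sites_for_mode(g, mode)
    id <- records$record_id[i]
    if (length(sites) == 0L) {
      macro_rows[[i]] <- data.frame(record_id = id, mode = mode,
                                    macro_pka = NA_real_, no_site = TRUE)
      next
    }
    raw <- predict_atom_pka(state, g)
    macro <- pool_sites(raw[sites], mode)
    row <- data.frame(record_id = id, mode = mode, macro_pka = macro,
                      no_site = FALSE)
    if (uncertainty) {
      u <- mc_dropout_predict(state, g, n_samples = n_samples,
                              seed = seed + i)
      row$ci_low <- u$ci_low
      row$ci_high <- u$ci_high
    }
    macro_rows[[i]] <- row
    micro_rows[[i]] <- data.frame(record_id = id, atom_index = sites,
                                  element = g$element[sites],
                                  micro_pka = raw[sites])
  }
  fill <- function(rows) {
    rows <- Filter(Negate(is.null), rows)
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  macro <- do.call(rbind, lapply(macro_rows, function(r) {
    if (uncertainty && is.null(r$ci_low)) { r$ci_low <- NA_real_; r$ci_high <- NA_real_ }
    r
  }))
  list(macro = macro, micro = fill(micro_rows))
}

#' Write prediction tables to CSV or JSON
#'
#' @param pred result of [predict_records()].
#' @param path output path; format chosen by extension (`.json` or `.csv`;
#'   CSV writes `<path>` for macro and `<stem>_sites.csv` for micro rows).
#' @export
write_predictions <- function(pred, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(pred, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else {
    utils::write.csv(pred$macro, path, row.names = FALSE)
    if (!is.null(pred$micro))
      utils::write.csv(pred$micro, sub("\\.csv$", "_sites.csv", path),
                       row.names = FALSE)
  }
  invisible(path)
}
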