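# Applicability-domain analysis by fingerprint similarity, and the
# dominant-ionization-site consistency metrics used to compare the model's
# site assignments against an expert reference.

# --- Circular fingerprints ----------------------------------------------------

# 32-bit integer mixing (xorshift-multiply), kept inside R's integer range
mix_hash <- function(x) {
  h <- 2166136261
  for (v in x) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(v %% 2147483647))
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

#' Circular (radius-2) hashed fingerprint of a molecular graph
#'
#' A 1024-bit circular fingerprint in the Morgan/ECFP family, implemented
#' over the package's own graph representation: each atom starts from an
#' invariant tuple (element, degree, formal charge, H count, ring and
#' aromatic flags); two rounds of neighborhood hashing fold in the sorted
#' (bond type, neighbor identifier) pairs; every identifier from rounds 0-2
#' sets one bit.
#'
#' @param graph a `molecule_graph`.
#' @param nbits fingerprint length (default 1024).
#' @param radius neighborhood rounds (default 2).
#' @return a logical vector of length `nbits`.
#' @export
circular_fingerprint <- function(graph, nbits = 1024L, radius = 2L) {
  stopifnot(inherits(graph, "molecule_graph"))
  n <- graph$n
  elt <- match(graph$element, c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P"),
               nomatch = 99L)
  ids <- vapply(seq_len(n), function(i) mix_hash(c(
    elt[i], graph$degree[i], graph$formal_charge[i] + 10L,
    graph$h_count[i], as.integer(graph$aromatic[i]),
    as.integer(graph$in_ring[i]))), 0L)
  bond_code <- match(graph$bond_type, c("single", "double", "triple",
                                        "aromatic"))
  nbr <- lapply(seq_len(n), function(i) {
    e1 <- which(graph$bonds[, 1] == i)
    e2 <- which(graph$bonds[, 2] == i)
    cbind(atom = c(graph$bonds[e1, 2], graph$bonds[e2, 1]),
          code = bond_code[c(e1, e2)])
  })
  all_ids <- ids
  for (r in seq_len(radius)) {
    ids <- vapply(seq_len(n), function(i) {
      nb <- nbr[[i]]
      if (nrow(nb) == 0L) return(mix_hash(c(r, ids[i])))
      pairs <- cbind(nb[, "code"], ids[nb[, "atom"]])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      mix_hash(c(r, ids[i], as.vector(t(pairs))))
    }, 0L)
    all_ids <- c(all_ids, ids)
  }
  bits <- rep(FALSE, nbits)
  bits[(unique(all_ids) %% nbits) + 1L] <- TRUE
  bits
}

#' Tanimoto coefficient between two bit fingerprints
#'
#' @param a,b logical vectors of equal length.
#' @return similarity in `[0, 1]`; 0 when neither has a set bit.
#' @export
tanimoto <- function(a, b) {
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

#' Maximum train-set similarity and per-bin MAE table
#'
#' For each test molecule, computes the maximum Tanimoto similarity over all
#' training molecules (1024-bit radius-2 circular fingerprints) and assigns
#' it to one of the similarity bins; when predictions and truths are given,
#' also reports the MAE per bin. Default bins: right-open
#' `[0,0.3), [0.3,0.4), [0.4,0.5), [0.5,0.6)` and closed `[0.6,1]`.
#'
#' @param test_graphs,train_graphs lists of `molecule_graph` objects.
#' @param bin_edges increasing numeric vector of bin boundaries starting at
#'   0 and ending at 1.
#' @param predictions,truths optional numeric vectors aligned with
#'   `test_graphs` for the per-bin MAE.
#' @return list with `max_similarity` (per test molecule), `bin` (integer
#'   bin index), and `table` (data.frame: bin interval, n, mae).
#' @export
max_similarity_bins <- function(test_graphs, train_graphs,
                                bin_edges = c(0, 0.3, 0.4, 0.5, 0.6, 1),
                                predictions = NULL, truths = NULL) {
  if (length(train_graphs) == 0L) stop("empty training set")
  stopifnot(!is.unsorted(bin_edges), bin_edges[1] == 0,
            bin_edges[length(bin_edges)] == 1)
  train_fp <- lapply(train_graphs, circular_fingerprint)
  max_sim <- vapply(test_graphs, function(g) {
    fp <- circular_fingerprint(g)
    max(vapply(train_fp, tanimoto, 0, a = fp))
  }, 0)
  nb <- length(bin_edges) - 1L
  bin <- findInterval(max_sim, bin_edges, rightmost.closed = TRUE)
  err <- if (!is.null(predictions)) abs(predictions - truths) else NULL
  tab <- do.call(rbind, lapply(seq_len(nb), function(b) {
    ii <- which(bin == b)
    data.frame(
      bin = sprintf("[%.2g,%.2g%s", bin_edges[b], bin_edges[b + 1L],
                    if (b == nb) "]" else ")"),
      n = length(ii),
      mae = if (is.null(err) || length(ii) == 0L) NA_real_ else mean(err[ii]))
  }))
  list(max_similarity = max_sim, bin = bin, table = tab)
}

# --- Dominant-site metrics ----------------------------------------------------

#' Dominant ionization sites of a molecule
#'
#' The predicted dominant set G is every site whose micro-pKa lies within
#' `epsilon` of the extreme (minimum for acidic, maximum for basic) over the
#' site set — set-valued because near-ties are chemically indistinguishable.
#'
#' @param state a `model_state`.
#' @param graph a `molecule_graph` with at least one site of the mode.
#' @param epsilon tie tolerance in pKa units (default 0.1).
#' @return a `dominant_sites` object: list with `G` (atom indices),
#'   `extreme_value`, `micro` (named micro-pKa over sites), `mode`,
#'   `epsilon`.
#' @export
dominant_sites <- function(state, graph, epsilon = 0.1) {
  mode <- state$config$mode
  sites <- sites_for_mode(graph, mode)
  if (length(sites) == 0L) stop("molecule has no ", mode, " site")
  raw <- predict_atom_pka(state, graph)
  dominant_from_values(setNames(raw[sites], sites), mode, epsilon)
}

# shared tie logic, also used on ground-truth values
dominant_from_values <- function(micro, mode, epsilon) {
  v <- as.numeric(micro)
  idx <- as.integer(names(micro))
  extreme <- if (mode == "acidic") min(v) else max(v)
  keep <- abs(v - extreme) <= epsilon
  structure(list(G = idx[keep], extreme_value = extreme, micro = micro,
                 mode = mode, epsilon = epsilon),
            class = "dominant_sites")
}

#' Consistency rate between predicted and expert dominant sites
#'
#' For each molecule i the indicator \eqn{c_i} is 1 when the expert site
#' \eqn{h_i} belongs to the predicted dominant set \eqn{G_i}; the
#' consistency rate is the mean of the indicators. For disagreements the
#' difference value |f(g) - f(h)| is reported, taking the worst case over
#' g in G when the prediction is set-valued.
#'
#' @param assignments list of `dominant_sites` objects.
#' @param expert integer vector of expert-assigned site indices, aligned
#'   with `assignments`.
#' @return a `consistency_report`: list with `c` (0/1 per molecule),
#'   `consistency_rate`, `n`, and `difference_values` (one per
#'   disagreement, `NA` when the expert site has no prediction).
#' @export
consistency_rate <- function(assignments, expert) {
  if (length(assignments) != length(expert))
    stop("assignments and expert lists differ in length")
  n <- length(assignments)
  ci <- integer(n)
  dv <- numeric(0)
  for (i in seq_len(n)) {
    a <- assignments[[i]]
    ci[i] <- as.integer(expert[i] %in% a$G)
    if (ci[i] == 0L) {
      fh <- a$micro[as.character(expert[i])]
      fg <- a$micro[as.character(a$G)]
      dv <- c(dv, if (length(fh) == 0L || is.na(fh)) NA_real_
              else max(abs(fg - fh)))
    }
  }
  structure(list(c = ci, consistency_rate = mean(ci), n = n,
                 difference_values = dv),
            class = "consistency_report")
}

#' Difference value between two sites of one molecule
#'
#' The absolute gap |f(g) - f(h)| between the model's micro-pKa at two site
#' indices, quantifying how far apart the model rates them.
#'
#' @param state a `model_state`.
#' @param graph a `molecule_graph`.
#' @param g,h site indices (must be sites of the model's mode).
#' @return non-negative scalar.
#' @export
difference_value <- function(state, graph, g, h) {
  sites <- sites_for_mode(graph, state$config$mode)
  if (!(g %in% sites) || !(h %in% sites))
    stop("g and h must be ", state$config$mode, " site indices")
  raw <- predict_atom_pka(state, graph)
  abs(raw[g] - raw[h])
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report: %d/%d consistent (rate %.3f)>\n",
              sum(x$c), x$n, x$consistency_rate))
  invisible(x)
}
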