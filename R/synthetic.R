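# Synthetic benchmark generator. Real micro-pKa ground truth is essentially
# unmeasurable, so the generator builds molecule sets where it is known by
# construction: every ionizable site's true micro-pKa comes from a
# deterministic group-contribution model (base value per functional group
# plus additive shifts from nearby electron-withdrawing halogens), and the
# molecule's macro label is computed exactly by the pooling algebra before
# optional Gaussian noise is added. Training on those macro labels alone and
# then checking the recovered micro values against the construction is an
# end-to-end test of the multi-instance mechanism.

#' Group-contribution table for synthetic micro-pKa ground truth
#'
#' Base micro-pKa per functional group (rough literature-scale values:
#' carboxyl 4.2, phenol 10.0, thiol 8.3, aliphatic alcohol 15.5,
#' sulfonamide N-H 10.1; aliphatic amine 10.6, anilinic amine 4.6,
#' pyridinic N 5.2) plus perturbation weights for electron-withdrawing
#' halogen substituents: each F (weight 1.0) or Cl (weight 0.8) within graph
#' distance d <= 3 of a site shifts its micro-pKa by -weight/d, with the
#' total shift capped at 1.5 pKa units in magnitude. Values are
#' configuration, not chemistry: they only need to be deterministic and
#' structure-dependent.
#'
#' @param base optional named overrides of base values, e.g.
#'   `c(carboxyl = 4.0)`.
#' @return a `group_table` object.
#' @export
group_contribution_table <- function(base = NULL) {
  groups <- data.frame(
    group = c("carboxyl", "phenol", "thiol", "alcohol", "sulfonamide",
              "amine_nh", "other_acidic",
              "amine", "aniline", "pyridine", "sulfonamide_n", "other_basic"),
    mode = c(rep("acidic", 7L), rep("basic", 5L)),
    base = c(4.2, 10.0, 8.3, 15.5, 10.1, 33.0, 12.0,
             10.6, 4.6, 5.2, -1.0, 2.0),
    stringsAsFactors = FALSE
  )
  if (!is.null(base)) {
    i <- match(names(base), groups$group)
    if (anyNA(i)) stop("unknown group: ",
                       paste(names(base)[is.na(i)], collapse = ", "))
    groups$base[i] <- as.numeric(base)
  }
  structure(
    list(groups = groups,
         halogen_weight = c(F = 1.0, Cl = 0.8),
         max_distance = 3L, max_shift = 1.5),
    class = "group_table"
  )
}

graph_neighbors <- function(graph, i) {
  c(graph$bonds[graph$bonds[, 1] == i, 2],
    graph$bonds[graph$bonds[, 2] == i, 1])
}

# functional-group classification of a site by its local environment
classify_site <- function(graph, i, mode) {
  nb <- graph_neighbors(graph, i)
  dbl_oxygens <- function(j) {
    e <- which((graph$bonds[, 1] == j | graph$bonds[, 2] == j) &
                 graph$bond_type == "double")
    others <- ifelse(graph$bonds[e, 1] == j, graph$bonds[e, 2],
                     graph$bonds[e, 1])
    sum(graph$element[others] == "O")
  }
  if (mode == "acidic") {
    el <- graph$element[i]
    if (el == "O") {
      if (any(graph$element[nb] == "C" & graph$aromatic[nb])) return("phenol")
      cn <- nb[graph$element[nb] == "C"]
      if (length(cn) && any(vapply(cn, dbl_oxygens, 0L) >= 1L))
        return("carboxyl")
      return("alcohol")
    }
    if (el == "S") return("thiol")
    if (el == "N") {
      sn <- nb[graph$element[nb] == "S"]
      if (length(sn) && any(vapply(sn, dbl_oxygens, 0L) >= 2L))
        return("sulfonamide")
      return("amine_nh")
    }
    return("other_acidic")
  }
  # basic: i is a nitrogen
  if (graph$aromatic[i]) return("pyridine")
  if (any(graph$element[nb] == "C" & graph$aromatic[nb])) return("aniline")
  sn <- nb[graph$element[nb] == "S"]
  if (length(sn) && any(vapply(sn, dbl_oxygens, 0L) >= 2L))
    return("sulfonamide_n")
  "amine"
}

#' True micro-pKa of every site of a graph under the group model
#'
#' @param graph a `molecule_graph`.
#' @param mode `"acidic"` or `"basic"`.
#' @param table a [group_contribution_table()].
#' @return named numeric vector (names are site atom indices); attribute
#'   `group` carries the classification.
#' @export
true_micro_pka <- function(graph, mode, table = group_contribution_table()) {
  sites <- sites_for_mode(graph, mode)
  if (length(sites) == 0L)
    return(structure(numeric(0), group = character(0)))
  hal <- which(graph$element %in% names(table$halogen_weight))
  d <- NULL
  if (length(hal)) {
    ig <- igraph::graph_from_edgelist(graph$bonds, directed = FALSE)
    if (igraph::vcount(ig) < graph$n)
      ig <- igraph::add_vertices(ig, graph$n - igraph::vcount(ig))
    d <- igraph::distances(ig, v = sites, to = hal)
  }
  grp <- vapply(sites, classify_site, "", graph = graph, mode = mode)
  base <- table$groups$base[match(grp, table$groups$group)]
  shift <- numeric(length(sites))
  if (length(hal)) {
    w <- table$halogen_weight[graph$element[hal]]
    for (k in seq_along(sites)) {
      dd <- d[k, ]
      near <- which(dd >= 1 & dd <= table$max_distance)
      if (length(near))
        shift[k] <- -min(table$max_shift, sum(w[near] / dd[near]))
    }
  }
  structure(setNames(base + shift, sites), group = grp)
}

# fragment library: substituents attachable to an aliphatic backbone carbon.
# Aromatic fragments carry their own optional ring halogens so that ring
# sites also see perturbed environments.
synthetic_fragments <- function(mode) {
  if (mode == "acidic") {
    list(
      carboxyl = "C(=O)O",
      phenol = c("c1ccc(O)cc1", "c1ccc(O)c(Cl)c1", "c1ccc(O)c(F)c1"),
      thiol = "S",
      alcohol = "O",
      sulfonamide = "S(N)(=O)=O"
    )
  } else {
    list(
      amine = "N",
      aniline = c("c1ccc(N)cc1", "c1ccc(N)c(Cl)c1"),
      pyridine = c("c1ccncc1", "c1cc(Cl)ncc1", "c1cc(F)ncc1")
    )
  }
}

assemble_smiles <- function(len, subs_at) {
  parts <- vapply(seq_len(len), function(i) {
    s <- subs_at[[i]]
    if (is.null(s)) "C" else paste0("C(", s, ")")
  }, "")
  paste(parts, collapse = "")
}

#' Generate a synthetic molecule set with known micro-pKa ground truth
#'
#' Molecules are assembled from short alkyl backbones (2-8 carbons)
#' carrying 1-6 ionizable groups drawn from the mode's fragment library
#' plus 0-2 halogen substituents; aromatic fragments (phenol, aniline,
#' pyridine) bring their own rings. True micro-pKa values are evaluated by
#' [true_micro_pka()] on the standardized graph — so any site the assembly
#' creates is covered, by construction. The macro label is the exact pooled
#' value of the true micro values plus `rnorm(1, 0, noise_sigma)`.
#'
#' @param n_molecules number of records.
#' @param mode `"acidic"` or `"basic"`.
#' @param noise_sigma Gaussian label noise standard deviation (pKa units).
#' @param seed integer seed; regeneration is bit-identical.
#' @param table a [group_contribution_table()].
#' @return a `synthetic_set`: list with `records` (standardized records
#'   data.frame), `truth` (per-record named micro-pKa vector),
#'   `truth_group` (per-record site classifications), `mode`,
#'   `noise_sigma`, `seed`, `table`.
#' @export
generate_set <- function(n_molecules, mode = c("acidic", "basic"),
                         noise_sigma = 0.2, seed = 1L,
                         table = group_contribution_table()) {
  mode <- match.arg(mode)
  stopifnot(n_molecules >= 1L, noise_sigma >= 0)
  frags <- synthetic_fragments(mode)
  if (!any(table$groups$mode == mode))
    stop("group table has no ", mode, " groups")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  records <- new_records(sprintf("syn%05d", seq_len(n_molecules)),
                         rep(NA_character_, n_molecules))
  truth <- vector("list", n_molecules)
  truth_group <- vector("list", n_molecules)
  for (i in seq_len(n_molecules)) {
    n_groups <- sample(1:6, 1L, prob = c(.35, .25, .15, .10, .08, .07))
    n_hal <- sample(0:2, 1L, prob = c(.5, .3, .2))
    picks <- sample(names(frags), n_groups, replace = TRUE)
    subs <- vapply(picks, function(p) sample(frags[[p]], 1L), "")
    subs <- c(subs, sample(c("F", "Cl"), n_hal, replace = TRUE))
    len <- min(8L, max(2L, length(subs) + sample(0:2, 1L)))
    if (length(subs) > len) len <- length(subs)
    pos <- sample(len, length(subs))
    subs_at <- vector("list", len)
    subs_at[pos] <- as.list(subs)
    smi <- assemble_smiles(len, subs_at)

    std <- standardize_structure(smi)
    g <- build_graph(as.character(std))
    tv <- true_micro_pka(g, mode, table)
    if (length(tv) == 0L) stop("internal: assembled molecule has no site")
    macro <- pool_sites(tv, mode)
    label <- macro + if (noise_sigma > 0) rnorm(1L, 0, noise_sigma) else 0
    records$raw_structure[i] <- smi
    records$standardized_smiles[i] <- as.character(std)
    records$flagged[i] <- attr(std, "flagged")
    if (mode == "acidic") records$acidic_label[i] <- label
    else records$basic_label[i] <- label
    truth[[i]] <- setNames(as.numeric(tv), names(tv))
    truth_group[[i]] <- attr(tv, "group")
  }
  structure(
    list(records = records, truth = truth, truth_group = truth_group,
         mode = mode, noise_sigma = noise_sigma, seed = as.integer(seed),
         table = table),
    class = "synthetic_set"
  )
}

#' @export
print.synthetic_set <- function(x, ...) {
  cat(sprintf("<synthetic_set %s: %d molecules, noise sigma %.2g, seed %d>\n",
              x$mode, nrow(x$records), x$noise_sigma, x$seed))
  invisible(x)
}

#' Ground-truth dominant sites of a synthetic record
#'
#' The argmin (acidic) / argmax (basic) of the true micro values, with the
#' same epsilon tie logic as [dominant_sites()] — the synthetic stand-in for
#' an expert's site assignment.
#'
#' @param set a `synthetic_set`.
#' @param i record index.
#' @param epsilon tie tolerance (pKa units).
#' @return a `dominant_sites` object over the true values.
#' @export
true_dominant_site <- function(set, i, epsilon = 0.1) {
  stopifnot(inherits(set, "synthetic_set"))
  dominant_from_values(set$truth[[i]], set$mode, epsilon)
}

#' Export / import a synthetic set as plain-text fixtures
#'
#' Writes `records.csv` (id, smiles, labels), `truth.csv` (one row per
#' site), and `records.sdf` with labels as named SDF properties. The CSV
#' pair round-trips losslessly through [import_fixture()].
#'
#' @param set a `synthetic_set`.
#' @param dir output directory (created if needed).
#' @export
export_fixture <- function(set, dir) {
  stopifnot(inherits(set, "synthetic_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- set$records
  utils::write.csv(
    data.frame(id = rec$record_id, smiles = rec$standardized_smiles,
               pka_acidic = rec$acidic_label, pka_basic = rec$basic_label),
    file.path(dir, "records.csv"), row.names = FALSE, na = "")
  tr <- do.call(rbind, lapply(seq_along(set$truth), function(i)
    data.frame(record_id = rec$record_id[i],
               atom_index = as.integer(names(set$truth[[i]])),
               group = set$truth_group[[i]],
               micro_pka = as.numeric(set$truth[[i]]))))
  utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)

  label_tag <- if (set$mode == "acidic") "PKA_ACIDIC" else "PKA_BASIC"
  labels <- if (set$mode == "acidic") rec$acidic_label else rec$basic_label
  sdf <- vapply(seq_len(nrow(rec)), function(i) {
    block <- ob_convert(rec$standardized_smiles[i], "SMI", "SDF")
    block <- sub("\\$\\$\\$\\$\n?$", "", block)
    paste0(block, sprintf(">  <%s>\n%.10g\n\n$$$$\n", label_tag, labels[i]))
  }, "")
  writeLines(paste(sdf, collapse = ""), file.path(dir, "records.sdf"),
             sep = "")
  invisible(dir)
}

#' @rdname export_fixture
#' @param mode the mode the set was generated for.
#' @return `import_fixture()` returns a list with `records` and `truth` in
#'   the same layout as a `synthetic_set`.
#' @export
import_fixture <- function(dir, mode = c("acidic", "basic")) {
  mode <- match.arg(mode)
  rec <- read_molecule_csv(file.path(dir, "records.csv"))
  rec$standardized_smiles <- rec$raw_structure
  rec$flagged <- FALSE
  tr <- utils::read.csv(file.path(dir, "truth.csv"),
                        stringsAsFactors = FALSE)
  truth <- lapply(rec$record_id, function(id) {
    rows <- tr[tr$record_id == id, , drop = FALSE]
    setNames(rows$micro_pka, rows$atom_index)
  })
  list(records = rec, truth = truth, mode = mode)
}
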