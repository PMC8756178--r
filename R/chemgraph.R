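#' @importFrom ChemmineOB convertFormat
#' @importFrom ChemmineR read.SDFset atomblock bondblock rings datablock sdfid validSDF
#' @importFrom utils read.csv write.csv head
#' @importFrom stats quantile rnorm runif setNames cor sd
NULL

# --- OpenBabel helpers -------------------------------------------------------

ob_options <- function(...) {
  nm <- c(character(0), ...)
  data.frame(names = nm, args = rep("", length(nm)), stringsAsFactors = FALSE)
}

# Convert through OpenBabel; returns "" on parse failure (OB prints its own
# diagnostics to stderr). The first token before any tab/newline is the
# structure; obabel appends a title field.
ob_convert <- function(input, from, to, opts = ob_options()) {
  out <- tryCatch(
    ChemmineOB::convertFormat(from, to, input, options = opts),
    error = function(e) ""
  )
  out
}

ob_first_token <- function(x) {
  x <- strsplit(trimws(x), "[\t\n]")[[1]]
  if (length(x) == 0L) "" else x[1]
}

canonical_smiles <- function(smiles, neutralize = FALSE) {
  opts <- if (neutralize) ob_options("neutralize") else ob_options()
  ob_first_token(ob_convert(smiles, "SMI", "CAN", opts))
}

# Minimal molfile field extraction for what ChemmineR does not expose by atom
# index: the counts line, element symbols, bonds and "M  CHG" formal charges.
molfile_tables <- function(mol) {
  lines <- strsplit(mol, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) stop("empty or truncated molfile")
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  if (is.na(natoms) || natoms < 1L) stop("molecule has no atoms")
  atom_lines <- lines[5:(4 + natoms)]
  element <- trimws(substr(atom_lines, 32, 34))
  bonds <- if (nbonds > 0L) {
    bl <- lines[(5 + natoms):(4 + natoms + nbonds)]
    cbind(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else {
    cbind(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  charge <- rep(0L, natoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    k <- toks[1]
    for (j in seq_len(k)) {
      charge[toks[2 * j]] <- toks[2 * j + 1]
    }
  }
  list(element = element, bonds = bonds, charge = charge, natoms = natoms)
}

# --- Standardization ---------------------------------------------------------

#' Standardize a molecular structure
#'
#' Applies the curation convention used throughout the package: parse the
#' input (SMILES or a molfile/SDF block), drop all but the largest covalently
#' connected fragment (salt stripping), neutralize charges by adding or
#' removing protons wherever standard valence allows, and emit canonical
#' SMILES. Charges that cannot be neutralized (e.g. a quaternary nitrogen)
#' are kept and the result is flagged; the basic-site rule (formal charge
#' <= 0) then excludes such atoms downstream. The function is idempotent and
#' insensitive to the listing order of salt fragments.
#'
#' @param raw a single SMILES string, or a molfile/SDF block (detected by the
#'   presence of the `V2000` counts line).
#' @return canonical SMILES (character scalar) with attribute `flagged`
#'   (`TRUE` when a non-neutralizable formal charge remains).
#' @examples
#' standardize_structure("CC(=O)[O-].[Na+]")  # -> neutral acetic acid
#' @export
standardize_structure <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(trimws(raw))) stop("empty structure input")
  from <- if (grepl("V2000", raw, fixed = TRUE)) "SDF" else "SMI"
  smi <- ob_first_token(ob_convert(raw, from, "CAN"))
  if (!nzchar(smi)) stop("unparseable structure: ", substr(raw, 1, 80))

  # salt stripping: canonical SMILES writes disconnected fragments dot-joined
  frags <- strsplit(smi, ".", fixed = TRUE)[[1]]
  if (length(frags) > 1L) {
    sizes <- vapply(frags, function(f) {
      mt <- molfile_tables(ob_convert(f, "SMI", "SDF"))
      sum(mt$element != "H")
    }, integer(1))
    smi <- frags[which.max(sizes)]
  }
  if (!nzchar(smi)) stop("empty structure after salt stripping")

  out <- canonical_smiles(smi, neutralize = TRUE)
  if (!nzchar(out)) stop("standardization failed for: ", substr(raw, 1, 80))
  flagged <- any(molfile_tables(ob_convert(out, "SMI", "SDF"))$charge != 0L)
  structure(out, flagged = flagged)
}

# --- Featurization schema ----------------------------------------------------

#' Default atom/bond featurization schema
#'
#' Eight atom descriptors and four bond descriptors, one-hot encoded where
#' categorical. Atom: element (C,N,O,S,F,Cl,Br,I,P,other), heavy-atom degree
#' (0-5), formal charge (-1,0,+1,other), hybridization (sp,sp2,sp3,other),
#' aromaticity flag, total attached hydrogens (0-4, clipped), ring-membership
#' flag, chirality flag. Bond: bond type (single,double,triple,aromatic),
#' conjugation flag, ring flag, stereo flag. Serializing the schema with a
#' model checkpoint guarantees identical encodings at load time.
#'
#' @return a `feature_config` object (list with `atom_schema`, `bond_schema`,
#'   `atom_dim`, `bond_dim`).
#' @export
default_feature_config <- function() {
  atom_schema <- list(
    element = c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "other"),
    degree = as.character(0:5),
    formal_charge = c("-1", "0", "1", "other"),
    hybridization = c("sp", "sp2", "sp3", "other"),
    aromatic = "flag",
    h_count = as.character(0:4),
    in_ring = "flag",
    chirality = "flag"
  )
  bond_schema <- list(
    bond_type = c("single", "double", "triple", "aromatic"),
    conjugated = "flag",
    in_ring = "flag",
    stereo = "flag"
  )
  dim_of <- function(s) sum(vapply(s, function(v)
    if (identical(v, "flag")) 1L else length(v), integer(1)))
  structure(
    list(atom_schema = atom_schema, bond_schema = bond_schema,
         atom_dim = dim_of(atom_schema), bond_dim = dim_of(bond_schema)),
    class = "feature_config"
  )
}

one_hot <- function(value, levels) {
  v <- numeric(length(levels))
  i <- match(value, levels)
  if (is.na(i)) i <- length(levels) # 'other' is always last
  v[i] <- 1
  v
}

encode_atom <- function(g, i, schema) {
  c(
    one_hot(g$element[i], schema$element),
    one_hot(as.character(min(g$degree[i], 5L)), schema$degree),
    one_hot(as.character(g$formal_charge[i]), schema$formal_charge),
    one_hot(g$hybridization[i], schema$hybridization),
    as.numeric(g$aromatic[i]),
    one_hot(as.character(min(g$h_count[i], 4L)), schema$h_count),
    as.numeric(g$in_ring[i]),
    as.numeric(g$chirality[i])
  )
}

encode_bond <- function(g, e, schema) {
  c(
    one_hot(g$bond_type[e], schema$bond_type),
    as.numeric(g$bond_conjugated[e]),
    as.numeric(g$bond_in_ring[e]),
    as.numeric(g$bond_stereo[e])
  )
}

# --- Graph construction ------------------------------------------------------

#' Build a featurized molecular graph from canonical SMILES
#'
#' One node per heavy atom with hydrogens folded into per-atom counts
#' (implicit and explicit hydrogens agree, so `"O"` and `"[OH2]"` give the
#' same graph). Bonds are undirected and stored once. Atom order follows the
#' canonical atom ranking of the OpenBabel parser, so indices are stable for
#' a given standardized SMILES. Aromaticity and ring membership come from
#' ring perception; hybridization is assigned from bond orders (any triple
#' bond or two double bonds: sp; any double/aromatic bond: sp2; else sp3).
#'
#' @param smiles canonical SMILES, typically from [standardize_structure()].
#' @param config a `feature_config`; defaults to [default_feature_config()].
#' @return a `molecule_graph` object: list with `n`, `element`,
#'   `formal_charge`, `h_count`, `degree`, `aromatic`, `in_ring`,
#'   `hybridization`, `chirality`, `bonds` (E x 2 matrix, 1-based),
#'   `bond_type`, `bond_conjugated`, `bond_in_ring`, `bond_stereo`,
#'   `atom_features` (N x atom_dim), `bond_features` (E x bond_dim),
#'   `smiles`.
#' @export
build_graph <- function(smiles, config = default_feature_config()) {
  stopifnot(is.character(smiles), length(smiles) == 1L,
            inherits(config, "feature_config"))
  mol <- ob_convert(smiles, "SMI", "SDF", ob_options("h"))
  if (!nzchar(mol)) stop("unparseable SMILES: ", smiles)
  mt <- molfile_tables(mol)

  heavy <- which(mt$element != "H")
  if (length(heavy) == 0L) stop("molecule has no heavy atoms: ", smiles)
  n <- length(heavy)
  idx_map <- integer(mt$natoms) # molfile index -> heavy index (0 for H)
  idx_map[heavy] <- seq_len(n)

  is_h1 <- mt$element[mt$bonds[, "a1"]] == "H"
  is_h2 <- mt$element[mt$bonds[, "a2"]] == "H"
  h_count <- integer(n)
  hb <- mt$bonds[is_h1 | is_h2, , drop = FALSE]
  if (nrow(hb)) {
    partner <- ifelse(mt$element[hb[, "a1"]] == "H", hb[, "a2"], hb[, "a1"])
    partner <- partner[mt$element[partner] != "H"] # ignore H-H (if ever)
    tab <- table(idx_map[partner])
    h_count[as.integer(names(tab))] <- as.integer(tab)
  }

  bb <- mt$bonds[!(is_h1 | is_h2), , drop = FALSE]
  bonds <- cbind(idx_map[bb[, "a1"]], idx_map[bb[, "a2"]])
  order_raw <- bb[, "order"]

  # ring perception via ChemmineR on the same molfile
  in_ring <- rep(FALSE, n)
  aromatic <- rep(FALSE, n)
  bond_in_ring <- rep(FALSE, nrow(bonds))
  bond_aromatic <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0L) {
    sdf <- ChemmineR::read.SDFset(strsplit(mol, "\n")[[1]])
    rg <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf[[1]], upper = 12, type = "all",
                                        arom = TRUE)),
      error = function(e) list(RINGS = list(), AROMATIC = logical(0))
    )
    ring_atom_sets <- lapply(rg$RINGS, function(r)
      idx_map[as.integer(sub("^.*_", "", r))])
    for (k in seq_along(ring_atom_sets)) {
      ra <- ring_atom_sets[[k]]
      in_ring[ra] <- TRUE
      on_ring <- bonds[, 1] %in% ra & bonds[, 2] %in% ra
      bond_in_ring <- bond_in_ring | on_ring
      if (isTRUE(rg$AROMATIC[[k]])) {
        aromatic[ra] <- TRUE
        bond_aromatic <- bond_aromatic | on_ring
      }
    }
  }

  bond_type <- ifelse(bond_aromatic, "aromatic",
                      c("single", "double", "triple")[pmin(order_raw, 3L)])

  degree <- integer(n)
  if (nrow(bonds)) {
    tab <- table(factor(c(bonds[, 1], bonds[, 2]), levels = seq_len(n)))
    degree <- as.integer(tab)
  }

  # hybridization from incident bond orders
  hybridization <- vapply(seq_len(n), function(i) {
    inc <- which(bonds[, 1] == i | bonds[, 2] == i)
    ords <- order_raw[inc]
    arom <- any(bond_aromatic[inc])
    if (any(ords >= 3L) || sum(ords == 2L) >= 2L) "sp"
    else if (arom || any(ords == 2L)) "sp2"
    else "sp3"
  }, character(1))

  # conjugation: multiple/aromatic bonds, and single bonds bridging two
  # atoms that each carry another multiple/aromatic bond
  multi <- bond_aromatic | order_raw >= 2L
  atom_has_multi <- rep(FALSE, n)
  atom_has_multi[unique(c(bonds[multi, 1], bonds[multi, 2]))] <- TRUE
  bond_conjugated <- multi |
    (order_raw == 1L & atom_has_multi[bonds[, 1]] & atom_has_multi[bonds[, 2]])

  g <- list(
    n = n,
    element = mt$element[heavy],
    formal_charge = mt$charge[heavy],
    h_count = h_count,
    degree = degree,
    aromatic = aromatic,
    in_ring = in_ring,
    hybridization = hybridization,
    chirality = rep(FALSE, n),
    bonds = bonds,
    bond_type = bond_type,
    bond_conjugated = as.logical(bond_conjugated),
    bond_in_ring = bond_in_ring,
    bond_stereo = rep(FALSE, nrow(bonds)),
    smiles = smiles
  )
  g$atom_features <- do.call(rbind, lapply(seq_len(n), function(i)
    encode_atom(g, i, config$atom_schema)))
  g$bond_features <- if (nrow(bonds)) {
    do.call(rbind, lapply(seq_len(nrow(bonds)), function(e)
      encode_bond(g, e, config$bond_schema)))
  } else {
    matrix(0, 0, config$bond_dim)
  }
  class(g) <- "molecule_graph"
  g
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("<molecule_graph %s: %d atoms, %d bonds>\n",
              x$smiles, x$n, nrow(x$bonds)))
  invisible(x)
}

# --- Ionizable-site enumeration ----------------------------------------------

#' Enumerate ionizable sites of a molecular graph
#'
#' Acidic sites are non-carbon heavy atoms bearing at least one hydrogen
#' (able to donate a proton); basic sites are nitrogen atoms with no positive
#' formal charge (able to accept one). The two sets may overlap: a neutral
#' N-H is both. C-H acidity is deliberately unsupported.
#'
#' @param graph a `molecule_graph` from [build_graph()].
#' @return integer vector of 1-based atom indices (possibly empty).
#' @export
enumerate_acidic_sites <- function(graph) {
  stopifnot(inherits(graph, "molecule_graph"))
  which(graph$element != "C" & graph$h_count >= 1L)
}

#' @rdname enumerate_acidic_sites
#' @export
enumerate_basic_sites <- function(graph) {
  stopifnot(inherits(graph, "molecule_graph"))
  which(graph$element == "N" & graph$formal_charge <= 0L)
}

#' Site sets of a molecule for both modes
#'
#' @param graph a `molecule_graph`.
#' @return a `site_annotation` object: list with `acidic_sites` (P) and
#'   `basic_sites` (Q), 1-based atom indices.
#' @export
annotate_sites <- function(graph) {
  structure(
    list(acidic_sites = enumerate_acidic_sites(graph),
         basic_sites = enumerate_basic_sites(graph)),
    class = "site_annotation"
  )
}

sites_for_mode <- function(graph, mode) {
  if (mode == "acidic") enumerate_acidic_sites(graph)
  else enumerate_basic_sites(graph)
}

# --- Record readers ----------------------------------------------------------

new_records <- function(record_id, raw, acidic_label = NA_real_,
                        basic_label = NA_real_) {
  data.frame(
    record_id = as.character(record_id),
    raw_structure = as.character(raw),
    standardized_smiles = NA_character_,
    flagged = NA,
    acidic_label = as.numeric(acidic_label),
    basic_label = as.numeric(basic_label),
    stringsAsFactors = FALSE
  )
}

#' Read molecule records from standard inputs
#'
#' `read_smiles_file()` reads one SMILES per line (an optional second
#' whitespace-separated token is taken as the record id). `read_molecule_csv()`
#' expects columns `id, smiles, pka_acidic, pka_basic` (empty cells are
#' missing labels). `read_sdf_records()` reads an SDF and takes labels from
#' the named properties `PKA_ACIDIC` / `PKA_BASIC`.
#'
#' @param path file path.
#' @return a records data.frame with columns `record_id`, `raw_structure`,
#'   `standardized_smiles` (NA until [standardize_records()] is applied),
#'   `flagged`, `acidic_label`, `basic_label`.
#' @export
read_smiles_file <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\\s+")
  smi <- vapply(toks, `[`, "", 1)
  ids <- vapply(seq_along(toks), function(i)
    if (length(toks[[i]]) > 1L) toks[[i]][2] else sprintf("mol%04d", i), "")
  new_records(ids, smi)
}

#' @rdname read_smiles_file
#' @export
read_molecule_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "smiles")
  if (!all(need %in% names(df)))
    stop("CSV must have columns 'id' and 'smiles'")
  num_or_na <- function(x) if (is.null(x)) NA_real_ else
    suppressWarnings(as.numeric(x))
  new_records(df$id, df$smiles,
              acidic_label = num_or_na(df$pka_acidic),
              basic_label = num_or_na(df$pka_basic))
}

#' @rdname read_smiles_file
#' @export
read_sdf_records <- function(path) {
  sdf <- ChemmineR::read.SDFset(path)
  smi <- vapply(seq_along(sdf), function(i) {
    block <- paste(ChemmineR::sdf2str(sdf[[i]]), collapse = "\n")
    ob_first_token(ob_convert(block, "SDF", "CAN"))
  }, "")
  get_prop <- function(i, key) {
    db <- ChemmineR::datablock(sdf[[i]])
    if (key %in% names(db)) suppressWarnings(as.numeric(db[[key]])) else NA_real_
  }
  ids <- ChemmineR::sdfid(sdf)
  new_records(ids, smi,
              acidic_label = vapply(seq_along(sdf), get_prop, 0, key = "PKA_ACIDIC"),
              basic_label = vapply(seq_along(sdf), get_prop, 0, key = "PKA_BASIC"))
}

#' Standardize all records in a table
#'
#' Applies [standardize_structure()] to every record; unparseable records
#' raise an error naming the offending id.
#'
#' @param records a records data.frame (see [read_smiles_file()]).
#' @return the same data.frame with `standardized_smiles` and `flagged` filled.
#' @export
standardize_records <- function(records) {
  for (i in seq_len(nrow(records))) {
    s <- tryCatch(standardize_structure(records$raw_structure[i]),
                  error = function(e)
                    stop("record ", records$record_id[i], ": ",
                         conditionMessage(e), call. = FALSE))
    records$standardized_smiles[i] <- as.character(s)
    records$flagged[i] <- attr(s, "flagged")
  }
  records
}

#' Tabulate ionizable sites for a set of records
#'
#' @param records standardized records data.frame.
#' @param mode `"acidic"`, `"basic"` or `"both"`.
#' @param config feature configuration used to build graphs.
#' @return data.frame with columns `record_id`, `mode`, `atom_index`,
#'   `element`, `rule` (the textual rule matched).
#' @export
site_table <- function(records, mode = c("both", "acidic", "basic"),
                       config = default_feature_config()) {
  mode <- match.arg(mode)
  modes <- if (mode == "both") c("acidic", "basic") else mode
  out <- list()
  for (i in seq_len(nrow(records))) {
    g <- build_graph(records$standardized_smiles[i], config)
    for (m in modes) {
      idx <- sites_for_mode(g, m)
      if (length(idx)) {
        rule <- if (m == "acidic") "non-carbon with >=1 H"
                else "nitrogen with formal charge <= 0"
        out[[length(out) + 1L]] <- data.frame(
          record_id = records$record_id[i], mode = m, atom_index = idx,
          element = g$element[idx], rule = rule, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(record_id = character(0), mode = character(0),
               atom_index = integer(0), element = character(0),
               rule = character(0), stringsAsFactors = FALSE)
}
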