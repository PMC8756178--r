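# Named molecule fixture set with frozen expectations. Site expectations
# (heavy-atom count; multiset of site elements for each rule) were computed
# with an independent cheminformatics toolkit applying the textual rules
# atom by atom, and are frozen here.
fixture_molecules <- function() {
  tab <- rbind(
    c("acetic acid", "CC(=O)O", 4, "O", ""),
    c("phenol", "Oc1ccccc1", 7, "O", ""),
    c("pyridine", "c1ccncc1", 6, "", "N"),
    c("propane-1,2,3-triamine", "NCC(N)CN", 6, "N;N;N", "N;N;N"),
    c("methanesulfonamide", "CS(N)(=O)=O", 5, "N", "N"),
    c("tetramethylammonium", "C[N+](C)(C)C", 5, "", ""),
    c("ethane", "CC", 2, "", ""),
    c("ethanol", "CCO", 3, "O", ""),
    c("methylamine", "CN", 2, "N", "N"),
    c("aniline", "Nc1ccccc1", 7, "N", "N"),
    c("glycine", "NCC(=O)O", 5, "N;O", "N"),
    c("benzoic acid", "OC(=O)c1ccccc1", 9, "O", ""),
    c("p-cresol", "Cc1ccc(O)cc1", 8, "O", ""),
    c("imidazole", "c1cnc[nH]1", 5, "N", "N;N"),
    c("piperazine", "C1CNCCN1", 6, "N;N", "N;N"),
    c("thiophenol", "Sc1ccccc1", 7, "S", ""),
    c("acetamide", "CC(N)=O", 4, "N", "N"),
    c("dimethylamine", "CNC", 3, "N", "N"),
    c("trimethylamine", "CN(C)C", 4, "", "N"),
    c("4-chlorophenol", "Oc1ccc(Cl)cc1", 8, "O", ""),
    c("salicylic acid", "OC(=O)c1ccccc1O", 10, "O;O", ""),
    c("benzene", "c1ccccc1", 6, "", ""),
    c("methanol", "CO", 2, "O", ""),
    c("ethylenediamine", "NCCN", 4, "N;N", "N;N")
  )
  data.frame(
    name = tab[, 1], smiles = tab[, 2], n_heavy = as.integer(tab[, 3]),
    acidic_elements = tab[, 4], basic_elements = tab[, 5],
    stringsAsFactors = FALSE
  )
}

split_elements <- function(x) {
  if (!nzchar(x)) character(0) else sort(strsplit(x, ";", fixed = TRUE)[[1]])
}

# A tiny trained-free model for structural tests
tiny_config <- function(mode = "acidic", hidden = 16, seed = 1,
                        dropout = 0.2) {
  model_config(mode = mode, hidden_dim = hidden, seed = seed,
               dropout_rate = dropout, head_hidden_dims = 8)
}
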