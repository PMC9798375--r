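# Fixture builders shared across the suite. Everything is generated in code;
# no binary or stored data.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A random, already-normalized link_dataset. Decoy accessions use "decoy_".
random_dataset <- function(n = 100, n_proteins = 12, n_replicates = 3,
                           p_mono = 0.35, p_intra = 0.25, p_decoy = 0.2) {
  prots <- sprintf("P%02d", seq_len(n_proteins))
  type <- sample(c("MONO", "INTRA", "INTER"), n, replace = TRUE,
    prob = c(p_mono, p_intra, 1 - p_mono - p_intra))
  pa <- sample(prots, n, replace = TRUE)
  pb <- ifelse(type == "MONO", NA_character_, sample(prots, n, replace = TRUE))
  pb[type == "INTER" & pb == pa] <- NA  # re-draw clashes below
  clash <- type == "INTER" & is.na(pb)
  while (any(clash)) {
    pb[clash] <- sample(prots, sum(clash), replace = TRUE)
    clash <- type == "INTER" & !is.na(pb) & pb == pa
    pb[clash] <- NA
    clash <- type == "INTER" & is.na(pb)
  }
  pb[type == "INTRA"] <- pa[type == "INTRA"]
  dec_a <- runif(n) < p_decoy / 2
  dec_b <- !is.na(pb) & runif(n) < p_decoy / 2
  pa[dec_a] <- paste0("decoy_", pa[dec_a])
  pb[dec_b] <- paste0("decoy_", pb[dec_b])
  raw <- c(MONO = "monolink", INTRA = "intralink", INTER = "xlink")[type]
  ds <- link_dataset(data.frame(
    record_id = sprintf("r%04d", seq_len(n)),
    raw_type = unname(raw),
    protein_a = pa, protein_b = pb,
    pos_a = sample(1:400, n, replace = TRUE),
    pos_b = ifelse(type == "MONO", NA, sample(1:400, n, replace = TRUE)),
    ld_score = round(runif(n, 10, 45), 2),
    replicate_id = sample(sprintf("rep%d", seq_len(n_replicates)), n,
      replace = TRUE),
    stringsAsFactors = FALSE
  ), source_files = sprintf("rep%d", seq_len(n_replicates)))
  normalize_types(annotate_decoys(ds))
}

# Write an xQuest-dialect TSV from row vectors; returns the path.
write_xq_fixture <- function(path, id, type, p1, p2, pos1, pos2, score,
                             extra_cols = NULL) {
  df <- data.frame(Id = id, Type = type, Protein1 = p1, Protein2 = p2,
    AbsPos1 = pos1, AbsPos2 = pos2, `ld-Score` = score,
    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(extra_cols)) df <- cbind(df, extra_cols)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8")
  path
}

# Canonical 3-row fixture: one record of each raw type.
three_row_fixture <- function(path = tempfile(fileext = ".tsv")) {
  write_xq_fixture(path,
    id = c("id1", "id2", "id3"),
    type = c("monolink", "intralink", "xlink"),
    p1 = c("P1", "P2", "P1"), p2 = c("", "P2", "P3"),
    pos1 = c(10, 20, 30), pos2 = c("", 40, 50),
    score = c(31.5, 28.2, 22.9))
}

# Toy structure writers: identical model in PDB and mmCIF encodings.
# `atoms` is a data.frame(chain, resno, x, y, z); all residues are LYS CA.
write_toy_pdb <- function(atoms, path = tempfile(fileext = ".pdb")) {
  lines <- sprintf(
    "ATOM  %5d  CA  LYS %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(atoms)), atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z)
  writeLines(c(lines, "END"), path)
  path
}

write_toy_cif <- function(atoms, path = tempfile(fileext = ".cif")) {
  fields <- c("group_PDB", "id", "type_symbol", "label_atom_id",
    "label_alt_id", "label_comp_id", "label_asym_id", "label_entity_id",
    "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
    "occupancy", "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
    "auth_comp_id", "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")
  rows <- sprintf("ATOM %d C CA . LYS %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d LYS %s CA 1",
    seq_len(nrow(atoms)), atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z, atoms$resno, atoms$chain)
  writeLines(c("data_toy", "loop_", paste0("_atom_site.", fields), rows, "#"),
    path)
  path
}

# Brute-force oracles, deliberately written as plain loops over rows so they
# share no code with the implementation they check.
oracle_eligible <- function(ds) {
  out <- character()
  for (i in seq_len(nrow(ds))) {
    if (ds$link_type[i] == "MONO") out <- c(out, ds$protein_a[i])
    if (ds$link_type[i] == "INTRA") out <- c(out, ds$protein_a[i], ds$protein_b[i])
  }
  sort(unique(out[!is.na(out)]))
}

oracle_mi_retained <- function(ds) {
  elig <- oracle_eligible(ds)
  keep <- logical(nrow(ds))
  for (i in seq_len(nrow(ds))) {
    keep[i] <- if (ds$link_type[i] != "INTER") TRUE
    else (ds$protein_a[i] %in% elig) && (ds$protein_b[i] %in% elig)
  }
  ds$record_id[keep]
}

oracle_replicate_sites <- function(ds, min_replicates) {
  tab <- list()
  for (i in seq_len(nrow(ds))) {
    k <- ds$unique_key[i]
    tab[[k]] <- union(tab[[k]], ds$replicate_id[i])
  }
  names(tab)[vapply(tab, length, integer(1)) >= min_replicates]
}
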