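#' Load a structure's Cα coordinates for cross-link validation
#'
#' Reads a PDB or mmCIF file (via bio3d), extracts the alpha-carbon
#' coordinate table, and attaches the accession-to-chain mapping needed to
#' place cross-linked residues. A protein may map to several chain copies
#' (e.g. the pseudo-symmetric duplicate subunits of large complexes);
#' distances are later minimized over all copy combinations. Residue numbers
#' follow the structure's author numbering; per-chain integer offsets in
#' `offsets` translate sequence numbering to structure numbering
#' (structure residue = sequence position + offset).
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`, `.mmcif`) file.
#' @param chain_map named list, protein accession -> character vector of
#'   chain ids present in the structure.
#' @param offsets optional named numeric vector, chain id -> numbering
#'   offset (default 0 for unlisted chains).
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return a `structure_model`: list with `coords` (data frame `chain`,
#'   `resno`, `x`, `y`, `z`, Å), `chain_map`, `offsets`.
#' @export
load_structure <- function(path, chain_map, offsets = NULL,
                           format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- if (format == "cif") {
    suppressWarnings(bio3d::read.cif(path))  # beta-status warning is noise
  } else {
    bio3d::read.pdb(path)
  }
  atoms <- pdb$atom
  ca <- atoms[atoms$elety == "CA" & atoms$type == "ATOM", , drop = FALSE]
  coords <- data.frame(
    chain = as.character(ca$chain), resno = as.integer(ca$resno),
    x = as.numeric(ca$x), y = as.numeric(ca$y), z = as.numeric(ca$z),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(coords[c("x", "y", "z")])))) {
    stop("load_structure: non-finite C-alpha coordinates in ", path,
      call. = FALSE)
  }
  chain_map <- lapply(chain_map, as.character)
  missing <- setdiff(unique(unlist(chain_map)), unique(coords$chain))
  if (length(missing)) {
    stop("load_structure: chain(s) named in chain_map absent from structure: ",
      paste(missing, collapse = ", "), call. = FALSE)
  }
  coords <- coords[coords$chain %in% unlist(chain_map), , drop = FALSE]
  rownames(coords) <- NULL
  off <- stats::setNames(numeric(length(unique(coords$chain))),
    unique(coords$chain))
  if (!is.null(offsets)) off[names(offsets)] <- offsets
  structure(list(coords = coords, chain_map = chain_map, offsets = off),
    class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d C-alpha atoms, %d chain(s), %d mapped protein(s)\n",
    nrow(x$coords), length(unique(x$coords$chain)), length(x$chain_map)))
  invisible(x)
}

# Cα coordinates of residue `pos` of protein `acc`, one row per chain copy.
.residue_coords <- function(model, acc, pos) {
  chains <- model$chain_map[[acc]]
  if (is.null(chains)) return(NULL)
  hits <- lapply(chains, function(ch) {
    resno <- pos + model$offsets[[ch]]
    model$coords[model$coords$chain == ch &
      model$coords$resno == resno, , drop = FALSE]
  })
  do.call(rbind, hits)
}

#' Minimal Cα–Cα distance of one cross-link on a structure
#'
#' Computes the Euclidean distance between the alpha-carbons of the two
#' linked residues, minimized over every combination of chain copies of the
#' two proteins. Cross-linkers bridge a bounded Cα–Cα span (about 35 Å for
#' DSS/BS3 on lysines), so links within the cutoff are structurally
#' compatible.
#'
#' @param rec one record of a [link_dataset()] (a one-row subset or a list
#'   with fields `record_id`, `link_type`, `protein_a`, `protein_b`,
#'   `pos_a`, `pos_b`); must be `INTER` or `INTRA`, never `MONO`.
#' @param model a `structure_model` from [load_structure()].
#' @param cutoff distance cutoff in Å used for the `satisfied` flag
#'   (default 35).
#' @return list (class `distance_result`) with `record_id`, `min_distance`
#'   (Å, `NA` when unmappable), `mappable`, `satisfied` (`NA` when
#'   unmappable).
#' @export
link_distance <- function(rec, model, cutoff = 35) {
  if (is.data.frame(rec)) {
    stopifnot(nrow(rec) == 1L)
    rec <- as.list(rec)
  }
  if (is.na(rec$link_type) || rec$link_type == "MONO") {
    stop("link_distance: monolinks have a single residue; ",
      "only INTRA and INTER records can be mapped", call. = FALSE)
  }
  a <- .residue_coords(model, rec$protein_a, rec$pos_a)
  b <- .residue_coords(model, rec$protein_b, rec$pos_b)
  res <- list(record_id = rec$record_id, min_distance = NA_real_,
    mappable = FALSE, satisfied = NA)
  if (!is.null(a) && !is.null(b) && nrow(a) && nrow(b)) {
    am <- as.matrix(a[c("x", "y", "z")])
    bm <- as.matrix(b[c("x", "y", "z")])
    # all copy pairs
    d2 <- outer(rowSums(am^2), rowSums(bm^2), "+") - 2 * am %*% t(bm)
    res$min_distance <- sqrt(max(0, min(d2)))
    res$mappable <- TRUE
    res$satisfied <- res$min_distance <= cutoff
  }
  structure(res, class = "distance_result")
}

#' Map every inter/intra link of a dataset onto a structure
#'
#' @param ds a [link_dataset()] with normalized link types; monolinks are
#'   skipped.
#' @param model a `structure_model`.
#' @param cutoff distance cutoff in Å (default 35).
#' @return data frame with one row per INTER/INTRA record: `record_id`,
#'   `link_type`, `min_distance`, `mappable`, `satisfied`.
#' @export
link_distances <- function(ds, model, cutoff = 35) {
  require_normalized(ds, "link_distances")
  idx <- which(ds$link_type %in% c("INTER", "INTRA"))
  rows <- lapply(idx, function(i) {
    r <- link_distance(ld_subset(ds, i), model, cutoff = cutoff)
    data.frame(record_id = r$record_id, link_type = ds$link_type[i],
      min_distance = r$min_distance, mappable = r$mappable,
      satisfied = r$satisfied, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(record_id = character(), link_type = character(),
      min_distance = numeric(), mappable = logical(), satisfied = logical(),
      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise distance satisfaction at a cutoff
#'
#' Fraction of mappable links whose minimal Cα–Cα distance falls within the
#' cutoff. Unmappable links (residue missing from the structure or protein
#' absent from the chain map) are excluded from the denominator and counted
#' separately.
#'
#' @param results data frame from [link_distances()] (or a list of
#'   `distance_result` objects).
#' @param cutoff distance cutoff in Å (default 35).
#' @return list with `n_mappable`, `n_satisfied`, `n_unmappable`, `fraction`
#'   (`NA` when nothing is mappable).
#' @export
satisfaction_summary <- function(results, cutoff = 35) {
  if (!is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, function(r)
      data.frame(min_distance = r$min_distance, mappable = r$mappable)))
  }
  mp <- results[results$mappable, , drop = FALSE]
  n_sat <- sum(mp$min_distance <= cutoff)
  list(
    n_mappable = nrow(mp), n_satisfied = n_sat,
    n_unmappable = sum(!results$mappable),
    fraction = if (nrow(mp) > 0) n_sat / nrow(mp) else NA_real_
  )
}

#' Write per-link distance results as CSV
#'
#' @param results data frame from [link_distances()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, na = "")
  invisible(path)
}
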