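#' Column layout of the xQuest TSV dialect
#'
#' xQuest result exports are tab-separated tables with one identification per
#' row. Published exports vary slightly in header spelling, so the layout is
#' configurable; the defaults below cover the common export. Positions are
#' absolute 1-based residue indices within the protein.
#'
#' @param id,type,protein_a,protein_b,pos_a,pos_b,ld_score,replicate source
#'   column names for the canonical fields. `replicate` is optional in the
#'   file; when absent, the file label is used as the replicate id.
#' @return named list mapping canonical field names to source column names.
#' @export
xquest_columns <- function(id = "Id", type = "Type",
                           protein_a = "Protein1", protein_b = "Protein2",
                           pos_a = "AbsPos1", pos_b = "AbsPos2",
                           ld_score = "ld-Score", replicate = "Replicate") {
  list(id = id, type = type, protein_a = protein_a, protein_b = protein_b,
    pos_a = pos_a, pos_b = pos_b, ld_score = ld_score, replicate = replicate)
}

# Fields a table must provide; `id` and `replicate` have fallbacks,
# `protein_b`/`pos_b` may be absent column-wise only if every record is a
# monolink, so they are mandatory as columns.
.mandatory_fields <- c("type", "protein_a", "protein_b", "pos_a", "pos_b", "ld_score")

.read_link_table <- function(path, column_map, sep, decoy_prefixes,
                             replicate_id, strict, dialect) {
  if (!file.exists(path)) {
    stop(sprintf("%s: file not found: %s", dialect, path), call. = FALSE)
  }
  missing_map <- setdiff(.mandatory_fields, names(column_map))
  if (length(missing_map)) {
    stop(sprintf("%s: column_map does not cover mandatory field(s): %s",
      dialect, paste(missing_map, collapse = ", ")), call. = FALSE)
  }
  raw <- utils::read.table(path, sep = sep, header = TRUE,
    check.names = FALSE, stringsAsFactors = FALSE, quote = "\"",
    comment.char = "", colClasses = "character")
  missing_cols <- setdiff(unlist(column_map[.mandatory_fields]), names(raw))
  if (length(missing_cols)) {
    stop(sprintf("%s: %s is missing mandatory column(s): %s",
      dialect, basename(path), paste(missing_cols, collapse = ", ")),
      call. = FALSE)
  }
  col <- function(field, default = NA_character_) {
    nm <- column_map[[field]]
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]]
    else rep(default, nrow(raw))
  }
  scores_chr <- col("ld_score")
  scores <- suppressWarnings(as.numeric(scores_chr))
  bad <- which(is.na(scores) & !(is.na(scores_chr) | scores_chr == ""))
  if (length(bad)) {
    msg <- sprintf("%s: unparsable ld-score in %s at data row(s) %s",
      dialect, basename(path), paste(utils::head(bad, 5L), collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, " -- rows skipped (lenient mode)", call. = FALSE)
  }
  pos_chr <- list(a = col("pos_a"), b = col("pos_b"))
  pos <- lapply(pos_chr, function(p) suppressWarnings(as.integer(p)))
  keep <- rep(TRUE, nrow(raw))
  if (!strict && length(bad)) keep[bad] <- FALSE
  ids <- col("id")
  if (all(is.na(ids))) ids <- as.character(seq_len(nrow(raw)))
  reps <- col("replicate")
  reps[is.na(reps) | reps == ""] <- replicate_id
  recs <- data.frame(
    record_id = ids, raw_type = col("type"),
    protein_a = col("protein_a"), protein_b = col("protein_b"),
    pos_a = pos$a, pos_b = pos$b, ld_score = scores,
    replicate_id = reps, stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  sf <- unique(recs$replicate_id)
  if (!length(sf)) sf <- replicate_id
  ds <- link_dataset(recs, source_files = sf,
    metadata = list(path = path, dialect = dialect))
  annotate_decoys(ds, decoy_prefixes)
}

#' Read an xQuest-dialect cross-link result table
#'
#' Reads a tab-separated xQuest export into a [link_dataset()]. Row order is
#' preserved, the raw link-type label is kept verbatim in `raw_type`
#' (normalize later with [normalize_types()]), and decoy status is assigned
#' from accession prefixes.
#'
#' @param path path to the TSV file.
#' @param decoy_prefixes case-sensitive accession prefixes marking decoy
#'   entries; use `character(0)` to treat every record as a target.
#' @param columns column layout, see [xquest_columns()].
#' @param replicate_id label for this file / biological replicate; defaults to
#'   the file name without extension. A `Replicate` column in the file, when
#'   present, takes precedence row-wise (so round trips preserve labels).
#' @param strict if `TRUE` (default) an unparsable score aborts with the row
#'   number; if `FALSE` such rows are skipped with a warning.
#' @return a [link_dataset()].
#' @export
read_xquest_tsv <- function(path, decoy_prefixes = default_decoy_prefixes(),
                            columns = xquest_columns(),
                            replicate_id = NULL, strict = TRUE) {
  if (is.null(replicate_id)) {
    replicate_id <- tools::file_path_sans_ext(basename(path))
  }
  .read_link_table(path, columns, sep = "\t", decoy_prefixes = decoy_prefixes,
    replicate_id = replicate_id, strict = strict, dialect = "xquest_tsv")
}

#' Read a cross-link table in a generic CSV schema
#'
#' For exports from other identification platforms (MeroX, XlinkX, pLink2,
#' ...): supply a `column_map` translating canonical field names (`type`,
#' `protein_a`, `protein_b`, `pos_a`, `pos_b`, `ld_score`, optionally `id`
#' and `replicate`) to the source column names.
#'
#' @inheritParams read_xquest_tsv
#' @param column_map named list/character vector, canonical field -> source
#'   column name; must cover the mandatory fields.
#' @param sep field separator (default comma).
#' @return a [link_dataset()].
#' @export
read_generic_csv <- function(path, column_map,
                             decoy_prefixes = default_decoy_prefixes(),
                             replicate_id = NULL, sep = ",", strict = TRUE) {
  if (is.null(replicate_id)) {
    replicate_id <- tools::file_path_sans_ext(basename(path))
  }
  .read_link_table(path, as.list(column_map), sep = sep,
    decoy_prefixes = decoy_prefixes, replicate_id = replicate_id,
    strict = strict, dialect = "generic_csv")
}

#' Write a dataset back to the xQuest TSV dialect
#'
#' Writes the table with the default [xquest_columns()] header plus a
#' `Replicate` column, so `read_xquest_tsv(write_dataset(ds))` reproduces all
#' fields. Link types are written as the original `raw_type` labels; decoy
#' status is re-derived from accessions on read.
#'
#' @param ds a [link_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  cols <- xquest_columns()
  out <- data.frame(
    a = ds$record_id, b = ds$raw_type,
    c = ds$protein_a, d = ifelse(is.na(ds$protein_b), "", ds$protein_b),
    e = ds$pos_a, f = ifelse(is.na(ds$pos_b), "", as.character(ds$pos_b)),
    g = ds$ld_score, h = ds$replicate_id,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  names(out) <- unlist(cols[c("id", "type", "protein_a", "protein_b",
    "pos_a", "pos_b", "ld_score", "replicate")])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Export inter-protein links as a xiNET edge list
#'
#' Writes one row per unique inter-protein cross-linking site in the xiNET
#' cross-link CSV convention (`Protein1, Protein2, LinkPos1, LinkPos2`).
#' Monolinks and intra-protein links are omitted; duplicate sites (e.g. the
#' same link seen in several replicates) collapse to a single edge.
#'
#' @param ds a [link_dataset()] with normalized link types.
#' @param path output CSV path.
#' @return number of edge rows written, invisibly.
#' @export
export_xinet_edges <- function(ds, path) {
  require_normalized(ds, "export_xinet_edges")
  inter <- ds[ds$link_type == "INTER", , drop = FALSE]
  inter <- inter[!duplicated(inter$unique_key), , drop = FALSE]
  edges <- data.frame(
    Protein1 = inter$protein_a, Protein2 = inter$protein_b,
    LinkPos1 = inter$pos_a, LinkPos2 = inter$pos_b,
    stringsAsFactors = FALSE
  )
  utils::write.csv(edges, path, row.names = FALSE, quote = FALSE)
  invisible(nrow(edges))
}
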