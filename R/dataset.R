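#' Cross-link identification datasets
#'
#' A `link_dataset` is the package's central container: a data frame with one
#' row per cross-link identification (PSM-level, i.e. redundant), carrying the
#' columns listed below plus two attributes, `source_files` (ordered character
#' vector of replicate labels) and `metadata` (free-form provenance list).
#'
#' Columns:
#' \describe{
#'   \item{record_id}{opaque identifier, unique within a source file}
#'   \item{raw_type}{link-type label as found in the input table}
#'   \item{link_type}{canonical class `"MONO"`, `"INTRA"` or `"INTER"`;
#'     `NA` until [normalize_types()] has run}
#'   \item{protein_a, protein_b}{protein accessions; `protein_b` is `NA` for
#'     monolinks}
#'   \item{pos_a, pos_b}{1-based residue indices of the linked residues}
#'   \item{ld_score}{identification score (xQuest ld-score convention:
#'     higher is better)}
#'   \item{is_decoy}{`TRUE` iff at least one accession matches a decoy prefix}
#'   \item{decoy_class}{`"TT"`, `"TD"` or `"DD"`: none, some, or all of the
#'     record's accessions are decoys}
#'   \item{replicate_id}{label of the source file / biological replicate}
#'   \item{unique_key}{canonical string identifying the cross-linking site;
#'     invariant under swapping the two sides of the record}
#' }
#'
#' @param records data frame holding at least `raw_type`, `protein_a`,
#'   `pos_a`, `ld_score` and `replicate_id`; missing optional columns are
#'   filled with `NA` / defaults.
#' @param source_files character vector of replicate labels; defaults to the
#'   distinct `replicate_id` values in order of first appearance.
#' @param metadata free-form provenance list.
#' @return An object of class `link_dataset` (also a `data.frame`).
#' @seealso [read_xquest_tsv()], [normalize_types()], [apply_mi_filter()]
#' @export
link_dataset <- function(records, source_files = NULL, metadata = list()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  defaults <- list(
    record_id = if (nrow(records)) as.character(seq_len(nrow(records))) else character(),
    raw_type = NA_character_, link_type = NA_character_,
    protein_a = NA_character_, protein_b = NA_character_,
    pos_a = NA_integer_, pos_b = NA_integer_,
    ld_score = NA_real_, is_decoy = FALSE, decoy_class = NA_character_,
    replicate_id = NA_character_, unique_key = NA_character_
  )
  for (nm in names(defaults)) {
    if (is.null(records[[nm]])) {
      records[[nm]] <- if (length(defaults[[nm]]) == 1L)
        rep(defaults[[nm]], nrow(records)) else defaults[[nm]]
    }
  }
  records <- records[names(defaults)]
  records$record_id <- as.character(records$record_id)
  records$protein_a <- as.character(records$protein_a)
  records$protein_b <- as.character(records$protein_b)
  records$pos_a <- as.integer(records$pos_a)
  records$pos_b <- as.integer(records$pos_b)
  records$ld_score <- as.numeric(records$ld_score)
  records$replicate_id <- as.character(records$replicate_id)
  # empty-string protein_b means absent
  records$protein_b[!is.na(records$protein_b) & records$protein_b == ""] <- NA_character_
  records$pos_b[is.na(records$protein_b)] <- NA_integer_
  if (is.null(source_files)) {
    source_files <- unique(records$replicate_id)
    source_files <- source_files[!is.na(source_files)]
  }
  records$unique_key <- compute_unique_keys(records)
  ds <- structure(records,
    class = c("link_dataset", "data.frame"),
    source_files = as.character(source_files),
    metadata = metadata
  )
  validate_link_dataset(ds)
  ds
}

#' @rdname link_dataset
#' @param ds a `link_dataset`.
#' @export
source_files <- function(ds) attr(ds, "source_files")

#' @rdname link_dataset
#' @export
dataset_metadata <- function(ds) attr(ds, "metadata")

validate_link_dataset <- function(ds) {
  stopifnot(is.data.frame(ds))
  if (nrow(ds) == 0L) return(invisible(ds))
  bad_rep <- !ds$replicate_id %in% attr(ds, "source_files")
  if (any(bad_rep)) {
    stop("link_dataset: replicate_id not listed in source_files: ",
      paste(unique(ds$replicate_id[bad_rep]), collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(ds$pos_a) & ds$pos_a < 1L) || any(!is.na(ds$pos_b) & ds$pos_b < 1L)) {
    stop("link_dataset: residue positions must be >= 1 (1-based convention)",
      call. = FALSE)
  }
  known <- is.na(ds$link_type) | ds$link_type %in% c("MONO", "INTRA", "INTER")
  if (!all(known)) {
    stop("link_dataset: invalid link_type value(s): ",
      paste(unique(ds$link_type[!known]), collapse = ", "), call. = FALSE)
  }
  mono <- !is.na(ds$link_type) & ds$link_type == "MONO"
  if (any(mono & !is.na(ds$protein_b))) {
    stop("link_dataset: MONO records must not carry protein_b", call. = FALSE)
  }
  dec <- !is.na(ds$decoy_class)
  if (any(dec & (ds$is_decoy != ds$decoy_class %in% c("TD", "DD")))) {
    stop("link_dataset: is_decoy must equal decoy_class %in% {TD, DD}", call. = FALSE)
  }
  invisible(ds)
}

# Canonical site key: the (accession, position) tuples sorted lexicographically
# so the key is invariant under swapping the two sides; prefixed with the link
# type (canonical if normalized, raw label otherwise).
compute_unique_keys <- function(records) {
  n <- nrow(records)
  if (n == 0L) return(character())
  type_lab <- ifelse(is.na(records$link_type), records$raw_type, records$link_type)
  side_a <- paste0(records$protein_a, ":", records$pos_a)
  side_b <- ifelse(is.na(records$protein_b), NA_character_,
    paste0(records$protein_b, ":", records$pos_b))
  lo <- ifelse(is.na(side_b) | side_a <= side_b, side_a, side_b)
  hi <- ifelse(is.na(side_b) | side_a <= side_b, side_b, side_a)
  ifelse(is.na(hi),
    paste0(type_lab, "|", lo),
    paste0(type_lab, "|", lo, "--", hi))
}

# Subset rows while preserving class and attributes.
ld_subset <- function(ds, idx) {
  out <- as.data.frame(ds)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
    class = c("link_dataset", "data.frame"),
    source_files = attr(ds, "source_files"),
    metadata = attr(ds, "metadata"))
}

#' Annotate decoy status from accession prefixes
#'
#' Sets `is_decoy` and `decoy_class` by matching each accession against a list
#' of decoy prefixes (case-sensitive). A record is `TT` when no accession
#' matches, `DD` when all present accessions match, and `TD` otherwise.
#' With an empty prefix list every record is a target (`TT`).
#'
#' @param ds a `link_dataset`.
#' @param decoy_prefixes character vector of accession prefixes marking decoy
#'   database entries.
#' @return the dataset with `is_decoy` / `decoy_class` (re)computed.
#' @export
annotate_decoys <- function(ds, decoy_prefixes = default_decoy_prefixes()) {
  has_prefix <- function(acc) {
    hit <- rep(FALSE, length(acc))
    for (p in decoy_prefixes) hit <- hit | startsWith(acc, p)
    hit & !is.na(acc)
  }
  dec_a <- has_prefix(ds$protein_a)
  dec_b <- has_prefix(ds$protein_b)
  n_prot <- 1L + !is.na(ds$protein_b)
  n_dec <- dec_a + dec_b
  ds$decoy_class <- ifelse(n_dec == 0L, "TT", ifelse(n_dec == n_prot, "DD", "TD"))
  if (nrow(ds) == 0L) ds$decoy_class <- character()
  ds$is_decoy <- ds$decoy_class %in% c("TD", "DD")
  md <- attr(ds, "metadata")
  md$decoy_prefixes <- decoy_prefixes
  attr(ds, "metadata") <- md
  ds
}

#' @rdname annotate_decoys
#' @export
default_decoy_prefixes <- function() c("decoy_", "rev_", "REV_")

#' Concatenate replicate datasets
#'
#' Row-binds several `link_dataset` objects, preserving record order within
#' each source and the order of the inputs, and merging their `source_files`.
#'
#' @param ... `link_dataset` objects (or a single list of them).
#' @return a single `link_dataset`.
#' @export
concat_datasets <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1L]], "link_dataset")) {
    parts <- parts[[1L]]
  }
  stopifnot(all(vapply(parts, inherits, logical(1), "link_dataset")))
  recs <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(recs) <- NULL
  sf <- unique(unlist(lapply(parts, attr, "source_files")))
  md <- list()
  for (p in parts) md <- utils::modifyList(md, attr(p, "metadata"))
  structure(recs,
    class = c("link_dataset", "data.frame"),
    source_files = sf, metadata = md)
}

# TRUE when every record carries a canonical link type.
is_normalized <- function(ds) {
  nrow(ds) == 0L || all(!is.na(ds$link_type) &
    ds$link_type %in% c("MONO", "INTRA", "INTER"))
}

require_normalized <- function(ds, op) {
  if (!is_normalized(ds)) {
    stop(op, ": dataset contains unnormalized link types; ",
      "run normalize_types() first", call. = FALSE)
  }
  invisible(ds)
}

#' @export
print.link_dataset <- function(x, ...) {
  cat(sprintf("<link_dataset> %d records from %d source file(s)\n",
    nrow(x), length(attr(x, "source_files"))))
  if (nrow(x)) {
    if (is_normalized(x)) {
      tab <- table(x$link_type)
      cat("  types:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
    } else {
      cat("  raw types:", paste(unique(x$raw_type), collapse = ", "),
        "(not yet normalized)\n")
    }
    cat(sprintf("  decoys: %d / %d records\n", sum(x$is_decoy), nrow(x)))
    cat(sprintf("  ld-score range: [%.2f, %.2f]\n",
      min(x$ld_score, na.rm = TRUE), max(x$ld_score, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.link_dataset <- function(object, ...) {
  cat(sprintf("link_dataset: %d records, %d replicates (%s)\n",
    nrow(object), length(attr(object, "source_files")),
    paste(attr(object, "source_files"), collapse = ", ")))
  if (nrow(object) && is_normalized(object)) {
    print(table(type = object$link_type, decoy = object$decoy_class))
  }
  invisible(object)
}
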