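#' Raw-label to canonical link-type mapping
#'
#' Identification software labels link types inconsistently ("xlink",
#' "crosslink", "intralink", "monolink", "looplink", ...). A `type_mapping`
#' reduces them to the three canonical classes `MONO`, `INTRA` and `INTER`.
#' Lookup is on the lower-cased raw label. Looplinks (cross-linker reacted
#' twice within one peptide) map to `INTRA` by default: they are evidence
#' that the protein is present and cross-linkable, which is what the
#' mi-filter needs; map them to `"DROP"` to discard instead.
#'
#' @param map named character vector, lower-cased raw label -> canonical
#'   class (`"MONO"`, `"INTRA"`, `"INTER"` or `"DROP"`). Entries supplied
#'   here override/extend the defaults.
#' @param unmapped policy for labels absent from the map: `"error"` (default)
#'   aborts naming the label, `"drop"` discards those records.
#' @return an object of class `type_mapping`.
#' @export
type_mapping <- function(map = character(), unmapped = c("error", "drop")) {
  unmapped <- match.arg(unmapped)
  defaults <- c(
    monolink = "MONO", mono = "MONO", monolinks = "MONO",
    intralink = "INTRA", intra = "INTRA", intraprotein = "INTRA",
    xlink = "INTER", crosslink = "INTER", interlink = "INTER",
    inter = "INTER", interprotein = "INTER",
    looplink = "INTRA", loop = "INTRA", looplinks = "INTRA"
  )
  map <- c(map, defaults[setdiff(names(defaults), names(map))])
  bad <- !map %in% c("MONO", "INTRA", "INTER", "DROP")
  if (any(bad)) {
    stop("type_mapping: invalid canonical class for label(s): ",
      paste(names(map)[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(map = map, unmapped = unmapped), class = "type_mapping")
}

#' Normalize link-type labels to MONO / INTRA / INTER
#'
#' Replaces heterogeneous raw labels by the three canonical classes, then
#' applies two semantic corrections: a cross-link whose two accessions are
#' identical is intra-protein regardless of its label (without isotope or
#' stoichiometry evidence, the same-accession reading of a homodimer link is
#' the conservative one), and a record classified `MONO` carries no second
#' protein. Site keys and decoy annotation are recomputed afterwards.
#' The operation is idempotent.
#'
#' @param ds a [link_dataset()].
#' @param mapping a [type_mapping()].
#' @param same_protein_inter what to do with an inter-labelled link between
#'   identical accessions: reclassify `"INTRA"` (default) or keep `"INTER"`.
#' @return the dataset with `link_type` populated.
#' @export
normalize_types <- function(ds, mapping = type_mapping(),
                            same_protein_inter = c("INTRA", "INTER")) {
  same_protein_inter <- match.arg(same_protein_inter)
  stopifnot(inherits(mapping, "type_mapping"))
  if (nrow(ds) == 0L) return(ds)
  # idempotence: already-canonical labels pass through
  labels <- ifelse(ds$raw_type %in% c("MONO", "INTRA", "INTER") |
      (!is.na(ds$link_type) & ds$link_type %in% c("MONO", "INTRA", "INTER")),
    ifelse(is.na(ds$link_type), ds$raw_type, ds$link_type),
    NA_character_)
  todo <- is.na(labels)
  if (any(todo)) {
    key <- tolower(ds$raw_type[todo])
    hit <- mapping$map[key]
    unmapped <- is.na(hit)
    if (any(unmapped)) {
      if (mapping$unmapped == "error") {
        stop("normalize_types: unmapped link-type label(s): ",
          paste(unique(ds$raw_type[todo][unmapped]), collapse = ", "),
          call. = FALSE)
      }
      hit[unmapped] <- "DROP"
    }
    labels[todo] <- unname(hit)
  }
  ds$link_type <- labels
  ds <- ld_subset(ds, which(ds$link_type != "DROP"))
  same <- ds$link_type == "INTER" & !is.na(ds$protein_b) &
    ds$protein_a == ds$protein_b
  if (same_protein_inter == "INTRA") ds$link_type[same] <- "INTRA"
  mono <- ds$link_type == "MONO"
  ds$protein_b[mono] <- NA_character_
  ds$pos_b[mono] <- NA_integer_
  ds$unique_key <- compute_unique_keys(ds)
  prefixes <- attr(ds, "metadata")$decoy_prefixes
  if (is.null(prefixes)) prefixes <- default_decoy_prefixes()
  annotate_decoys(ds, prefixes)
}
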