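#' Read a pipeline configuration from a YAML file
#'
#' The file may define any of the keys below; unknown keys are rejected so a
#' typo cannot silently change a filtering run.
#'
#' \preformatted{
#' format: xquest            # or "generic"
#' decoy_prefixes: [decoy_, rev_, REV_]
#' strict: true
#' pair_level: false
#' columns:                  # xQuest column layout overrides
#'   ld_score: "ld-Score"
#' column_map:               # generic-CSV field -> source column
#'   protein_a: Protein_1
#' type_mapping:             # raw label -> MONO/INTRA/INTER/DROP
#'   looplink: INTRA
#' unmapped_policy: error    # or "drop"
#' chain_map:                # structure validation: accession -> chains
#'   P12345: [A, B]
#' chain_offsets:            # chain -> residue numbering offset
#'   A: 0
#' distance_cutoff: 35
#' cutoffs: [20, 25, 28, 32]
#' }
#'
#' @param path YAML file.
#' @return list with elements `pipeline` (a [pipeline_config()]), plus
#'   `chain_map`, `chain_offsets`, `distance_cutoff` and `cutoffs` when
#'   given.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("format", "decoy_prefixes", "strict", "pair_level", "columns",
    "column_map", "type_mapping", "unmapped_policy", "chain_map",
    "chain_offsets", "distance_cutoff", "cutoffs")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("read_run_config: unknown configuration key(s): ",
      paste(unknown, collapse = ", "), call. = FALSE)
  }
  columns <- do.call(xquest_columns, as.list(raw$columns %||% list()))
  mapping <- type_mapping(
    map = unlist(raw$type_mapping %||% list()),
    unmapped = raw$unmapped_policy %||% "error")
  pipeline <- pipeline_config(
    format = raw$format %||% "xquest",
    columns = columns,
    column_map = raw$column_map,
    decoy_prefixes = unlist(raw$decoy_prefixes %||%
      default_decoy_prefixes()),
    mapping = mapping,
    strict = raw$strict %||% TRUE,
    pair_level = raw$pair_level %||% FALSE)
  list(pipeline = pipeline,
    chain_map = raw$chain_map,
    chain_offsets = unlist(raw$chain_offsets),
    distance_cutoff = raw$distance_cutoff %||% 35,
    cutoffs = unlist(raw$cutoffs %||% c(20, 25, 28, 32)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a provenance sidecar for an output file
#'
#' Records the inputs, parameters and package version that produced an
#' artifact, so filtering decisions that change PPI conclusions stay
#' auditable.
#'
#' @param path the output file the provenance describes; the sidecar is
#'   written next to it as `<path>.provenance.json`.
#' @param inputs character vector of input paths/labels.
#' @param params named list of parameters.
#' @return sidecar path, invisibly.
#' @export
write_provenance <- function(path, inputs, params = list()) {
  side <- paste0(path, ".provenance.json")
  jsonlite::write_json(list(
    output = basename(path),
    inputs = as.character(inputs),
    params = params,
    tool = "mifilter",
    version = as.character(utils::packageVersion("mifilter")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), side, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(side)
}
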