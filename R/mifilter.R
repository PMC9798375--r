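#' Build the set of proteins eligible for inter-protein links
#'
#' The mono-/intralink filter rests on one rule: a protein may take part in
#' an inter-protein cross-link only if the same dataset contains at least one
#' monolink or intra-protein cross-link for it. This function collects those
#' proteins, with per-protein counts of the supporting records.
#'
#' Decoy accessions qualify through decoy monolinks/intralinks in the same
#' way targets do: eligibility is drawn from the dataset symmetrically, so
#' the decoy proportion after filtering remains an unbiased error estimate.
#'
#' @param ds a [link_dataset()] with normalized link types (see
#'   [normalize_types()]); the dataset should already reflect the active
#'   ld-score cutoff, since support is assessed at the same cutoff as the
#'   links it licenses.
#' @return an object of class `eligible_set`: list with `proteins`
#'   (character vector) and `support` (data frame `protein`, `n_mono`,
#'   `n_intra`).
#' @export
build_eligible_set <- function(ds) {
  require_normalized(ds, "build_eligible_set")
  mono <- ds$protein_a[ds$link_type == "MONO"]
  intra <- c(ds$protein_a[ds$link_type == "INTRA"],
             ds$protein_b[ds$link_type == "INTRA"])
  intra <- intra[!is.na(intra)]
  proteins <- sort(unique(c(mono, intra)))
  support <- data.frame(
    protein = proteins,
    n_mono = as.vector(table(factor(mono, levels = proteins))),
    n_intra = as.vector(table(factor(intra, levels = proteins))),
    stringsAsFactors = FALSE
  )
  structure(list(proteins = proteins, support = support),
    class = "eligible_set")
}

#' @export
print.eligible_set <- function(x, ...) {
  cat(sprintf("<eligible_set> %d proteins with >=1 monolink or intralink\n",
    length(x$proteins)))
  if (length(x$proteins)) {
    cat(sprintf("  total support: %d monolinks, %d intralink endpoints\n",
      sum(x$support$n_mono), sum(x$support$n_intra)))
  }
  invisible(x)
}

#' Apply the mono-/intralink (mi) filter
#'
#' Removes every inter-protein cross-link for which either partner protein is
#' not in the eligible set; monolinks and intra-protein links pass through
#' unchanged. The filter is binary and idempotent: since it never removes
#' MONO/INTRA records, re-deriving eligibility from its output and filtering
#' again changes nothing.
#'
#' @param ds a [link_dataset()] with normalized link types.
#' @param eligible an `eligible_set`; defaults to [build_eligible_set()] on
#'   `ds` itself.
#' @return list with elements `dataset` (the filtered [link_dataset()]) and
#'   `report` (a `filter_report`: input/retained/removed inter-link counts,
#'   the removed record ids with their ineligible partners, and the TT/TD/DD
#'   decoy breakdown of inter-links before and after).
#' @export
apply_mi_filter <- function(ds, eligible = build_eligible_set(ds)) {
  require_normalized(ds, "apply_mi_filter")
  stopifnot(inherits(eligible, "eligible_set"))
  inter <- ds$link_type == "INTER"
  ok_a <- ds$protein_a %in% eligible$proteins
  ok_b <- !is.na(ds$protein_b) & ds$protein_b %in% eligible$proteins
  keep <- !inter | (ok_a & ok_b)
  removed <- which(!keep)
  partner <- function(i) {
    bad <- c(if (!ok_a[i]) ds$protein_a[i], if (!ok_b[i]) ds$protein_b[i])
    paste(bad, collapse = ";")
  }
  removed_records <- data.frame(
    record_id = ds$record_id[removed],
    ineligible_partners = vapply(removed, partner, character(1)),
    stringsAsFactors = FALSE
  )
  out <- ld_subset(ds, which(keep))
  breakdown <- function(d) {
    cls <- d$decoy_class[d$link_type == "INTER"]
    as.vector(table(factor(cls, levels = c("TT", "TD", "DD"))))
  }
  report <- structure(list(
    n_input_inter = sum(inter),
    n_retained_inter = sum(inter & keep),
    n_removed_inter = length(removed),
    removed_records = removed_records,
    decoy_breakdown = data.frame(
      decoy_class = c("TT", "TD", "DD"),
      before = breakdown(ds), after = breakdown(out),
      stringsAsFactors = FALSE
    )
  ), class = "filter_report")
  stopifnot(report$n_input_inter ==
    report$n_retained_inter + report$n_removed_inter)
  list(dataset = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "<filter_report> inter-protein links: %d in, %d retained, %d removed\n",
    x$n_input_inter, x$n_retained_inter, x$n_removed_inter))
  bd <- x$decoy_breakdown
  cat(sprintf("  inter decoy classes (before -> after): %s\n",
    paste(sprintf("%s %d->%d", bd$decoy_class, bd$before, bd$after),
      collapse = ", ")))
  invisible(x)
}

#' Default per-stage configuration for the filtering pipeline
#'
#' @param format `"xquest"` (tab-separated, [xquest_columns()]) or
#'   `"generic"` (CSV via `column_map`).
#' @param columns xQuest column layout, see [xquest_columns()].
#' @param column_map canonical-field -> source-column map for
#'   `format = "generic"`.
#' @param decoy_prefixes accession prefixes marking decoys.
#' @param mapping a [type_mapping()].
#' @param strict fail on unparsable rows instead of skipping them.
#' @param pair_level replicate-filter sites at protein-pair level.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(format = c("xquest", "generic"),
                            columns = xquest_columns(), column_map = NULL,
                            decoy_prefixes = default_decoy_prefixes(),
                            mapping = type_mapping(), strict = TRUE,
                            pair_level = FALSE) {
  structure(list(format = match.arg(format), columns = columns,
    column_map = column_map, decoy_prefixes = decoy_prefixes,
    mapping = mapping, strict = strict, pair_level = pair_level),
    class = "pipeline_config")
}

.read_replicates <- function(paths, config) {
  lapply(paths, function(p) {
    if (inherits(p, "link_dataset")) return(p)
    switch(config$format,
      xquest = read_xquest_tsv(p, decoy_prefixes = config$decoy_prefixes,
        columns = config$columns, strict = config$strict),
      generic = read_generic_csv(p, column_map = config$column_map,
        decoy_prefixes = config$decoy_prefixes, strict = config$strict))
  })
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full mi-filter pipeline
#'
#' Executes the stages in their canonical order: per-replicate read, ld-score
#' cutoff (`ld_score >= ld_cutoff`, applied per file before merging),
#' concatenation, optional replicate-consistency filter, decoy annotation,
#' link-type normalization, eligible-set construction, and (optionally) the
#' mi-filter. Because the score cutoff precedes everything else, the
#' monolink/intralink support that licenses an inter-protein link must itself
#' pass the cutoff — and, when the replicate filter is on, the replicate
#' requirement too.
#'
#' @param paths input files, one per biological replicate (or a list of
#'   pre-read [link_dataset()] objects, one per replicate).
#' @param ld_cutoff minimum ld-score; `-Inf` disables score filtering.
#' @param min_replicates required replicate support per cross-linking site;
#'   `NULL` disables the replicate filter.
#' @param mi apply the mono-/intralink filter (`TRUE` by default).
#' @param config a [pipeline_config()].
#' @return list with `dataset` (final [link_dataset()]), `report` (the
#'   mi-filter's `filter_report`; when `mi = FALSE`, the report of a
#'   hypothetical filter, with the dataset left unfiltered), `eligible`
#'   (the `eligible_set`), and `stages` (record counts after each stage).
#' @export
run_pipeline <- function(paths, ld_cutoff = -Inf, min_replicates = NULL,
                         mi = TRUE, config = pipeline_config()) {
  if (length(paths) < 1L) {
    stop("run_pipeline: at least one input file is required", call. = FALSE)
  }
  reps <- .stage("read", .read_replicates(paths, config))
  reps <- .stage("score_cutoff", lapply(reps, function(d)
    ld_subset(d, which(!is.na(d$ld_score) & d$ld_score >= ld_cutoff))))
  ds <- .stage("concatenate", concat_datasets(reps))
  stages <- c(score_cutoff = nrow(ds))
  if (!is.null(min_replicates)) {
    ds <- .stage("replicate_filter",
      filter_by_replicates(ds, min_replicates, pair_level = config$pair_level))
  }
  stages <- c(stages, replicate_filter = nrow(ds))
  ds <- .stage("decoy_annotation", annotate_decoys(ds, config$decoy_prefixes))
  ds <- .stage("type_normalization", normalize_types(ds, config$mapping))
  stages <- c(stages, type_normalization = nrow(ds))
  eligible <- .stage("eligible_set", build_eligible_set(ds))
  filtered <- .stage("mi_filter", apply_mi_filter(ds, eligible))
  out <- if (mi) filtered$dataset else ds
  stages <- c(stages, mi_filter = nrow(out))
  list(dataset = out, report = filtered$report, eligible = eligible,
    stages = stages)
}
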