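#' Biological-replicate consistency filter on cross-linking sites
#'
#' Retains a record iff its cross-linking site (the `unique_key`: canonical
#' accession/position pair plus link type) was observed in at least
#' `min_replicates` distinct replicates. All occurrences of a passing site
#' are kept, so the filter never splits a site across replicates. With
#' `pair_level = TRUE` site identity is relaxed to the unordered protein
#' pair (positions ignored).
#'
#' The retained set is monotone non-increasing in `min_replicates` and does
#' not depend on input file order.
#'
#' @param ds a [link_dataset()] whose `replicate_id` distinguishes the
#'   biological replicates (one source file per replicate).
#' @param min_replicates required number of distinct replicates, >= 1;
#'   `1` is a no-op.
#' @param pair_level count replicate support per protein pair instead of per
#'   residue-level site.
#' @return the filtered [link_dataset()].
#' @export
filter_by_replicates <- function(ds, min_replicates, pair_level = FALSE) {
  min_replicates <- as.integer(min_replicates)
  if (is.na(min_replicates) || min_replicates < 1L) {
    stop("filter_by_replicates: min_replicates must be a count >= 1",
      call. = FALSE)
  }
  n_files <- length(attr(ds, "source_files"))
  if (min_replicates > n_files) {
    stop(sprintf(paste0("filter_by_replicates: min_replicates (%d) exceeds ",
      "the number of source files (%d)"), min_replicates, n_files),
      call. = FALSE)
  }
  if (min_replicates == 1L || nrow(ds) == 0L) return(ds)
  key <- if (pair_level) {
    a <- ds$protein_a
    b <- ifelse(is.na(ds$protein_b), "", ds$protein_b)
    ifelse(a <= b | b == "", paste(a, b, sep = "--"), paste(b, a, sep = "--"))
  } else {
    ds$unique_key
  }
  # distinct replicates per site
  seen <- unique(data.frame(key = key, rep = ds$replicate_id,
    stringsAsFactors = FALSE))
  support <- table(seen$key)
  keep <- support[key] >= min_replicates
  ld_subset(ds, which(as.vector(keep)))
}
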