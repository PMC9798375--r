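#' Target/decoy counts per link class
#'
#' Tallies target (`TT`) and decoy (`TD` + `DD`) records for each canonical
#' link class. Counts are at the record (redundant identification) level by
#' default; `unique = TRUE` collapses to unique cross-linking sites first.
#'
#' @param ds a [link_dataset()] with normalized link types.
#' @param unique collapse on `unique_key` before counting.
#' @return data frame with columns `class`, `n_target`, `n_decoy`, one row
#'   per class `MONO`, `INTRA`, `INTER`.
#' @export
count_by_class <- function(ds, unique = FALSE) {
  require_normalized(ds, "count_by_class")
  if (unique && nrow(ds)) ds <- ld_subset(ds, which(!duplicated(ds$unique_key)))
  cls <- factor(ds$link_type, levels = c("MONO", "INTRA", "INTER"))
  data.frame(
    class = c("MONO", "INTRA", "INTER"),
    n_target = as.vector(table(cls[!ds$is_decoy])),
    n_decoy = as.vector(table(cls[ds$is_decoy])),
    stringsAsFactors = FALSE
  )
}

#' Decoy proportion and decoy/target ratio
#'
#' Two conventions are in use for summarising decoy content and they are kept
#' side by side throughout this package: `decoy_fraction` is decoy hits over
#' all hits, decoy / (target + decoy); `decoy_target_ratio` is decoy / target.
#' They are mutually consistent via
#' ratio = fraction / (1 - fraction). Undefined values (empty class for the
#' fraction; zero targets for the ratio) are returned as `NA`, never as 0.
#'
#' @param n_target,n_decoy non-negative counts (vectorized).
#' @return numeric vector.
#' @export
decoy_fraction <- function(n_target, n_decoy) {
  stopifnot(all(n_target >= 0), all(n_decoy >= 0))
  tot <- n_target + n_decoy
  ifelse(tot > 0, n_decoy / tot, NA_real_)
}

#' @rdname decoy_fraction
#' @export
decoy_target_ratio <- function(n_target, n_decoy) {
  stopifnot(all(n_target >= 0), all(n_decoy >= 0))
  ifelse(n_target > 0, n_decoy / n_target, NA_real_)
}

#' Target/decoy sweep over ld-score cutoffs, with and without the mi-filter
#'
#' Runs the full pipeline at each cutoff twice — once without and once with
#' the mono-/intralink filter — and tabulates per-class target/decoy counts
#' and both decoy ratios. This reproduces the shape of the classic
#' before/after comparison: bar heights (counts) and decoy-ratio curves as a
#' function of score stringency. The default cutoffs are 20, 25, 28 and 32.
#'
#' @param files input files (or pre-read per-replicate [link_dataset()]s).
#' @param cutoffs numeric vector of ld-score cutoffs; use `-Inf` for an
#'   unfiltered tier.
#' @param config a [pipeline_config()].
#' @param min_replicates optional replicate requirement, see [run_pipeline()].
#' @param unique count unique sites instead of redundant records.
#' @return a `sweep_result`: long-format data frame with columns `cutoff`,
#'   `class`, `condition` (`"unfiltered"` / `"mi_filtered"`), `n_target`,
#'   `n_decoy`, `decoy_fraction`, `decoy_target_ratio`.
#' @export
decoy_sweep <- function(files, cutoffs = c(20, 25, 28, 32),
                        config = pipeline_config(), min_replicates = NULL,
                        unique = FALSE) {
  if (length(cutoffs) < 1L) {
    stop("decoy_sweep: cutoffs must be non-empty", call. = FALSE)
  }
  reps <- .read_replicates(files, config)
  rows <- lapply(sort(cutoffs), function(cut) {
    res <- run_pipeline(reps, ld_cutoff = cut,
      min_replicates = min_replicates, mi = FALSE, config = config)
    unf <- count_by_class(res$dataset, unique = unique)
    mif <- count_by_class(apply_mi_filter(res$dataset)$dataset,
      unique = unique)
    unf$condition <- "unfiltered"
    mif$condition <- "mi_filtered"
    out <- rbind(unf, mif)
    out$cutoff <- cut
    out
  })
  res <- do.call(rbind, rows)
  res$decoy_fraction <- decoy_fraction(res$n_target, res$n_decoy)
  res$decoy_target_ratio <- decoy_target_ratio(res$n_target, res$n_decoy)
  res <- res[c("cutoff", "class", "condition", "n_target", "n_decoy",
    "decoy_fraction", "decoy_target_ratio")]
  rownames(res) <- NULL
  structure(res, class = c("sweep_result", "data.frame"))
}

#' @export
print.sweep_result <- function(x, digits = 4, ...) {
  cat("<sweep_result> target/decoy accounting over ld-score cutoffs\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Plot decoy-ratio curves from a sweep
#'
#' Draws the decoy/target ratio of inter-protein links against the ld-score
#' cutoff, unfiltered versus mi-filtered — the standard before/after view of
#' the filter's effect.
#'
#' @param x a `sweep_result` from [decoy_sweep()].
#' @param class link class to plot (default `"INTER"`).
#' @param measure `"decoy_target_ratio"` or `"decoy_fraction"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.sweep_result <- function(x, class = "INTER",
                              measure = c("decoy_target_ratio",
                                "decoy_fraction"), ...) {
  measure <- match.arg(measure)
  d <- x[x$class == class, , drop = FALSE]
  cuts <- sort(unique(d$cutoff))
  unf <- d[d$condition == "unfiltered", , drop = FALSE]
  mif <- d[d$condition == "mi_filtered", , drop = FALSE]
  y <- cbind(
    unfiltered = unf[[measure]][match(cuts, unf$cutoff)],
    mi_filtered = mif[[measure]][match(cuts, mif$cutoff)]
  )
  graphics::matplot(cuts, y, type = "b", pch = c(19, 17),
    col = c("firebrick", "steelblue"), lty = 1,
    xlab = "ld-score cutoff", ylab = gsub("_", " ", measure),
    main = sprintf("%s links: unfiltered vs mi-filtered", class), ...)
  graphics::legend("topright", legend = c("unfiltered", "mi-filtered"),
    col = c("firebrick", "steelblue"), pch = c(19, 17), lty = 1, bty = "n")
  invisible(x)
}

#' Write a sweep as tidy CSV or JSON
#'
#' The long-format CSV has one row per cutoff x class x condition and is
#' directly plottable; the JSON form nests the same rows under a `sweep` key
#' with the cutoffs echoed.
#'
#' @param sweep a `sweep_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
write_sweep_json <- function(sweep, path) {
  jsonlite::write_json(
    list(cutoffs = sort(unique(sweep$cutoff)), sweep = as.data.frame(sweep)),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
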