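mk_ds <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(raw_type = r[[1]], protein_a = r[[2]],
      protein_b = if (is.na(r[[3]])) NA_character_ else r[[3]],
      pos_a = as.integer(r[[4]]),
      pos_b = if (is.na(r[[5]])) NA_integer_ else as.integer(r[[5]]),
      ld_score = as.numeric(r[[6]]), replicate_id = "r1",
      stringsAsFactors = FALSE)))
  df$record_id <- sprintf("rec%d", seq_len(nrow(df)))
  normalize_types(annotate_decoys(link_dataset(df)))
}

test_that("eligibility requires at least one monolink or intralink", {
  ds <- mk_ds(
    list("monolink", "A", NA, 10, NA, 30),
    list("intralink", "B", "B", 5, 9, 30),
    list("xlink", "A", "C", 3, 7, 30))
  elig <- build_eligible_set(ds)
  expect_setequal(elig$proteins, c("A", "B"))
  expect_equal(elig$support$n_mono[elig$support$protein == "A"], 1L)
  expect_equal(elig$support$n_intra[elig$support$protein == "B"], 2L)
  # empty dataset -> empty set
  empty <- normalize_types(link_dataset(data.frame()))
  expect_length(build_eligible_set(empty)$proteins, 0L)
})

test_that("mi-filter keeps inter-links only when both partners are eligible", {
  ds <- mk_ds(
    list("monolink", "A", NA, 10, NA, 30),
    list("intralink", "B", "B", 5, 9, 30),
    list("xlink", "A", "B", 3, 7, 30),   # both eligible -> retained
    list("xlink", "A", "C", 4, 8, 30),   # C has no support -> removed
    list("xlink", "C", "D", 1, 2, 30))   # neither -> removed
  res <- apply_mi_filter(ds)
  expect_equal(res$report$n_input_inter, 3L)
  expect_equal(res$report$n_retained_inter, 1L)
  expect_equal(res$report$n_removed_inter, 2L)
  expect_setequal(res$report$removed_records$record_id, c("rec4", "rec5"))
  expect_equal(
    res$report$removed_records$ineligible_partners[
      res$report$removed_records$record_id == "rec5"], "C;D")
  # MONO and INTRA pass through untouched
  expect_true(all(c("rec1", "rec2") %in% res$dataset$record_id))
  # no INTER records -> no-op
  noint <- mk_ds(list("monolink", "A", NA, 1, NA, 30))
  r2 <- apply_mi_filter(noint)
  expect_equal(nrow(r2$dataset), nrow(noint))
  expect_equal(r2$report$n_removed_inter, 0L)
})

test_that("unnormalized input is a state error", {
  raw <- link_dataset(data.frame(record_id = "1", raw_type = "xlink",
    protein_a = "A", protein_b = "B", pos_a = 1L, pos_b = 2L,
    ld_score = 30, replicate_id = "r1"))
  expect_error(build_eligible_set(raw), "normalize_types")
  expect_error(apply_mi_filter(normalize_types(raw), structure(
    list(proteins = "A"), class = "eligible_set")), NA)
})

test_that("filter equals the brute-force membership oracle on random data", {
  set.seed(77)
  for (k in 1:8) {
    ds <- random_dataset(n = sample(100:1000, 1),
      n_proteins = sample(6:25, 1))
    res <- apply_mi_filter(ds)
    expect_setequal(res$dataset$record_id, oracle_mi_retained(ds))
    expect_setequal(build_eligible_set(ds)$proteins, oracle_eligible(ds))
    # report consistency
    expect_equal(res$report$n_input_inter,
      res$report$n_retained_inter + res$report$n_removed_inter)
    expect_equal(colSums(res$report$decoy_breakdown[c("before", "after")]),
      c(before = res$report$n_input_inter,
        after = res$report$n_retained_inter))
  }
})

test_that("mi-filter is idempotent and symmetric under endpoint swap", {
  set.seed(88)
  for (k in 1:5) {
    ds <- random_dataset(n = 300)
    once <- apply_mi_filter(ds)$dataset
    twice <- apply_mi_filter(once)$dataset
    expect_identical(as.data.frame(once), as.data.frame(twice))
    # swap the two sides of every two-protein record: retention unchanged
    sw <- as.data.frame(ds)
    two <- !is.na(sw$protein_b)
    tmp <- sw[two, c("protein_a", "pos_a")]
    sw$protein_a[two] <- sw$protein_b[two]
    sw$pos_a[two] <- sw$pos_b[two]
    sw$protein_b[two] <- tmp$protein_a
    sw$pos_b[two] <- tmp$pos_a
    swapped <- normalize_types(annotate_decoys(
      link_dataset(sw, source_files = source_files(ds))))
    expect_setequal(apply_mi_filter(swapped)$dataset$record_id,
      once$record_id)
  }
})

test_that("pipeline equals manual stage composition and handles no-op settings", {
  set.seed(99)
  dir <- withr::local_tempdir()
  sim <- synth_generate(synth_config(seed = 5, n_proteins_present = 20,
    n_proteins_absent = 20), dir = dir)
  files <- sim$files
  res <- run_pipeline(files, ld_cutoff = 25, min_replicates = 2, mi = TRUE)
  # manual composition in the stated order
  reps <- lapply(files, read_xquest_tsv)
  reps <- lapply(reps, function(d) d[d$ld_score >= 25, , drop = FALSE])
  reps <- lapply(reps, function(d) {
    rownames(d) <- NULL
    link_dataset(as.data.frame(d))
  })
  man <- concat_datasets(reps)
  man <- filter_by_replicates(man, 2)
  man <- annotate_decoys(man)
  man <- normalize_types(man)
  man <- apply_mi_filter(man, build_eligible_set(man))$dataset
  expect_equal(as.data.frame(res$dataset), as.data.frame(man),
    ignore_attr = TRUE)
  # cutoff below all scores, mi off -> concatenation of the inputs
  all_in <- run_pipeline(files, ld_cutoff = -Inf, mi = FALSE)
  expect_equal(nrow(all_in$dataset), sum(sapply(sim$datasets, nrow)))
  # cutoff above all scores -> empty dataset, empty report
  none <- run_pipeline(files, ld_cutoff = 1e6, mi = TRUE)
  expect_equal(nrow(none$dataset), 0L)
  expect_equal(none$report$n_input_inter, 0L)
  expect_error(run_pipeline(character(0)), "at least one")
})

test_that("stage errors are tagged with the stage name", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "only.tsv")
  write_xq_fixture(f, id = 1, type = "monolink", p1 = "P1", p2 = "",
    pos1 = 1, pos2 = "", score = 30)
  expect_error(run_pipeline(f, min_replicates = 5),
    "\\[stage replicate_filter\\]")
})
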