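test_that("per-class target/decoy counts match a brute-force tally", {
  set.seed(60)
  ds <- random_dataset(n = 200)
  counts <- count_by_class(ds)
  for (cl in c("MONO", "INTRA", "INTER")) {
    tgt <- 0L; dec <- 0L
    for (i in seq_len(nrow(ds))) {
      if (ds$link_type[i] != cl) next
      if (ds$decoy_class[i] %in% c("TD", "DD")) dec <- dec + 1L
      else tgt <- tgt + 1L
    }
    expect_equal(counts$n_target[counts$class == cl], tgt)
    expect_equal(counts$n_decoy[counts$class == cl], dec)
  }
  expect_equal(sum(counts$n_target) + sum(counts$n_decoy), nrow(ds))
  # empty dataset -> all zeros
  e <- count_by_class(normalize_types(link_dataset(data.frame())))
  expect_true(all(e$n_target == 0L & e$n_decoy == 0L))
})

test_that("unique counting collapses redundant identifications of a site", {
  df <- data.frame(
    record_id = as.character(1:3), raw_type = "xlink",
    protein_a = c("A", "B", "A"), protein_b = c("B", "A", "C"),
    pos_a = c(3L, 7L, 1L), pos_b = c(7L, 3L, 2L),
    ld_score = 30, replicate_id = c("r1", "r2", "r1"),
    stringsAsFactors = FALSE)
  ds <- normalize_types(annotate_decoys(
    link_dataset(df, source_files = c("r1", "r2"))))
  expect_equal(count_by_class(ds)$n_target[3], 3L)
  expect_equal(count_by_class(ds, unique = TRUE)$n_target[3], 2L)
})

test_that("decoy fraction and decoy/target ratio follow their definitions", {
  expect_equal(decoy_fraction(90, 10), 0.10)
  expect_equal(decoy_fraction(0, 5), 1.0)
  expect_equal(decoy_fraction(7, 3), 0.3)
  expect_true(is.na(decoy_fraction(0, 0)))   # undefined, never 0
  expect_true(is.na(decoy_target_ratio(0, 5)))
  expect_error(decoy_fraction(-1, 2))
})

test_that("sweep counts are cutoff-monotone and the two ratios are consistent", {
  set.seed(61)
  sim <- synth_generate(synth_config(seed = 17, n_proteins_present = 25,
    n_proteins_absent = 25))
  sw <- decoy_sweep(sim$datasets, cutoffs = c(20, 25, 28, 32))
  unf <- sw[sw$condition == "unfiltered", ]
  for (cl in c("MONO", "INTRA", "INTER")) {
    tot <- unf$n_target[unf$class == cl] + unf$n_decoy[unf$class == cl]
    expect_true(all(diff(tot[order(unf$cutoff[unf$class == cl])]) <= 0))
  }
  ok <- !is.na(sw$decoy_fraction) & !is.na(sw$decoy_target_ratio)
  expect_equal(sw$decoy_target_ratio[ok],
    sw$decoy_fraction[ok] / (1 - sw$decoy_fraction[ok]))
  # per-cutoff class totals equal the pipeline dataset size (unfiltered)
  for (cut in c(20, 28)) {
    n <- nrow(run_pipeline(sim$datasets, ld_cutoff = cut, mi = FALSE)$dataset)
    expect_equal(sum(unf$n_target[unf$cutoff == cut]) +
      sum(unf$n_decoy[unf$cutoff == cut]), n)
  }
})

test_that("a single no-op cutoff reproduces count_by_class of the concatenation", {
  set.seed(62)
  sim <- synth_generate(synth_config(seed = 3, n_proteins_present = 15,
    n_proteins_absent = 10, n_replicates = 2))
  sw <- decoy_sweep(sim$datasets, cutoffs = -Inf)
  raw <- normalize_types(annotate_decoys(concat_datasets(sim$datasets)))
  direct <- count_by_class(raw)
  unf <- sw[sw$condition == "unfiltered", ]
  expect_equal(unf$n_target[match(direct$class, unf$class)], direct$n_target)
  expect_equal(unf$n_decoy[match(direct$class, unf$class)], direct$n_decoy)
  expect_error(decoy_sweep(sim$datasets, cutoffs = numeric(0)), "non-empty")
})

test_that("sweep equals run_pipeline + count_by_class composed manually", {
  set.seed(63)
  sim <- synth_generate(synth_config(seed = 9, n_proteins_present = 20,
    n_proteins_absent = 20))
  sw <- decoy_sweep(sim$datasets, cutoffs = 25)
  manual_unf <- count_by_class(
    run_pipeline(sim$datasets, ld_cutoff = 25, mi = FALSE)$dataset)
  manual_mif <- count_by_class(
    run_pipeline(sim$datasets, ld_cutoff = 25, mi = TRUE)$dataset)
  for (cl in c("MONO", "INTRA", "INTER")) {
    expect_equal(
      sw$n_decoy[sw$class == cl & sw$condition == "unfiltered"],
      manual_unf$n_decoy[manual_unf$class == cl])
    expect_equal(
      sw$n_target[sw$class == cl & sw$condition == "mi_filtered"],
      manual_mif$n_target[manual_mif$class == cl])
  }
})

test_that("no decoys in, zero decoy fraction out", {
  set.seed(64)
  sim <- synth_generate(synth_config(seed = 2, p_td = 0, p_dd = 0,
    p_decoy_monointra = 0, n_proteins_present = 15, n_proteins_absent = 5))
  sw <- decoy_sweep(sim$datasets, cutoffs = c(20, 25))
  expect_true(all(sw$n_decoy == 0L))
  expect_true(all(sw$decoy_fraction[!is.na(sw$decoy_fraction)] == 0))
})

test_that("sweep CSV/JSON exports carry the tidy long format", {
  set.seed(65)
  sim <- synth_generate(synth_config(seed = 4, n_proteins_present = 10,
    n_proteins_absent = 5, n_replicates = 2))
  sw <- decoy_sweep(sim$datasets, cutoffs = c(20, 28))
  csv <- tempfile(fileext = ".csv")
  write_sweep_csv(sw, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), 2 * 3 * 2)  # cutoffs x classes x conditions
  expect_named(back, c("cutoff", "class", "condition", "n_target",
    "n_decoy", "decoy_fraction", "decoy_target_ratio"))
  js <- tempfile(fileext = ".json")
  write_sweep_json(sw, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$cutoffs, c(20, 28))
  expect_equal(nrow(parsed$sweep), nrow(back))
})
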