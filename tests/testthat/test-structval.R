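toy_atoms <- function() {
  data.frame(
    chain = c("A", "A", "B", "B", "C"),
    resno = c(1L, 2L, 5L, 6L, 5L),
    x = c(0, 3, 3, 40, 0),
    y = c(0, 4, 4, 0, 0),
    z = c(0, 0, 10, 0, 7),
    stringsAsFactors = FALSE)
}

toy_model <- function(chain_map = list(PA = "A", PB = c("B", "C")),
                      offsets = NULL) {
  load_structure(write_toy_pdb(toy_atoms()), chain_map, offsets)
}

inter_rec <- function(pa, pb, xa, xb, id = "rec1") {
  list(record_id = id, link_type = "INTER", protein_a = pa, protein_b = pb,
    pos_a = xa, pos_b = xb)
}

test_that("structure loading restricts to mapped chains and flags missing ones", {
  m <- toy_model()
  expect_equal(nrow(m$coords), 5L)
  m2 <- load_structure(write_toy_pdb(toy_atoms()), list(PA = "A"))
  expect_equal(sort(unique(m2$coords$chain)), "A")
  expect_error(load_structure(write_toy_pdb(toy_atoms()),
    list(PA = "A", PZ = "Z")), "Z")
})

test_that("PDB and mmCIF encodings of the same model load identically", {
  atoms <- toy_atoms()
  cm <- list(PA = "A", PB = c("B", "C"))
  m_pdb <- load_structure(write_toy_pdb(atoms), cm)
  m_cif <- load_structure(write_toy_cif(atoms), cm)
  expect_equal(m_pdb$coords, m_cif$coords)
})

test_that("link distance is the closed-form Euclidean distance", {
  m <- toy_model(list(PA = "A", PB = "C"))
  # (0,0,0) vs (3,4,0): the 3-4-5 triangle
  m345 <- toy_model(list(PA = "A"))
  d <- link_distance(
    list(record_id = "x", link_type = "INTRA", protein_a = "PA",
      protein_b = "PA", pos_a = 1L, pos_b = 2L), m345)
  expect_equal(d$min_distance, 5.0, tolerance = 1e-12)
  expect_true(d$mappable && d$satisfied)
  # degenerate self-pair -> exactly 0
  d0 <- link_distance(
    list(record_id = "x", link_type = "INTRA", protein_a = "PA",
      protein_b = "PA", pos_a = 1L, pos_b = 1L), m345)
  expect_identical(d0$min_distance, 0)
})

test_that("multiple chain copies resolve to the minimum distance", {
  # PB maps to chains B and C; residue 5 sits at (3,4,10) on B and (0,0,7) on C
  m <- toy_model()
  d <- link_distance(inter_rec("PA", "PB", 1L, 5L), m)
  exhaustive <- min(sqrt(sum(c(3, 4, 10)^2)), sqrt(sum(c(0, 0, 7)^2)))
  expect_equal(d$min_distance, exhaustive, tolerance = 1e-12)
  # dropping the closer copy can only increase the distance
  m1 <- toy_model(list(PA = "A", PB = "B"))
  d1 <- link_distance(inter_rec("PA", "PB", 1L, 5L), m1)
  expect_gte(d1$min_distance, d$min_distance)
})

test_that("distances are symmetric and rigid-motion invariant", {
  set.seed(70)
  # 3-decimal coordinates: the PDB text format is the fixture's ground truth
  atoms <- data.frame(
    chain = rep(c("A", "B"), each = 4),
    resno = rep(1:4, 2),
    x = round(runif(8, -20, 20), 3), y = round(runif(8, -20, 20), 3),
    z = round(runif(8, -20, 20), 3))
  cm <- list(PA = "A", PB = "B")
  m <- load_structure(write_toy_pdb(atoms), cm)
  # random rotation (QR of a random matrix) + translation
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_); if (det(R) < 0) R[, 1] <- -R[, 1]
  t0 <- c(5, -3, 11)
  moved <- atoms
  xyz <- t(R %*% t(as.matrix(atoms[c("x", "y", "z")])) + t0)
  # re-round: the text format carries 3 decimals
  moved$x <- round(xyz[, 1], 3); moved$y <- round(xyz[, 2], 3)
  moved$z <- round(xyz[, 3], 3)
  mm <- load_structure(write_toy_pdb(moved), cm)
  for (i in 1:4) {
    d_ab <- link_distance(inter_rec("PA", "PB", i, 5L - i), m)
    d_ba <- link_distance(inter_rec("PB", "PA", 5L - i, i), m)
    d_mv <- link_distance(inter_rec("PA", "PB", i, 5L - i), mm)
    expect_equal(d_ab$min_distance, d_ba$min_distance, tolerance = 1e-9)
    expect_equal(d_ab$min_distance, d_mv$min_distance, tolerance = 1e-3)
  }
})

test_that("monolinks, unmapped residues and offsets are handled", {
  m <- toy_model()
  expect_error(link_distance(
    list(record_id = "m", link_type = "MONO", protein_a = "PA",
      protein_b = NA, pos_a = 1L, pos_b = NA), m), "monolink")
  d <- link_distance(inter_rec("PA", "PB", 99L, 5L), m)
  expect_false(d$mappable)
  expect_true(is.na(d$min_distance) && is.na(d$satisfied))
  # numbering offset: sequence position 11 = structure residue 1 on chain A
  mo <- toy_model(offsets = c(A = -10))
  do <- link_distance(inter_rec("PA", "PB", 11L, 5L), mo)
  expect_true(do$mappable)
  expect_equal(do$min_distance, 7, tolerance = 1e-12)
})

test_that("satisfaction summary matches a brute-force recount on toy geometry", {
  set.seed(71)
  n <- 12
  atoms <- data.frame(chain = "A", resno = 1:(2 * n),
    x = round(runif(2 * n, 0, 60), 3), y = round(runif(2 * n, 0, 60), 3),
    z = 0)
  m <- load_structure(write_toy_pdb(atoms), list(PA = "A"))
  df <- data.frame(
    record_id = sprintf("l%d", 1:n), raw_type = "intralink",
    protein_a = "PA", protein_b = "PA",
    pos_a = seq(1L, 2L * n, by = 2L), pos_b = seq(2L, 2L * n, by = 2L),
    ld_score = 30, replicate_id = "r1", stringsAsFactors = FALSE)
  ds <- normalize_types(link_dataset(df))
  ds$pos_a[n] <- 999L  # one unmappable link
  res <- link_distances(ds, m, cutoff = 35)
  n_sat <- 0L; n_map <- 0L
  for (i in 1:(n - 1)) {
    dd <- sqrt(sum((atoms[atoms$resno == ds$pos_a[i], c("x", "y", "z")] -
      atoms[atoms$resno == ds$pos_b[i], c("x", "y", "z")])^2))
    n_map <- n_map + 1L
    if (dd <= 35) n_sat <- n_sat + 1L
    expect_equal(res$min_distance[i], dd, tolerance = 1e-9)
  }
  s <- satisfaction_summary(res, 35)
  expect_equal(s$n_mappable, n_map)
  expect_equal(s$n_satisfied, n_sat)
  expect_equal(s$n_unmappable, 1L)
  expect_equal(s$fraction, n_sat / n_map)
  # all links unmappable -> fraction absent
  none <- satisfaction_summary(
    data.frame(min_distance = NA_real_, mappable = FALSE), 35)
  expect_equal(none$n_mappable, 0L)
  expect_true(is.na(none$fraction))
})
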