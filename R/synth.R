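#' Configuration of the synthetic XL-MS dataset generator
#'
#' The generator emulates the observation process behind cross-link
#' identification tables: a mixture of proteins actually present in the
#' sample (with log-normal abundances) and proteins that are merely in the
#' search database; link formation rates ordered monolink >= intralink >>
#' interlink and scaled by abundance; abundance-dependent detectability per
#' replicate; spurious inter-protein identifications biased toward absent
#' proteins; decoy records re-emitted symmetrically from targets; and
#' class-conditional identification scores on the ld-score scale, with true
#' links scoring higher than false and decoy ones.
#'
#' Scores: true links draw from Normal(`score_true_mean`, `score_true_sd`);
#' false/decoy monolinks and intralinks from Normal(`score_false_mean`,
#' `score_false_sd`); false/decoy *inter*-links from a two-component mixture
#' that adds a high-scoring component (weight
#' `score_inter_false_hi_prob`, mean `score_inter_false_hi_mean`) — false
#' inter-protein identifications are the error class that persists at
#' stringent score cutoffs, so the generator gives them a heavy right tail.
#' All scores are truncated at 0.
#'
#' @param n_proteins_present proteins actually in the sample (default 40).
#' @param n_proteins_absent proteins only in the search database (default 60).
#' @param abundance_sdlog log-normal abundance spread (meanlog is set to
#'   -sdlog^2/2 so mean abundance is 1).
#' @param protein_length_range residue-count range proteins are drawn from.
#' @param rate_mono,rate_intra expected true mono / intra link sites per
#'   present protein per unit abundance (defaults 5 and 2.5).
#' @param rate_inter expected true inter-protein link sites per present
#'   protein (default 0.5); pairs are sampled proportional to the product of
#'   the partners' abundances.
#' @param false_inter_rate expected spurious inter-protein records per
#'   database protein per replicate (default 0.8).
#' @param absent_bias probability each endpoint of a spurious inter-link is
#'   drawn from the absent pool (default 0.85).
#' @param p_td,p_dd probability an emitted inter record is re-emitted as a
#'   target-decoy / decoy-decoy record (defaults 0.12 / 0.06).
#' @param p_decoy_monointra probability an emitted mono/intra record is
#'   re-emitted as its decoy version (default 0.08).
#' @param detect_scale half-saturation constant of the detection curve
#'   p(a) = a / (a + detect_scale) (default 0.4); inter-links use the
#'   geometric mean of the two partners' detection probabilities.
#' @param score_true_mean,score_true_sd,score_false_mean,score_false_sd,score_inter_false_hi_mean,score_inter_false_hi_sd,score_inter_false_hi_prob
#'   ld-score model, see Details.
#' @param n_replicates biological replicates / output files (default 3).
#' @param leak_rate probability an absent protein nevertheless emits one
#'   monolink site (default 0: absent proteins emit no mono/intra support at
#'   all, the idealization under which the mi-filter has perfect recall).
#' @param ensure_support if `TRUE`, guarantee every present protein has at
#'   least one mono/intra record in the generated dataset (adds one
#'   true-scored monolink where detection left none).
#' @param decoy_prefix accession prefix for generated decoy records.
#' @param seed default RNG seed used by [synth_generate()].
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_proteins_present = 40, n_proteins_absent = 60,
                         abundance_sdlog = 0.7,
                         protein_length_range = c(150L, 800L),
                         rate_mono = 5, rate_intra = 2.5, rate_inter = 0.5,
                         false_inter_rate = 0.8, absent_bias = 0.85,
                         p_td = 0.12, p_dd = 0.06, p_decoy_monointra = 0.08,
                         detect_scale = 0.4,
                         score_true_mean = 30, score_true_sd = 4,
                         score_false_mean = 18, score_false_sd = 4,
                         score_inter_false_hi_mean = 29,
                         score_inter_false_hi_sd = 4,
                         score_inter_false_hi_prob = 0.35,
                         n_replicates = 3, leak_rate = 0,
                         ensure_support = FALSE,
                         decoy_prefix = "decoy_", seed = NULL) {
  cfg <- as.list(environment())
  rates <- c(rate_mono, rate_intra, rate_inter, false_inter_rate)
  if (any(rates < 0)) {
    stop("synth_config: rates must be non-negative", call. = FALSE)
  }
  probs <- c(absent_bias, p_td, p_dd, p_decoy_monointra, leak_rate)
  if (any(probs < 0 | probs > 1) || p_td + p_dd > 1) {
    stop("synth_config: probabilities must lie in [0, 1] (and p_td + p_dd <= 1)",
      call. = FALSE)
  }
  if (n_proteins_present < 1 || n_replicates < 1) {
    stop("synth_config: need >= 1 present protein and >= 1 replicate",
      call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

# Normal truncated at zero via inverse-CDF sampling.
.rtrunc0 <- function(n, mean, sd) {
  if (n == 0L) return(numeric())
  u <- stats::runif(n, stats::pnorm(0, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

.score_inter_false <- function(n, cfg) {
  if (n == 0L) return(numeric())
  hi <- stats::runif(n) < cfg$score_inter_false_hi_prob
  out <- numeric(n)
  out[!hi] <- .rtrunc0(sum(!hi), cfg$score_false_mean, cfg$score_false_sd)
  out[hi] <- .rtrunc0(sum(hi), cfg$score_inter_false_hi_mean,
    cfg$score_inter_false_hi_sd)
  out
}

#' Generate a synthetic XL-MS identification dataset with ground truth
#'
#' Produces one xQuest-dialect table per biological replicate plus a
#' record-level ground-truth table labelling every identification true or
#' false and every protein present or absent. With a fixed seed the output
#' is fully deterministic.
#'
#' @param config a [synth_config()].
#' @param dir if non-`NULL`, write one TSV per replicate (plus
#'   `truth.csv` and `proteins.csv`) into this directory.
#' @param seed RNG seed; overrides `config$seed`.
#' @return list with `datasets` (per-replicate [link_dataset()]s), `files`
#'   (paths, when `dir` was given), `truth` (data frame: `record_id`,
#'   `replicate_id`, `link_type`, `is_true`, `is_decoy`), `proteins`
#'   (`accession`, `present`, `abundance`, `length`), `sites` (master table
#'   of true link sites with per-replicate detection probabilities, for
#'   checking empirical counts against their expectations), and `config`.
#' @export
synth_generate <- function(config = synth_config(), dir = NULL,
                           seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  present <- sprintf("PRES%03d", seq_len(cfg$n_proteins_present))
  absent <- if (cfg$n_proteins_absent > 0) {
    sprintf("ABS%03d", seq_len(cfg$n_proteins_absent))
  } else character()
  all_prot <- c(present, absent)
  lens <- stats::setNames(
    sample(seq(cfg$protein_length_range[1], cfg$protein_length_range[2]),
      length(all_prot), replace = TRUE), all_prot)
  meanlog <- -cfg$abundance_sdlog^2 / 2
  abund <- stats::setNames(
    stats::rlnorm(length(present), meanlog, cfg$abundance_sdlog), present)
  pdet <- abund / (abund + cfg$detect_scale)

  # --- master tables of true link sites ---------------------------------
  rpos <- function(prot, n = length(prot)) {
    vapply(prot, function(p) sample.int(lens[[p]], 1L), integer(1))
  }
  n_mono <- stats::rpois(length(present), cfg$rate_mono * abund)
  mono_sites <- data.frame(
    protein = rep(present, n_mono), stringsAsFactors = FALSE)
  mono_sites$pos <- rpos(mono_sites$protein)
  mono_sites$p_detect <- pdet[mono_sites$protein]
  if (cfg$leak_rate > 0 && length(absent)) {
    leak <- absent[stats::runif(length(absent)) < cfg$leak_rate]
    if (length(leak)) {
      mono_sites <- rbind(mono_sites, data.frame(protein = leak,
        pos = rpos(leak), p_detect = 0.5, stringsAsFactors = FALSE))
    }
  }
  n_intra <- stats::rpois(length(present), cfg$rate_intra * abund)
  intra_sites <- data.frame(
    protein = rep(present, n_intra), stringsAsFactors = FALSE)
  intra_sites$pos_a <- rpos(intra_sites$protein)
  intra_sites$pos_b <- rpos(intra_sites$protein)
  intra_sites$p_detect <- pdet[intra_sites$protein]
  n_inter <- stats::rpois(1L, cfg$rate_inter * length(present))
  inter_sites <- if (n_inter > 0 && length(present) >= 2) {
    pairs <- utils::combn(present, 2)
    w <- abund[pairs[1, ]] * abund[pairs[2, ]]
    idx <- sample.int(ncol(pairs), n_inter, replace = TRUE, prob = w)
    data.frame(protein_a = pairs[1, idx], protein_b = pairs[2, idx],
      stringsAsFactors = FALSE)
  } else {
    data.frame(protein_a = character(), protein_b = character(),
      stringsAsFactors = FALSE)
  }
  if (nrow(inter_sites)) {
    inter_sites$pos_a <- rpos(inter_sites$protein_a)
    inter_sites$pos_b <- rpos(inter_sites$protein_b)
    inter_sites$p_detect <-
      sqrt(pdet[inter_sites$protein_a] * pdet[inter_sites$protein_b])
  } else {
    inter_sites$pos_a <- integer(); inter_sites$pos_b <- integer()
    inter_sites$p_detect <- numeric()
  }

  # --- per-replicate emission -------------------------------------------
  emit_rep <- function(r) {
    rep_id <- sprintf("rep%d", r)
    rows <- list()
    add <- function(raw_type, link_type, pa, pb, xa, xb, score, is_true) {
      n <- length(pa)
      if (n == 0L) return()
      rows[[length(rows) + 1L]] <<- data.frame(
        raw_type = raw_type, link_type_truth = link_type,
        protein_a = pa, protein_b = pb, pos_a = xa, pos_b = xb,
        ld_score = score, is_true = is_true, stringsAsFactors = FALSE)
    }
    det <- function(sites) sites[stats::runif(nrow(sites)) < sites$p_detect, ,
      drop = FALSE]
    m <- det(mono_sites)
    add("monolink", "MONO", m$protein, rep(NA_character_, nrow(m)),
      m$pos, rep(NA_integer_, nrow(m)),
      .rtrunc0(nrow(m), cfg$score_true_mean, cfg$score_true_sd), TRUE)
    i <- det(intra_sites)
    add("intralink", "INTRA", i$protein, i$protein, i$pos_a, i$pos_b,
      .rtrunc0(nrow(i), cfg$score_true_mean, cfg$score_true_sd), TRUE)
    x <- det(inter_sites)
    add("xlink", "INTER", x$protein_a, x$protein_b, x$pos_a, x$pos_b,
      .rtrunc0(nrow(x), cfg$score_true_mean, cfg$score_true_sd), TRUE)
    # spurious inter identifications, biased toward absent proteins
    n_false <- stats::rpois(1L, cfg$false_inter_rate * length(all_prot))
    if (n_false > 0) {
      pick <- function(n) {
        from_abs <- stats::runif(n) < cfg$absent_bias & length(absent) > 0
        out <- character(n)
        out[from_abs] <- sample(absent, sum(from_abs), replace = TRUE)
        out[!from_abs] <- sample(present, sum(!from_abs), replace = TRUE)
        out
      }
      fa <- pick(n_false); fb <- pick(n_false)
      clash <- fa == fb
      while (any(clash)) {
        fb[clash] <- pick(sum(clash))
        clash <- fa == fb
      }
      add("xlink", "INTER", fa, fb, rpos(fa), rpos(fb),
        .score_inter_false(n_false, cfg), FALSE)
    }
    emitted <- if (length(rows)) do.call(rbind, rows) else NULL
    # decoy re-emission, symmetric to targets
    if (!is.null(emitted) && nrow(emitted)) {
      dec <- list()
      inter <- emitted[emitted$link_type_truth == "INTER", , drop = FALSE]
      if (nrow(inter)) {
        u <- stats::runif(nrow(inter))
        td <- inter[u < cfg$p_td, , drop = FALSE]
        dd <- inter[u >= cfg$p_td & u < cfg$p_td + cfg$p_dd, , drop = FALSE]
        if (nrow(td)) {
          flip <- stats::runif(nrow(td)) < 0.5
          td$protein_a[flip] <- paste0(cfg$decoy_prefix, td$protein_a[flip])
          td$protein_b[!flip] <- paste0(cfg$decoy_prefix, td$protein_b[!flip])
        }
        if (nrow(dd)) {
          dd$protein_a <- paste0(cfg$decoy_prefix, dd$protein_a)
          dd$protein_b <- paste0(cfg$decoy_prefix, dd$protein_b)
        }
        both <- rbind(td, dd)
        if (nrow(both)) {
          both$ld_score <- .score_inter_false(nrow(both), cfg)
          both$is_true <- FALSE
          dec[[length(dec) + 1L]] <- both
        }
      }
      mi <- emitted[emitted$link_type_truth %in% c("MONO", "INTRA"), ,
        drop = FALSE]
      if (nrow(mi)) {
        dmi <- mi[stats::runif(nrow(mi)) < cfg$p_decoy_monointra, ,
          drop = FALSE]
        if (nrow(dmi)) {
          dmi$protein_a <- paste0(cfg$decoy_prefix, dmi$protein_a)
          dmi$protein_b <- ifelse(is.na(dmi$protein_b), NA_character_,
            paste0(cfg$decoy_prefix, dmi$protein_b))
          dmi$ld_score <- .rtrunc0(nrow(dmi), cfg$score_false_mean,
            cfg$score_false_sd)
          dmi$is_true <- FALSE
          dec[[length(dec) + 1L]] <- dmi
        }
      }
      if (length(dec)) emitted <- rbind(emitted, do.call(rbind, dec))
    }
    if (is.null(emitted)) {
      emitted <- data.frame(raw_type = character(),
        link_type_truth = character(), protein_a = character(),
        protein_b = character(), pos_a = integer(), pos_b = integer(),
        ld_score = numeric(), is_true = logical(), stringsAsFactors = FALSE)
    }
    emitted$replicate_id <- rep_id
    emitted
  }
  reps <- lapply(seq_len(cfg$n_replicates), emit_rep)

  # guaranteed mono/intra support regime
  if (cfg$ensure_support) {
    seen <- unlist(lapply(reps, function(e)
      e$protein_a[e$link_type_truth %in% c("MONO", "INTRA") & e$is_true]))
    missing <- setdiff(present, seen)
    if (length(missing)) {
      reps[[1L]] <- rbind(reps[[1L]], data.frame(
        raw_type = "monolink", link_type_truth = "MONO",
        protein_a = missing, protein_b = NA_character_,
        pos_a = rpos(missing), pos_b = NA_integer_,
        ld_score = .rtrunc0(length(missing), cfg$score_true_mean,
          cfg$score_true_sd),
        is_true = TRUE, replicate_id = reps[[1L]]$replicate_id[1],
        stringsAsFactors = FALSE))
      if (is.na(reps[[1L]]$replicate_id[1])) reps[[1L]]$replicate_id <- "rep1"
    }
  }

  datasets <- lapply(seq_along(reps), function(r) {
    e <- reps[[r]]
    e$record_id <- if (nrow(e)) sprintf("rep%d_%05d", r, seq_len(nrow(e)))
      else character()
    ds <- link_dataset(e[c("record_id", "raw_type", "protein_a", "protein_b",
      "pos_a", "pos_b", "ld_score", "replicate_id")],
      source_files = sprintf("rep%d", r),
      metadata = list(generator = "synth", replicate = r))
    annotate_decoys(ds, cfg$decoy_prefix)
  })
  truth <- do.call(rbind, lapply(seq_along(reps), function(r) {
    e <- reps[[r]]
    data.frame(
      record_id = if (nrow(e)) sprintf("rep%d_%05d", r, seq_len(nrow(e)))
        else character(),
      replicate_id = e$replicate_id, link_type = e$link_type_truth,
      is_true = e$is_true,
      is_decoy = startsWith(e$protein_a, cfg$decoy_prefix) |
        (!is.na(e$protein_b) & startsWith(e$protein_b, cfg$decoy_prefix)),
      stringsAsFactors = FALSE)
  }))
  proteins <- data.frame(
    accession = all_prot,
    present = all_prot %in% present,
    abundance = c(abund, rep(NA_real_, length(absent))),
    length = as.integer(lens), stringsAsFactors = FALSE)
  sites <- rbind(
    data.frame(link_type = "MONO", protein_a = mono_sites$protein,
      protein_b = NA_character_, p_detect = mono_sites$p_detect,
      stringsAsFactors = FALSE),
    data.frame(link_type = "INTRA", protein_a = intra_sites$protein,
      protein_b = intra_sites$protein, p_detect = intra_sites$p_detect,
      stringsAsFactors = FALSE),
    data.frame(link_type = "INTER", protein_a = inter_sites$protein_a,
      protein_b = inter_sites$protein_b, p_detect = inter_sites$p_detect,
      stringsAsFactors = FALSE))
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- vapply(seq_along(datasets), function(r) {
      p <- file.path(dir, sprintf("rep%d.tsv", r))
      write_dataset(datasets[[r]], p)
      p
    }, character(1))
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    utils::write.csv(proteins, file.path(dir, "proteins.csv"),
      row.names = FALSE)
  }
  list(datasets = datasets, files = files, truth = truth,
    proteins = proteins, sites = sites, config = cfg)
}

#' Recall of true inter-protein links after filtering
#'
#' Fraction of ground-truth-true inter-protein records of the generated
#' input that are still present (by `record_id` and replicate) in a filtered
#' dataset — the sensitivity of the filter on synthetic data.
#'
#' @param ds filtered [link_dataset()].
#' @param truth ground-truth table from [synth_generate()].
#' @return recall in `[0, 1]` (`NA` if the truth holds no true inter
#'   records).
#' @export
true_inter_recall <- function(ds, truth) {
  tr <- truth[truth$is_true & truth$link_type == "INTER", , drop = FALSE]
  if (!nrow(tr)) return(NA_real_)
  key <- function(d) paste(d$replicate_id, d$record_id)
  mean(key(tr) %in% key(as.data.frame(ds)))
}
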