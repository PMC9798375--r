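---
title: "Mono-/intralink filtering of cross-link identifications: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mono-/intralink filtering of cross-link identifications: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifilter)
```

## Rationale

Cross-linking mass spectrometry identifies three classes of product:
monolinks (the linker reacted on one side and hydrolyzed on the other),
intra-protein cross-links, and inter-protein cross-links. Only the last
class carries protein–protein interaction information, and it is also the
class with the worst error characteristics: in target–decoy accounting,
decoy inter-links persist at score cutoffs where decoy monolinks and
intralinks are already negligible.

The asymmetry the filter exploits is chemical and statistical at once.
For a protein present at detectable abundance, the number of opportunities
to form a monolink or an intralink (any reactive residue, any intramolecular
residue pair within the linker's span) vastly exceeds the number of
opportunities to form a detectable inter-link (a residue pair across a
physical interface). So a protein that is genuinely observable by XL-MS in
a sample essentially always leaves mono/intra evidence. Conversely, an
inter-link naming a protein with *no* such evidence is more plausibly a
mis-assigned spectrum than the sole trace of a real interaction — a
proposition the decoy counts bear out.

The filter therefore builds the **eligible set** — all proteins with at
least one monolink or intra-protein link in the dataset — and removes
every inter-link with at least one ineligible partner. It is a binary,
pre-FDR filter: no partial weighting, no score adjustment, and estimator
choice downstream is unaffected.

## Pipeline order

`run_pipeline()` fixes the stage order:

1. read each replicate file;
2. ld-score cutoff, per file;
3. concatenation across replicates;
4. (optional) replicate-consistency filter on cross-linking sites;
5. decoy annotation from accession prefixes;
6. link-type normalization to MONO / INTRA / INTER;
7. eligible-set construction;
8. (optional, `mi = TRUE`) the mi-filter.

Two consequences are deliberate. *Eligibility is assessed at the active
score cutoff*: mono/intra support that scores below the cutoff does not
license an inter-link, because support the analyst would not accept as an
identification should not rescue one. And *eligibility is computed on the
concatenated dataset*, not per replicate: the filter asks whether the
protein is addressable in the experiment, not in each injection.

When the replicate filter is active it runs **before** eligibility, so
mono/intra support must itself be replicate-consistent. Site identity for
replicate counting is the canonical residue-pair key (accession:position
pairs, sorted, plus link type), which is invariant under swapping the two
sides of a record; a `pair_level` option relaxes identity to the unordered
protein pair.

## Decisions on ambiguous inputs

- **Looplinks** (linker reacted twice within one peptide) normalize to
  INTRA by default: they join two residues of one polypeptide and are
  exactly the kind of evidence the filter needs — the protein is present
  and cross-linkable. Published pipelines differ in whether looplinks are
  kept at all, so the mapping is overridable (map the label to `DROP`).
- **Same-accession "inter" labels** (homodimer ambiguity): without
  isotope-labeling or stoichiometry evidence, a cross-link between two
  copies of one accession cannot be distinguished from an intramolecular
  link, so the conservative default reclassifies it INTRA
  (`same_protein_inter = "INTER"` keeps the label).
- **Decoy support counts.** Decoy accessions become eligible through decoy
  monolinks/intralinks exactly as targets do. The alternative — requiring
  target support — would deplete decoy inter-links by construction and
  bias the post-filter decoy proportion downward as an error estimate.
  Symmetric treatment keeps the decoy ratio interpretable after filtering.
- **Decoy classes.** A record is TT, TD or DD according to whether none,
  some, or all of its accessions match a decoy prefix. A decoy monolink
  involves only decoy sequence and is classed DD, preserving the exact
  invariant `is_decoy ⇔ class ∈ {TD, DD}`.
- **Both decoy-ratio conventions** are always reported side by side:
  `decoy_fraction` = decoy/(target+decoy) and `decoy_target_ratio` =
  decoy/target, related by ratio = fraction/(1 − fraction). Undefined
  values (empty class; zero targets) are `NA`, never 0 — a class with no
  observations has no error rate.
- **Counting level.** Counts are record-level (redundant identifications)
  by default, with `unique = TRUE` collapsing to unique sites; both are
  offered because published tallies use both conventions.

## Structure validation

`link_distances()` maps INTER/INTRA records onto a structure and reports
the Euclidean **Cα–Cα** distance — the conventional measure for lysine
cross-linkers, whose spacer plus side chains bridge at most ~35 Å for the
DSS/BS3 class; the cutoff is a parameter (`cutoff`, Å, default 35). When a
protein maps to several chain copies (pseudo-symmetric assemblies,
crystallographic copies), the distance is minimized over all copy
combinations — the permissive standard choice, since copy assignment of a
cross-link is unobservable. Residue numbering follows the structure's
author numbering; per-chain integer offsets reconcile sequence-vs-structure
numbering shifts. Unmappable links are excluded from the satisfaction
denominator and reported separately rather than counted as failures.
PDB and mmCIF parsing is delegated to bio3d; the package's own code starts
at the extracted coordinate table.

## The synthetic-data generator

`synth_generate()` emulates the observation process that motivates the
filter, with ground truth attached. Defaults (chosen once, as the study
conditions for all tests):

- **Panel**: 40 present proteins, 60 database-only ("absent") proteins —
  a search space dominated by proteins not in the sample, as in
  proteome-scale searches; lengths uniform on 150–800 residues.
- **Abundance**: log-normal with sdlog 0.7, normalized to mean 1 —
  a realistic one-to-two-order dynamic range.
- **Link formation**: expected true sites per present protein scale with
  abundance at rates 5 (mono) ≥ 2.5 (intra) ≫ 0.5 (inter), the rate
  ordering that underpins the filter; inter partners are drawn with
  probability proportional to the product of abundances.
- **Detection**: each true site is seen in a replicate with probability
  a/(a + 0.4) (abundance a), independently across 3 replicates — so
  abundant proteins recur across replicates and marginal ones flicker.
- **False inter-links**: Poisson, 0.8 per database protein per replicate,
  with each endpoint drawn from the absent pool with probability 0.85 —
  spurious identifications concentrate on proteins that are not there,
  which is the regime in which the filter can act.
- **Decoys**: each emitted inter record is re-emitted as TD with
  probability 0.12 or DD with 0.06 (random side decoyed for TD); mono/intra
  records re-emit their decoy version with probability 0.08 — decoy
  generation is symmetric to targets, as in a real target–decoy search.
- **Scores** (ld-score scale, truncated at 0): true links
  Normal(30, 4); false/decoy mono- and intralinks Normal(18, 4); false and
  decoy *inter*-links a mixture 0.65·Normal(18, 4) + 0.35·Normal(29, 4).
  The high-scoring component encodes the empirical signature the filter
  targets: inter-link errors, unlike mono/intra errors, persist at
  stringent cutoffs. The four standard cutoffs 20/25/28/32 then span the
  interesting range: 20 admits most of the false bulk, 32 admits
  essentially only true links plus the high-scoring error tail. These
  are modelling choices of this package, not measured values.
- `leak_rate` (default 0) lets absent proteins emit occasional monolinks,
  to probe the filter's failure mode; `ensure_support = TRUE` guarantees
  every present protein at least one mono/intra record — the idealized
  regime in which the filter provably retains every true inter-link.

What the generator does **not** model: spectra and spectral re-scoring,
peptide-level effects (missed cleavages, modifications, chargestates),
retention time, shared peptides between proteins, and correlated decoy
structure. Tests passing on this generator therefore demonstrate the
filter's combinatorial and statistical behaviour under its stated
assumptions — not performance on any particular real dataset.

## Numerical and degenerate-input choices

- Score filtering is `ld_score >= cutoff`; records with unparsable scores
  are an error by default (`strict`), because silently dropped rows hide
  corruption; a lenient flag downgrades them to logged skips.
- Positions are 1-based throughout (xQuest convention); position 0 in an
  input is rejected.
- An empty dataset flows through every stage and yields empty, typed
  outputs (header-only files, all-zero count tables, `NA` ratios).
- Distances: squared distances are computed by matrix cross-product and
  clamped at 0 before the square root, so degenerate self-pairs return
  exactly 0; ties between chain copies resolve to the same minimum either
  way.
- Determinism: a fixed generator seed reproduces output files byte for
  byte; reading a file twice yields identical datasets.

## Problem sizes used in the checks

The bundled checks run on datasets of roughly 200–1000 records (6–30
proteins, 3 replicates), 50–100 seeded repetitions for the frequency
claims, and toy structures of a few dozen residues — sizes at which the
brute-force oracles (exhaustive membership scans, per-site recounts,
all-pairs distance enumeration) are feasible and exact.

## Known limitations

- A protein genuinely detected *only* through inter-links (e.g. a small,
  lysine-poor partner crosslinked through a single interface) is
  ineligible and its true inter-links are lost; `leak_rate` simulations
  quantify this regime.
- The filter cannot remove false inter-links between two well-supported
  proteins; it reduces, not estimates, error — FDR control remains the
  caller's responsibility downstream.
- Homodimeric inter-links are conservatively folded into INTRA by default
  and thus never counted as PPI evidence.
- Cα–Cα distance validation ignores side-chain geometry and solvent
  accessibility; a satisfied distance is necessary, not sufficient, for a
  correct link.
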