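---
title: "Testing proximity between disease mutations and PTM sites"
author: "ptmenrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing proximity between disease mutations and PTM sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmenrich)
```

## The question

Enzymes and binding domains that read a post-translational modification
(PTM) recognize the linear sequence around the modified residue: a 14-3-3
protein binding a phosphoserine, a kinase docking on its substrate motif, a
ubiquitin ligase engaging its degron. A missense mutation landing inside
that recognition window can disturb regulation without touching the modified
residue itself. `ptmenrich` asks, proteome-wide, whether missense mutations
annotated as pathogenic (dbSNP "Clinical Significance" vocabulary) or
Disease (UniProtKB humsavar vocabulary) lie within a window of PTM sites
more often than other mutations do — and whether that signal survives two
well-known confounders: annotation study bias and amino-acid composition.

## The data model

Annotation data arrive as a ProteomeScout-like tab-separated flat file (one
protein per line; "; "-delimited annotation tokens; see
`?readProteomeFlatfile` for the documented dialect) and, optionally, a
UniProt humsavar-style variant index. Both are parsed into a `PTMProteome`,
an S4 container holding the sequences (`AAStringSet`), the per-instance
modification and mutation tables, and GO terms, with validity checks that
enforce the chemistry of every typed modification (a phosphoserine must sit
on S, ubiquitination and N6-acetylation on K, N-glycosylation on N) and the
coordinate invariants (1-based positions within the sequence, counting the
initiator methionine as 1).

The dialect is deliberately ProteomeScout-LIKE, not byte-compatible with
any particular database release: the analysis depends only on the fields the
container carries, and a thin adapter for other column layouts is future
work.

## The statistical procedure

**Counting unit.** The unit is the *mutated residue*: a unique
(protein, position) pair. If several mutations hit the same residue, the
residue is counted once, and it is assigned the pathogenic phenotype if
*any* of its mutations is pathogenic/Disease (the OR-collapse). PTM
proximity is evaluated per modification type with an inclusive window:
a PTM is "within 8" iff `|ptmPosition - position| <= 8`, so window 0 means
a PTM on the mutated residue itself and the window-8 feature set subsumes
the window-0 one. Windows clip at the termini; nothing is padded.

**Study-bias control.** Proteins carrying a pathogenic mutation are
systematically better studied, and annotation burdens of all kinds
(GO terms, PTMs, mutations, even length) correlate positively
(`annotationCorrelations()`, `studyBiasTest()`). All enrichment tests are
therefore restricted to the proteins that have at least one pathogenic
mutation (`pathogenicProteinSet()`): within this set, foreground
(pathogenic residues) and background (all other mutated residues) share the
same annotation depth.

**The test.** Per modification type, the 2x2 table
`[pathogenic x PTM-within-window]` over the bias-controlled mutated
residues is evaluated with a one-sided Fisher's exact test
(`fisherOneSided()`), enrichment tail only — the hypothesis is that
pathogenic mutations are *more* likely to sit near PTMs, not less. The
tail is accumulated in log-space via log-gamma (`lchoose`), so tables with
hundreds of thousands of residues are exact and p-values far below
`1e-300` are representable; below the double floor the p is reported at
`.Machine$double.xmin` rather than 0, keeping the documented range (0, 1].
Benjamini–Hochberg q-values (`bhFdr()`, delegating to
`stats::p.adjust(method = "BH")`) are computed within each analysis family
— the tested modification types, or the 20 amino acids of `aaBiasTest()` —
and never pooled across families. Types with no PTM instances on the
analyzed proteins are flagged `testable = FALSE` with `NA` statistics
rather than a misleading p of 1; sparse modification classes simply cannot
be tested.

**Composition control.** Pathogenic mutations skew toward arginine, and
arginine-rich neighbourhoods could co-locate with PTMs for reasons that have
nothing to do with regulation. `resamplingControl()` therefore draws random
pseudo-foregrounds of exactly the real foreground's size *and* wild-type
amino-acid composition (sampling without replacement within each residue
class), relabels them, and reruns the identical test. Pseudo-foregrounds are
drawn from the non-pathogenic residues only: the control asks whether
composition alone produces enrichment, and contaminating the candidate pool
with truly co-localized pathogenic residues would bias it toward the
alternative. Ten trials per report mirrors common practice for this kind of
spot control; the per-trial seeds are `seed + 1 ... seed + n` and are
logged, so a report is bit-reproducible.

## The synthetic proteome generator

Because the real annotation snapshots are moving targets (and large), every
claim the package makes is validated on synthetic proteomes with planted
ground truth (`generateProteome()` + `SyntheticProteomeConfig()`):

* sequences i.i.d. from a configurable composition (default uniform over
  the 20 residues; lengths uniform on 100–400);
* PTMs placed independently on chemically eligible residues, per-type rates
  0.02–0.05 per eligible residue — of the order of, e.g., phosphosite
  density among serines in curated human data. Placement ignores sequence
  motifs (no N-X-S/T sequon): the statistics under test never read motifs,
  and single-residue chemistry keeps the ground truth exact;
* mutations per residue at rate 0.05 (roughly the per-residue density of
  missense annotations on well-studied human proteins), multiplied by an
  arginine skew (default 3) emulating the elevated mutability of arginine
  codons; about 10% of mutated residues receive a second, distinct mutation
  so the OR-collapse path is exercised on generated data;
* pathogenic labels drawn per *mutation* (never pre-collapsed) with
  probability `basePathogenicProb` (default 0.09, matching the pathogenic
  fraction of annotated missense variants in curated sets), multiplied by
  `rho` when the residue lies within `windowW` of a PTM whose type is in
  `rhoModTypes`. `rho = 1` is the exact null; `rho > 1` with
  `rhoModTypes = "Ubiquitination"` plants a type-specific co-localization
  effect;
* optionally, `pathogenicProteinFraction` confines pathogenic labels to a
  protein subset — the "hubs of pathogenicity" clustering that makes the
  disease fraction of curated variant indexes rise steeply (from roughly a
  third to roughly two-thirds) when the index is restricted to proteins
  with at least one Disease variant.

The truth ledger returned alongside the proteome records, for every planted
mutation, whether it was near a PTM, whether the `rho` boost applied, the
labelling probability used, and the drawn label — enough to recompute every
pipeline statistic by an independent oracle, which the test suite does with
a quadratic scan over all (mutation, PTM) pairs.

What the generator does *not* emulate: protein families and paralogy,
disorder, real mutation spectra beyond the single arginine knob, PTM motif
context, and correlated annotation depth between PTMs and mutations on the
same protein. Passing tests therefore demonstrate that the machinery is
correct and calibrated under the stated generative model — not that any
particular biological dataset will show an effect.

## Numerical and design choices

* **Window arithmetic.** "Within eight amino acids" includes the residue
  itself (`|Δ| ≤ 8`, Δ = 0 included); the boundary is inclusive at 8 and
  exclusive at 9, which the tests pin down explicitly. Proximity queries are
  resolved on a single sorted global coordinate axis (per-protein offset
  blocks wider than any window), so flagging is `O(n log n)` rather than
  quadratic; the quadratic scan survives only as the test oracle.
* **Background definition.** The background is *all* non-pathogenic mutated
  residues in the bias-controlled set, including unannotated ones; the two
  rows of the 2x2 are disjoint by construction. A residue carrying both a
  PTM and a mutation counts in both roles — the uniqueness rule de-duplicates
  residues within a role, it does not exclude overlap between roles.
* **Odds ratio.** The sample odds ratio `ad/bc` is reported (`Inf` when
  `bc = 0` with `ad > 0`); it is descriptive, the inference is the exact
  test.
* **Correlation flavour.** Pearson on raw counts by default (annotation
  burdens scale roughly linearly with length), Spearman by option.
* **Humsavar vocabulary.** Category matching is case-sensitive on the
  classic tokens (`Disease` / `Polymorphism` / `Unclassified`); newer
  vocabularies are folded in only via an explicit `categoryMap`, never
  silently. Only simple `p.Xaa123Xaa` missense changes are parsed; accession
  strings are identities as printed (no isoform-suffix handling).
* **Tie-breaks.** `rankMutationsByNearbyPtms()` sorts by descending count,
  then (accession, position) — fully deterministic.
* **Degenerate inputs.** All-zero tables, empty foregrounds, empty variant
  sets, unknown accessions and infeasible composition targets raise typed
  conditions (`ptmenrich_degenerate_input`, `ptmenrich_empty_foreground`,
  `ptmenrich_undefined_fraction`, `ptmenrich_accession_not_found`,
  `ptmenrich_infeasible_composition`) rather than returning sentinel values.
* **Reproducibility.** Output files carry `#`-prefixed manifest headers
  (tool version, input digests, parameters, seed). The manifest deliberately
  omits a timestamp: reruns with identical inputs must be byte-identical,
  and a timestamp in the header would break exactly the property the
  manifest exists to certify. Seeded helpers restore the caller's RNG
  state.

## Problem sizes used in validation

The shipped test suite and the acceptance script size their simulations as
follows: exact-test verification enumerates every 2x2 table with total at
most 60 against a `dhyper` oracle; generator self-audits use ~1e5 mutated
residues; null calibration runs 100–200 proteomes of 2,000 proteins at
`rho = 1` (per-type rejection rate expected close to, and not above, the
nominal 5%); effect recovery runs 50–100 proteomes with `rho = 8` on
ubiquitination only at `basePathogenicProb = 0.01`; oracle-equivalence
sweeps use proteomes of at most 50 proteins where the quadratic scan is
cheap. These sizes give binomial standard errors comfortably below the
decision margins of the corresponding checks.

## Known limitations

* The flat-file dialect is this package's own; real ProteomeScout releases
  need an adapter.
* The per-type test treats modification types independently; residues near
  PTMs of two types appear in both tables, and the BH correction does not
  model that dependence (the resampling control is the robustness check).
* The study-bias control conditions on having one pathogenic mutation; it
  cannot separate "hub of pathogenicity" biology from "rich-get-richer"
  annotation sociology — both produce the same restriction effect.
* Structure- or accessibility-matched controls (beyond amino-acid
  composition) are out of scope.

## A worked example

```{r example, eval = FALSE}
sim <- generateProteome(SyntheticProteomeConfig(
  nProteins = 2000, basePathogenicProb = 0.01,
  rho = 8, rhoModTypes = "Ubiquitination", seed = 42))
res <- testEnrichment(sim$proteome, source = "dbsnp", window = 8)
res[, c("modType", "a", "b", "c", "d", "oddsRatio", "p", "q")]
ctrl <- resamplingControl(sim$proteome, "dbsnp", window = 8,
                          nTrials = 10, seed = 43)
print(ctrl)
```

The planted type is the only one that should come out with `q < 0.05`, and
its composition-matched pseudo-foregrounds should stay quiet — the same
structure the acceptance checks assert at scale.
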