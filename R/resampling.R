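# Composition-matched random-foreground control: does amino-acid composition
# alone (e.g. the arginine skew of pathogenic mutated residues) explain the
# PTM-proximity enrichment?

#' Draw a composition-matched residue foreground
#'
#' Samples, without replacement and independently within each wild-type
#' amino-acid class, a subset of candidate mutated residues with EXACTLY the
#' target amino-acid composition (same size, same per-residue-type counts).
#'
#' @param candidates `data.frame` of mutated residues (as from
#'   [collectMutatedResidues()]): must have a `wtResidue` column.
#' @param targetComposition Named integer vector: required count per
#'   one-letter residue code. Zero-count entries may be omitted.
#' @param seed Integer seed; the draw is reproducible under a fixed seed.
#' @return Integer vector of row indices into `candidates` (sorted), with
#'   exactly `targetComposition[aa]` rows of each wild-type `aa`.
#' @export
compositionMatchedForeground <- function(candidates, targetComposition, seed) {
  targetComposition <- targetComposition[targetComposition > 0]
  avail <- table(candidates$wtResidue)
  short <- names(targetComposition)[
    !(names(targetComposition) %in% names(avail)) |
      targetComposition > as.integer(avail[names(targetComposition)])]
  if (length(short)) {
    have <- ifelse(names(targetComposition[short]) %in% names(avail),
                   as.integer(avail[short]), 0L)
    .stopInfeasible(sprintf(
      "not enough candidate residues to match composition: %s",
      paste(sprintf("%s (need %d, have %d)", short,
                    as.integer(targetComposition[short]), have),
            collapse = ", ")))
  }
  rng <- .withSeed(seed)
  on.exit(rng())
  picked <- unlist(lapply(names(targetComposition), function(aa) {
    idx <- which(candidates$wtResidue == aa)
    if (length(idx) == 1L) idx else sample(idx, targetComposition[[aa]])
  }), use.names = FALSE)
  sort(picked)
}

# Run code under a seed, restoring the caller's RNG state afterwards.
.withSeed <- function(seed) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Composition-matched resampling control
#'
#' Repeats the enrichment test with random pseudo-foregrounds drawn from the
#' NON-pathogenic mutated residues of the study-bias-controlled set, each
#' matched exactly in size and wild-type amino-acid composition to the real
#' pathogenic foreground. If PTM proximity enrichment were driven by residue
#' composition alone (arginine skew in particular), these matched random
#' foregrounds would be significant about as often as the real one; under a
#' genuine co-localization signal they are not.
#'
#' The real pathogenic residues keep their labels and are excluded from the
#' candidate pool, so each trial compares a drawn pseudo-foreground against
#' the remaining non-pathogenic residues.
#'
#' @param proteome A [PTMProteome-class].
#' @param source `"dbsnp"` or `"humsavar"`.
#' @param modTypes Modification types to test.
#' @param window Window half-width in residues.
#' @param nTrials Number of random foregrounds (default 10).
#' @param alpha Per-test significance threshold for the trial tally.
#' @param seed Master seed; per-trial seeds are `seed + 1, ..., seed + nTrials`
#'   and are recorded in the report.
#' @return A `ResamplingReport`: list with `nTrials`, `alpha`, `seed`,
#'   `trialSeeds`, `targetComposition` (the real foreground's residue
#'   counts), `pvalues` (nTrials x modTypes matrix; `NA` for untestable
#'   types), `nSignificant` (per-type count of trials with `p < alpha`), and
#'   `real` (the real-foreground [testEnrichment()] result). With
#'   `nTrials = 0` the report is returned with empty trial fields.
#' @export
resamplingControl <- function(proteome, source = c("dbsnp", "humsavar"),
                              modTypes = names(modificationTypes()),
                              window = 8L, nTrials = 10L, alpha = 0.05,
                              seed = 1L) {
  source <- match.arg(source)
  subset <- pathogenicProteinSet(proteome, source)
  if (length(subset) == 0L)
    .stopEmptyForeground("no proteins with a pathogenic/Disease mutation")
  residues <- collectMutatedResidues(proteome, subset, source,
                                     modTypes = modTypes, windows = window)
  nPtm <- attr(residues, "nPtmInSubset")
  if (!any(residues$isPathogenic))
    .stopEmptyForeground("real pathogenic foreground is empty")
  targetComposition <- table(residues$wtResidue[residues$isPathogenic])
  candidates <- residues[!residues$isPathogenic, , drop = FALSE]

  real <- testEnrichment(proteome, source, modTypes, window)
  trialSeeds <- if (nTrials > 0) seed + seq_len(nTrials) else integer(0)
  pvals <- matrix(NA_real_, nrow = nTrials, ncol = length(modTypes),
                  dimnames = list(NULL, modTypes))
  for (t in seq_len(nTrials)) {
    pick <- compositionMatchedForeground(candidates,
                                         as.integer(targetComposition) |>
                                           stats::setNames(names(targetComposition)),
                                         seed = trialSeeds[t])
    isFg <- seq_len(nrow(candidates)) %in% pick
    res <- .enrichFromResidues(candidates, isFg, modTypes,
                               as.integer(window), nPtm)
    pvals[t, res$modType] <- res$p
  }
  nSignificant <- apply(pvals, 2L, function(p) sum(p < alpha, na.rm = TRUE))
  structure(list(
    nTrials = as.integer(nTrials), alpha = alpha, seed = as.integer(seed),
    trialSeeds = as.integer(trialSeeds),
    targetComposition = targetComposition,
    pvalues = pvals, nSignificant = nSignificant, real = real,
    window = as.integer(window), source = source
  ), class = "ResamplingReport")
}

#' @export
print.ResamplingReport <- function(x, ...) {
  cat(sprintf("Composition-matched resampling control (%d trial(s), alpha = %g, seed = %d)\n",
              x$nTrials, x$alpha, x$seed))
  cat(sprintf("  foreground size %d; composition: %s\n",
              sum(x$targetComposition),
              paste(sprintf("%s:%d", names(x$targetComposition),
                            as.integer(x$targetComposition)), collapse = " ")))
  for (tp in colnames(x$pvalues)) {
    realP <- x$real$p[match(tp, x$real$modType)]
    cat(sprintf("  %-18s real p = %s; significant random trials: %d / %d\n",
                tp, format(realP, digits = 3), x$nSignificant[[tp]], x$nTrials))
  }
  invisible(x)
}
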