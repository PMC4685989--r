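# Residue-unique counting and windowed PTM-proximity enrichment.
#
# The counting unit is the mutated residue: a unique (accession, position)
# pair, assigned the pathogenic phenotype if ANY mutation recorded on it is
# pathogenic/Disease (OR-collapse). Windows are inclusive: a PTM is "within
# w" of a residue iff |ptmPosition - position| <= w, so window 0 means a PTM
# on the mutated residue itself and the window-8 feature set subsumes the
# window-0 one. Windows clip at sequence termini automatically.

.nearbyColumn <- function(modType, window) sprintf("near|%s|w%d", modType, window)

#' Proteins carrying at least one pathogenic mutation
#'
#' The study-bias-controlled analysis set: accessions of proteins with at
#' least one mutation of the given source whose category is `pathogenic`
#' (dbSNP vocabulary) or `Disease` (humsavar vocabulary). Restricting
#' enrichment tests to this set controls for well-studied proteins carrying
#' more annotations of every kind.
#'
#' @param proteome A [PTMProteome-class].
#' @param source `"dbsnp"` or `"humsavar"`.
#' @return Character vector of primary accessions (possibly empty).
#' @export
pathogenicProteinSet <- function(proteome, source = c("dbsnp", "humsavar")) {
  source <- match.arg(source)
  token <- .pathogenicToken(source)
  mt <- mutations(proteome)
  sort(unique(mt$accession[mt$source == source &
                           mt$clinicalSignificance == token]))
}

#' Is a PTM of a given type within a window of a position?
#'
#' @param proteome A [PTMProteome-class].
#' @param acc Accession of the protein record.
#' @param position 1-based residue position; must lie within the sequence.
#' @param modType Modification type to look for.
#' @param window Non-negative window half-width in residues; `0` asks for a
#'   PTM on the residue itself.
#' @return `TRUE` iff some modification of `modType` on the record satisfies
#'   `|ptmPosition - position| <= window`.
#' @export
hasPtmWithin <- function(proteome, acc, position, modType, window) {
  i <- .resolveAccession(proteome, acc)
  len <- proteins(proteome)$length[i]
  if (position < 1L || position > len)
    .stopDegenerate(sprintf("position %d out of range [1, %d] for '%s'",
                            position, len, acc))
  if (window < 0L) .stopDegenerate("window must be >= 0")
  md <- modifications(proteome)
  pos <- md$position[md$accession == proteins(proteome)$accession[i] &
                     md$modType == modType]
  any(abs(pos - position) <= window)
}

#' Collect residue-unique mutated residues with nearby-PTM features
#'
#' De-duplicates mutations to one row per (accession, position), OR-collapses
#' pathogenicity over all mutations on each residue, and precomputes, for
#' every requested (modification type, window) pair, whether a PTM of that
#' type lies within the window. Only mutations of the requested source are
#' counted; the analysis is restricted to `proteinSubset`.
#'
#' @param proteome A [PTMProteome-class].
#' @param proteinSubset Character vector of primary accessions (non-empty),
#'   typically [pathogenicProteinSet()].
#' @param source `"dbsnp"` or `"humsavar"`.
#' @param modTypes Modification types to flag (default all of
#'   [modificationTypes()]).
#' @param windows Integer vector of windows to flag (default `c(0, 8)`).
#' @return `data.frame` with one row per mutated residue: `accession`,
#'   `position`, `wtResidue`, `isPathogenic`, and one logical column per
#'   (type, window) pair named `near|<type>|w<window>`. Attributes `modTypes`,
#'   `windows` and `nPtmInSubset` (named count of PTM instances per type on
#'   the subset) describe the feature columns.
#' @export
collectMutatedResidues <- function(proteome, proteinSubset,
                                   source = c("dbsnp", "humsavar"),
                                   modTypes = names(modificationTypes()),
                                   windows = c(0L, 8L)) {
  source <- match.arg(source)
  if (length(proteinSubset) == 0L)
    .stopEmptyForeground("empty protein subset: no proteins to analyze")
  token <- .pathogenicToken(source)
  mt <- mutations(proteome)
  mt <- mt[mt$source == source & mt$accession %in% proteinSubset, , drop = FALSE]
  if (nrow(mt) == 0L)
    .stopEmptyForeground("no mutations of the requested source in the protein subset")

  key <- paste(mt$accession, mt$position)
  first <- !duplicated(key)
  isPath <- tapply(mt$clinicalSignificance == token, key, any)
  residues <- data.frame(
    accession = as.character(mt$accession[first]),
    position = as.integer(mt$position[first]),
    wtResidue = as.character(mt$wtResidue[first]),
    stringsAsFactors = FALSE
  )
  residues$isPathogenic <- as.logical(isPath[paste(residues$accession,
                                                   residues$position)])
  residues <- residues[order(residues$accession, residues$position), , drop = FALSE]
  rownames(residues) <- NULL

  md <- modifications(proteome)
  md <- md[md$accession %in% proteinSubset, , drop = FALSE]
  offset <- .globalOffset(proteome, max(windows, 0L))
  accLevels <- accessions(proteome)
  resCoord <- .globalCoord(residues$accession, residues$position, accLevels, offset)
  nPtm <- integer(0)
  for (tp in modTypes) {
    ptmCoord <- .globalCoord(md$accession[md$modType == tp],
                             md$position[md$modType == tp], accLevels, offset)
    nPtm[tp] <- length(ptmCoord)
    for (w in windows)
      residues[[.nearbyColumn(tp, w)]] <- .anyWithinWindow(resCoord, ptmCoord, w)
  }
  attr(residues, "modTypes") <- modTypes
  attr(residues, "windows") <- as.integer(windows)
  attr(residues, "nPtmInSubset") <- nPtm
  residues
}

# Fisher tests per modification type on a residue table with precomputed
# nearby flags. Used by testEnrichment() and by the resampling control (which
# relabels the foreground without recomputing flags).
.enrichFromResidues <- function(residues, isForeground, modTypes, window,
                                nPtmInSubset) {
  rows <- lapply(modTypes, function(tp) {
    near <- residues[[.nearbyColumn(tp, window)]]
    a <- sum(isForeground & near); b <- sum(isForeground & !near)
    cc <- sum(!isForeground & near); d <- sum(!isForeground & !near)
    testable <- nPtmInSubset[[tp]] > 0L
    if (testable) {
      f <- fisherOneSided(a, b, cc, d)
      data.frame(modType = tp, window = window, a = a, b = b, c = cc, d = d,
                 oddsRatio = f$oddsRatio, p = f$p, testable = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(modType = tp, window = window, a = a, b = b, c = cc, d = d,
                 oddsRatio = NA_real_, p = NA_real_, testable = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  out$q[out$testable] <- bhFdr(out$p[out$testable])
  out
}

#' Windowed PTM-proximity enrichment of pathogenic mutations
#'
#' The core test. Within the study-bias-controlled protein set
#' ([pathogenicProteinSet()]), mutated residues are split into foreground
#' (pathogenic, OR-collapsed) and background (all other mutated residues).
#' For each modification type a 2x2 table
#' `[pathogenic x PTM-of-type within window]` is tested with
#' [fisherOneSided()] (enrichment tail) and Benjamini-Hochberg corrected
#' across the tested types (never pooled with other analysis families).
#'
#' Modification types with zero PTM instances on the analyzed proteins are
#' reported with `testable = FALSE` and `NA` statistics rather than a
#' misleading p of 1.
#'
#' @param proteome A [PTMProteome-class].
#' @param source `"dbsnp"` or `"humsavar"`: which vocabulary defines
#'   pathogenicity (and which mutation records are analyzed).
#' @param modTypes Modification types to test.
#' @param window Window half-width in residues (default 8).
#' @return A `DataFrame` with one row per modification type, columns
#'   `modType`, `window`, `a`, `b`, `c`, `d`, `oddsRatio`, `p`, `q`,
#'   `testable`, `nForegroundProteins`; rows sorted by `q` (untestable rows
#'   last). `metadata()` records the source, window, foreground/background
#'   residue counts and the analyzed protein set size.
#' @export
#' @examples
#' sim <- generateProteome(SyntheticProteomeConfig(nProteins = 200, seed = 42))
#' testEnrichment(sim$proteome, source = "dbsnp", window = 8)
testEnrichment <- function(proteome, source = c("dbsnp", "humsavar"),
                           modTypes = names(modificationTypes()),
                           window = 8L) {
  source <- match.arg(source)
  subset <- pathogenicProteinSet(proteome, source)
  if (length(subset) == 0L)
    .stopEmptyForeground("no proteins with a pathogenic/Disease mutation")
  residues <- collectMutatedResidues(proteome, subset, source,
                                     modTypes = modTypes, windows = window)
  res <- .enrichFromResidues(residues, residues$isPathogenic, modTypes,
                             as.integer(window), attr(residues, "nPtmInSubset"))
  res$nForegroundProteins <- length(subset)
  ord <- order(!res$testable, res$q, res$p, res$modType)
  out <- DataFrame(res[ord, , drop = FALSE])
  rownames(out) <- NULL
  metadata(out) <- list(
    source = source, window = as.integer(window),
    nForegroundResidues = sum(residues$isPathogenic),
    nBackgroundResidues = sum(!residues$isPathogenic),
    nProteinsAnalyzed = length(subset))
  out
}

#' Rank mutated residues by nearby-PTM burden
#'
#' Counts, for every mutated residue in the proteome (all sources, no
#' study-bias restriction), the number of modifications of ANY type within
#' the window, and ranks residues by that count. Heavily modified
#' neighbourhoods point at mutations most likely to disturb PTM-mediated
#' regulation. Ties are broken deterministically by (accession, position).
#'
#' @param proteome A [PTMProteome-class].
#' @param window Window half-width in residues (default 8).
#' @return `data.frame` sorted by decreasing `nNearbyPtms` with columns
#'   `accession`, `position`, `wtResidue`, `isPathogenic` (OR over both
#'   vocabularies' disease categories), `nNearbyPtms`.
#' @export
rankMutationsByNearbyPtms <- function(proteome, window = 8L) {
  mt <- mutations(proteome)
  if (nrow(mt) == 0L)
    return(data.frame(accession = character(), position = integer(),
                      wtResidue = character(), isPathogenic = logical(),
                      nNearbyPtms = integer(), stringsAsFactors = FALSE))
  key <- paste(mt$accession, mt$position)
  first <- !duplicated(key)
  isPath <- tapply(mt$clinicalSignificance %in% c("pathogenic", "Disease"),
                   key, any)
  residues <- data.frame(
    accession = as.character(mt$accession[first]),
    position = as.integer(mt$position[first]),
    wtResidue = as.character(mt$wtResidue[first]),
    stringsAsFactors = FALSE
  )
  residues$isPathogenic <- as.logical(isPath[key[first]])

  md <- modifications(proteome)
  offset <- .globalOffset(proteome, window)
  accLevels <- accessions(proteome)
  resCoord <- .globalCoord(residues$accession, residues$position, accLevels, offset)
  ptmCoord <- sort(.globalCoord(md$accession, md$position, accLevels, offset))
  # number of PTM coordinates in [x - w, x + w]
  lo <- findInterval(resCoord - window - 0.5, ptmCoord)
  hi <- findInterval(resCoord + window + 0.5, ptmCoord)
  residues$nNearbyPtms <- as.integer(hi - lo)
  residues[order(-residues$nNearbyPtms, residues$accession, residues$position), ,
           drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
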