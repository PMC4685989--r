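# Synthetic proteomes with known ground truth. Sequences are i.i.d. draws
# from the configured amino-acid composition; PTMs are placed independently
# on chemically eligible residues (single-residue chemistry only, no sequence
# motifs); mutations are placed per residue with an arginine-skewed rate; and
# pathogenic labels are assigned per MUTATION (never pre-collapsed per
# residue) with probability basePathogenicProb, multiplied by rho when the
# residue lies within windowW of any PTM. The ground-truth ledger records
# every planted fact so each pipeline statistic can be recomputed by an
# independent oracle.

#' Generate a synthetic proteome with ground truth
#'
#' @param config A [SyntheticProteomeConfig-class] (see
#'   [SyntheticProteomeConfig()]); all randomness is fixed by `config@seed`.
#' @return List with two elements: `proteome`, a [PTMProteome-class] whose
#'   accessions are synthetic (`SYN00001`, ... with alternate accessions
#'   `ALT00001`, ...); and `truth`, a `data.frame` ledger with one row per
#'   planted mutation: `accession`, `position`, `wtResidue`, `mutResidue`,
#'   `nearPtm` (within `windowW` of any PTM), `boosted` (within `windowW` of
#'   a `rhoModTypes` PTM, i.e. the `rho` multiplier applied), `pPathogenic`
#'   (the labelling
#'   probability actually used, 0 for proteins outside the eligible subset
#'   when `pathogenicProteinFraction` is set), `pathogenic`, and
#'   `eligibleProtein`.
#' @export
#' @examples
#' sim <- generateProteome(SyntheticProteomeConfig(nProteins = 10, seed = 3))
#' sim$proteome
#' head(sim$truth)
generateProteome <- function(config) {
  stopifnot(methods::is(config, "SyntheticProteomeConfig"))
  methods::validObject(config)
  restore <- .withSeed(config@seed)
  on.exit(restore())

  n <- config@nProteins
  lens <- if (config@lengthRange[1] == config@lengthRange[2])
    rep(config@lengthRange[1], n)
  else sample(config@lengthRange[1]:config@lengthRange[2], n, replace = TRUE)
  acc <- sprintf("SYN%05d", seq_len(n))
  total <- sum(lens)
  aa <- sample(aminoAcids(), total, replace = TRUE, prob = config@aaComposition)
  protIdx <- rep.int(seq_len(n), lens)
  pos <- sequence(lens)

  # PTM placement per type on eligible residues
  modList <- lapply(names(config@ptmRate), function(tp) {
    rate <- config@ptmRate[[tp]]
    elig <- which(aa == .MOD_ELIGIBILITY[[tp]])
    if (rate <= 0 || length(elig) == 0L) return(NULL)
    hit <- elig[stats::runif(length(elig)) < rate]
    if (length(hit) == 0L) return(NULL)
    data.frame(accession = acc[protIdx[hit]], residue = aa[hit],
               position = pos[hit], modType = tp, stringsAsFactors = FALSE)
  })
  mods <- do.call(rbind, modList[!vapply(modList, is.null, logical(1))])
  if (!is.null(mods)) {
    mods <- mods[order(mods$accession, mods$position, mods$modType), , drop = FALSE]
    rownames(mods) <- NULL
  }

  # which residues lie within windowW of any PTM (generator's own
  # bookkeeping), and of a rho-boosting PTM type in particular
  offset <- max(lens) + 2L * config@windowW + 2L
  globalAll <- as.numeric(protIdx) * offset + as.numeric(pos)
  ptmGlobal <- if (is.null(mods)) numeric(0) else
    as.numeric(match(mods$accession, acc)) * offset + as.numeric(mods$position)
  boostGlobal <- if (is.null(mods)) numeric(0) else
    ptmGlobal[mods$modType %in% config@rhoModTypes]

  # mutations: per-residue Bernoulli, arginine-skewed
  pMut <- pmin(1, config@mutationRate *
                 ifelse(aa == "R", config@arginineSkew, 1))
  isMut <- stats::runif(total) < pMut
  mutIdx <- which(isMut)
  # a second, distinct mutation on ~10% of mutated residues exercises the
  # downstream OR-collapse on generated data
  secondIdx <- mutIdx[stats::runif(length(mutIdx)) < 0.1]
  allIdx <- c(mutIdx, secondIdx)

  nearPtm <- .anyWithinWindow(globalAll[allIdx], ptmGlobal, config@windowW)
  boosted <- .anyWithinWindow(globalAll[allIdx], boostGlobal, config@windowW)

  eligibleProt <- rep(TRUE, n)
  if (!is.na(config@pathogenicProteinFraction)) {
    k <- max(1L, round(config@pathogenicProteinFraction * n))
    eligibleProt <- seq_len(n) %in% sample(seq_len(n), k)
  }
  elig <- eligibleProt[protIdx[allIdx]]
  pPath <- ifelse(elig,
                  pmin(1, config@basePathogenicProb *
                         ifelse(boosted, config@rho, 1)),
                  0)
  pathogenic <- stats::runif(length(allIdx)) < pPath

  # mutant residues: any residue other than wild type; the second mutation on
  # a residue also differs from the first so tokens stay distinct
  aaSet <- aminoAcids()
  notWt <- vapply(aaSet, function(r) setdiff(aaSet, r), character(19))  # 19 x 20
  drawMut <- function(wt, avoid = NULL) {
    if (length(wt) == 0L) return(character(0))
    wtIdx <- match(wt, aaSet)
    out <- notWt[cbind(sample.int(19L, length(wt), replace = TRUE), wtIdx)]
    if (!is.null(avoid)) {
      clash <- which(out == avoid)
      while (length(clash)) {
        out[clash] <- notWt[cbind(sample.int(19L, length(clash), replace = TRUE),
                                  wtIdx[clash])]
        clash <- clash[out[clash] == avoid[clash]]
      }
    }
    out
  }
  mut1 <- drawMut(aa[mutIdx])
  mut2 <- drawMut(aa[secondIdx],
                  avoid = mut1[match(secondIdx, mutIdx)])
  mutResidue <- c(mut1, mut2)

  truth <- data.frame(
    accession = acc[protIdx[allIdx]],
    position = pos[allIdx],
    wtResidue = aa[allIdx],
    mutResidue = mutResidue,
    nearPtm = nearPtm,
    boosted = boosted,
    pPathogenic = pPath,
    pathogenic = pathogenic,
    eligibleProtein = elig,
    stringsAsFactors = FALSE
  )
  truth <- truth[order(truth$accession, truth$position, truth$mutResidue), ,
                 drop = FALSE]
  rownames(truth) <- NULL

  mutsDF <- data.frame(
    accession = truth$accession,
    position = truth$position,
    wtResidue = truth$wtResidue,
    mutResidue = truth$mutResidue,
    clinicalSignificance = ifelse(truth$pathogenic, "pathogenic", "unannotated"),
    source = "dbsnp",
    variantId = "",
    stringsAsFactors = FALSE
  )

  # GO terms: Poisson(5) identifiers per protein
  nGo <- stats::rpois(n, 5)
  goList <- lapply(nGo, function(k)
    if (k == 0L) character() else
      sprintf("GO:%07d", sample.int(9999999L, k, useHash = TRUE)))

  seqs <- vapply(split(aa, protIdx), paste, character(1), collapse = "")
  proteinsDF <- DataFrame(
    accession = acc,
    altAccessions = CharacterList(as.list(sprintf("ALT%05d", seq_len(n)))),
    gene = sprintf("GENE%04d", seq_len(n)),
    species = "synthetic"
  )
  proteome <- PTMProteome(
    proteins = proteinsDF,
    sequences = stats::setNames(unname(seqs), acc),
    modifications = mods,
    mutations = if (nrow(mutsDF)) mutsDF else NULL,
    goTerms = goList
  )
  list(proteome = proteome, truth = truth)
}
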