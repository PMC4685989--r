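#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges CharacterList
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom IRanges CharacterList
#' @importClassesFrom Biostrings AAStringSet
NULL

#' PTMProteome: an annotated proteome
#'
#' Container for a set of protein records as parsed from a ProteomeScout-like
#' flat file (or built by the synthetic generator): sequences, post-translational
#' modification (PTM) sites, missense mutations and Gene Ontology terms, all
#' keyed by UniProtKB-style accession.
#'
#' Coordinates are 1-based on the protein sequence, counting the initiator
#' methionine as position 1.
#'
#' @slot proteins `DataFrame` with columns `accession` (primary, unique),
#'   `altAccessions` (`CharacterList`), `gene`, `species`, `length`.
#' @slot sequences `AAStringSet` named by primary accession, parallel to
#'   `proteins`.
#' @slot modifications `DataFrame` with columns `accession`, `residue`,
#'   `position`, `modType`. One row per PTM instance.
#' @slot mutations `DataFrame` with columns `accession`, `position`,
#'   `wtResidue`, `mutResidue`, `clinicalSignificance`, `source`
#'   (`"dbsnp"` or `"humsavar"`), `variantId`.
#' @slot goTerms `CharacterList` of GO identifiers, named by primary accession.
#'
#' @seealso [readProteomeFlatfile()], [generateProteome()], [getMutations()]
#' @export
setClass("PTMProteome",
  slots = c(
    proteins      = "DataFrame",
    sequences     = "AAStringSet",
    modifications = "DataFrame",
    mutations     = "DataFrame",
    goTerms       = "CharacterList"
  )
)

.validPTMProteome <- function(object) {
  msg <- character()
  pr <- object@proteins
  need <- c("accession", "altAccessions", "gene", "species", "length")
  if (!all(need %in% colnames(pr)))
    return(sprintf("proteins must have columns %s", paste(need, collapse = ", ")))
  acc <- pr$accession
  if (anyNA(acc) || any(!nzchar(acc)))
    msg <- c(msg, "primary accessions must be non-empty")
  if (anyDuplicated(acc))
    msg <- c(msg, "primary accessions must be unique")
  if (length(object@sequences) != nrow(pr) ||
      !identical(names(object@sequences), as.character(acc)))
    msg <- c(msg, "sequences must be named by, and parallel to, proteins$accession")
  if (!all(pr$length == Biostrings::width(object@sequences)))
    msg <- c(msg, "protein length must equal the number of sequence residues")
  lens <- stats::setNames(pr$length, acc)

  md <- object@modifications
  if (nrow(md) > 0) {
    if (!all(md$accession %in% acc))
      msg <- c(msg, "modification rows reference unknown accessions")
    else {
      bad <- md$position < 1L | md$position > lens[md$accession]
      if (any(bad)) msg <- c(msg, "modification positions out of sequence range")
      known <- md$modType %in% names(.MOD_ELIGIBILITY)
      chem <- .MOD_ELIGIBILITY[md$modType[known]]
      if (any(md$residue[known] != chem))
        msg <- c(msg, "modification residue inconsistent with modification-type chemistry")
    }
  }
  mt <- object@mutations
  if (nrow(mt) > 0) {
    if (!all(mt$accession %in% acc))
      msg <- c(msg, "mutation rows reference unknown accessions")
    else {
      bad <- mt$position < 1L | mt$position > lens[mt$accession]
      if (any(bad)) msg <- c(msg, "mutation positions out of sequence range")
    }
    if (any(mt$wtResidue == mt$mutResidue))
      msg <- c(msg, "mutation wild-type and mutant residues must differ")
    okCat <- mt$clinicalSignificance %in% c(.DBSNP_CATEGORIES, .HUMSAVAR_CATEGORIES)
    if (!all(okCat))
      msg <- c(msg, "unknown clinical-significance category")
    if (!all(mt$source %in% c("dbsnp", "humsavar")))
      msg <- c(msg, "mutation source must be 'dbsnp' or 'humsavar'")
  }
  if (length(object@goTerms) != nrow(pr) ||
      !identical(names(object@goTerms), as.character(acc)))
    msg <- c(msg, "goTerms must be named by, and parallel to, proteins$accession")
  if (length(msg)) msg else TRUE
}

setValidity("PTMProteome", .validPTMProteome)

.emptyModifications <- function() {
  DataFrame(accession = character(), residue = character(),
            position = integer(), modType = character())
}

.emptyMutations <- function() {
  DataFrame(accession = character(), position = integer(),
            wtResidue = character(), mutResidue = character(),
            clinicalSignificance = character(), source = character(),
            variantId = character())
}

#' Construct a PTMProteome
#'
#' Low-level constructor; most users obtain a `PTMProteome` from
#' [readProteomeFlatfile()] or [generateProteome()].
#'
#' @param proteins `DataFrame` (or data.frame) with columns `accession`,
#'   `gene`, `species` and optionally `altAccessions` (a `CharacterList`).
#'   `length` is derived from `sequences`.
#' @param sequences `AAStringSet` or named character vector of sequences,
#'   parallel to `proteins`.
#' @param modifications,mutations `DataFrame`/data.frame of annotation rows
#'   (see slot documentation); may be `NULL` for none.
#' @param goTerms `CharacterList` (or list of character vectors) parallel to
#'   `proteins`; may be `NULL`.
#' @return A validated [PTMProteome-class] object.
#' @export
PTMProteome <- function(proteins, sequences, modifications = NULL,
                        mutations = NULL, goTerms = NULL) {
  proteins <- DataFrame(proteins, check.names = FALSE)
  if (!methods::is(sequences, "AAStringSet"))
    sequences <- Biostrings::AAStringSet(sequences)
  names(sequences) <- proteins$accession
  if (is.null(proteins$altAccessions))
    proteins$altAccessions <- CharacterList(rep(list(character()), nrow(proteins)))
  if (is.null(proteins$gene)) proteins$gene <- rep("", nrow(proteins))
  if (is.null(proteins$species)) proteins$species <- rep("", nrow(proteins))
  proteins$length <- Biostrings::width(sequences)
  if (is.null(modifications)) modifications <- .emptyModifications()
  if (is.null(mutations)) mutations <- .emptyMutations()
  modifications <- DataFrame(modifications, check.names = FALSE)
  mutations <- DataFrame(mutations, check.names = FALSE)
  if (nrow(mutations) > 0 && is.null(mutations$variantId))
    mutations$variantId <- rep("", nrow(mutations))
  if (is.null(goTerms))
    goTerms <- rep(list(character()), nrow(proteins))
  goTerms <- CharacterList(goTerms)
  names(goTerms) <- proteins$accession
  methods::new("PTMProteome",
    proteins = proteins, sequences = sequences,
    modifications = modifications, mutations = mutations, goTerms = goTerms)
}

#' Synthetic proteome configuration
#'
#' Parameters of the synthetic-proteome generator. Defaults describe a
#' proteome of moderately sized proteins with uniform amino-acid composition,
#' PTM and mutation densities of the same order as curated human annotation
#' sets, a pathogenic labelling rate matching the observed pathogenic fraction
#' of annotated missense variants (~9%), an arginine-skewed mutation spectrum,
#' and no PTM-pathogenicity co-localization effect (`rho = 1`, the null).
#'
#' @slot nProteins Number of proteins to generate.
#' @slot lengthRange Integer `[min, max]` protein length in residues.
#' @slot aaComposition Named probability vector over [aminoAcids()]; sums to 1.
#' @slot ptmRate Named per-eligible-residue placement probability for each
#'   modification type in [modificationTypes()].
#' @slot mutationRate Per-residue probability of carrying a missense mutation.
#' @slot basePathogenicProb Probability a mutation is labelled pathogenic when
#'   the residue is NOT within `windowW` of any PTM.
#' @slot rho Relative risk multiplier on pathogenic labelling for residues
#'   within `windowW` of a PTM of a type in `rhoModTypes`; `rho = 1` is the
#'   null.
#' @slot rhoModTypes Modification types whose proximity carries the `rho`
#'   boost (default: all types), so a co-localization effect can be planted
#'   on one modification type only.
#' @slot windowW Window (residues) used by the generator's co-localization
#'   effect.
#' @slot arginineSkew Multiplier on the mutation probability at arginine (R)
#'   residues, emulating the elevated mutability of arginine codons.
#' @slot pathogenicProteinFraction If not `NA`, pathogenic labels are confined
#'   to this fraction of proteins ("hubs for pathogenicity"), producing the
#'   per-protein clustering of disease annotations seen in curated variant
#'   indexes.
#' @slot seed Integer seed fixing every random draw of the generator.
#' @seealso [SyntheticProteomeConfig()], [generateProteome()]
#' @export
setClass("SyntheticProteomeConfig",
  slots = c(
    nProteins = "integer",
    lengthRange = "integer",
    aaComposition = "numeric",
    ptmRate = "numeric",
    mutationRate = "numeric",
    basePathogenicProb = "numeric",
    rho = "numeric",
    rhoModTypes = "character",
    windowW = "integer",
    arginineSkew = "numeric",
    pathogenicProteinFraction = "numeric",
    seed = "integer"
  )
)

.validSyntheticConfig <- function(object) {
  msg <- character()
  if (object@nProteins < 1L) msg <- c(msg, "nProteins must be >= 1")
  lr <- object@lengthRange
  if (length(lr) != 2L || lr[1] < 1L || lr[2] < lr[1])
    msg <- c(msg, "lengthRange must be [min, max] with 1 <= min <= max")
  comp <- object@aaComposition
  if (!identical(sort(names(comp)), aminoAcids()))
    msg <- c(msg, "aaComposition must be named by the 20 amino acids")
  else if (any(comp < 0 | comp > 1) || abs(sum(comp) - 1) > 1e-9)
    msg <- c(msg, "aaComposition must be probabilities summing to 1 (tol 1e-9)")
  pr <- object@ptmRate
  if (!all(names(pr) %in% names(.MOD_ELIGIBILITY)))
    msg <- c(msg, "ptmRate names must be modification types")
  if (any(pr < 0 | pr > 1)) msg <- c(msg, "ptmRate entries must be in [0,1]")
  for (nm in c("mutationRate", "basePathogenicProb")) {
    v <- methods::slot(object, nm)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must be in [0,1]", nm))
  }
  if (object@rho < 0) msg <- c(msg, "rho must be >= 0")
  if (!all(object@rhoModTypes %in% names(.MOD_ELIGIBILITY)))
    msg <- c(msg, "rhoModTypes must be modification types")
  if (object@windowW < 0L) msg <- c(msg, "windowW must be >= 0")
  if (object@arginineSkew < 0) msg <- c(msg, "arginineSkew must be >= 0")
  ppf <- object@pathogenicProteinFraction
  if (!is.na(ppf) && (ppf <= 0 || ppf > 1))
    msg <- c(msg, "pathogenicProteinFraction must be in (0,1] or NA")
  if (length(msg)) msg else TRUE
}

setValidity("SyntheticProteomeConfig", .validSyntheticConfig)

#' Create a synthetic-proteome configuration
#'
#' @param nProteins Number of proteins (default 2000).
#' @param lengthRange Integer vector `c(min, max)` of protein lengths.
#' @param aaComposition Named probability vector over the 20 amino acids
#'   (default uniform).
#' @param ptmRate Named per-eligible-residue PTM placement probabilities; any
#'   modification type omitted keeps its default.
#' @param mutationRate Per-residue mutation probability.
#' @param basePathogenicProb Pathogenic labelling probability away from PTMs.
#' @param rho Co-localization relative risk (1 = null). `rho *
#'   basePathogenicProb` is capped at 1 with a warning.
#' @param rhoModTypes Modification types carrying the `rho` boost (default
#'   all of [modificationTypes()]).
#' @param windowW Co-localization window in residues.
#' @param arginineSkew Mutation-probability multiplier at arginines.
#' @param pathogenicProteinFraction Optional fraction of proteins eligible to
#'   carry pathogenic labels (`NA` = all proteins eligible).
#' @param seed Integer random seed.
#' @return A validated [SyntheticProteomeConfig-class] object.
#' @export
#' @examples
#' cfg <- SyntheticProteomeConfig(nProteins = 50, seed = 7)
#' cfg
SyntheticProteomeConfig <- function(nProteins = 2000L,
                                    lengthRange = c(100L, 400L),
                                    aaComposition = NULL,
                                    ptmRate = NULL,
                                    mutationRate = 0.05,
                                    basePathogenicProb = 0.09,
                                    rho = 1,
                                    rhoModTypes = names(modificationTypes()),
                                    windowW = 8L,
                                    arginineSkew = 3,
                                    pathogenicProteinFraction = NA_real_,
                                    seed = 1L) {
  if (is.null(aaComposition))
    aaComposition <- stats::setNames(rep(1 / 20, 20), aminoAcids())
  defaultRate <- c("Phosphoserine" = 0.05, "Phosphothreonine" = 0.03,
                   "Phosphotyrosine" = 0.03, "Ubiquitination" = 0.05,
                   "N6-acetyllysine" = 0.03, "N-Glycosylation" = 0.02)
  if (!is.null(ptmRate)) {
    bad <- setdiff(names(ptmRate), names(defaultRate))
    if (length(bad)) .stopConfig(sprintf("unknown ptmRate type(s): %s",
                                         paste(bad, collapse = ", ")))
    defaultRate[names(ptmRate)] <- ptmRate
  }
  if (rho * basePathogenicProb > 1)
    warning("rho * basePathogenicProb exceeds 1; pathogenic probability capped at 1")
  obj <- methods::new("SyntheticProteomeConfig",
    nProteins = as.integer(nProteins),
    lengthRange = as.integer(lengthRange),
    aaComposition = aaComposition[aminoAcids()],
    ptmRate = defaultRate,
    mutationRate = mutationRate,
    basePathogenicProb = basePathogenicProb,
    rho = rho,
    rhoModTypes = rhoModTypes,
    windowW = as.integer(windowW),
    arginineSkew = arginineSkew,
    pathogenicProteinFraction = pathogenicProteinFraction,
    seed = as.integer(seed))
  obj
}
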