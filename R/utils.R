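# Internal constants and helpers shared across modules.

#' The twenty standard one-letter amino-acid codes
#'
#' @return Character vector of the 20 standard residues, alphabetical.
#' @export
#' @examples aminoAcids()
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Chemistry: which wild-type residue each modification type requires.
.MOD_ELIGIBILITY <- c(
  "Phosphoserine"   = "S",
  "Phosphothreonine" = "T",
  "Phosphotyrosine" = "Y",
  "Ubiquitination"  = "K",
  "N6-acetyllysine" = "K",
  "N-Glycosylation" = "N"
)

#' Modification-type vocabulary
#'
#' The controlled vocabulary of modification types tested per type. Labels
#' outside this set are carried through parsing as `"Other:<label>"` and are
#' excluded from per-type tests by default.
#'
#' @return Named character vector mapping each modification type to the
#'   wild-type residue its chemistry requires.
#' @export
#' @examples modificationTypes()
modificationTypes <- function() .MOD_ELIGIBILITY

# Clinical-significance vocabularies by mutation source.
.DBSNP_CATEGORIES    <- c("pathogenic", "non-pathogenic", "unannotated")
.HUMSAVAR_CATEGORIES <- c("Disease", "Polymorphism", "Unclassified")

.pathogenicToken <- function(source) {
  switch(match.arg(source, c("dbsnp", "humsavar")),
         dbsnp = "pathogenic", humsavar = "Disease")
}

# Three-letter <-> one-letter amino-acid code maps, built from Biostrings.
.THREE_TO_ONE <- local({
  code <- Biostrings::AMINO_ACID_CODE[aminoAcids()]
  stats::setNames(names(code), unname(code))
})
.ONE_TO_THREE <- stats::setNames(names(.THREE_TO_ONE), unname(.THREE_TO_ONE))

# ---- condition constructors -------------------------------------------------
# Typed conditions so callers (and tests) can distinguish failure modes.

.stopNotFound <- function(acc) {
  stop(errorCondition(sprintf("accession not found: '%s'", acc),
                      class = c("ptmenrich_accession_not_found", "ptmenrich_error")))
}

.stopFormat <- function(msg) {
  stop(errorCondition(msg, class = c("ptmenrich_format_error", "ptmenrich_error")))
}

.stopDegenerate <- function(msg) {
  stop(errorCondition(msg, class = c("ptmenrich_degenerate_input", "ptmenrich_error")))
}

.stopEmptyForeground <- function(msg) {
  stop(errorCondition(msg, class = c("ptmenrich_empty_foreground", "ptmenrich_error")))
}

.stopInfeasible <- function(msg) {
  stop(errorCondition(msg, class = c("ptmenrich_infeasible_composition", "ptmenrich_error")))
}

.stopUndefined <- function(msg) {
  stop(errorCondition(msg, class = c("ptmenrich_undefined_fraction", "ptmenrich_error")))
}

.stopConfig <- function(msg) {
  stop(errorCondition(msg, class = c("ptmenrich_config_error", "ptmenrich_error")))
}

.stopUsage <- function(msg) {
  stop(errorCondition(msg, class = c("ptmenrich_usage_error", "ptmenrich_error")))
}

# ---- positional indexing ----------------------------------------------------
# Residues across a proteome are mapped to one strictly increasing "global"
# coordinate axis so that windowed proximity queries reduce to interval lookups
# on a sorted vector. The per-protein offset exceeds any protein length plus
# twice the widest window, so a window around a residue can never reach into a
# neighbouring protein's coordinate block.

.globalOffset <- function(proteome, window) {
  max(proteinLengths(proteome)) + 2L * max(window, 0L) + 2L
}

.globalCoord <- function(accession, position, accLevels, offset) {
  idx <- match(accession, accLevels)
  as.numeric(idx) * offset + as.numeric(position)
}

# For each query coordinate, is there any site coordinate within +/- window?
.anyWithinWindow <- function(queryCoord, siteCoord, window) {
  if (length(siteCoord) == 0L) return(rep(FALSE, length(queryCoord)))
  s <- sort(siteCoord)
  # first site strictly greater than query - window - 1: candidate nearest site
  idx <- findInterval(queryCoord - window - 0.5, s)
  nxt <- s[pmin(idx + 1L, length(s))]
  idx < length(s) & nxt <= queryCoord + window
}

# quiet logging helper: emits a message only when count > 0
.logDropped <- function(n, what) {
  if (n > 0L) message(sprintf("ptmenrich: dropped %d %s", n, what))
  invisible(n)
}
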