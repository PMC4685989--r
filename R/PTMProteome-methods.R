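#' Accessors for PTMProteome objects
#'
#' `proteins()` returns the protein-level table; `modifications()` and
#' `mutations()` the proteome-wide annotation tables; `goTerms()` the
#' per-protein GO identifier list; `proteinSequences()` the `AAStringSet`;
#' `accessions()`, `nProteins()` and `proteinLengths()` the obvious summaries.
#'
#' @param x A [PTMProteome-class] object.
#' @return See individual accessor descriptions.
#' @name PTMProteome-accessors
#' @aliases proteins modifications mutations goTerms proteinSequences
#'   accessions nProteins proteinLengths
NULL

#' @rdname PTMProteome-accessors
#' @export
setMethod("proteins", "PTMProteome", function(x) x@proteins)

#' @rdname PTMProteome-accessors
#' @export
setMethod("modifications", "PTMProteome", function(x) x@modifications)

#' @rdname PTMProteome-accessors
#' @export
setMethod("mutations", "PTMProteome", function(x) x@mutations)

#' @rdname PTMProteome-accessors
#' @export
setMethod("goTerms", "PTMProteome", function(x) x@goTerms)

#' @rdname PTMProteome-accessors
#' @export
setMethod("proteinSequences", "PTMProteome", function(x) x@sequences)

#' @rdname PTMProteome-accessors
#' @export
setMethod("accessions", "PTMProteome", function(x) as.character(x@proteins$accession))

#' @rdname PTMProteome-accessors
#' @export
setMethod("nProteins", "PTMProteome", function(x) nrow(x@proteins))

#' @rdname PTMProteome-accessors
#' @export
setMethod("proteinLengths", "PTMProteome",
          function(x) stats::setNames(x@proteins$length, x@proteins$accession))

setMethod("show", "PTMProteome", function(object) {
  cat(sprintf("PTMProteome with %d protein(s)\n", nProteins(object)))
  cat(sprintf("  modifications: %d  (types: %s)\n",
              nrow(object@modifications),
              paste(sort(unique(object@modifications$modType)), collapse = ", ")))
  src <- table(factor(object@mutations$source, levels = c("dbsnp", "humsavar")))
  cat(sprintf("  mutations: %d  (dbsnp: %d, humsavar: %d)\n",
              nrow(object@mutations), src[["dbsnp"]], src[["humsavar"]]))
  cat(sprintf("  GO terms: %d\n", sum(lengths(object@goTerms))))
  invisible(NULL)
})

# Resolve a primary-or-alternate accession to the row index of its record.
.resolveAccession <- function(x, acc) {
  stopifnot(is.character(acc), length(acc) == 1L)
  i <- match(acc, x@proteins$accession)
  if (!is.na(i)) return(i)
  alt <- x@proteins$altAccessions
  hits <- which(any(alt == acc))
  if (length(hits) >= 1L) return(hits[1L])
  .stopNotFound(acc)
}

#' Per-record retrieval API
#'
#' Retrieve the annotations of one protein record by primary or alternate
#' accession, mirroring a flat-file database API: `getMutations()`,
#' `getPTMs()`, `getSequence()` and `getGoTerms()`. An unknown accession
#' raises an error of class `"ptmenrich_accession_not_found"` — distinct from
#' the empty result a known but unannotated protein returns.
#'
#' @param x A [PTMProteome-class].
#' @param acc A single accession string (primary or alternate).
#' @return `getMutations()` and `getPTMs()` return the matching rows of the
#'   proteome-wide annotation `DataFrame`s; `getSequence()` a single character
#'   string; `getGoTerms()` a character vector of GO identifiers.
#' @name record-api
#' @aliases getMutations getPTMs getSequence getGoTerms
#' @examples
#' pg <- generateProteome(SyntheticProteomeConfig(nProteins = 5, seed = 1))
#' getSequence(pg$proteome, accessions(pg$proteome)[1])
NULL

#' @rdname record-api
#' @export
setMethod("getMutations", "PTMProteome", function(x, acc) {
  i <- .resolveAccession(x, acc)
  mt <- x@mutations
  mt[mt$accession == x@proteins$accession[i], , drop = FALSE]
})

#' @rdname record-api
#' @export
setMethod("getPTMs", "PTMProteome", function(x, acc) {
  i <- .resolveAccession(x, acc)
  md <- x@modifications
  md[md$accession == x@proteins$accession[i], , drop = FALSE]
})

#' @rdname record-api
#' @export
setMethod("getSequence", "PTMProteome", function(x, acc) {
  i <- .resolveAccession(x, acc)
  as.character(x@sequences[[i]])
})

#' @rdname record-api
#' @export
setMethod("getGoTerms", "PTMProteome", function(x, acc) {
  i <- .resolveAccession(x, acc)
  as.character(x@goTerms[[i]])
})

#' Subset a proteome by accession or index
#'
#' Keeps the selected protein records together with their modification,
#' mutation and GO annotations.
#'
#' @param x A [PTMProteome-class].
#' @param i Character vector of primary accessions, or integer/logical index
#'   into the protein table.
#' @param j,...,drop Ignored (present for generic compatibility).
#' @return A [PTMProteome-class] restricted to the selected records.
#' @export
setMethod("[", "PTMProteome", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, x@proteins$accession)
    if (anyNA(idx)) .stopNotFound(i[which(is.na(idx))[1L]])
  } else idx <- seq_len(nProteins(x))[i]
  keep <- as.character(x@proteins$accession[idx])
  md <- x@modifications; mt <- x@mutations
  methods::new("PTMProteome",
    proteins = x@proteins[idx, , drop = FALSE],
    sequences = x@sequences[idx],
    modifications = md[md$accession %in% keep, , drop = FALSE],
    mutations = mt[mt$accession %in% keep, , drop = FALSE],
    goTerms = x@goTerms[idx])
})
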