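# ProteomeScout-like flat-file dialect: TSV, UTF-8, header row, one protein
# per line, annotation cells holding "; "-separated tokens.
#
#   accession        primary UniProtKB-style accession (unique)
#   alt_accessions   "; "-separated alternate accessions
#   gene, species    free text
#   sequence         one-letter amino acids (X permitted)
#   modifications    tokens "R P-T", e.g. "S 259-Phosphoserine"
#   mutations        tokens "XposY[:annotation]", e.g. "V263A:pathogenic";
#                    absent annotation means unannotated
#   GO_terms         "GO:0008284; GO:0004672"
#
# This dialect is ProteomeScout-LIKE: same column-wise, semicolon-delimited
# structure, not byte-compatible with any particular database release.

.FLATFILE_COLUMNS <- c("accession", "alt_accessions", "gene", "species",
                       "sequence", "modifications", "mutations", "GO_terms")

.splitTokens <- function(cell) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(character())
  trimws(strsplit(cell, ";", fixed = TRUE)[[1L]])
}

#' Read a ProteomeScout-like flat file
#'
#' Parses the tab-separated protein-annotation dialect documented above into a
#' [PTMProteome-class]. Every annotation token is validated against the record
#' it belongs to: modification tokens must name a residue consistent with
#' their type's chemistry and with the sequence at that position; mutation
#' tokens must match the wild-type sequence residue and mutate it to a
#' different residue. Duplicate tokens (identical position and type /
#' substitution) are de-duplicated.
#'
#' In lenient mode (default) invalid tokens are dropped with a logged count —
#' the expected behaviour on real data, where isoform or sequence-version
#' mismatches are routine. With `strict = TRUE` the first invalid token aborts
#' parsing.
#'
#' @param path Path to the flat file.
#' @param strict Abort on the first malformed or inconsistent annotation token
#'   instead of dropping it.
#' @return A [PTMProteome-class].
#' @seealso [writeProteomeFlatfile()], [getMutations()]
#' @export
readProteomeFlatfile <- function(path, strict = FALSE) {
  if (!file.exists(path)) .stopFormat(sprintf("no such file: '%s'", path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           check.names = FALSE, na.strings = NULL,
                           fileEncoding = "UTF-8")
  missing <- setdiff(.FLATFILE_COLUMNS, colnames(tab))
  if (length(missing))
    .stopFormat(sprintf("flat file is missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  if (anyDuplicated(tab$accession))
    .stopFormat("duplicate primary accession in flat file")
  if (any(!nzchar(tab$accession)))
    .stopFormat("empty primary accession in flat file")

  alphabet <- c(aminoAcids(), "X")
  badSeq <- !grepl(sprintf("^[%s]+$", paste(alphabet, collapse = "")), tab$sequence)
  if (any(badSeq))
    .stopFormat(sprintf("invalid sequence characters in record '%s'",
                        tab$accession[which(badSeq)[1L]]))

  nDroppedMod <- 0L; nDroppedMut <- 0L
  modRows <- vector("list", nrow(tab))
  mutRows <- vector("list", nrow(tab))

  for (i in seq_len(nrow(tab))) {
    acc <- tab$accession[i]
    seqChars <- strsplit(tab$sequence[i], "")[[1L]]
    len <- length(seqChars)

    # modifications: "R P-T"
    toks <- .splitTokens(tab$modifications[i])
    if (length(toks)) {
      m <- regmatches(toks, regexec("^([A-Z]) (\\d+)-(.+)$", toks))
      parsed <- lapply(seq_along(toks), function(k) {
        g <- m[[k]]
        if (length(g) != 4L) {
          if (strict) .stopFormat(sprintf(
            "malformed modification token '%s' in record '%s'", toks[k], acc))
          return(NULL)
        }
        res <- g[2]; pos <- as.integer(g[3]); lab <- g[4]
        known <- lab %in% names(.MOD_ELIGIBILITY)
        if (!known && !startsWith(lab, "Other:")) lab <- paste0("Other:", lab)
        ok <- pos >= 1L && pos <= len && seqChars[pos] == res &&
          (!known || .MOD_ELIGIBILITY[[lab]] == res)
        if (!ok) {
          if (strict) .stopFormat(sprintf(
            "inconsistent modification token '%s' in record '%s'", toks[k], acc))
          return(NULL)
        }
        data.frame(accession = acc, residue = res, position = pos,
                   modType = lab, stringsAsFactors = FALSE)
      })
      nDroppedMod <- nDroppedMod + sum(vapply(parsed, is.null, logical(1)))
      keep <- do.call(rbind, parsed[!vapply(parsed, is.null, logical(1))])
      if (!is.null(keep))
        modRows[[i]] <- keep[!duplicated(keep[c("position", "modType")]), , drop = FALSE]
    }

    # mutations: "XposY[:annotation]"
    toks <- .splitTokens(tab$mutations[i])
    if (length(toks)) {
      m <- regmatches(toks, regexec("^([A-Z])(\\d+)([A-Z])(:(.+))?$", toks))
      parsed <- lapply(seq_along(toks), function(k) {
        g <- m[[k]]
        if (length(g) != 6L) {
          if (strict) .stopFormat(sprintf(
            "malformed mutation token '%s' in record '%s'", toks[k], acc))
          return(NULL)
        }
        wt <- g[2]; pos <- as.integer(g[3]); mut <- g[4]
        ann <- if (nzchar(g[6])) g[6] else "unannotated"
        ok <- pos >= 1L && pos <= len && seqChars[pos] == wt && wt != mut &&
          ann %in% .DBSNP_CATEGORIES
        if (!ok) {
          if (strict) .stopFormat(sprintf(
            "inconsistent mutation token '%s' in record '%s'", toks[k], acc))
          return(NULL)
        }
        data.frame(accession = acc, position = pos, wtResidue = wt,
                   mutResidue = mut, clinicalSignificance = ann,
                   source = "dbsnp", variantId = "", stringsAsFactors = FALSE)
      })
      nDroppedMut <- nDroppedMut + sum(vapply(parsed, is.null, logical(1)))
      keep <- do.call(rbind, parsed[!vapply(parsed, is.null, logical(1))])
      if (!is.null(keep))
        mutRows[[i]] <- keep[!duplicated(keep[c("position", "mutResidue",
                                                "clinicalSignificance")]), ,
                             drop = FALSE]
    }
  }
  .logDropped(nDroppedMod, "modification token(s)")
  .logDropped(nDroppedMut, "mutation token(s)")

  goList <- lapply(tab$GO_terms, .splitTokens)
  altList <- lapply(tab$alt_accessions, .splitTokens)

  proteinsDF <- DataFrame(
    accession = tab$accession,
    altAccessions = CharacterList(altList),
    gene = tab$gene,
    species = tab$species
  )
  PTMProteome(
    proteins = proteinsDF,
    sequences = Biostrings::AAStringSet(stats::setNames(tab$sequence, tab$accession)),
    modifications = do.call(rbind, modRows[!vapply(modRows, is.null, logical(1))]),
    mutations = do.call(rbind, mutRows[!vapply(mutRows, is.null, logical(1))]),
    goTerms = goList
  )
}

#' Write a proteome in the flat-file dialect
#'
#' Inverse of [readProteomeFlatfile()]: emits one tab-separated line per
#' protein with "; "-joined annotation tokens. Humsavar-sourced mutations are
#' not representable in this dialect (its annotation vocabulary is the
#' dbSNP-style one) and are skipped with a logged count.
#'
#' @param proteome A [PTMProteome-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeProteomeFlatfile <- function(proteome, path) {
  pr <- proteins(proteome)
  md <- modifications(proteome)
  mt <- mutations(proteome)
  keepMt <- mt$source == "dbsnp"
  .logDropped(sum(!keepMt), "non-dbsnp mutation(s) not representable in the flat-file dialect")
  mt <- mt[keepMt, , drop = FALSE]

  modCell <- function(acc) {
    rows <- md[md$accession == acc, , drop = FALSE]
    if (nrow(rows) == 0L) return("")
    rows <- rows[order(rows$position, rows$modType), , drop = FALSE]
    paste(sprintf("%s %d-%s", rows$residue, rows$position, rows$modType),
          collapse = "; ")
  }
  mutCell <- function(acc) {
    rows <- mt[mt$accession == acc, , drop = FALSE]
    if (nrow(rows) == 0L) return("")
    rows <- rows[order(rows$position, rows$mutResidue), , drop = FALSE]
    ann <- ifelse(rows$clinicalSignificance == "unannotated", "",
                  paste0(":", rows$clinicalSignificance))
    paste(sprintf("%s%d%s%s", rows$wtResidue, rows$position, rows$mutResidue, ann),
          collapse = "; ")
  }
  lines <- vapply(seq_len(nrow(pr)), function(i) {
    acc <- pr$accession[i]
    paste(c(acc,
            paste(pr$altAccessions[[i]], collapse = "; "),
            pr$gene[i], pr$species[i],
            as.character(proteinSequences(proteome)[[i]]),
            modCell(acc), mutCell(acc),
            paste(goTerms(proteome)[[i]], collapse = "; ")),
          collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(.FLATFILE_COLUMNS, collapse = "\t"), lines), con)
  invisible(path)
}
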