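# UniProt humsavar-style variant index: whitespace-aligned columnar text
# (gene, accession, FT id VAR_NNNNNN, change p.Xaa123Xaa, category, dbSNP id,
# disease name), with free-text preamble and footer around the data block.

.HUMSAVAR_LINE <- "^\\s*(\\S+)\\s+(\\S+)\\s+(VAR_\\d{6})\\s+(\\S+)\\s+(\\S+)\\s*(\\S*)\\s*(.*)$"

#' Read a humsavar-style variant index file
#'
#' Data lines are recognized by their `VAR_NNNNNN` feature identifier, so any
#' preamble or footer text is tolerated. Only simple missense substitutions
#' (`p.Xaa123Xaa` with mappable three-letter codes and differing wild-type and
#' mutant residues) are retained; other change tokens (deletions, frameshifts,
#' extensions, unmappable codes) are skipped with a logged count.
#'
#' Categories are matched case-sensitively against the classic vocabulary
#' `Disease` / `Polymorphism` / `Unclassified`. Newer vocabularies (e.g.
#' `LB/B`, `LP/P`) can be folded in via `categoryMap`.
#'
#' @param path Path to the humsavar-style file.
#' @param categoryMap Optional named character vector mapping file category
#'   tokens onto the classic vocabulary, e.g. `c("LP/P" = "Disease")`.
#' @return `data.frame` with one row per retained variant: `gene`,
#'   `accession`, `ftid`, `wtResidue`, `position`, `mutResidue`, `category`,
#'   `dbsnpId`, `diseaseName`.
#' @export
readHumsavar <- function(path, categoryMap = NULL) {
  if (!file.exists(path)) .stopFormat(sprintf("no such file: '%s'", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  isData <- grepl("\\bVAR_\\d{6}\\b", lines)
  if (!any(isData)) .stopFormat("no humsavar data block found (no VAR_ lines)")
  m <- regmatches(lines[isData], regexec(.HUMSAVAR_LINE, lines[isData]))

  nSkipped <- 0L
  rows <- lapply(m, function(g) {
    if (length(g) != 8L) { nSkipped <<- nSkipped + 1L; return(NULL) }
    chg <- regexec("^p\\.([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})$", g[5])
    cg <- regmatches(g[5], chg)[[1L]]
    if (length(cg) != 4L) { nSkipped <<- nSkipped + 1L; return(NULL) }
    wt <- .THREE_TO_ONE[cg[2]]; mut <- .THREE_TO_ONE[cg[4]]
    if (is.na(wt) || is.na(mut) || wt == mut) { nSkipped <<- nSkipped + 1L; return(NULL) }
    cat <- g[6]
    if (!is.null(categoryMap) && cat %in% names(categoryMap))
      cat <- unname(categoryMap[[cat]])
    if (!cat %in% .HUMSAVAR_CATEGORIES) { nSkipped <<- nSkipped + 1L; return(NULL) }
    dbsnp <- if (g[7] %in% c("-", "")) "" else g[7]
    data.frame(gene = g[2], accession = g[3], ftid = g[4],
               wtResidue = unname(wt), position = as.integer(cg[3]),
               mutResidue = unname(mut), category = cat,
               dbsnpId = dbsnp, diseaseName = trimws(g[8]),
               stringsAsFactors = FALSE)
  })
  .logDropped(nSkipped, "non-missense or unparseable humsavar line(s)")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(gene = character(), accession = character(),
                      ftid = character(), wtResidue = character(),
                      position = integer(), mutResidue = character(),
                      category = character(), dbsnpId = character(),
                      diseaseName = character(), stringsAsFactors = FALSE)
  out
}

#' Cross-reference humsavar variants onto a proteome
#'
#' Attaches each variant whose accession matches a record (primary or
#' alternate; matched variants are attributed to the primary record) and
#' whose wild-type residue agrees with the sequence at its position as a
#' humsavar-sourced mutation. Variants failing the residue check (including
#' positions beyond the sequence) or with no matching record are tallied, not
#' attached. Identity is the accession string as printed; isoform-suffixed
#' accessions are distinct.
#'
#' @param variants `data.frame` from [readHumsavar()].
#' @param proteome A [PTMProteome-class].
#' @return List with `proteome` (augmented [PTMProteome-class]) and `report`,
#'   a one-row `data.frame` of counts (`matched`, `residueMismatch`,
#'   `accessionUnmatched`) that always sum to `nrow(variants)`.
#' @export
crossrefHumsavar <- function(variants, proteome) {
  pr <- proteins(proteome)
  primary <- as.character(pr$accession)
  altFlat <- unlist(pr$altAccessions)
  altOwner <- rep(primary, lengths(pr$altAccessions))
  toPrimary <- c(stats::setNames(primary, primary),
                 stats::setNames(altOwner, altFlat))

  mapped <- toPrimary[variants$accession]
  unmatched <- is.na(mapped)
  okRows <- !unmatched
  residueOk <- rep(FALSE, nrow(variants))
  if (any(okRows)) {
    lens <- proteinLengths(proteome)[mapped[okRows]]
    inRange <- variants$position[okRows] >= 1L & variants$position[okRows] <= lens
    seqChar <- rep(NA_character_, sum(okRows))
    if (any(inRange)) {
      idx <- which(okRows)[inRange]
      seqChar[inRange] <- vapply(seq_along(idx), function(k) {
        substring(getSequence(proteome, mapped[idx[k]]),
                  variants$position[idx[k]], variants$position[idx[k]])
      }, character(1))
    }
    residueOk[okRows] <- inRange & !is.na(seqChar) &
      seqChar == variants$wtResidue[okRows]
  }
  attach <- residueOk
  report <- data.frame(
    matched = sum(attach),
    residueMismatch = sum(!attach & !unmatched),
    accessionUnmatched = sum(unmatched)
  )
  if (any(attach)) {
    newMut <- DataFrame(
      accession = unname(mapped[attach]),
      position = variants$position[attach],
      wtResidue = variants$wtResidue[attach],
      mutResidue = variants$mutResidue[attach],
      clinicalSignificance = variants$category[attach],
      source = "humsavar",
      variantId = variants$ftid[attach]
    )
    proteome@mutations <- rbind(proteome@mutations, newMut)
    methods::validObject(proteome)
  }
  list(proteome = proteome, report = report)
}

#' Disease fraction of a variant set
#'
#' The proportion of variants categorized `Disease`. With
#' `restrictToDiseaseProteins = TRUE` the variant set is first restricted to
#' proteins (accessions) carrying at least one `Disease` variant — the
#' study-bias-controlled view. Since every variant removed by the restriction
#' is non-Disease by construction, the restricted fraction can never be
#' smaller than the overall one.
#'
#' @param variants `data.frame` from [readHumsavar()].
#' @param restrictToDiseaseProteins Apply the restriction described above.
#' @return List with `nTotal`, `nDisease` and `fraction = nDisease/nTotal`.
#' @export
diseaseFraction <- function(variants, restrictToDiseaseProteins = FALSE) {
  if (nrow(variants) == 0L)
    .stopUndefined("disease fraction is undefined for an empty variant set")
  if (restrictToDiseaseProteins) {
    diseaseAcc <- unique(variants$accession[variants$category == "Disease"])
    variants <- variants[variants$accession %in% diseaseAcc, , drop = FALSE]
    if (nrow(variants) == 0L)
      .stopUndefined("no proteins with a Disease variant")
  }
  nTotal <- nrow(variants)
  nDisease <- sum(variants$category == "Disease")
  list(nTotal = nTotal, nDisease = nDisease, fraction = nDisease / nTotal)
}

#' Write a humsavar-style variant index file
#'
#' Emits the mutations of a proteome as simple missense lines in the
#' humsavar dialect, with a short preamble and footer framing the data block.
#' Clinical-significance categories are mapped onto the humsavar vocabulary:
#' `pathogenic` becomes `Disease`, `non-pathogenic` becomes `Polymorphism`,
#' `unannotated` becomes `Unclassified`; humsavar-sourced categories pass
#' through unchanged.
#'
#' @param proteome A [PTMProteome-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeHumsavar <- function(proteome, path) {
  mt <- mutations(proteome)
  pr <- proteins(proteome)
  gene <- stats::setNames(as.character(pr$gene), pr$accession)
  catMap <- c(pathogenic = "Disease", "non-pathogenic" = "Polymorphism",
              unannotated = "Unclassified",
              Disease = "Disease", Polymorphism = "Polymorphism",
              Unclassified = "Unclassified")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("Index of protein variants (synthetic)",
               "_________________________________________",
               ""), con)
  if (nrow(mt) > 0) {
    ord <- order(mt$accession, mt$position, mt$mutResidue)
    mt <- mt[ord, , drop = FALSE]
    ftid <- ifelse(nzchar(mt$variantId) & grepl("^VAR_\\d{6}$", mt$variantId),
                   mt$variantId, sprintf("VAR_%06d", seq_len(nrow(mt))))
    g <- gene[mt$accession]
    g[!nzchar(g) | is.na(g)] <- "-"
    writeLines(sprintf("%-10s %-10s %-10s %-14s %-14s %-12s %s",
                       g, mt$accession, ftid,
                       sprintf("p.%s%d%s", .ONE_TO_THREE[mt$wtResidue],
                               mt$position, .ONE_TO_THREE[mt$mutResidue]),
                       unname(catMap[mt$clinicalSignificance]),
                       "-", "-"), con)
  }
  writeLines(c("", "End of index."), con)
  invisible(path)
}
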