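flatHeader <- paste(c("accession", "alt_accessions", "gene", "species",
                      "sequence", "modifications", "mutations", "GO_terms"),
                    collapse = "\t")

writeFlatLines <- function(dataLines, header = flatHeader) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(header, dataLines), path)
  path
}

test_that("semicolon-delimited annotation cells parse into typed rows", {
  seq <- paste(c(rep("A", 256), "S", "T", "S", rep("A", 10)), collapse = "")
  line <- paste("P00001", "X00001; X00002", "KIN", "human", seq,
                "S 259-Phosphoserine; S 257-Phosphoserine",
                "A263G:pathogenic; A100C", "GO:0008284; GO:0004672",
                sep = "\t")
  p <- readProteomeFlatfile(writeFlatLines(line))
  md <- getPTMs(p, "P00001")
  expect_equal(sort(md$position), c(257L, 259L))
  expect_equal(unique(md$modType), "Phosphoserine")
  mt <- getMutations(p, "P00001")
  expect_equal(nrow(mt), 2L)
  expect_equal(mt$clinicalSignificance[mt$position == 263], "pathogenic")
  expect_equal(mt$clinicalSignificance[mt$position == 100], "unannotated")
  expect_equal(getGoTerms(p, "P00001"), c("GO:0008284", "GO:0004672"))
})

test_that("empty annotation cells give empty lists without error", {
  line <- paste("P00002", "", "G2", "human", "MASTR", "", "", "", sep = "\t")
  p <- readProteomeFlatfile(writeFlatLines(line))
  expect_equal(nrow(getPTMs(p, "P00002")), 0L)
  expect_equal(nrow(getMutations(p, "P00002")), 0L)
  expect_equal(getGoTerms(p, "P00002"), character(0))
})

test_that("alternate accessions resolve to the same record; unknowns error", {
  p <- kinaseFixture()
  expect_equal(as.data.frame(getMutations(p, "XK001")),
               as.data.frame(getMutations(p, "KIN001")))
  expect_equal(getSequence(p, "XK001"), getSequence(p, "KIN001"))
  expect_error(getMutations(p, "NOSUCH"),
               class = "ptmenrich_accession_not_found")
  expect_equal(nrow(getMutations(p, "KIN001")), 3L)
})

test_that("lenient parsing drops inconsistent tokens with a log; strict aborts", {
  seq <- "MASTKR"
  line <- paste("P00003", "", "G3", "human", seq,
                "S 99-Phosphoserine; T 4-Phosphothreonine",
                "V2A:pathogenic; A2G", "", sep = "\t")
  # S 99 beyond length and V2 disagreeing with sequence 'A' are dropped
  expect_message(p <- readProteomeFlatfile(writeFlatLines(line)),
                 "dropped 1 modification")
  expect_equal(getPTMs(p, "P00003")$position, 4L)
  expect_equal(getMutations(p, "P00003")$mutResidue, "G")
  expect_error(readProteomeFlatfile(writeFlatLines(line), strict = TRUE),
               class = "ptmenrich_format_error")
})

test_that("chemistry-inconsistent modification tokens are rejected", {
  # residue A at position 2 cannot carry a serine-only modification type
  line <- paste("P00004", "", "G4", "human", "MASTKR",
                "A 2-Phosphoserine", "", "", sep = "\t")
  expect_message(p <- readProteomeFlatfile(writeFlatLines(line)),
                 "dropped 1 modification")
  expect_equal(nrow(getPTMs(p, "P00004")), 0L)
  # unknown labels survive as Other:<label>, excluded from the typed vocabulary
  line2 <- paste("P00005", "", "G5", "human", "MASTKR",
                 "K 5-Sumoylation", "", "", sep = "\t")
  p2 <- readProteomeFlatfile(writeFlatLines(line2))
  expect_equal(getPTMs(p2, "P00005")$modType, "Other:Sumoylation")
})

test_that("duplicate annotation tokens are de-duplicated", {
  line <- paste("P00006", "", "G6", "human", "MASTKR",
                "S 3-Phosphoserine; S 3-Phosphoserine",
                "S3A:pathogenic; S3A:pathogenic", "", sep = "\t")
  p <- readProteomeFlatfile(writeFlatLines(line))
  expect_equal(nrow(getPTMs(p, "P00006")), 1L)
  expect_equal(nrow(getMutations(p, "P00006")), 1L)
})

test_that("missing required columns and duplicate accessions are format errors", {
  path <- writeFlatLines("P1\tx", header = "accession\tgene")
  expect_error(readProteomeFlatfile(path), class = "ptmenrich_format_error")
  expect_error(readProteomeFlatfile(path), "modifications")
  dup <- paste("P1", "", "G", "h", "MAST", "", "", "", sep = "\t")
  expect_error(readProteomeFlatfile(writeFlatLines(c(dup, dup))),
               class = "ptmenrich_format_error")
})

test_that("write-then-parse is the identity on generated record sets", {
  sim <- smallSim(seed = 101, nProteins = 30)
  path <- tempfile(fileext = ".tsv")
  writeProteomeFlatfile(sim$proteome, path)
  p <- readProteomeFlatfile(path)
  orig <- sim$proteome
  expect_equal(accessions(p), accessions(orig))
  expect_equal(as.character(proteinSequences(p)), as.character(proteinSequences(orig)))
  expect_equal(as.data.frame(modifications(p)), as.data.frame(modifications(orig)))
  expect_equal(as.data.frame(mutations(p)), as.data.frame(mutations(orig)))
  expect_equal(lapply(goTerms(p), as.character), lapply(goTerms(orig), as.character))
  expect_equal(as.data.frame(proteins(p)), as.data.frame(proteins(orig)))
})

test_that("parsing is order-independent over data lines", {
  sim <- smallSim(seed = 102, nProteins = 15)
  path <- tempfile(fileext = ".tsv")
  writeProteomeFlatfile(sim$proteome, path)
  lines <- readLines(path)
  perm <- c(lines[1], sample(lines[-1]))
  path2 <- tempfile(fileext = ".tsv")
  writeLines(perm, path2)
  a <- readProteomeFlatfile(path)
  b <- readProteomeFlatfile(path2)
  ordB <- match(accessions(a), accessions(b))
  expect_equal(accessions(b)[ordB], accessions(a))
  mdA <- as.data.frame(modifications(a))
  mdB <- as.data.frame(modifications(b))
  mdB <- mdB[order(mdB$accession, mdB$position, mdB$modType), ]
  mdA <- mdA[order(mdA$accession, mdA$position, mdA$modType), ]
  rownames(mdA) <- rownames(mdB) <- NULL
  expect_equal(mdB, mdA)
})

test_that("every retained annotation satisfies its invariants proteome-wide", {
  sim <- smallSim(seed = 103, nProteins = 40)
  path <- tempfile(fileext = ".tsv")
  writeProteomeFlatfile(sim$proteome, path)
  p <- readProteomeFlatfile(path)
  lens <- proteinLengths(p)
  md <- as.data.frame(modifications(p))
  expect_true(all(md$position >= 1 & md$position <= lens[md$accession]))
  known <- md$modType %in% names(modificationTypes())
  expect_true(all(md$residue[known] == modificationTypes()[md$modType[known]]))
  mt <- as.data.frame(mutations(p))
  expect_true(all(mt$position >= 1 & mt$position <= lens[mt$accession]))
  expect_true(all(mt$wtResidue != mt$mutResidue))
})
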