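# Hand-built fixtures, constructed in code at test time.

# A sequence of the given length that is 'G' everywhere except at named
# positions, e.g. seqWith(300, c(`259` = "S", `263` = "V")).
seqWith <- function(len, residues) {
  s <- rep("G", len)
  s[as.integer(names(residues))] <- residues
  paste(s, collapse = "")
}

# A kinase-like record: phosphosites clustered around position 259 and a
# cluster of mutations between 256 and 263, one of them pathogenic.
kinaseFixture <- function() {
  seqs <- c(
    KIN001 = seqWith(300, c(`256` = "R", `257` = "S", `258` = "T", `259` = "S",
                            `260` = "T", `263` = "V", `100` = "K")),
    SPR002 = seqWith(120, c(`10` = "S", `100` = "K", `108` = "S", `109` = "S"))
  )
  proteins <- data.frame(accession = names(seqs),
                         gene = c("KIN1", "SPR2"),
                         species = "synthetic",
                         stringsAsFactors = FALSE)
  proteins$altAccessions <- IRanges::CharacterList(list("XK001", character()))
  mods <- data.frame(
    accession = c("KIN001", "KIN001", "KIN001", "SPR002", "SPR002"),
    residue   = c("S", "S", "T", "S", "K"),
    position  = c(257L, 259L, 260L, 108L, 100L),
    modType   = c("Phosphoserine", "Phosphoserine", "Phosphothreonine",
                  "Phosphoserine", "Ubiquitination"),
    stringsAsFactors = FALSE)
  muts <- data.frame(
    accession = c("KIN001", "KIN001", "KIN001", "SPR002"),
    position  = c(263L, 263L, 256L, 100L),
    wtResidue = c("V", "V", "R", "K"),
    mutResidue = c("A", "G", "S", "R"),
    clinicalSignificance = c("pathogenic", "unannotated", "unannotated",
                             "non-pathogenic"),
    source = "dbsnp",
    variantId = "",
    stringsAsFactors = FALSE)
  PTMProteome(proteins, seqs, mods, muts,
              goTerms = list(c("GO:0008284", "GO:0004672"), character()))
}

# Random small proteome for oracle-equivalence sweeps.
smallSim <- function(seed, nProteins = 20, rho = 1) {
  generateProteome(SyntheticProteomeConfig(
    nProteins = nProteins, lengthRange = c(60L, 150L),
    mutationRate = 0.08, basePathogenicProb = 0.3, rho = rho, seed = seed))
}

# humsavar-format text lines for parser tests.
humsavarFixtureLines <- function() {
  c("Human polymorphisms and disease mutations: index",
    "(synthetic fixture)",
    "",
    "Gene       AC         FTId       Change         Category       dbSNP  Disease",
    "_________  _________  _________  _____________  _____________  _____  _______",
    "RAF1       P04049     VAR_999999 p.Val263Ala    Disease        -      Noonan syndrome",
    "RAF1       P04049     VAR_999998 p.Arg256Ser    Polymorphism   rs123  -",
    "TP53X      Q99999     VAR_999997 p.Arg175His    Disease        -      synthetic tumour syndrome",
    "TP53X      Q99999     VAR_999996 p.Pro72Arg     Unclassified   -      -",
    "TP53X      Q99999     VAR_999995 p.Arg175del    Disease        -      not a missense",
    "TP53X      Q99999     VAR_999994 p.Xyz175His    Disease        -      unmappable code",
    "",
    "End of file.")
}

writeHumsavarFixture <- function(path = tempfile(fileext = ".txt")) {
  writeLines(humsavarFixtureLines(), path)
  path
}
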