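test_that("pathogenic protein set matches the generator's planted truth", {
  sim <- smallSim(seed = 301, nProteins = 40)
  planted <- sort(unique(sim$truth$accession[sim$truth$pathogenic]))
  expect_equal(pathogenicProteinSet(sim$proteome, "dbsnp"), planted)
  # no pathogenic mutations at all: empty set, downstream refuses explicitly
  cfg <- SyntheticProteomeConfig(nProteins = 10, basePathogenicProb = 0,
                                 seed = 302)
  nullSim <- generateProteome(cfg)
  expect_length(pathogenicProteinSet(nullSim$proteome, "dbsnp"), 0L)
  expect_error(testEnrichment(nullSim$proteome, "dbsnp"),
               class = "ptmenrich_empty_foreground")
  # the source switch only changes which category token is read
  expect_length(pathogenicProteinSet(sim$proteome, "humsavar"), 0L)
})

test_that("windowed PTM lookup is inclusive at |d|=8 and type-specific", {
  p <- kinaseFixture()
  # Phosphoserine at 259; queries around it
  expect_true(hasPtmWithin(p, "KIN001", 263L, "Phosphoserine", 8L))
  expect_true(hasPtmWithin(p, "KIN001", 259L, "Phosphoserine", 0L))
  expect_false(hasPtmWithin(p, "KIN001", 263L, "Phosphoserine", 0L))
  # SPR002: PTM at 108 vs query 100 (|d|=8 in), PTM at 109 would be |d|=9
  expect_true(hasPtmWithin(p, "SPR002", 100L, "Phosphoserine", 8L))
  expect_false(hasPtmWithin(p, "SPR002", 117L, "Phosphoserine", 8L))
  expect_true(hasPtmWithin(p, "SPR002", 116L, "Phosphoserine", 8L))
  # a PTM of a different type never satisfies the queried type
  expect_false(hasPtmWithin(p, "SPR002", 100L, "N6-acetyllysine", 8L))
  expect_true(hasPtmWithin(p, "SPR002", 100L, "Ubiquitination", 0L))
  expect_error(hasPtmWithin(p, "KIN001", 0L, "Phosphoserine", 8L),
               class = "ptmenrich_degenerate_input")
  expect_error(hasPtmWithin(p, "KIN001", 9999L, "Phosphoserine", 8L),
               class = "ptmenrich_degenerate_input")
})

test_that("residue collection OR-collapses multi-mutation residues", {
  p <- kinaseFixture()
  res <- collectMutatedResidues(p, accessions(p), "dbsnp")
  # V263A (pathogenic) + V263G (unannotated) -> one pathogenic residue
  r263 <- res[res$accession == "KIN001" & res$position == 263, ]
  expect_equal(nrow(r263), 1L)
  expect_true(r263$isPathogenic)
  # distinct positions count once each
  expect_equal(nrow(res), 3L)
  expect_error(collectMutatedResidues(p, character(0), "dbsnp"),
               class = "ptmenrich_empty_foreground")
})

test_that("residue collection and flags equal the quadratic-scan oracle", {
  for (seed in c(311, 312, 313)) {
    sim <- smallSim(seed = seed, nProteins = 30)
    subset <- pathogenicProteinSet(sim$proteome, "dbsnp")
    got <- collectMutatedResidues(sim$proteome, subset, "dbsnp",
                                  windows = c(0L, 8L))
    want <- quadraticResidueOracle(sim$proteome, subset, "dbsnp",
                                   windows = c(0L, 8L))
    attributes(got)[c("modTypes", "windows", "nPtmInSubset")] <- NULL
    expect_equal(got, want)
  }
})

test_that("contingency tables conserve residue totals across types", {
  sim <- smallSim(seed = 321, nProteins = 50)
  subset <- pathogenicProteinSet(sim$proteome, "dbsnp")
  residues <- collectMutatedResidues(sim$proteome, subset, "dbsnp", windows = 8L)
  res <- testEnrichment(sim$proteome, "dbsnp", window = 8L)
  nPath <- sum(residues$isPathogenic)
  nOther <- sum(!residues$isPathogenic)
  expect_true(all(res$a + res$b == nPath))
  expect_true(all(res$c + res$d == nOther))
  expect_true(all(res$a + res$b + res$c + res$d == nrow(residues)))
  expect_equal(S4Vectors::metadata(res)$nForegroundResidues, nPath)
  # every analyzed residue belongs to a bias-controlled protein
  expect_true(all(residues$accession %in% subset))
  # q is always >= p on testable rows
  ok <- res$testable
  expect_true(all(res$q[ok] >= res$p[ok] - 1e-12))
})

test_that("widening the window never loses feature hits", {
  sim <- smallSim(seed = 331, nProteins = 40)
  subset <- pathogenicProteinSet(sim$proteome, "dbsnp")
  residues <- collectMutatedResidues(sim$proteome, subset, "dbsnp",
                                     windows = c(0L, 3L, 8L))
  for (tp in names(modificationTypes())) {
    w0 <- residues[[sprintf("near|%s|w0", tp)]]
    w3 <- residues[[sprintf("near|%s|w3", tp)]]
    w8 <- residues[[sprintf("near|%s|w8", tp)]]
    expect_true(all(w8[w0]))   # window-0 features are a subset of window-8
    expect_true(all(w3[w0]))
    expect_true(all(w8[w3]))
  }
  r0 <- testEnrichment(sim$proteome, "dbsnp", window = 0L)
  r8 <- testEnrichment(sim$proteome, "dbsnp", window = 8L)
  for (tp in names(modificationTypes())) {
    expect_gte(r8$a[r8$modType == tp], r0$a[r0$modType == tp])
    expect_gte(r8$c[r8$modType == tp], r0$c[r0$modType == tp])
  }
})

test_that("window 0 with disjoint PTM and mutation positions gives a=0, p=1", {
  seqs <- c(T00001 = paste(rep("S", 50), collapse = ""))
  proteins <- data.frame(accession = "T00001", gene = "T", species = "syn")
  mods <- data.frame(accession = "T00001", residue = "S",
                     position = c(10L, 20L), modType = "Phosphoserine")
  muts <- data.frame(accession = "T00001", position = c(11L, 30L),
                     wtResidue = "S", mutResidue = "A",
                     clinicalSignificance = c("pathogenic", "unannotated"),
                     source = "dbsnp", variantId = "")
  p <- PTMProteome(proteins, seqs, mods, muts)
  res <- testEnrichment(p, "dbsnp", modTypes = "Phosphoserine", window = 0L)
  expect_equal(res$a, 0L)
  expect_equal(res$p, 1)
})

test_that("modification types absent from the subset are flagged untestable", {
  seqs <- c(T00002 = paste(rep("K", 40), collapse = ""))
  proteins <- data.frame(accession = "T00002", gene = "T", species = "syn")
  mods <- data.frame(accession = "T00002", residue = "K",
                     position = 5L, modType = "Ubiquitination")
  muts <- data.frame(accession = "T00002", position = c(6L, 30L),
                     wtResidue = "K", mutResidue = "R",
                     clinicalSignificance = c("pathogenic", "unannotated"),
                     source = "dbsnp", variantId = "")
  p <- PTMProteome(proteins, seqs, mods, muts)
  res <- testEnrichment(p, "dbsnp", window = 8L)
  expect_false(res$testable[res$modType == "Phosphoserine"])
  expect_true(is.na(res$p[res$modType == "Phosphoserine"]))
  expect_true(res$testable[res$modType == "Ubiquitination"])
  # untestable rows sort last
  expect_true(all(which(!res$testable) > which(res$testable)))
})

test_that("mutation ranking counts all nearby modifications and breaks ties", {
  p <- kinaseFixture()
  # KIN001 263: PTMs at 257, 259, 260 -> within 8 of 263: 257? |263-257|=6 yes,
  # 259 (4), 260 (3) -> 3 modifications of any type
  ranked <- rankMutationsByNearbyPtms(p, window = 8L)
  expect_equal(ranked$nNearbyPtms[ranked$accession == "KIN001" &
                                  ranked$position == 263], 3L)
  expect_equal(ranked, quadraticRankOracle(p, 8L))
  # residue with offsets -8, -1, 0, +8 counts 4
  seqs <- c(T00003 = paste(rep("S", 60), collapse = ""))
  proteins <- data.frame(accession = "T00003", gene = "T", species = "syn")
  mods <- data.frame(accession = "T00003", residue = "S",
                     position = c(22L, 29L, 30L, 38L), modType = "Phosphoserine")
  muts <- data.frame(accession = "T00003", position = 30L,
                     wtResidue = "S", mutResidue = "A",
                     clinicalSignificance = "unannotated",
                     source = "dbsnp", variantId = "")
  pp <- PTMProteome(proteins, seqs, mods, muts)
  expect_equal(rankMutationsByNearbyPtms(pp, 8L)$nNearbyPtms, 4L)
})

test_that("ranking equals the quadratic oracle on random small proteomes", {
  for (seed in c(341, 342)) {
    sim <- smallSim(seed = seed, nProteins = 25)
    expect_equal(rankMutationsByNearbyPtms(sim$proteome, 8L),
                 quadraticRankOracle(sim$proteome, 8L))
    expect_equal(rankMutationsByNearbyPtms(sim$proteome, 0L),
                 quadraticRankOracle(sim$proteome, 0L))
  }
})

test_that("a protein loaded with PTMs around its mutation ranks first", {
  seqs <- c(DENSE1 = paste(rep("K", 80), collapse = ""),
            SPARSE2 = paste(rep("K", 80), collapse = ""))
  proteins <- data.frame(accession = names(seqs), gene = c("D1", "S2"),
                         species = "syn")
  mods <- rbind(
    data.frame(accession = "DENSE1", residue = "K",
               position = 32:41, modType = "Ubiquitination"),
    data.frame(accession = "SPARSE2", residue = "K",
               position = 40L, modType = "Ubiquitination"))
  muts <- data.frame(accession = c("DENSE1", "SPARSE2"), position = 40L,
                     wtResidue = "K", mutResidue = "R",
                     clinicalSignificance = "unannotated",
                     source = "dbsnp", variantId = "")
  p <- PTMProteome(proteins, seqs, mods, muts)
  ranked <- rankMutationsByNearbyPtms(p, 8L)
  expect_equal(ranked$accession, c("DENSE1", "SPARSE2"))
  expect_equal(ranked$nNearbyPtms, c(10L, 1L))
})
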