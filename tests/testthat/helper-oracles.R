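# Independent oracles. These deliberately take different routes from the
# package implementation: the Fisher oracle enumerates the hypergeometric
# support with stats::dhyper, and the proximity oracle is a quadratic scan
# over all (mutation, PTM) pairs.

# Right-tail p by exhaustive enumeration of all feasible tables with the
# margins fixed, summing hypergeometric masses for k >= a.
fisherEnumOracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  kmax <- min(r1, c1)
  if (a > kmax) return(0)
  sum(stats::dhyper(a:kmax, m = c1, n = N - c1, k = r1))
}

# Hand step-up BH: q_(i) = min_{j>=i}(p_(j) m / j), returned in input order.
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- pmin(1, p[ord] * m / seq_len(m))
  q <- rev(cummin(rev(q)))
  q[order(ord)]
}

# Quadratic-scan recount of mutated residues and their nearby-PTM flags.
# Loops over every mutation and every PTM; no shared code with the package's
# sorted-coordinate implementation.
quadraticResidueOracle <- function(proteome, proteinSubset, source,
                                   modTypes = names(modificationTypes()),
                                   windows = c(0L, 8L)) {
  token <- if (source == "dbsnp") "pathogenic" else "Disease"
  mt <- as.data.frame(mutations(proteome))
  mt <- mt[mt$source == source & mt$accession %in% proteinSubset, , drop = FALSE]
  md <- as.data.frame(modifications(proteome))
  md <- md[md$accession %in% proteinSubset, , drop = FALSE]
  keys <- unique(mt[c("accession", "position")])
  keys <- keys[order(keys$accession, keys$position), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    acc <- keys$accession[i]; pos <- keys$position[i]
    hits <- mt[mt$accession == acc & mt$position == pos, , drop = FALSE]
    out <- data.frame(accession = acc, position = pos,
                      wtResidue = hits$wtResidue[1],
                      isPathogenic = any(hits$clinicalSignificance == token),
                      stringsAsFactors = FALSE)
    for (tp in modTypes) for (w in windows) {
      ptms <- md[md$accession == acc & md$modType == tp, , drop = FALSE]
      near <- FALSE
      for (pp in ptms$position) if (abs(pp - pos) <= w) near <- TRUE
      out[[sprintf("near|%s|w%d", tp, w)]] <- near
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# Quadratic recount of nearby modifications of any type, for the ranking.
quadraticRankOracle <- function(proteome, window) {
  mt <- as.data.frame(mutations(proteome))
  md <- as.data.frame(modifications(proteome))
  keys <- unique(mt[c("accession", "position")])
  n <- integer(nrow(keys))
  path <- logical(nrow(keys))
  wt <- character(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    acc <- keys$accession[i]; pos <- keys$position[i]
    ptms <- md[md$accession == acc, , drop = FALSE]
    n[i] <- sum(abs(ptms$position - pos) <= window)
    hits <- mt[mt$accession == acc & mt$position == pos, , drop = FALSE]
    path[i] <- any(hits$clinicalSignificance %in% c("pathogenic", "Disease"))
    wt[i] <- hits$wtResidue[1]
  }
  out <- data.frame(accession = keys$accession, position = keys$position,
                    wtResidue = wt, isPathogenic = path, nNearbyPtms = n,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$nNearbyPtms, out$accession, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
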