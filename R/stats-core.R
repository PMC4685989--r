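# Exact and resampling statistics shared by every analysis stage.

#' One-sided Fisher's exact test (enrichment tail)
#'
#' Exact right-tail hypergeometric p-value for a 2x2 contingency table
#' \preformatted{          feature  no feature
#'   foreground   a         b
#'   background   c         d}
#' i.e. `p = Pr[X >= a]` with all margins fixed, the probability that the
#' foreground captures at least `a` feature-positive units by chance.
#' The tail is accumulated in log-space via `lchoose()` (log-gamma), so tables
#' with totals up to 1e6 are numerically stable and p-values far below the
#' double-precision underflow of naive factorial ratios are returned exactly.
#'
#' `p` is exactly 1 when `a` sits at its minimum feasible value given the
#' margins (in particular when `a = 0`), because the right tail then covers
#' the whole support.
#'
#' @param a,b,c,d Non-negative integer cell counts (see layout above). `a` may
#'   also be a length-4 vector/matrix giving the whole table.
#' @return A list with elements `p` (in (0, 1]), `oddsRatio` (the sample odds
#'   ratio `ad/bc`; `Inf` when `bc = 0` and `ad > 0`, `NaN` when both products
#'   are 0) and `table` (the four counts).
#' @export
#' @examples
#' fisherOneSided(3, 1, 1, 3)$p  # 17/70
fisherOneSided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.null(b)) { x <- as.vector(a); a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4] }
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells)))
    .stopDegenerate("contingency cells must be non-negative integers")
  if (sum(cells) == 0)
    .stopDegenerate("all-zero contingency table")
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  kmin <- max(0, r1 + c1 - N)
  kmax <- min(r1, c1)
  if (a <= kmin) {
    p <- 1
  } else {
    k <- a:kmax
    logp <- lchoose(r1, k) + lchoose(N - r1, c1 - k) - lchoose(N, c1)
    m <- max(logp)
    p <- min(1, exp(m + log(sum(exp(logp - m)))))
    # tails smaller than the representable range are reported at the floor,
    # keeping the contract p in (0, 1]
    p <- max(p, .Machine$double.xmin)
  }
  orNum <- a * d; orDen <- b * c
  oddsRatio <- if (orDen > 0) orNum / orDen else if (orNum > 0) Inf else NaN
  list(p = p, oddsRatio = oddsRatio, table = c(a = a, b = b, c = c, d = d))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment
#' `q_(i) = min_(j >= i) ( p_(j) * m / j )`, capped at 1 and returned in the
#' input order. Delegates to `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bhFdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    .stopDegenerate("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-protein annotation counts
#'
#' Summarizes a proteome into one row per protein: the number of GO terms,
#' mutations and PTMs, the sequence length, and whether the protein carries at
#' least one pathogenic (or Disease) mutation of the given source. This is the
#' input of the study-bias diagnostics.
#'
#' @param proteome A [PTMProteome-class].
#' @param source `"dbsnp"` or `"humsavar"`: which clinical-significance
#'   vocabulary marks a mutation as pathogenic.
#' @return `data.frame` with columns `accession`, `nGo`, `nMutations`,
#'   `nPtms`, `length`, `hasPathogenic`.
#' @export
annotationCounts <- function(proteome, source = c("dbsnp", "humsavar")) {
  source <- match.arg(source)
  token <- .pathogenicToken(source)
  acc <- accessions(proteome)
  mt <- mutations(proteome)
  md <- modifications(proteome)
  nMut <- table(factor(mt$accession, levels = acc))
  nPtm <- table(factor(md$accession, levels = acc))
  path <- mt$accession[mt$clinicalSignificance == token]
  data.frame(
    accession = acc,
    nGo = as.integer(lengths(goTerms(proteome))),
    nMutations = as.integer(nMut),
    nPtms = as.integer(nPtm),
    length = as.integer(proteins(proteome)$length),
    hasPathogenic = acc %in% path,
    stringsAsFactors = FALSE
  )
}

#' Pairwise correlations between annotation burdens
#'
#' Correlates the per-protein counts of GO terms, mutations and PTMs and the
#' protein length against each other, over all proteins and again over the
#' subset carrying a pathogenic mutation — the classic well-studied-protein
#' (study bias) diagnostic.
#'
#' @param counts A data.frame from [annotationCounts()] (>= 3 rows).
#' @param method `"pearson"` (default; annotation burdens scale roughly
#'   linearly with length) or `"spearman"`.
#' @return List with elements `all` and `pathogenic`, each a list of matrices
#'   `r` (coefficients; unit diagonal) and `p` (correlation-test p-values)
#'   over `nGo`, `nMutations`, `nPtms`, `length`. Pairs involving a
#'   zero-variance column are `NA`. `pathogenic` is `NULL` when fewer than 3
#'   proteins carry a pathogenic mutation.
#' @export
annotationCorrelations <- function(counts, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(counts) < 3L) .stopDegenerate("need at least 3 proteins")
  vars <- c("nGo", "nMutations", "nPtms", "length")
  corSet <- function(df) {
    r <- diag(1, length(vars)); dimnames(r) <- list(vars, vars)
    p <- r * NA_real_; diag(p) <- 0
    for (i in seq_along(vars)) for (j in seq_along(vars)) {
      if (j <= i) next
      x <- df[[vars[i]]]; y <- df[[vars[j]]]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        r[i, j] <- r[j, i] <- NA_real_
        next
      }
      ct <- suppressWarnings(stats::cor.test(x, y, method = method))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
    list(r = r, p = p)
  }
  sub <- counts[counts$hasPathogenic, , drop = FALSE]
  list(all = corSet(counts),
       pathogenic = if (nrow(sub) >= 3L) corSet(sub) else NULL)
}

#' Study-bias enrichment test
#'
#' Tests whether proteins carrying a pathogenic mutation are enriched for
#' being heavily annotated: a one-sided Fisher's exact test on the 2x2 table
#' `[has pathogenic mutation x (annotation count >= threshold)]` over the full
#' proteome. A small p indicates study bias — well-studied proteins accumulate
#' annotations of every kind — and motivates restricting enrichment analyses
#' to the pathogenic-protein set.
#'
#' @param counts A data.frame from [annotationCounts()] over the full
#'   proteome.
#' @param annotation Which burden to threshold: `"go"` or `"ptm"`.
#' @param threshold Count cut-off defining "heavily annotated" (default 10).
#' @return The [fisherOneSided()] result list.
#' @export
studyBiasTest <- function(counts, annotation = c("go", "ptm"), threshold = 10L) {
  annotation <- match.arg(annotation)
  n <- counts[[if (annotation == "go") "nGo" else "nPtms"]]
  heavy <- n >= threshold
  fg <- counts$hasPathogenic
  fisherOneSided(sum(fg & heavy), sum(fg & !heavy),
                 sum(!fg & heavy), sum(!fg & !heavy))
}

#' Amino-acid composition bias between residue sets
#'
#' For each of the 20 amino acids, tests whether the foreground residue set is
#' enriched for that residue relative to the background (one-sided Fisher's
#' exact test on `[set membership x is-this-residue]`), with
#' Benjamini-Hochberg correction across the 20 tests. Used to quantify, e.g.,
#' the arginine skew of pathogenic mutated residues.
#'
#' @param foreground,background Character vectors of one-letter residue codes
#'   (multisets; both non-empty).
#' @return `data.frame` with one row per amino acid: `aa`, cell counts
#'   `a, b, c, d`, `oddsRatio`, `p`, `q`; rows ordered by increasing `q`, ties
#'   by `p` then residue.
#' @export
aaBiasTest <- function(foreground, background) {
  if (length(foreground) == 0L || length(background) == 0L)
    .stopDegenerate("foreground and background must be non-empty")
  aa <- aminoAcids()
  fg <- table(factor(foreground, levels = aa))
  bg <- table(factor(background, levels = aa))
  nf <- sum(fg); nb <- sum(bg)
  res <- lapply(aa, function(r) {
    f <- fisherOneSided(fg[[r]], nf - fg[[r]], bg[[r]], nb - bg[[r]])
    data.frame(aa = r, a = fg[[r]], b = nf - fg[[r]], c = bg[[r]],
               d = nb - bg[[r]], oddsRatio = f$oddsRatio, p = f$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- bhFdr(res$p)
  res[order(res$q, res$p, res$aa), , drop = FALSE]
}
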