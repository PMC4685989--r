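# ptmenrich

Are disease-causing missense mutations unusually close to sites of
post-translational modification (PTM)? Because the enzymes and binding
domains that read a PTM recognize the linear sequence around it, a mutation
landing within that recognition window can disrupt regulation without
touching the modified residue itself. `ptmenrich` is an R package for
proteome-wide versions of that question: it parses protein-annotation flat
files (ProteomeScout-like dialect) and UniProt humsavar-style variant
indexes, and tests whether pathogenic mutations are enriched within a
window of PTM sites, per modification type, while controlling for the two
confounders that dominate this kind of analysis — annotation study bias and
amino-acid composition.

It is aimed at computational biologists working with PTM compendia and
clinical variant annotations who want the statistics to be exact,
reproducible, and validated against planted ground truth.

## The statistic

The counting unit is the **mutated residue**: a unique (protein, position)
pair, assigned the pathogenic phenotype if *any* mutation recorded on it is
pathogenic ("OR-collapse"). Within the study-bias-controlled protein set
(proteins with ≥ 1 pathogenic mutation), each modification type *t* and
window *w* defines a 2×2 table over mutated residues

|                | PTM of *t* within *w* | none |
|----------------|-----------------------|------|
| pathogenic     | a                     | b    |
| non-pathogenic | c                     | d    |

where "within *w*" means |PTM position − mutation position| ≤ *w*
(inclusive; *w* = 0 is a PTM on the mutated residue). The one-sided
(enrichment-tail) Fisher's exact p-value

&nbsp;&nbsp;&nbsp;&nbsp;p = Σ<sub>k ≥ a</sub> C(a+b, k) · C(c+d, a+c−k) / C(N, a+c)

is computed in log-space via log-gamma (stable to N ≈ 10⁶ and p-values far
below 1e-300), with Benjamini–Hochberg q-values across the tested types.
A composition-matched resampling control re-runs the test on random
foregrounds with exactly the real foreground's size and wild-type
amino-acid composition, which separates positional signal from the arginine
skew of pathogenic mutation spectra. A synthetic-proteome generator with a
tunable PTM–pathogenicity co-localization effect (relative risk `rho` near
PTMs of chosen types) provides ground truth for calibration and power
checks.

## Worked example

```r
library(ptmenrich)

sim <- generateProteome(SyntheticProteomeConfig(
  nProteins = 2000, basePathogenicProb = 0.01,
  rho = 8, rhoModTypes = "Ubiquitination", seed = 42))
sim$proteome
#> PTMProteome with 2000 protein(s)
#>   modifications: 5314  (types: N-Glycosylation, N6-acetyllysine, Phosphoserine, ...)
#>   mutations: 30444  (dbsnp: 30444, humsavar: 0)
#>   GO terms: 10003

testEnrichment(sim$proteome, source = "dbsnp", window = 8)
#> DataFrame with 6 rows and 11 columns
#>            modType    window         a         b         c         d oddsRatio
#> 1   Ubiquitination         8       100       275       242      4880  7.332832
#> 2  N-Glycosylation         8        10       365        74      5048  1.868937
#> 3  N6-acetyllysine         8        12       363       119      5003  1.389819
#> ...
#>             p  testable           q nForegroundProteins
#> 1 2.13555e-40      TRUE 1.28133e-39                 336
#> 2 5.83343e-02      TRUE 1.75003e-01                 336
#> ...
```

The generator planted an 8-fold pathogenic-labelling boost near
ubiquitination sites only; the test recovers exactly that type (a = 100 of
375 pathogenic residues near a ubiquitination site, odds ratio 7.3,
q ≈ 1e-39) and leaves the other five types non-significant. The
composition-matched control confirms the signal is positional, not
compositional:

```r
resamplingControl(sim$proteome, "dbsnp", window = 8, nTrials = 10, seed = 43)
#> Composition-matched resampling control (10 trial(s), alpha = 0.05, seed = 43)
#>   foreground size 375; composition: A:18 C:25 D:10 ... R:50 S:25 ...
#>   Phosphoserine      real p = 0.638; significant random trials: 0 / 10
#>   Phosphothreonine   real p = 0.883; significant random trials: 0 / 10
#>   Phosphotyrosine    real p = 0.984; significant random trials: 2 / 10
#>   Ubiquitination     real p = 2.14e-40; significant random trials: 0 / 10
#>   N6-acetyllysine    real p = 0.181; significant random trials: 1 / 10
#>   N-Glycosylation    real p = 0.0583; significant random trials: 1 / 10
```

Other entry points: `readProteomeFlatfile()` / `getMutations()` /
`getPTMs()` / `getSequence()` / `getGoTerms()` for the flat-file API;
`readHumsavar()`, `crossrefHumsavar()`, `diseaseFraction()` for variant
indexes; `annotationCorrelations()`, `studyBiasTest()`, `aaBiasTest()` for
the bias diagnostics; `rankMutationsByNearbyPtms()` for prioritizing
mutations by nearby-PTM burden; and a command-line interface
(`inst/scripts/ptmenrich`, or `cliMain()` in R) wiring
`simulate / enrich / study-bias / resample / rank / crossref` with
manifest-headed, byte-reproducible TSV outputs. The methods vignette
(`vignettes/ptm-mutation-proximity.Rmd`) documents the model, the
generator, and every numerical choice.

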