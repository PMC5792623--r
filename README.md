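# epiline

Natural epialleles — heritable allelic states defined by DNA methylation
rather than sequence — are hard to study because every line of evidence
needs a different computational tool-chain. The motivating case is a LINE1
retrotransposon in *Arabidopsis thaliana* whose genomic position (4.45 Mb
vs 16.75 Mb on chromosome 5) and methylation state vary among accessions,
silencing the neighbouring *PPH* (pheophytin pheophorbide hydrolase) gene
and delaying leaf senescence when methylated, with methylation status
tracking the local climate of the accession's origin.

`epiline` packages that whole chain as tested, reusable R functions, plus a
synthetic-data generator with known ground truth so every stage runs end to
end without external downloads:

* **TE insertion detection** from discordant read pairs (one mate on the
  element, one uniquely on the genome), with breakpoint-interval calling
  and exact **target-site duplication (TSD)** identification at the
  junction.
* **Methylation statistics**: weighted per-context (CG/CHG/CHH) region
  levels `m = Σ mC / Σ C`, in-silico methylation-sensitive digestion PCR
  (Chop-PCR), pooled Fisher exact comparisons, and classification of
  accessions into the five epiallele categories.
* **Inheritance**: Pearson χ² segregation tests (e.g. the 3:1 dominant
  band ratio in an F2), recombinant-count linkage mapping under the
  recessive-selection design, and Welch-t co-segregation summaries.
* **Molecular dating** of the insertion with two estimators under the
  Tamura–Nei (TN93) model: the star-phylogeny estimate
  `T_star = d̄ / (2 r)` from mean pairwise distances, and the MRCA
  estimate `T_mrca = d̄_anc / r` from maximum-likelihood ancestral
  reconstruction, with the substitution rate calibrated from ortholog
  divergence as `r = d / (2 T_div)`.
* **Climate association**: Spearman scans of methylation, expression and
  senescence phenotypes against 19 bioclim variables at two epochs
  (present and last interglacial), with exact small-sample Wilcoxon and
  Spearman p-values.

## Worked example

The demo pipeline simulates a 60 kb reference, plants a 2 kb truncated,
inverted element with a 7 bp TSD at position 30,000, sequences it at 30×,
and runs every analysis stage:

```r
library(epiline)
res <- runPipeline(demoConfig(seed = 7), outDir = "demo_run")

res$detect$calls[[1]]
#> TEInsertionCall chr1:[29993,30033) inverted support 27+/32- TSD 7 bp 'CAACTGA'
```

The planted insertion is recovered: the breakpoint interval [29993, 30033)
contains the true point 30,000, the orientation is called inverted, and the
7 bp TSD is read off the junction exactly.

```r
unlist(res$segregation[c("observed", "chisq", "p")])
#> observed1 observed2     chisq         p
#> 1514.000   486.000     0.523     0.470
```

A 2,000-plant synthetic F2 from a methylated × unmethylated cross shows
1514 : 486 methylated-band : bandless plants — consistent with the 3:1
Mendelian ratio of a single dominant-band epiallele locus (χ² = 0.52,
p = 0.47).

```r
res$dating
#> DatingResult (20 sequences)
#>   rate r        : 5.88e-09 subst/site/year (T_div 4.65e+06 y)
#>   mean pairwise : 0.005343   mean tip-ancestor: 0.002667
#>   T_star        : 4.544e+05 years
#>   T_mrca        : 4.536e+05 years
#>   reported range: [4.54e+05, 4.54e+05] years
```

Twenty element copies evolved for a true 5 × 10⁵ years are dated at
≈4.5 × 10⁵ years by both estimators, using a rate calibrated from a
simulated ortholog pair at the 4.65 MYA species-split midpoint.

```r
res$climate$scan$significantCounts
#> present     LIG
#>       2       1
```

With the planted bio9 (mean temperature of the driest quarter) effect,
bio9 is flagged in both epochs with negative rho; one additional variable
crosses p < 0.05 by chance in the present epoch, as expected at the 5%
level over 19 variables.

## Documentation

The methods vignette (`vignettes/epiline-methods.Rmd`) documents the
models, defaults and numerical choices: what the synthetic generators
emulate (and deliberately do not), the breakpoint-interval semantics
with TSD and micro-homology allowances, the weighted-methylation and
pooled-Fisher conventions, the Haldane meiosis model with irreversible
ddm1 methylation loss, the TN93 machinery behind both dating estimators,
and the association-criterion choices in the climate scan.
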