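---
title: "Models and methods behind epiline"
author: "epiline maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epiline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiline)
```

# Scope

`epiline` re-implements, as a reusable and fully testable pipeline, the
computational chain used to characterise a naturally occurring DNA
methylation epiallele created by a LINE1 retrotransposon insertion in
*Arabidopsis thaliana*: detection of a non-reference insertion from
paired-end reads with target-site-duplication (TSD) calling; per-context
methylation quantification, in-silico Chop-PCR and epiallele
classification; segregation and recombinant-count linkage mapping with
methylation as the phenotype; two-estimator molecular dating of the
insertion under the Tamura–Nei (TN93) model; and association of
methylation status with 19 bioclimatic variables at two epochs. A
synthetic-data generator with known ground truth stands in for the
study's real inputs (accession bisulfite data, C24 resequencing,
WorldClim extracts), so every stage can be exercised end to end without
downloads.

All internal coordinates are 0-based half-open; 1-based coordinates
appear only at Bioconductor (`GRanges`) and formatted-output boundaries.

# Synthetic data: what it emulates, and what it does not

`makeReference()` draws i.i.d. bases at a target GC content (default
0.36, Arabidopsis-like). `plantInsertion()` reproduces the sequence
structure of LINE1 integration: the `tsdLength` bases immediately 5' of
the insertion point are duplicated so the (optionally 5'-truncated,
optionally inverted) element is flanked by two direct target-site
copies. `simulateReadPairs()` samples fragments uniformly
(Normal(insertMean, insertSd) lengths) and emits inner-facing mates with
optional substitution errors — no quality modelling, PCR duplicates or
indel errors, which the detection method does not rely on.

`simulateBisulfiteCalls()` assigns contexts from the sequence on both
strands (CG, CHG, CHH with H ∈ {A,C,T}; cytosines within two bases of
the chromosome end are skipped — the community convention). Per-cytosine
methylation levels are beta-distributed around per-context state means
(defaults: methylated 0.85/0.65/0.10 for CG/CHG/CHH, unmethylated 0.02
everywhere; overdispersion 0.1) with Poisson depths and binomial counts.
The state means are *configurable placeholders* chosen to mimic
heterochromatic TE methylation — no published per-context levels exist
for these loci — and the overdispersion default avoids unrealistically
tight binomial counts.

`simulateCross()` models meioses independently with the Haldane
(no-interference) map function on a centimorgan map; the epiallele
methylation state travels in cis, unchanged except in a *ddm1*
background, where each transmitted methylated allele is irreversibly
lost with probability ε per meiosis (default 0.2 where used; the loss
rate is not known empirically, only its stochastic, irreversible
character). `evolveStar()` evolves tips independently from an ancestor
under TN93 scaled to a stated substitution rate; there is no coalescent
structure among accessions, a deliberate simplification with a visible
consequence for dating (below). `simulateClimateTable()` draws 19
bioclim variables at two correlated epochs, plants a monotone decreasing
methylation–bio9 relation of configurable strength (attenuated to 60% at
the last-interglacial epoch) and leaves every other variable null;
group proportions default to 21:39:77 across methylated, unmethylated
and deletion groups of 137 accessions.

Because the generators are idealised, passing tests demonstrate
correctness of the algorithms *under the stated models* — uniform
coverage, independent meioses, star genealogy, exchangeable accessions —
not robustness to alignment artefacts, population structure or spatial
autocorrelation in real data.

# TE insertion detection

Detection follows the pair-based logic used to discover the C24-specific
insertion: read pairs with exactly one mate uniquely on the element
contig and the other uniquely on the genome anchor the breakpoint.
`naiveMap()` is an exact-match placer for (near-)error-free synthetic
reads; junction-spanning reads simply fail to map, which is the property
the method relies on. Split-read refinement is deliberately out of
scope. Anchors cluster within `insertMean + 3*insertSd`; plus-strand
anchors sit left of the breakpoint, minus-strand anchors right of it,
and the element-side strand pattern votes the orientation.

The breakpoint interval runs from the rightmost left-anchor end to the
leftmost right-anchor start **plus `maxTsd`**: integration duplicates
the target site, so right-flank reads carry the duplicated copy and map
up to one TSD length *left* of the true point; without this allowance a
deeply covered junction with a long TSD would exclude the true point.
Both bounds are further relaxed by a small `junctionSlack` (8 bp):
junctional micro-homology lets reads cross the junction by a few
matching bases while still anchoring exactly, and within such homology
the breakpoint is intrinsically ambiguous. Should anchors still overlap,
the interval collapses deterministically to the 1-base midpoint. A call
requires `minSupport` (default 3) pairs on each side — the original
study reports no threshold, so the default is ours — and one-sided
clusters are reported as candidates with a reason rather than calls.

`detectTSD()` returns the longest s (≤ `maxTsd`, default 30) that
immediately precedes and follows the element in the insertion allele
such that collapsing the element and one copy of s reconstructs the
reference junction; adjacency makes equal-length candidates unambiguous
by construction. The two real loci in the study carry 15 bp and 7 bp
TSDs; the synthetic tests plant and recover 0–30 bp exactly.

# Methylation statistics

`weightedLevel()` uses the weighted (count-summed) methylation level —
total methylated reads over total reads across a region's covered
cytosines — rather than a mean of per-cytosine levels; it is the field's
standard and robust to uneven depth. A region with no covered cytosine
is *undefined*, never 0. `fisherRegionCompare()` pools reads across the
region's cytosines into one 2×2 table before the exact test; a
per-cytosine alternative would be defensible (the original analysis does
not say which it used) but pooling is the simplest faithful reading and
is what the exhaustive-enumeration oracle verifies.

Chop-PCR is modelled at the molecule level: a template survives
methylation-sensitive digestion with probability equal to the product of
the methylation levels at each recognition site's diagnostic cytosine,
alleles contribute at equal dosage, and a band is visible when the uncut
fraction reaches a threshold (default 0.1). A heterozygote with one
fully methylated and one unmethylated allele shows the half-intensity
band seen in F1 hybrids. Enzyme definitions (recognition sequence and
diagnostic-cytosine offset; HhaI and MspI built in) are configurable
because enzyme-specific sensitivity nuances differ.

`classifyAccession()` maps presence/absence of the element at the two
chromosome-5 positions and their levels to the five observed categories
(NMR19-16u, NMR19-4m, NMR19-4m/16m, NMR19-4u, deletion), scoring an
element methylated at CG level ≥ 0.2 — a numeric stand-in for the
study's gel-based binary call, which had no threshold to inherit. The
function is total: the (never observed) methylated-16-only combination
is labelled NMR19-16m rather than forced into a wrong category.

# Inheritance and mapping

`segregationTest()` is the Pearson goodness-of-fit chi-square without
continuity correction — the targeted populations are large (the study
selected 1,223 unmethylated F2 plants); a Yates flag exists.
`countRecombinants()` implements the recessive-selection design
directly: among plants selected for the recessive (unmethylated)
phenotype, every marker allele inherited from the methylated parent is
one recombinant chromosome out of 2n. `mapLocus()` takes the marker
with the minimum count as the point estimate and the nearest flanking
markers with strictly more recombinants as the interval; ties widen the
interval and monotone runs to an end leave it unbounded and flagged.
`cosegregationSummary()` groups same-plant measurements by Chop-PCR
genotype and uses the Welch (unequal-variance) two-tailed t-test between
homozygous classes — the original reports only "two-tailed t-test", and
Welch is the safer default.

# Molecular dating

`tn93Distance()` is the closed-form TN93 distance from the proportions
of purine transitions, pyrimidine transitions and transversions, with
base frequencies estimated empirically from each pair over their shared
(pairwise-deleted) sites; saturated pairs return `NA` and are excluded
with a message. `njTree()` wraps Saitou–Nei neighbor joining and clamps
negative branch lengths to zero, transferring the deficit to a sibling
branch. Rate calibration is r = d/(2T) from an ortholog pair; the
divergence is TN93-corrected by default (raw optional), and T defaults
to the midpoint, 4.65 MYA, of the ~3.5–5.8 MYA species-split range —
which value produced the study's 6.8 × 10⁻⁹ per site per year is not
recorded, so both endpoints are natural sensitivity settings.

The star estimator is T_star = d̄/(2r) with d̄ the mean pairwise TN93
distance. The MRCA estimator reconstructs the root sequence by marginal
maximum likelihood (pruning algorithm) under TN93 on the NJ tree of the
copies (reconstruction on the tree, rather than a star, is our reading
of the original MEGA-based procedure; at the divergences involved the
two differ negligibly and both agree with the majority consensus), then
takes T_mrca = d̄_anc/r with d̄_anc the mean *raw* tip-to-ancestor
mismatch proportion — "counted substitutions", uncorrected, with a
corrected mode available. Per-site reconstruction ties break to the
higher stationary frequency, then alphabetically, and are counted in a
message; all-gap sites emit gaps. Alignment construction is out of
scope: inputs must be pre-aligned (`stripAllGapColumns()` is provided).

One property of the synthetic study design deserves emphasis. On data
simulated under a *true* star phylogeny, T_star and T_mrca estimate the
same quantity from the same substitution events: both are unbiased and
tightly correlated, so the interval [T_star, T_mrca] is only about 1%
wide while each estimate carries a few percent of Monte-Carlo noise. The
interval therefore almost never contains the true age even though both
point estimates recover it well within 15%. The lower/upper-bound
reading of [T_star, T_mrca] is meaningful for *real* data, where
shared internal branches depress pairwise distances (star estimate
biased down) and the MRCA predates the sampled radiation (MRCA estimate
biased up); our generator deliberately lacks that genealogical
structure.

# Climate association

`assignGroups()` collapses classification to the three analysis groups
(methylated / unmethylated / deletion), with methylation set to 0
whenever the element is absent — the convention the study states.
`spearmanAssoc()` computes rho on tie-averaged ranks with the exact
permutation null for n ≤ 10 (untied) and the t approximation otherwise;
`wilcoxonGroups()` uses the exact rank-sum/signed-rank null for combined
n ≤ 20 without ties and the tie-corrected normal approximation
otherwise, with present-vs-LIG comparisons within a group treated as
paired (same accessions, two epochs). `climateScan()` tests each
phenotype against each of the 19 variables per epoch and counts a
variable as associated when the total-methylation correlation has raw
p < 0.05 — no multiple-testing correction, mirroring how such scans are
reported; a Benjamini–Hochberg mode exists but is off by default, and
the choice of criterion (total methylation, rather than any context) is
flagged in the output structure rather than hidden.

# Numerical and design choices

* Stage seeds derive deterministically from one global seed plus the
  stage name, so `runPipeline()` is byte-reproducible per config.
* TN93 matrix exponentials use the symmetrized eigendecomposition of
  the reversible rate matrix; probabilities are clipped to [0,1] and
  renormalised against rounding.
* Pruning likelihoods are rescaled per node to guard against underflow
  on large trees.
* `chopPCR` treats per-allele site levels ≥ 0.5 as protective only
  through the survival product — no hidden binarisation; binary allele
  scoring in the cross simulator is the dominant-band rule (any
  methylated copy yields a band).
* Degenerate inputs are first-class: empty regions are undefined (not
  zero), empty Fisher margins and constant correlation inputs are
  flagged, all-zero paired differences give p = 1 with a degenerate
  flag, all-equal recombinant counts flag the whole span.

# Problem sizes used in the shipped checks

The packaged tests run the study-scale analyses at sizes a laptop
handles comfortably: 10,000-plant F2 populations for segregation; 200
mapping replicates of 4,000 plants (≈1,000 selected) with 17 markers at
2 cM; 50 detection replicates on 60 kb genomes with a 2.5 kb truncated
element at 20–40× coverage and TSDs of 0–15 bp; 20 dating replicates of
50 copies × 3 kb at r = 6.8 × 10⁻⁹ and T = 5 × 10⁵ years; and 500 null
climate tables of 137 accessions. These sizes were chosen so sampling
error is small relative to the tested tolerances.

# Known limitations

* The exact-match placer is for synthetic reads; real libraries need a
  production aligner upstream (the module boundary accepts a minimal
  SAM subset for exactly that reason).
* No split-read breakpoint refinement; resolution is pair-level.
* The accession generator has no relatedness structure, so dating and
  association power estimates do not transfer quantitatively to real
  panels.
* Insertion-allele frequency genotyping across populations and
  genome-wide DMR discovery are out of scope.

# A worked end-to-end run

```{r, eval = FALSE}
res <- runPipeline(demoConfig(seed = 7), outDir = "demo_run")
res$detect$calls[[1]]      # the recovered planted insertion, with TSD
res$segregation            # 3:1 band segregation in the synthetic F2
res$dating                 # star and MRCA ages at the calibrated rate
res$climate$scan$significantCounts
```
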