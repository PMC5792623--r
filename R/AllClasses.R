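#' @import methods
#' @importFrom Biostrings DNAStringSet reverseComplement DNAString
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

#' GenomeModel: a small reference genome with annotations
#'
#' Holds one or more chromosome sequences plus interval annotations
#' (TE copies, planted insertions, regions of interest). All coordinates
#' are 0-based half-open internally; \code{GRanges} annotations are stored
#' 1-based as usual for Bioconductor and converted at the boundary.
#'
#' @slot seqs a \code{DNAStringSet}, one element per chromosome.
#' @slot annotations a \code{GRanges} with an \code{mcols()} column
#'   \code{name}; intervals must lie within chromosome bounds.
#' @export
setClass("GenomeModel",
    representation(seqs = "DNAStringSet", annotations = "GRanges"))

setValidity("GenomeModel", function(object) {
    msg <- character()
    if (length(object@seqs) == 0L || any(Biostrings::width(object@seqs) == 0L))
        msg <- c(msg, "all chromosome sequences must be non-empty")
    if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
        msg <- c(msg, "chromosomes must have unique names")
    if (length(object@annotations)) {
        chr <- as.character(GenomicRanges::seqnames(object@annotations))
        if (!all(chr %in% names(object@seqs))) {
            msg <- c(msg, "annotation chromosome not present in genome")
        } else {
            len <- Biostrings::width(object@seqs)[match(chr, names(object@seqs))]
            if (any(GenomicRanges::start(object@annotations) < 1L) ||
                any(GenomicRanges::end(object@annotations) > len))
                msg <- c(msg, "annotation interval outside chromosome bounds")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GenomeModel
#'
#' @param seqs named \code{DNAStringSet} (or named character vector) of
#'   chromosome sequences.
#' @param annotations optional \code{GRanges} of features; default empty.
#' @return a \code{GenomeModel}.
#' @export
GenomeModel <- function(seqs, annotations = GenomicRanges::GRanges()) {
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    new("GenomeModel", seqs = seqs, annotations = annotations)
}

#' @describeIn GenomeModel chromosome sequences as a \code{DNAStringSet}.
#' @param x a \code{GenomeModel}.
#' @export
genomeSeqs <- function(x) x@seqs

#' @describeIn GenomeModel feature annotations as a \code{GRanges}.
#' @export
genomeAnnotations <- function(x) x@annotations

setMethod("show", "GenomeModel", function(object) {
    cat("GenomeModel with", length(object@seqs), "chromosome(s):\n")
    for (i in seq_along(object@seqs))
        cat("  ", names(object@seqs)[i], ": ",
            Biostrings::width(object@seqs)[i], " bp\n", sep = "")
    cat("  annotations:", length(object@annotations), "\n")
})

#' PlantedInsertion: specification of a TE insertion to plant in a genome
#'
#' @slot chrom chromosome name.
#' @slot point 0-based between-base insertion point.
#' @slot teSeq the element sequence (\code{DNAString}).
#' @slot inverted logical; insert the reverse complement.
#' @slot truncation bases removed from the element 5' end before insertion.
#' @slot tsdLength length of the target-site duplication created at
#'   integration (bases immediately 5' of the point are duplicated).
#' @export
setClass("PlantedInsertion",
    representation(chrom = "character", point = "integer",
        teSeq = "DNAString", inverted = "logical",
        truncation = "integer", tsdLength = "integer"))

setValidity("PlantedInsertion", function(object) {
    msg <- character()
    if (object@tsdLength < 0L) msg <- c(msg, "tsdLength must be >= 0")
    if (object@truncation < 0L || object@truncation >= length(object@teSeq))
        msg <- c(msg, "truncation must be in [0, element length)")
    if (object@point < 0L) msg <- c(msg, "insertion point must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @rdname PlantedInsertion-class
#' @param chrom,point,teSeq,inverted,truncation,tsdLength see slots.
#' @return a \code{PlantedInsertion}.
#' @export
PlantedInsertion <- function(chrom, point, teSeq, inverted = FALSE,
                             truncation = 0L, tsdLength = 0L) {
    if (is.character(teSeq)) teSeq <- Biostrings::DNAString(teSeq)
    new("PlantedInsertion", chrom = chrom, point = as.integer(point),
        teSeq = teSeq, inverted = inverted,
        truncation = as.integer(truncation), tsdLength = as.integer(tsdLength))
}

#' TEInsertionCall: a called non-reference TE insertion
#'
#' @slot chrom chromosome.
#' @slot lo,hi 0-based half-open breakpoint interval.
#' @slot orientation "same" or "inverted" relative to the TE contig.
#' @slot supportLeft,supportRight discordant-pair support per side.
#' @slot tsdLength,tsdSeq target-site duplication, if determined
#'   (\code{NA}/"" until \code{detectTSD} has been run).
#' @export
setClass("TEInsertionCall",
    representation(chrom = "character", lo = "integer", hi = "integer",
        orientation = "character", supportLeft = "integer",
        supportRight = "integer", tsdLength = "integer", tsdSeq = "character"))

setValidity("TEInsertionCall", function(object) {
    msg <- character()
    if (object@lo >= object@hi) msg <- c(msg, "require lo < hi")
    if (!object@orientation %in% c("same", "inverted"))
        msg <- c(msg, "orientation must be 'same' or 'inverted'")
    if (!is.na(object@tsdLength) && object@tsdLength != nchar(object@tsdSeq))
        msg <- c(msg, "tsdLength must equal nchar(tsdSeq)")
    if (length(msg)) msg else TRUE
})

setMethod("show", "TEInsertionCall", function(object) {
    cat(sprintf("TEInsertionCall %s:[%d,%d) %s support %d+/%d- TSD %s\n",
        object@chrom, object@lo, object@hi, object@orientation,
        object@supportLeft, object@supportRight,
        if (is.na(object@tsdLength)) "?" else
            sprintf("%d bp '%s'", object@tsdLength, object@tsdSeq)))
})

#' @describeIn TEInsertionCall breakpoint interval as c(lo, hi), 0-based half-open.
#' @param x a \code{TEInsertionCall}.
#' @export
breakpointInterval <- function(x) c(lo = x@lo, hi = x@hi)

#' CrossConfig: parameters of a two-parent cross at an epiallele locus
#'
#' Markers live on a genetic map (centimorgan); the epiallele locus sits at
#' \code{locusPos} cM and its methylation state travels in cis with the
#' haplotype. \code{epsilon} is the per-meiosis probability that a
#' transmitted methylated allele is irreversibly lost (switched to
#' unmethylated) when the plant is homozygous for a ddm1 loss-of-function
#' allele.
#'
#' @slot markers data.frame with columns \code{name}, \code{pos} (cM,
#'   non-decreasing).
#' @slot locusPos epiallele position (cM).
#' @slot parentalStates character(2), methylation state of the epiallele
#'   haplotype carried by parent 1 and parent 2 ("m" or "u"); parents are
#'   homozygous.
#' @slot epsilon ddm1 stochastic loss probability per transmitted methylated
#'   allele per meiosis, in [0,1].
#' @export
setClass("CrossConfig",
    representation(markers = "data.frame", locusPos = "numeric",
        parentalStates = "character", epsilon = "numeric"))

setValidity("CrossConfig", function(object) {
    msg <- character()
    if (!all(c("name", "pos") %in% names(object@markers)))
        msg <- c(msg, "markers needs columns name, pos")
    else if (is.unsorted(object@markers$pos))
        msg <- c(msg, "marker map positions must be non-decreasing")
    if (object@epsilon < 0 || object@epsilon > 1)
        msg <- c(msg, "epsilon must be in [0,1]")
    if (length(object@parentalStates) != 2L ||
        !all(object@parentalStates %in% c("m", "u")))
        msg <- c(msg, "parentalStates must be two of 'm'/'u'")
    if (length(msg)) msg else TRUE
})

#' @rdname CrossConfig-class
#' @param markers,locusPos,parentalStates,epsilon see slots.
#' @return a \code{CrossConfig}.
#' @export
CrossConfig <- function(markers, locusPos,
                        parentalStates = c("m", "u"), epsilon = 0) {
    new("CrossConfig", markers = as.data.frame(markers),
        locusPos = as.numeric(locusPos),
        parentalStates = parentalStates, epsilon = as.numeric(epsilon))
}

#' CrossPopulation: simulated individuals from a cross
#'
#' @slot individuals data.frame, one row per plant: two allele columns per
#'   marker (\code{<name>.a}, \code{<name>.b}; values 1/2 = parental origin),
#'   \code{locus.a}/\code{locus.b} epiallele states ("m"/"u") and
#'   \code{band} (logical, dominant Chop-PCR methylated-band phenotype).
#' @slot generation "F1", "F2" or "F3".
#' @slot config the \code{CrossConfig} used.
#' @export
setClass("CrossPopulation",
    representation(individuals = "data.frame", generation = "character",
        config = "CrossConfig"))

setMethod("show", "CrossPopulation", function(object) {
    cat(sprintf("CrossPopulation: %d %s individuals, %d markers\n",
        nrow(object@individuals), object@generation,
        nrow(object@config@markers)))
})

#' @describeIn CrossPopulation the per-plant data.frame.
#' @param x a \code{CrossPopulation}.
#' @export
individuals <- function(x) x@individuals

#' @describeIn CrossPopulation the marker map of the underlying config.
#' @export
markerMap <- function(x) x@config@markers

#' TN93Params: Tamura-Nei substitution model parameters
#'
#' @slot freqs stationary base frequencies (A,C,G,T), positive, summing to 1.
#' @slot alpha1 purine (A<->G) transition rate factor.
#' @slot alpha2 pyrimidine (C<->T) transition rate factor.
#' @slot beta transversion rate factor.
#' @export
setClass("TN93Params",
    representation(freqs = "numeric", alpha1 = "numeric",
        alpha2 = "numeric", beta = "numeric"))

setValidity("TN93Params", function(object) {
    msg <- character()
    if (length(object@freqs) != 4L || any(object@freqs <= 0) ||
        abs(sum(object@freqs) - 1) > 1e-8)
        msg <- c(msg, "freqs must be 4 positive values summing to 1")
    if (any(c(object@alpha1, object@alpha2, object@beta) < 0))
        msg <- c(msg, "rates must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @rdname TN93Params-class
#' @param freqs,alpha1,alpha2,beta see slots.
#' @return a \code{TN93Params}.
#' @export
TN93Params <- function(freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       alpha1 = 2, alpha2 = 2, beta = 1) {
    f <- as.numeric(freqs)
    names(f) <- c("A", "C", "G", "T")
    new("TN93Params", freqs = f, alpha1 = alpha1, alpha2 = alpha2, beta = beta)
}

#' DatingResult: two-estimator insertion dating summary
#'
#' @slot rate substitution rate r (substitutions per site per year).
#' @slot meanPairwise mean pairwise TN93 distance among the copies.
#' @slot meanAncestral mean raw tip-to-ancestor divergence.
#' @slot tStar star-phylogeny age estimate (years), d-bar / (2 r).
#' @slot tMrca MRCA age estimate (years), d-bar_anc / r.
#' @slot tDivUsed ortholog divergence time used for rate calibration (years).
#' @slot nSeqs number of sequences dated.
#' @export
setClass("DatingResult",
    representation(rate = "numeric", meanPairwise = "numeric",
        meanAncestral = "numeric", tStar = "numeric", tMrca = "numeric",
        tDivUsed = "numeric", nSeqs = "integer"))

setMethod("show", "DatingResult", function(object) {
    cat(sprintf(paste0(
        "DatingResult (%d sequences)\n",
        "  rate r        : %.3g subst/site/year (T_div %.3g y)\n",
        "  mean pairwise : %.4g   mean tip-ancestor: %.4g\n",
        "  T_star        : %.4g years\n",
        "  T_mrca        : %.4g years\n",
        "  reported range: [%.3g, %.3g] years\n"),
        object@nSeqs, object@rate, object@tDivUsed, object@meanPairwise,
        object@meanAncestral, object@tStar, object@tMrca,
        object@tStar, object@tMrca))
    if (length(object@tStar) && length(object@tMrca) &&
        is.finite(object@tStar) && is.finite(object@tMrca) &&
        object@tStar > object@tMrca)
        message("note: T_star > T_mrca on these data (soft expectation violated)")
})

#' @describeIn DatingResult the reported [T_star, T_mrca] range in years.
#' @param x a \code{DatingResult}.
#' @export
datingRange <- function(x) c(tStar = x@tStar, tMrca = x@tMrca)
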