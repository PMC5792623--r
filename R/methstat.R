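# Region-level methylation quantification, in-silico Chop-PCR, regional
# Fisher comparisons and epiallele-category classification.

#' Weighted methylation level of a region
#'
#' The weighted level is the sum of methylated read counts divided by the
#' sum of total read counts over the covered cytosines of the requested
#' context in the region — robust to uneven depth, unlike a mean of
#' per-cytosine levels. A region with no covered cytosine is undefined
#' (\code{defined = FALSE}, level \code{NA}), never 0.
#'
#' @param records cytosine data.frame (chrom, pos 0-based, strand, context,
#'   count_methylated, count_total).
#' @param chrom chromosome.
#' @param lo,hi 0-based half-open region.
#' @param context one of "all", "CG", "CHG", "CHH".
#' @return list: level, methylated, total, cytosines, context, defined.
#' @export
weightedLevel <- function(records, chrom, lo, hi,
                          context = c("all", "CG", "CHG", "CHH")) {
    context <- match.arg(context)
    stopifnot(all(records$count_methylated <= records$count_total))
    sel <- records$chrom == chrom & records$pos >= lo & records$pos < hi &
        records$count_total > 0L
    if (context != "all") sel <- sel & records$context == context
    r <- records[sel, , drop = FALSE]
    if (nrow(r) == 0L)
        return(list(level = NA_real_, methylated = 0L, total = 0L,
                    cytosines = 0L, context = context, defined = FALSE))
    list(level = sum(r$count_methylated) / sum(r$count_total),
         methylated = sum(r$count_methylated), total = sum(r$count_total),
         cytosines = nrow(r), context = context, defined = TRUE)
}

#' Per-context methylation summary of a region
#'
#' @inheritParams weightedLevel
#' @return one-row data.frame with weighted levels (NA when uncovered) and
#'   covered-cytosine counts for CG, CHG, CHH and all contexts combined.
#' @export
regionMethylation <- function(records, chrom, lo, hi) {
    out <- data.frame(chrom = chrom, lo = lo, hi = hi)
    for (ctx in c("CG", "CHG", "CHH", "all")) {
        w <- weightedLevel(records, chrom, lo, hi, ctx)
        nm <- if (ctx == "all") "total" else ctx
        out[[paste0("level_", nm)]] <- w$level
        out[[paste0("n_", nm)]] <- w$cytosines
    }
    out
}

#' Enzyme definition for methylation-sensitive digestion
#'
#' @param name enzyme name.
#' @param recognition recognition sequence (e.g. "CCGG" for MspI, "GCGC"
#'   for HhaI).
#' @param diagnosticOffset 0-based offset of the methylation-diagnostic
#'   cytosine within the recognition site.
#' @return list of class "EnzymeDef".
#' @export
enzymeDefinition <- function(name, recognition, diagnosticOffset) {
    structure(list(name = name, recognition = toupper(recognition),
                   diagnosticOffset = as.integer(diagnosticOffset)),
              class = "EnzymeDef")
}

#' Built-in methylation-sensitive enzymes
#'
#' HhaI (GCGC, blocked by methylation of the internal CG cytosine) and MspI
#' (CCGG; in its methylation-sensitive use here, blocked by methylation of
#' the outer C — CHG-context sensitivity — configurable via
#' \code{\link{enzymeDefinition}}).
#'
#' @return named list of \code{EnzymeDef}.
#' @export
defaultEnzymes <- function() {
    list(HhaI = enzymeDefinition("HhaI", "GCGC", 1L),
         MspI = enzymeDefinition("MspI", "CCGG", 0L))
}

#' Locate diagnostic cytosines of an enzyme within an amplicon
#'
#' @param sequence amplicon (or chromosome) sequence.
#' @param enzyme an \code{EnzymeDef}.
#' @param lo,hi optional 0-based half-open amplicon bounds within
#'   \code{sequence} (the primer-delimited region); default whole sequence.
#' @return integer vector of 0-based diagnostic-cytosine positions.
#' @export
findDigestSites <- function(sequence, enzyme, lo = 0L, hi = NULL) {
    s <- toupper(as.character(sequence))
    if (is.null(hi)) hi <- nchar(s)
    if (lo < 0L || hi > nchar(s) || lo >= hi)
        stop("amplicon bounds outside sequence")
    m <- gregexpr(enzyme$recognition, substring(s, lo + 1L, hi),
                  fixed = TRUE)[[1]]
    if (m[1] == -1L) return(integer(0))
    as.integer(m) - 1L + lo + enzyme$diagnosticOffset
}

#' In-silico Chop-PCR band scoring
#'
#' Methylation-sensitive digestion destroys every template molecule whose
#' diagnostic cytosines are unmethylated; a molecule survives digestion with
#' probability equal to the product over recognition sites of the
#' methylation level at the site's diagnostic cytosine. With several
#' templates (alleles at equal dosage) the uncut fraction is the mean of
#' the per-allele survivals. A PCR band is called present when the uncut
#' fraction reaches \code{threshold}.
#'
#' @param siteLevels numeric vector of methylation levels at the diagnostic
#'   cytosines of one template, or a matrix with one row per allele
#'   (equal dosage) and one column per site. At least one site is required
#'   (otherwise the amplicon is an undigestible control and the band is
#'   trivially present).
#' @param threshold uncut fraction needed for a visible band; default 0.1.
#' @return list: band ("present"/"absent"), uncutFraction.
#' @export
chopPCR <- function(siteLevels, threshold = 0.1) {
    if (is.null(dim(siteLevels))) siteLevels <- matrix(siteLevels, nrow = 1)
    if (ncol(siteLevels) == 0L)
        return(list(band = "present", uncutFraction = 1))
    if (any(siteLevels < 0 | siteLevels > 1))
        stop("methylation levels must be in [0,1]")
    surv <- mean(apply(siteLevels, 1, prod))
    list(band = if (surv >= threshold) "present" else "absent",
         uncutFraction = surv)
}

#' Fisher exact comparison of regional methylation between two samples
#'
#' Pools reads across the covered cytosines of the region and context into
#' a 2x2 table (methylated/unmethylated x sample a/b) and applies the
#' two-sided Fisher exact test (summation of hypergeometric probabilities
#' at or below the observed table's).
#'
#' @param recordsA,recordsB cytosine data.frames for the two samples.
#' @param chrom,lo,hi region, 0-based half-open.
#' @param context "all", "CG", "CHG" or "CHH".
#' @return list: p (NA with defined = FALSE on an empty margin), table,
#'   defined.
#' @export
fisherRegionCompare <- function(recordsA, recordsB, chrom, lo, hi,
                                context = "all") {
    a <- weightedLevel(recordsA, chrom, lo, hi, context)
    b <- weightedLevel(recordsB, chrom, lo, hi, context)
    tab <- matrix(c(a$methylated, a$total - a$methylated,
                    b$methylated, b$total - b$methylated), nrow = 2,
                  dimnames = list(c("methylated", "unmethylated"),
                                  c("a", "b")))
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
        return(list(p = NA_real_, table = tab, defined = FALSE))
    list(p = stats::fisher.test(tab)$p.value, table = tab, defined = TRUE)
}

#' Classify an accession into an epiallele category
#'
#' Maps presence/absence of the element at the two loci (4.45 Mb and 16.75
#' Mb) and their CG methylation levels to one of the five categories
#' NMR19-16u, NMR19-4m, NMR19-4m/16m, NMR19-4u and deletion. An element is
#' scored methylated when its level reaches \code{methThreshold} (a numeric
#' stand-in for the gel-based binary call). Vectorised.
#'
#' @param presence4,presence16 logical vectors.
#' @param level4,level16 methylation levels (may be NA when absent).
#' @param methThreshold level at or above which an element counts as
#'   methylated; default 0.2.
#' @return character vector of categories.
#' @export
classifyAccession <- function(presence4, presence16, level4 = NA,
                              level16 = NA, methThreshold = 0.2) {
    n <- length(presence4)
    level4 <- rep_len(level4, n); level16 <- rep_len(level16, n)
    if (any(!presence4 & !is.na(level4) & level4 > 0) ||
        any(!presence16 & !is.na(level16) & level16 > 0))
        stop("methylation level defined but element absent")
    m4 <- presence4 & !is.na(level4) & level4 >= methThreshold
    m16 <- presence16 & !is.na(level16) & level16 >= methThreshold
    out <- character(n)
    out[!presence4 & !presence16] <- "deletion"
    out[!presence4 & presence16] <- ifelse(m16[!presence4 & presence16],
                                           "NMR19-16m", "NMR19-16u")
    out[presence4 & !presence16] <- ifelse(m4[presence4 & !presence16],
                                           "NMR19-4m", "NMR19-4u")
    both <- presence4 & presence16
    out[both] <- ifelse(m4[both] & m16[both], "NMR19-4m/16m",
                 ifelse(m4[both], "NMR19-4m", "NMR19-4u"))
    out
}
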