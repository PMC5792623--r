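# Non-reference TE insertion calling from discordant read pairs, plus
# target-site-duplication identification at the called junction.

#' Exact-match read placement against a reference plus TE contigs
#'
#' A deliberately simple aligner for error-free (or near-error-free)
#' synthetic reads: each read is placed wherever it matches the reference or
#' a TE contig exactly, on either strand. Reads matching more than one
#' location are flagged non-unique (and are excluded by the downstream
#' discordant-pair logic); unmatched reads are dropped. Junction-spanning
#' reads therefore do not map, which is exactly the property the
#' discordant-pair method relies on.
#'
#' @param reads a \code{DNAStringSet} with names \code{<id>/1} or
#'   \code{<id>/2}, or the list returned by \code{\link{simulateReadPairs}}.
#' @param genome a \linkS4class{GenomeModel} (the reference without the
#'   insertion).
#' @param teSequences named \code{DNAStringSet} (or named character vector)
#'   of TE family consensus contigs.
#' @return data.frame of alignment records: qname, mate (1/2), ref, start
#'   (0-based), strand, width, unique.
#' @export
naiveMap <- function(reads, genome, teSequences) {
    stopifnot(is(genome, "GenomeModel"))
    if (is.list(reads) && !is.null(reads$read1))
        reads <- c(reads$read1, reads$read2)
    if (is.character(teSequences))
        teSequences <- Biostrings::DNAStringSet(teSequences)
    subjects <- c(genome@seqs, teSequences)
    if (length(subjects) == 0L || sum(Biostrings::width(subjects)) == 0L)
        stop("empty reference")
    widths <- Biostrings::width(reads)
    hits <- vector("list", 0L)
    for (w in unique(widths)) {
        sel <- which(widths == w)
        pd <- Biostrings::PDict(reads[sel])
        pdRC <- Biostrings::PDict(Biostrings::reverseComplement(reads[sel]))
        for (si in seq_along(subjects)) {
            for (strand in c("+", "-")) {
                m <- Biostrings::matchPDict(
                    if (strand == "+") pd else pdRC, subjects[[si]])
                cnt <- S4Vectors::elementNROWS(m)
                hit <- which(cnt > 0L)
                if (!length(hit)) next
                starts <- Biostrings::startIndex(m)
                hits[[length(hits) + 1L]] <- data.frame(
                    readIdx = rep(sel[hit], cnt[hit]),
                    ref = names(subjects)[si],
                    start = unlist(starts[hit], use.names = FALSE) - 1L,
                    strand = strand,
                    width = w)
            }
        }
    }
    if (!length(hits))
        return(data.frame(qname = character(), mate = integer(),
                          ref = character(), start = integer(),
                          strand = character(), width = integer(),
                          unique = logical()))
    al <- do.call(rbind, hits)
    nm <- names(reads)[al$readIdx]
    al$qname <- sub("/[12]$", "", nm)
    al$mate <- ifelse(grepl("/2$", nm), 2L, 1L)
    nhits <- table(al$readIdx)
    al$unique <- as.vector(nhits[as.character(al$readIdx)]) == 1L
    al <- al[order(al$qname, al$mate), c("qname", "mate", "ref", "start",
                                         "strand", "width", "unique")]
    rownames(al) <- NULL
    al
}

#' Find and cluster discordant read pairs anchoring a TE insertion
#'
#' Keeps read pairs with exactly one mate uniquely on a TE contig and the
#' other mate uniquely on the genome, then clusters the genome-side anchors:
#' anchors closer than \code{insertMean + 3*insertSd} along a chromosome are
#' merged. Within a cluster, anchors on the + strand sit left of the
#' breakpoint and anchors on the - strand sit right of it.
#'
#' @param alignments data.frame from \code{\link{naiveMap}} (or
#'   \code{\link{readSamSubset}}).
#' @param teNames character vector of TE contig names.
#' @param insertMean,insertSd library fragment-size parameters used for
#'   clustering.
#' @return list of clusters; each a data.frame with columns qname, chrom,
#'   start, end, strand, side ("left"/"right"), teRef, teStrand. May be
#'   empty.
#' @export
findDiscordantPairs <- function(alignments, teNames, insertMean = 500,
                                insertSd = 50) {
    al <- alignments[alignments$unique, , drop = FALSE]
    onTE <- al$ref %in% teNames
    te <- al[onTE, , drop = FALSE]
    ge <- al[!onTE, , drop = FALSE]
    ids <- intersect(te$qname, ge$qname)
    # exactly one mate on each side
    ids <- ids[vapply(ids, function(q)
        sum(te$qname == q) == 1L && sum(ge$qname == q) == 1L, logical(1))]
    if (!length(ids)) return(list())
    te <- te[match(ids, te$qname), ]
    ge <- ge[match(ids, ge$qname), ]
    anchors <- data.frame(qname = ids, chrom = ge$ref, start = ge$start,
                          end = ge$start + ge$width, strand = ge$strand,
                          side = ifelse(ge$strand == "+", "left", "right"),
                          teRef = te$ref, teStrand = te$strand)
    anchors <- anchors[order(anchors$chrom, anchors$start), , drop = FALSE]
    gapMax <- insertMean + 3 * insertSd
    newClust <- c(TRUE, diff(anchors$start) > gapMax |
                        anchors$chrom[-1] != anchors$chrom[-nrow(anchors)])
    split(anchors, cumsum(newClust))
}

#' Call a TE insertion from one discordant-pair cluster
#'
#' The breakpoint interval runs from the rightmost end of the left-side
#' anchors to the leftmost start of the right-side anchors plus
#' \code{maxTsd}: because integration duplicates the target site, reads from
#' the right flank carry the duplicated copy and may map up to one TSD
#' length left of the true point, so the upper bound allows for it. Both
#' bounds are additionally relaxed by \code{junctionSlack} bases: with
#' junctional micro-homology between the element end and the flank, reads
#' crossing the junction by a few matching bases still anchor cleanly, and
#' the breakpoint is only defined up to that homology. A call
#' is emitted only with \code{minSupport} pairs on each side; otherwise a
#' candidate record with the reason is returned. Orientation is voted from
#' the strand pattern of the TE-side mates.
#'
#' @param cluster one element of \code{\link{findDiscordantPairs}} output.
#' @param insertMean,insertSd library fragment-size parameters.
#' @param minSupport minimum discordant pairs per side; default 3.
#' @param maxTsd largest TSD allowed for; default 30.
#' @param junctionSlack micro-homology allowance (bp) applied to both
#'   interval bounds; default 8.
#' @return a \linkS4class{TEInsertionCall}, or a list of class
#'   \code{"TECandidate"} (fields chrom, supportLeft, supportRight, reason)
#'   when support is one-sided or insufficient.
#' @export
callInsertion <- function(cluster, insertMean = 500, insertSd = 50,
                          minSupport = 3L, maxTsd = 30L,
                          junctionSlack = 8L) {
    left <- cluster[cluster$side == "left", , drop = FALSE]
    right <- cluster[cluster$side == "right", , drop = FALSE]
    if (nrow(left) < minSupport || nrow(right) < minSupport) {
        return(structure(list(chrom = cluster$chrom[1],
            supportLeft = nrow(left), supportRight = nrow(right),
            reason = sprintf(
                "insufficient support (left %d, right %d; need %d per side)",
                nrow(left), nrow(right), minSupport)),
            class = "TECandidate"))
    }
    lo <- max(left$end) - junctionSlack
    hi <- min(right$start) + maxTsd + junctionSlack + 1L
    if (lo >= hi) {              # deep-coverage overlap: 1-base midpoint
        mid <- (lo + hi) %/% 2L
        lo <- mid; hi <- mid + 1L
    }
    sameVotes <- sum(left$teStrand == "-") + sum(right$teStrand == "+")
    invVotes <- sum(left$teStrand == "+") + sum(right$teStrand == "-")
    new("TEInsertionCall", chrom = cluster$chrom[1],
        lo = as.integer(lo), hi = as.integer(hi),
        orientation = if (sameVotes >= invVotes) "same" else "inverted",
        supportLeft = nrow(left), supportRight = nrow(right),
        tsdLength = NA_integer_, tsdSeq = "")
}

#' @export
print.TECandidate <- function(x, ...) {
    cat(sprintf("TE insertion candidate on %s: %s\n", x$chrom, x$reason))
    invisible(x)
}

#' Detect the target-site duplication at an insertion junction
#'
#' Finds the longest sequence s (length <= \code{maxTsd}) that immediately
#' precedes and immediately follows the TE in the insertion allele, such
#' that collapsing the TE and one copy of s reconstructs a substring of the
#' reference allele (i.e. s occurs exactly once at the breakpoint before
#' integration). Returns length 0 and an empty sequence when the junction
#' carries no duplication.
#'
#' @param refFlank reference-allele sequence spanning the breakpoint with at
#'   least \code{maxTsd} bases of context on each side.
#' @param insertionAllele insertion-allele sequence containing exactly one
#'   copy of the TE with its flanks.
#' @param teSequence the inserted element sequence (already truncated if the
#'   insertion is 5'-truncated); its reverse complement is also searched.
#' @param maxTsd maximum TSD length considered; default 30.
#' @return list: tsdLength (integer), tsdSeq (character).
#' @export
detectTSD <- function(refFlank, insertionAllele, teSequence, maxTsd = 30L) {
    refFlank <- toupper(as.character(refFlank))
    allele <- toupper(as.character(insertionAllele))
    te <- toupper(as.character(teSequence))
    t0 <- regexpr(te, allele, fixed = TRUE)
    if (t0 == -1L) {
        t0 <- regexpr(revcompChar(te), allele, fixed = TRUE)
    }
    if (t0 == -1L) stop("TE not found in insertion allele")
    k <- nchar(te)
    pre <- substring(allele, 1L, t0 - 1L)
    post <- substring(allele, t0 + k)
    w <- maxTsd + 10L          # junction context compared to the reference
    for (s in seq.int(min(maxTsd, nchar(pre), nchar(post)), 0L)) {
        if (s > 0L) {
            leftCopy <- substring(pre, nchar(pre) - s + 1L)
            rightCopy <- substring(post, 1L, s)
            if (leftCopy != rightCopy) next
        }
        afterTsd <- substring(post, s + 1L)
        candidate <- paste0(substring(pre, max(1L, nchar(pre) - w + 1L)),
                            substring(afterTsd, 1L, w))
        if (grepl(candidate, refFlank, fixed = TRUE))
            return(list(tsdLength = s,
                        tsdSeq = if (s > 0L)
                            substring(pre, nchar(pre) - s + 1L) else ""))
    }
    list(tsdLength = 0L, tsdSeq = "")
}

#' Run the full insertion-detection chain on simulated reads
#'
#' Convenience wrapper: \code{\link{naiveMap}} then
#' \code{\link{findDiscordantPairs}} then \code{\link{callInsertion}} per
#' cluster.
#'
#' @param reads output of \code{\link{simulateReadPairs}} (run on the
#'   insertion-bearing genome).
#' @param genome the reference \linkS4class{GenomeModel} (without the
#'   insertion).
#' @param teSequences named TE contigs as in \code{\link{naiveMap}}.
#' @param insertMean,insertSd,minSupport,maxTsd passed through.
#' @return list with elements \code{calls} (list of
#'   \linkS4class{TEInsertionCall}) and \code{candidates} (list of
#'   \code{TECandidate}).
#' @export
detectInsertions <- function(reads, genome, teSequences, insertMean = 500,
                             insertSd = 50, minSupport = 3L, maxTsd = 30L) {
    al <- naiveMap(reads, genome, teSequences)
    teNames <- if (is.character(teSequences) && !is.null(names(teSequences)))
        names(teSequences) else names(Biostrings::DNAStringSet(teSequences))
    clusters <- findDiscordantPairs(al, teNames, insertMean, insertSd)
    calls <- list(); cands <- list()
    for (cl in clusters) {
        res <- callInsertion(cl, insertMean, insertSd, minSupport, maxTsd)
        if (is(res, "TEInsertionCall")) calls[[length(calls) + 1L]] <- res
        else cands[[length(cands) + 1L]] <- res
    }
    list(calls = calls, candidates = cands)
}
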