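# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# reverse complement of a plain character string
revcompChar <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# substring on a DNAStringSet chromosome, 0-based half-open
subseq0 <- function(seqs, chrom, lo, hi) {
    as.character(Biostrings::subseq(seqs[[chrom]], start = lo + 1L, end = hi))
}

# deterministic integer sub-seed for a named stage, always < 2^31
deriveSeed <- function(seed, stage) {
    codes <- utf8ToInt(stage)
    as.integer((as.numeric(seed) * 48271 + sum(codes * seq_along(codes))) %%
               2147483647)
}

# alignment (character vector / DNAStringSet) -> integer matrix rows=seqs,
# A,C,G,T -> 1..4, gap/N/other -> NA
alignmentToMatrix <- function(aligned) {
    if (methods::is(aligned, "XStringSet")) aligned <- as.character(aligned)
    stopifnot(length(aligned) >= 1L)
    L <- unique(nchar(aligned))
    if (length(L) != 1L)
        stop("aligned sequences must all have the same length")
    m <- matrix(match(unlist(strsplit(toupper(aligned), "", fixed = TRUE)),
                      BASES),
                nrow = length(aligned), ncol = L, byrow = TRUE)
    rownames(m) <- names(aligned)
    m
}

# validate an aligned set (>=2 rows, equal lengths); returns character vector
asAlignedSet <- function(aligned, min = 2L) {
    if (methods::is(aligned, "XStringSet")) aligned <- as.character(aligned)
    if (length(aligned) < min)
        stop("need at least ", min, " aligned sequences")
    if (length(unique(nchar(aligned))) != 1L)
        stop("aligned sequences must all have the same length")
    aligned
}

#' Drop alignment columns that are gaps in every sequence
#'
#' Utility for pre-aligned input: removes columns consisting entirely of
#' \code{-} (or \code{.}) before distance or dating computations.
#'
#' @param aligned named character vector or \code{DNAStringSet} of equal-length
#'   aligned sequences.
#' @return character vector of the same sequences without all-gap columns.
#' @export
stripAllGapColumns <- function(aligned) {
    aligned <- asAlignedSet(aligned, min = 1L)
    chars <- strsplit(aligned, "", fixed = TRUE)
    m <- do.call(rbind, chars)
    gap <- m == "-" | m == "."
    keep <- colSums(gap) < nrow(m)
    vapply(chars, function(s) paste(s[keep], collapse = ""), character(1))
}
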