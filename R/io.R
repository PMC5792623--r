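# Format readers/writers shared by all stages. FASTA/FASTQ go through
# Biostrings, trees through ape; the TSV dialects are documented here and
# validated on read.

#' Read / write FASTA
#'
#' @param path file path.
#' @return \code{readFasta}: a named \code{DNAStringSet}.
#' @export
readFasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname readFasta
#' @param seqs named \code{DNAStringSet} or character vector.
#' @export
writeFasta <- function(seqs, path) {
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

#' Write simulated read pairs as a FASTQ pair
#'
#' Constant maximum quality is written (the simulator does not model
#' quality).
#'
#' @param reads list from \code{\link{simulateReadPairs}}.
#' @param prefix output prefix; writes \code{<prefix>_1.fastq} and
#'   \code{<prefix>_2.fastq}.
#' @return the two paths, invisibly.
#' @export
writeReadPairsFastq <- function(reads, prefix) {
    paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
    for (i in 1:2) {
        rs <- reads[[i]]
        q <- Biostrings::BStringSet(strrep("I", Biostrings::width(rs)))
        names(q) <- names(rs)
        Biostrings::writeXStringSet(rs, paths[i], format = "fastq",
                                    qualities = q)
    }
    invisible(paths)
}

#' Read / write the per-cytosine methylation TSV
#'
#' Columns: chrom, pos (0-based), strand, context, count_methylated,
#' count_total. Rows violating 0 <= count_methylated <= count_total are
#' rejected with their line number.
#'
#' @param path file path.
#' @return data.frame of cytosine records.
#' @export
readCytosineTsv <- function(path) {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "strand", "context", "count_methylated",
              "count_total")
    if (!all(need %in% names(df)))
        stop("cytosine TSV must have columns: ", paste(need, collapse = ", "))
    bad <- which(df$count_methylated < 0 |
                 df$count_methylated > df$count_total)
    if (length(bad))
        stop("count_methylated > count_total at data line ", bad[1])
    df
}

#' @rdname readCytosineTsv
#' @param records cytosine data.frame.
#' @param provenance optional character vector written as leading
#'   \code{#} comment lines.
#' @export
writeCytosineTsv <- function(records, path, provenance = NULL) {
    writeTsv(records, path, provenance)
}

# shared TSV writer with '#' provenance header
writeTsv <- function(df, path, provenance = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(provenance))
        writeLines(paste0("# ", provenance), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a minimal SAM subset into alignment records
#'
#' Parses QNAME, FLAG (strand bit 0x10, mate bits 0x40/0x80, secondary
#' 0x100), RNAME, POS and a CIGAR consisting of a single \code{<n>M}
#' operation. Unmapped records (0x4 or RNAME "*") are dropped; secondary
#' alignments are flagged non-unique. POS is converted to 0-based.
#'
#' @param path SAM file path.
#' @return alignment data.frame as from \code{\link{naiveMap}}.
#' @export
readSamSubset <- function(path) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@")]
    out <- list()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(f) < 6L)
            stop("malformed SAM record at line ", i)
        flag <- suppressWarnings(as.integer(f[2]))
        if (is.na(flag)) stop("malformed FLAG at line ", i)
        if (bitwAnd(flag, 4L) > 0L || f[3] == "*") next
        m <- regmatches(f[6], regexec("^([0-9]+)M$", f[6]))[[1]]
        if (length(m) == 0L)
            stop("unsupported CIGAR (only <n>M) at line ", i)
        out[[length(out) + 1L]] <- data.frame(
            qname = f[1],
            mate = if (bitwAnd(flag, 128L) > 0L) 2L else 1L,
            ref = f[3],
            start = as.integer(f[4]) - 1L,
            strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
            width = as.integer(m[2]),
            unique = bitwAnd(flag, 256L) == 0L)
    }
    if (!length(out))
        return(data.frame(qname = character(), mate = integer(),
                          ref = character(), start = integer(),
                          strand = character(), width = integer(),
                          unique = logical()))
    do.call(rbind, out)
}

#' Write TE insertion calls as a BED-like TSV
#'
#' Columns: chrom, lo, hi (0-based half-open), name, support (left+right),
#' orientation, tsd_length, tsd_seq.
#'
#' @param calls list of \linkS4class{TEInsertionCall}.
#' @param path output path.
#' @param provenance optional \code{#} header lines.
#' @export
writeBedlike <- function(calls, path, provenance = NULL) {
    df <- do.call(rbind, lapply(seq_along(calls), function(i) {
        x <- calls[[i]]
        data.frame(chrom = x@chrom, lo = x@lo, hi = x@hi,
                   name = paste0("insertion_", i),
                   support = x@supportLeft + x@supportRight,
                   orientation = x@orientation,
                   tsd_length = x@tsdLength,
                   tsd_seq = ifelse(nchar(x@tsdSeq), x@tsdSeq, "."))
    }))
    if (is.null(df))
        df <- data.frame(chrom = character(), lo = integer(),
                         hi = integer(), name = character(),
                         support = integer(), orientation = character(),
                         tsd_length = integer(), tsd_seq = character())
    writeTsv(df, path, provenance)
}

#' Write / read a tree in newick format
#'
#' @param tree an \code{ape} \code{phylo}.
#' @param path file path.
#' @export
writeNewick <- function(tree, path) {
    ape::write.tree(tree, path)
    invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) ape::read.tree(path)
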