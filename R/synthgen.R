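# Synthetic-data generators: every stage of the pipeline can be exercised
# against inputs with known ground truth. All generators are deterministic
# given (seed, parameters).

#' Generate a random reference genome
#'
#' Draws i.i.d. bases at a target GC fraction. Intended as a stand-in for a
#' chromosome-scale reference when planting TE insertions.
#'
#' @param seed integer seed.
#' @param chromLengths named integer vector of chromosome lengths (bp),
#'   each >= 1000.
#' @param gcFraction target GC content in [0,1]; default 0.36
#'   (Arabidopsis-like).
#' @return a \linkS4class{GenomeModel}.
#' @examples
#' g <- makeReference(1, c(chr1 = 2000))
#' @export
makeReference <- function(seed, chromLengths, gcFraction = 0.36) {
    if (any(chromLengths < 1000))
        stop("chromosome lengths must be >= 1 kb")
    if (gcFraction < 0 || gcFraction > 1)
        stop("gcFraction must be in [0,1]")
    if (is.null(names(chromLengths)))
        names(chromLengths) <- paste0("chr", seq_along(chromLengths))
    set.seed(seed)
    p <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
           G = gcFraction / 2, T = (1 - gcFraction) / 2)
    seqs <- vapply(chromLengths, function(L) {
        paste(sample(BASES, L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    GenomeModel(Biostrings::DNAStringSet(seqs))
}

#' Generate a random TE-like element sequence
#'
#' Convenience wrapper for a uniquely identifiable element to plant;
#' AT-rich by default, as heterochromatic LINE1 elements tend to be.
#'
#' @param seed integer seed.
#' @param length element length (bp).
#' @param gcFraction GC content; default 0.33.
#' @return character string of A/C/G/T.
#' @export
makeElement <- function(seed, length = 3000L, gcFraction = 0.33) {
    set.seed(seed)
    p <- c((1 - gcFraction) / 2, gcFraction / 2,
           gcFraction / 2, (1 - gcFraction) / 2)
    paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
}

#' Plant a TE insertion with a target-site duplication into a genome
#'
#' Reproduces the sequence structure created by LINE1 integration: the
#' \code{tsdLength} bases immediately 5' of the insertion point are
#' duplicated so that the (possibly 5'-truncated and/or inverted) element is
#' flanked by two direct copies of the target site. The derived chromosome is
#' \code{left-flank + TSD + element' + TSD + right-flank} and grows by
#' element length + \code{tsdLength}.
#'
#' @param genome a \linkS4class{GenomeModel}.
#' @param insertion a \linkS4class{PlantedInsertion}.
#' @return a new \code{GenomeModel}; the inserted element interval is added
#'   to the annotations (name \code{"planted_TE"}).
#' @export
plantInsertion <- function(genome, insertion) {
    stopifnot(is(genome, "GenomeModel"), is(insertion, "PlantedInsertion"))
    chrom <- insertion@chrom
    if (!chrom %in% names(genome@seqs))
        stop("unknown chromosome: ", chrom)
    L <- Biostrings::width(genome@seqs)[names(genome@seqs) == chrom]
    p <- insertion@point
    if (p < 0L || p > L)
        stop("insertion point outside chromosome")
    if (insertion@tsdLength > p)
        stop("tsdLength larger than available left flank")
    te <- as.character(insertion@teSeq)
    if (insertion@truncation > 0L)
        te <- substring(te, insertion@truncation + 1L)
    if (insertion@inverted)
        te <- revcompChar(te)
    src <- as.character(genome@seqs[[chrom]])
    tsd <- if (insertion@tsdLength > 0L)
        substring(src, p - insertion@tsdLength + 1L, p) else ""
    derived <- paste0(substring(src, 1L, p), te, tsd,
                      substring(src, p + 1L))
    seqs <- as.character(genome@seqs)
    names(seqs) <- names(genome@seqs)
    seqs[chrom] <- derived
    # element occupies [p, p + nchar(te)) in the derived genome (0-based)
    ann <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = p + 1L, end = p + nchar(te)),
        strand = if (insertion@inverted) "-" else "+")
    S4Vectors::mcols(ann)$name <- "planted_TE"
    S4Vectors::mcols(ann)$tsdLength <- insertion@tsdLength
    old <- genome@annotations
    S4Vectors::mcols(old) <- S4Vectors::mcols(old)[
        intersect(names(S4Vectors::mcols(old)), c("name", "tsdLength"))]
    GenomeModel(Biostrings::DNAStringSet(seqs),
                suppressWarnings(c(old, ann)))
}

#' Simulate inner-facing paired-end reads from a genome
#'
#' Fragments are sampled uniformly along each chromosome (proportionally to
#' length across chromosomes); the two mates are the outermost
#' \code{readLen} bases of the fragment, mate 2 reverse-complemented.
#' Substitution errors are applied at \code{errorRate} per base.
#'
#' @param genome a \linkS4class{GenomeModel}.
#' @param readLen read length (bp); default 150.
#' @param insertMean,insertSd fragment (outer) size distribution; requires
#'   \code{insertMean > 2*readLen}.
#' @param coverage target sequence coverage; pairs =
#'   \code{round(coverage * genome / (2*readLen))}.
#' @param errorRate per-base substitution error probability; default 0.
#' @param seed integer seed.
#' @return list with \code{read1}, \code{read2} (\code{DNAStringSet}, names
#'   \code{<id>/1}, \code{<id>/2}) and \code{truth} (data.frame id, chrom,
#'   fragStart, fragEnd; 0-based half-open source interval).
#' @export
simulateReadPairs <- function(genome, readLen = 150L, insertMean = 500,
                              insertSd = 50, coverage = 30, errorRate = 0,
                              seed = 1L) {
    stopifnot(is(genome, "GenomeModel"))
    if (coverage <= 0) stop("coverage must be > 0")
    if (insertMean <= 2 * readLen)
        stop("insertMean must exceed 2*readLen")
    set.seed(seed)
    lens <- Biostrings::width(genome@seqs)
    total <- sum(lens)
    nPairs <- max(1L, round(coverage * total / (2 * readLen)))
    chromIdx <- sample(seq_along(lens), nPairs, replace = TRUE,
                       prob = lens / total)
    fragLen <- pmax(2L * readLen,
                    pmin(round(stats::rnorm(nPairs, insertMean, insertSd)),
                         lens[chromIdx]))
    starts <- floor(stats::runif(nPairs) * (lens[chromIdx] - fragLen + 1))
    ends <- starts + fragLen                       # 0-based half-open
    chromStr <- as.character(genome@seqs)
    r1 <- r2 <- character(nPairs)
    for (ci in unique(chromIdx)) {
        sel <- chromIdx == ci
        s <- chromStr[[ci]]
        r1[sel] <- substring(s, starts[sel] + 1L, starts[sel] + readLen)
        r2[sel] <- substring(s, ends[sel] - readLen + 1L, ends[sel])
    }
    r2 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(r2)))
    if (errorRate > 0) {
        r1 <- injectErrors(r1, errorRate)
        r2 <- injectErrors(r2, errorRate)
    }
    ids <- sprintf("frag%06d", seq_len(nPairs))
    read1 <- Biostrings::DNAStringSet(r1)
    read2 <- Biostrings::DNAStringSet(r2)
    names(read1) <- paste0(ids, "/1")
    names(read2) <- paste0(ids, "/2")
    list(read1 = read1, read2 = read2,
         truth = data.frame(id = ids,
                            chrom = names(genome@seqs)[chromIdx],
                            fragStart = starts, fragEnd = ends))
}

# substitution errors: each base replaced by a different base w.p. rate
injectErrors <- function(reads, rate) {
    n <- nchar(reads[1])
    hit <- which(stats::rbinom(length(reads), n, rate) > 0)
    for (i in hit) {
        chars <- strsplit(reads[i], "")[[1]]
        pos <- which(stats::runif(n) < rate)
        for (j in pos)
            chars[j] <- sample(setdiff(BASES, chars[j]), 1L)
        reads[i] <- paste(chars, collapse = "")
    }
    reads
}

#' Enumerate cytosines and their sequence contexts
#'
#' Finds every cytosine on both strands of the given 0-based half-open
#' region and assigns its context (CG, CHG or CHH with H = A, C or T),
#' reading the context from the cytosine's own strand. Cytosines within two
#' bases of the chromosome end (no complete context) are skipped.
#'
#' @param genome a \linkS4class{GenomeModel}.
#' @param chrom chromosome name.
#' @param lo,hi 0-based half-open region; defaults to the whole chromosome.
#' @return data.frame: chrom, pos (0-based), strand, context.
#' @export
cytosineContexts <- function(genome, chrom, lo = 0L, hi = NULL) {
    s <- as.character(genome@seqs[[chrom]])
    L <- nchar(s)
    if (is.null(hi)) hi <- L
    stopifnot(lo >= 0L, hi <= L, lo < hi)
    chars <- strsplit(s, "")[[1]]
    pos <- seq.int(lo + 1L, hi)                    # 1-based positions in region
    ctx <- function(b1, b2) {
        ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH"))
    }
    # plus strand: C at p with context chars[p+1], chars[p+2]
    pPlus <- pos[chars[pos] == "C" & pos + 2L <= L]
    plus <- if (length(pPlus))
        data.frame(chrom = chrom, pos = pPlus - 1L, strand = "+",
                   context = ctx(chars[pPlus + 1L], chars[pPlus + 2L]))
    # minus strand: G at p; downstream on '-' is decreasing position, bases
    # complemented
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    pMinus <- pos[chars[pos] == "G" & pos - 2L >= 1L]
    minus <- if (length(pMinus))
        data.frame(chrom = chrom, pos = pMinus - 1L, strand = "-",
                   context = ctx(comp[chars[pMinus - 1L]],
                                 comp[chars[pMinus - 2L]]))
    out <- rbind(plus, minus)
    if (is.null(out))
        return(data.frame(chrom = character(), pos = integer(),
                          strand = character(), context = character()))
    out <- out[order(out$pos, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Simulate per-cytosine bisulfite methylation calls
#'
#' For each region a methylation state sets the per-context mean level;
#' per-cytosine levels are drawn from a beta distribution around the mean
#' (overdispersion \code{rho}), depths from a Poisson, and methylated counts
#' binomially. Incomplete bisulfite conversion adds apparent methylation at
#' rate \code{conversionError} on unmethylated molecules. Cytosines with
#' zero depth are excluded.
#'
#' @param genome a \linkS4class{GenomeModel}.
#' @param regionStates data.frame with columns chrom, lo, hi (0-based
#'   half-open) and state ("methylated"/"unmethylated").
#' @param depthMean mean read depth per cytosine (> 0).
#' @param conversionError incomplete-conversion rate; default 0.005.
#' @param overdispersion beta overdispersion rho in (0,1); default 0.1.
#' @param contextMeans named list of per-context mean levels per state.
#' @param seed integer seed.
#' @return data.frame: chrom, pos (0-based), strand, context,
#'   count_methylated, count_total.
#' @export
simulateBisulfiteCalls <- function(genome, regionStates, depthMean = 30,
        conversionError = 0.005, overdispersion = 0.1,
        contextMeans = list(
            methylated   = c(CG = 0.85, CHG = 0.65, CHH = 0.10),
            unmethylated = c(CG = 0.02, CHG = 0.02, CHH = 0.02)),
        seed = 1L) {
    if (depthMean <= 0) stop("depthMean must be > 0")
    set.seed(seed)
    rho <- overdispersion
    out <- vector("list", nrow(regionStates))
    for (i in seq_len(nrow(regionStates))) {
        r <- regionStates[i, ]
        cy <- cytosineContexts(genome, r$chrom, r$lo, r$hi)
        if (nrow(cy) == 0L) next
        mu <- contextMeans[[r$state]][cy$context]
        if (rho > 0) {
            a <- mu * (1 - rho) / rho
            b <- (1 - mu) * (1 - rho) / rho
            p <- stats::rbeta(nrow(cy), pmax(a, 1e-6), pmax(b, 1e-6))
        } else p <- mu
        pObs <- p + (1 - p) * conversionError
        depth <- stats::rpois(nrow(cy), depthMean)
        cy$count_methylated <- stats::rbinom(nrow(cy), depth, pObs)
        cy$count_total <- depth
        out[[i]] <- cy[depth > 0L, , drop = FALSE]
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

# one batch of gametes from heterozygous-by-construction parents:
# hapA/hapB are matrices (n x nLoci) of parental-origin codes, states
# stA/stB (n x 1 epiallele state at the locus travels with its haplotype)
gametesFrom <- function(hapA, hapB, stA, stB, rfrac, locusCol,
                        ddm1 = FALSE, epsilon = 0) {
    n <- nrow(hapA)
    nl <- ncol(hapA)
    # current strand: FALSE = hapA, TRUE = hapB; Haldane: independent
    # crossover in each marker interval with probability rfrac[j]
    cur <- stats::runif(n) < 0.5
    out <- matrix(0L, n, nl)
    state <- character(n)
    for (j in seq_len(nl)) {
        if (j > 1L)
            cur <- xor(cur, stats::runif(n) < rfrac[j - 1L])
        out[, j] <- ifelse(cur, hapB[, j], hapA[, j])
        if (j == locusCol)
            state <- ifelse(cur, stB, stA)
    }
    if (ddm1 && epsilon > 0) {
        loss <- state == "m" & stats::runif(n) < epsilon
        state[loss] <- "u"
    }
    list(hap = out, state = state)
}

#' Simulate a cross segregating an epiallele
#'
#' Parents are homozygous: parent 1 carries allele 1 at every marker and the
#' first parental epiallele state, parent 2 allele 2 and the second state.
#' Meioses are independent with Haldane (no-interference) recombination from
#' the centimorgan map. The epiallele methylation state is inherited in cis
#' and unchanged, except that when \code{ddm1 = TRUE} each transmitted
#' methylated allele is irreversibly switched to unmethylated with
#' probability \code{epsilon} per meiosis.
#'
#' @param config a \linkS4class{CrossConfig}.
#' @param generation "F1", "F2" or "F3" (F2 = selfed F1; F3 = selfed F2).
#' @param n number of individuals (> 0).
#' @param seed integer seed.
#' @param ddm1 logical; population homozygous for a ddm1 mutation.
#' @return a \linkS4class{CrossPopulation}. The \code{band} column is the
#'   dominant Chop-PCR phenotype (TRUE iff >= 1 methylated allele).
#' @export
simulateCross <- function(config, generation = c("F2", "F1", "F3"), n,
                          seed = 1L, ddm1 = FALSE) {
    stopifnot(is(config, "CrossConfig"))
    generation <- match.arg(generation)
    if (n <= 0) stop("n must be > 0")
    set.seed(seed)
    mk <- config@markers
    pos <- c(mk$pos, config@locusPos)
    ord <- order(pos)
    pos <- pos[ord]
    isLocus <- c(rep(FALSE, nrow(mk)), TRUE)[ord]
    locusCol <- which(isLocus)
    nl <- length(pos)
    rfrac <- 0.5 * (1 - exp(-2 * diff(pos) / 100))
    p1 <- matrix(1L, n, nl); p2 <- matrix(2L, n, nl)
    s1 <- rep(config@parentalStates[1], n)
    s2 <- rep(config@parentalStates[2], n)
    eps <- config@epsilon
    # F1: one gamete from each parent (parents homozygous: recombination
    # is invisible but the meiosis still applies ddm1 loss)
    g1 <- gametesFrom(p1, p1, s1, s1, rfrac, locusCol, ddm1, eps)
    g2 <- gametesFrom(p2, p2, s2, s2, rfrac, locusCol, ddm1, eps)
    hapA <- g1$hap; hapB <- g2$hap; stA <- g1$state; stB <- g2$state
    gens <- switch(generation, F1 = 0L, F2 = 1L, F3 = 2L)
    for (k in seq_len(gens)) {
        ga <- gametesFrom(hapA, hapB, stA, stB, rfrac, locusCol, ddm1, eps)
        gb <- gametesFrom(hapA, hapB, stA, stB, rfrac, locusCol, ddm1, eps)
        hapA <- ga$hap; hapB <- gb$hap; stA <- ga$state; stB <- gb$state
    }
    df <- data.frame(id = sprintf("plant%05d", seq_len(n)))
    midx <- which(!isLocus)
    for (j in seq_along(midx)) {
        nm <- mk$name[order(mk$pos)][j]
        df[[paste0(nm, ".a")]] <- hapA[, midx[j]]
        df[[paste0(nm, ".b")]] <- hapB[, midx[j]]
    }
    df$locus.a <- stA
    df$locus.b <- stB
    df$band <- stA == "m" | stB == "m"
    new("CrossPopulation", individuals = df, generation = generation,
        config = config)
}

#' Self a simulated population for one generation
#'
#' Each individual is replaced by one selfed offspring (two independent
#' gametes), with the same ddm1 loss semantics as \code{\link{simulateCross}}.
#'
#' @param pop a \linkS4class{CrossPopulation}.
#' @param seed integer seed.
#' @param ddm1 logical; apply ddm1 methylation loss at each meiosis.
#' @return a \linkS4class{CrossPopulation} of the next generation.
#' @export
selfPopulation <- function(pop, seed = 1L, ddm1 = FALSE) {
    stopifnot(is(pop, "CrossPopulation"))
    set.seed(seed)
    config <- pop@config
    mk <- config@markers
    pos <- c(mk$pos, config@locusPos)
    ord <- order(pos)
    pos <- pos[ord]
    isLocus <- c(rep(FALSE, nrow(mk)), TRUE)[ord]
    locusCol <- which(isLocus)
    rfrac <- 0.5 * (1 - exp(-2 * diff(pos) / 100))
    df <- pop@individuals
    n <- nrow(df)
    sortedNames <- mk$name[order(mk$pos)]
    hapA <- as.matrix(df[paste0(sortedNames, ".a")])
    hapB <- as.matrix(df[paste0(sortedNames, ".b")])
    insertLocus <- function(h, st) {
        m <- matrix(0L, n, length(pos))
        m[, !isLocus] <- h
        m
    }
    hA <- insertLocus(hapA); hB <- insertLocus(hapB)
    ga <- gametesFrom(hA, hB, df$locus.a, df$locus.b, rfrac, locusCol,
                      ddm1, config@epsilon)
    gb <- gametesFrom(hA, hB, df$locus.a, df$locus.b, rfrac, locusCol,
                      ddm1, config@epsilon)
    out <- data.frame(id = df$id)
    midx <- which(!isLocus)
    for (j in seq_along(midx)) {
        out[[paste0(sortedNames[j], ".a")]] <- ga$hap[, midx[j]]
        out[[paste0(sortedNames[j], ".b")]] <- gb$hap[, midx[j]]
    }
    out$locus.a <- ga$state
    out$locus.b <- gb$state
    out$band <- out$locus.a == "m" | out$locus.b == "m"
    new("CrossPopulation", individuals = out,
        generation = pop@generation, config = config)
}

#' TN93 rate matrix
#'
#' Builds the Tamura-Nei (1993) instantaneous rate matrix with rows/columns
#' A, C, G, T, scaled so the expected substitution rate at stationarity is
#' one per site per unit time.
#'
#' @param params a \linkS4class{TN93Params}.
#' @return 4x4 numeric matrix.
#' @export
tn93RateMatrix <- function(params) {
    stopifnot(is(params, "TN93Params"))
    pi <- params@freqs
    Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
    for (i in 1:4) for (j in 1:4) {
        if (i == j) next
        purines <- all(BASES[c(i, j)] %in% c("A", "G"))
        pyrimidines <- all(BASES[c(i, j)] %in% c("C", "T"))
        rate <- if (purines) params@alpha1
            else if (pyrimidines) params@alpha2
            else params@beta
        Q[i, j] <- rate * pi[j]
    }
    diag(Q) <- -rowSums(Q)
    mu <- -sum(pi * diag(Q))
    Q / mu
}

# transition probability matrix P(d) = expm(Q d), via symmetrized eigen
tn93TransitionProbs <- function(params, d) {
    Q <- tn93RateMatrix(params)
    pi <- params@freqs
    S <- diag(sqrt(pi)) %*% Q %*% diag(1 / sqrt(pi))
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    P <- diag(1 / sqrt(pi)) %*% e$vectors %*% diag(exp(e$values * d)) %*%
        t(e$vectors) %*% diag(sqrt(pi))
    P[P < 0] <- 0
    P <- P / rowSums(P)
    dimnames(P) <- list(BASES, BASES)
    P
}

#' Evolve sequences from an ancestor along a star phylogeny
#'
#' Each of \code{nTips} lineages evolves independently from the ancestor for
#' \code{ageYears} years under the TN93 model scaled to \code{rate}
#' substitutions per site per year; the output is a gap-free alignment with
#' the ancestor retained as truth.
#'
#' @param ancestor ancestor sequence (character or \code{DNAString}).
#' @param nTips number of tip sequences.
#' @param ageYears divergence time T (years, >= 0).
#' @param rate substitution rate r (per site per year, >= 0).
#' @param params \linkS4class{TN93Params}; default: empirical ancestor base
#'   frequencies, transition/transversion factors 2/2/1.
#' @param seed integer seed.
#' @return list: \code{tips} (named \code{DNAStringSet}), \code{ancestor}
#'   (character), \code{params}, \code{rate}, \code{ageYears}.
#' @export
evolveStar <- function(ancestor, nTips, ageYears, rate, params = NULL,
                       seed = 1L) {
    ancestor <- toupper(as.character(ancestor))
    if (nchar(ancestor) == 0L) stop("zero-length ancestor")
    if (rate < 0 || ageYears < 0) stop("rate and ageYears must be >= 0")
    anc <- match(strsplit(ancestor, "")[[1]], BASES)
    if (anyNA(anc)) stop("ancestor must contain only A/C/G/T")
    if (is.null(params)) {
        f <- tabulate(anc, 4) + 1
        params <- TN93Params(freqs = f / sum(f))
    }
    set.seed(seed)
    P <- tn93TransitionProbs(params, rate * ageYears)
    L <- length(anc)
    tips <- matrix(0L, nTips, L)
    for (s in 1:4) {
        idx <- which(anc == s)
        if (!length(idx)) next
        tips[, idx] <- sample.int(4, nTips * length(idx), replace = TRUE,
                                  prob = P[s, ])
    }
    seqs <- apply(tips, 1, function(v) paste(BASES[v], collapse = ""))
    tipSet <- Biostrings::DNAStringSet(seqs)
    names(tipSet) <- sprintf("tip%03d", seq_len(nTips))
    list(tips = tipSet, ancestor = ancestor, params = params,
         rate = rate, ageYears = ageYears)
}

# rough means/sds for the 19 bioclim variables (temperature degC, precip mm)
BIOCLIM_MEAN <- c(9, 10, 35, 700, 22, -3, 25, 14, 4, 17, 1, 650, 80, 30,
                  30, 200, 120, 160, 150)
BIOCLIM_SD <- c(4, 2, 6, 120, 4, 4, 4, 6, 5, 4, 4, 180, 25, 12, 10, 60,
                40, 50, 45)

#' Simulate an accession table with climate variables
#'
#' Accessions are assigned to the methylated / unmethylated / deletion
#' groups; methylation levels follow the group (zero when the element is
#' absent, by convention), PPH expression decreases and post-darkness
#' chlorophyll increases with methylation. The 19 bioclimatic variables are
#' drawn at two epochs (present and last interglacial, correlated 0.7). A
#' monotone decreasing relation between methylation and bio9 (mean
#' temperature of the driest quarter) of strength \code{bio9Effect}
#' (standard deviations of bio9 shift per unit methylation tendency) is
#' planted; the LIG-epoch effect is attenuated to 60%. All other variables
#' are null.
#'
#' @param nAccessions number of accessions; default 137.
#' @param groupProportions named proportions (methylated, unmethylated,
#'   deletion) summing to 1; default c(21, 39, 77)/137.
#' @param bio9Effect planted effect size in bio9 standard deviations;
#'   0 = null; default 0.
#' @param seed integer seed.
#' @return data.frame, one row per accession: accession, group, presence4,
#'   presence16, meth_total, meth_CG, meth_CHG, meth_CHH, pph, chl,
#'   bio1_present..bio19_present, bio1_LIG..bio19_LIG.
#' @export
simulateClimateTable <- function(nAccessions = 137,
        groupProportions = c(methylated = 21, unmethylated = 39,
                             deletion = 77) / 137,
        bio9Effect = 0, seed = 1L) {
    if (abs(sum(groupProportions) - 1) > 1e-8)
        stop("groupProportions must sum to 1")
    set.seed(seed)
    n <- nAccessions
    grp <- sample(names(groupProportions), n, replace = TRUE,
                  prob = groupProportions)
    clamp <- function(x, lo = 0, hi = 1) pmin(hi, pmax(lo, x))
    meth <- grp == "methylated"
    cg <- chg <- chh <- numeric(n)
    cg[meth] <- clamp(stats::rnorm(sum(meth), 0.85, 0.05))
    chg[meth] <- clamp(stats::rnorm(sum(meth), 0.65, 0.07))
    chh[meth] <- clamp(stats::rnorm(sum(meth), 0.10, 0.03))
    unm <- grp == "unmethylated"
    cg[unm] <- clamp(stats::rnorm(sum(unm), 0.02, 0.01))
    chg[unm] <- clamp(stats::rnorm(sum(unm), 0.02, 0.01))
    chh[unm] <- clamp(stats::rnorm(sum(unm), 0.02, 0.01))
    total <- clamp(0.3 * cg + 0.3 * chg + 0.4 * chh +
                   stats::rnorm(n, 0, 0.01) * (grp != "deletion"))
    pph <- clamp(stats::rnorm(n, 1.4, 0.15) - 1.0 * total, 0, Inf)
    chl <- clamp(stats::rnorm(n, 0.45, 0.08) + 0.8 * total, 0, Inf)
    out <- data.frame(accession = sprintf("acc%03d", seq_len(n)),
                      group = grp,
                      presence4 = grp != "deletion",
                      presence16 = FALSE,
                      meth_total = total, meth_CG = cg, meth_CHG = chg,
                      meth_CHH = chh, pph = pph, chl = chl)
    for (b in 1:19) {
        zP <- stats::rnorm(n)
        zL <- 0.7 * zP + sqrt(1 - 0.49) * stats::rnorm(n)
        if (b == 9 && bio9Effect != 0) {
            # accessions with high methylation sit at cooler dry seasons
            zP <- zP - bio9Effect * (meth + total)
            zL <- zL - 0.6 * bio9Effect * (meth + total)
        }
        out[[paste0("bio", b, "_present")]] <-
            BIOCLIM_MEAN[b] + BIOCLIM_SD[b] * zP
        out[[paste0("bio", b, "_LIG")]] <-
            BIOCLIM_MEAN[b] + BIOCLIM_SD[b] * zL
    }
    out
}
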