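# Insertion dating: TN93 distances, NJ tree, rate calibration from ortholog
# divergence, the star-phylogeny estimator and the MRCA estimator via
# maximum-likelihood ancestral reconstruction.

#' Tamura-Nei (TN93) pairwise distance
#'
#' Closed-form TN93 distance from the proportions of purine transitions
#' (P1, A<->G), pyrimidine transitions (P2, C<->T) and transversions (Q),
#' with base frequencies taken empirically from the two sequences over the
#' compared sites. Sites with a gap, N or other ambiguity in either
#' sequence are excluded (pairwise deletion). Saturated pairs (a logarithm
#' argument <= 0) return \code{NA}.
#'
#' @param a,b aligned sequences (character or \code{DNAString}) of equal
#'   length.
#' @return the distance in substitutions per site, or \code{NA} on
#'   saturation.
#' @export
tn93Distance <- function(a, b) {
    m <- alignmentToMatrix(c(as.character(a), as.character(b)))
    tn93FromRows(m[1, ], m[2, ])
}

# core of the closed form, on integer-coded site vectors
tn93FromRows <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n == 0L) return(NA_real_)
    f <- tabulate(c(x, y), 4) / (2 * n)
    piA <- f[1]; piC <- f[2]; piG <- f[3]; piT <- f[4]
    piR <- piA + piG; piY <- piC + piT
    P1 <- sum((x == 1 & y == 3) | (x == 3 & y == 1)) / n
    P2 <- sum((x == 2 & y == 4) | (x == 4 & y == 2)) / n
    Q <- sum((x %in% c(1, 3)) != (y %in% c(1, 3))) / n
    if (P1 + P2 + Q == 0) return(0)
    if (piR <= 0 || piY <= 0) return(NA_real_)
    k1 <- 2 * piA * piG / piR
    k2 <- 2 * piT * piC / piY
    k3 <- 2 * (piR * piY - piA * piG * piY / piR - piT * piC * piR / piY)
    w1 <- if (k1 > 0) 1 - P1 / k1 - Q / (2 * piR) else 1
    w2 <- if (k2 > 0) 1 - P2 / k2 - Q / (2 * piY) else 1
    w3 <- 1 - Q / (2 * piR * piY)
    if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(NA_real_)
    d <- -(if (k1 > 0) k1 * log(w1) else 0) -
        (if (k2 > 0) k2 * log(w2) else 0) - k3 * log(w3)
    max(d, 0)
}

#' TN93 distance matrix of an alignment
#'
#' @param aligned named character vector or \code{DNAStringSet} of aligned
#'   sequences (>= 2, equal length).
#' @return symmetric numeric matrix with zero diagonal; \code{NA} for
#'   saturated pairs.
#' @export
tn93DistanceMatrix <- function(aligned) {
    aligned <- asAlignedSet(aligned)
    m <- alignmentToMatrix(aligned)
    n <- nrow(m)
    D <- matrix(0, n, n,
                dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
        D[i, j] <- D[j, i] <- tn93FromRows(m[i, ], m[j, ])
    }
    D
}

#' Mean raw divergence of each sequence to a reference sequence
#'
#' Raw (uncorrected) per-site mismatch proportion, pairwise-deleting gaps
#' and ambiguities.
#'
#' @param aligned aligned sequences.
#' @param reference a single aligned sequence of the same length.
#' @return numeric vector, one proportion per sequence.
#' @export
rawDivergence <- function(aligned, reference) {
    aligned <- asAlignedSet(aligned, min = 1L)
    m <- alignmentToMatrix(c(aligned, ref = as.character(reference)))
    ref <- m[nrow(m), ]
    vapply(seq_len(nrow(m) - 1L), function(i) {
        ok <- !is.na(m[i, ]) & !is.na(ref)
        if (!any(ok)) return(NA_real_)
        mean(m[i, ok] != ref[ok])
    }, numeric(1))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining. Negative branch lengths, which NJ
#' can produce on noisy matrices, are clamped to zero with the deficit
#' transferred to a sibling branch so that path lengths are preserved as
#' closely as possible.
#'
#' @param D symmetric distance matrix with zero diagonal and row/column
#'   names (>= 3 taxa, no \code{NA}).
#' @return an \code{ape} \code{phylo} tree.
#' @export
njTree <- function(D) {
    D <- as.matrix(D)
    if (nrow(D) < 3L) stop("need >= 3 taxa")
    if (any(is.na(D))) stop("distance matrix contains NA (saturated pairs)")
    if (max(abs(D - t(D))) > 1e-12 || any(diag(D) != 0))
        stop("matrix must be symmetric with zero diagonal")
    tr <- ape::nj(D)
    neg <- which(tr$edge.length < 0)
    for (e in neg) {
        parent <- tr$edge[e, 1]
        sibs <- setdiff(which(tr$edge[, 1] == parent), e)
        if (length(sibs)) {
            tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] +
                tr$edge.length[e]
        }
        tr$edge.length[e] <- 0
    }
    tr
}

#' Calibrate a substitution rate from ortholog divergence
#'
#' Two lineages separated T years ago accumulate divergence d = 2 r T, so
#' r = d / (2 T).
#'
#' @param dOrtholog divergence between the orthologous sequences (>= 0).
#' @param tDiv species divergence time in years (> 0).
#' @return substitution rate per site per year.
#' @export
calibrateRate <- function(dOrtholog, tDiv) {
    if (tDiv <= 0) stop("tDiv must be > 0")
    if (dOrtholog < 0) stop("dOrtholog must be >= 0")
    dOrtholog / (2 * tDiv)
}

#' Star-phylogeny age estimate
#'
#' Under a star phylogeny all copies radiated from the common ancestor at
#' the insertion time T, so the expected pairwise distance is 2 r T:
#' T_star = d-bar / (2 r) with d-bar the mean pairwise TN93 distance.
#' Saturated (undefined) pairs are excluded with a message; if all pairs
#' are undefined this is an error.
#'
#' @param aligned aligned element copies (>= 2).
#' @param rate substitution rate r (> 0), e.g. from
#'   \code{\link{calibrateRate}}.
#' @return estimated age in years, with attributes \code{meanPairwise} and
#'   \code{nPairs}.
#' @export
starAge <- function(aligned, rate) {
    if (rate <= 0) stop("rate must be > 0")
    D <- tn93DistanceMatrix(aligned)
    d <- D[upper.tri(D)]
    bad <- sum(is.na(d))
    if (bad == length(d)) stop("all pairwise distances undefined")
    if (bad > 0)
        message(bad, " saturated pair(s) excluded from the star estimate")
    dbar <- mean(d, na.rm = TRUE)
    structure(dbar / (2 * rate), meanPairwise = dbar,
              nPairs = sum(!is.na(d)))
}

# tip conditional-likelihood column for integer states (NA = gap -> 1s)
tipLik <- function(states) {
    L <- length(states)
    lik <- matrix(0, 4, L)
    ok <- !is.na(states)
    lik[cbind(states[ok], which(ok))] <- 1
    lik[, !ok] <- 1
    lik
}

#' Maximum-likelihood ancestral sequence at the root
#'
#' Marginal ML reconstruction by the pruning algorithm under TN93 with
#' empirical base frequencies: per-site conditional likelihoods are
#' propagated to the root and the state maximising pi_s * L_s is emitted.
#' Per-site ties are broken by higher stationary frequency, then
#' alphabetically, and counted in a message. Sites that are gaps in every
#' sequence are emitted as gaps.
#'
#' @param aligned aligned sequences (>= 2, equal length).
#' @param tree an \code{ape} \code{phylo} with edge lengths, leaves matching
#'   the alignment names; \code{NULL} (default) uses a star tree with equal
#'   branch lengths of half the mean pairwise TN93 distance.
#' @param params \linkS4class{TN93Params}; default: empirical frequencies
#'   of the alignment with transition/transversion factors 2/2/1.
#' @return ancestor sequence (character; may contain "-").
#' @export
ancestralSequence <- function(aligned, tree = NULL, params = NULL) {
    aligned <- asAlignedSet(aligned)
    m <- alignmentToMatrix(aligned)
    n <- nrow(m); L <- ncol(m)
    if (is.null(params)) {
        f <- tabulate(m[!is.na(m)], 4) + 1
        params <- TN93Params(freqs = f / sum(f))
    }
    pi <- params@freqs
    if (is.null(tree)) {
        D <- tn93DistanceMatrix(aligned)
        dbar <- mean(D[upper.tri(D)], na.rm = TRUE)
        if (!is.finite(dbar)) dbar <- 0
        bl <- max(dbar / 2, 1e-8)
        P <- tn93TransitionProbs(params, bl)
        rootLik <- matrix(1, 4, L)
        for (i in seq_len(n))
            rootLik <- rootLik * (P %*% tipLik(m[i, ]))
    } else {
        if (is.null(tree$edge.length)) stop("tree needs edge lengths")
        if (!setequal(tree$tip.label, rownames(m)))
            stop("tree leaves must match alignment names")
        tr <- ape::reorder.phylo(tree, "postorder")
        nTip <- length(tr$tip.label)
        nNode <- max(tr$edge)
        lik <- vector("list", nNode)
        for (e in seq_len(nrow(tr$edge))) {
            parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
            cl <- if (child <= nTip)
                tipLik(m[match(tr$tip.label[child], rownames(m)), ])
            else lik[[child]]
            P <- tn93TransitionProbs(params, max(tr$edge.length[e], 1e-10))
            contrib <- P %*% cl
            if (is.null(lik[[parent]])) lik[[parent]] <- contrib
            else lik[[parent]] <- lik[[parent]] * contrib
            # rescale to guard against underflow on large trees
            sc <- apply(lik[[parent]], 2, max)
            sc[sc == 0] <- 1
            lik[[parent]] <- sweep(lik[[parent]], 2, sc, "/")
        }
        rootLik <- lik[[nTip + 1L]]
    }
    post <- rootLik * pi
    allGap <- colSums(!is.na(m)) == 0L
    best <- integer(L)
    nTies <- 0L
    cmax <- apply(post, 2, max)
    for (s in seq_len(L)) {
        if (cmax[s] <= 0) { best[s] <- NA_integer_; next }
        cand <- which(post[, s] >= cmax[s] * (1 - 1e-9))
        if (length(cand) > 1L) {
            nTies <- nTies + 1L
            cand <- cand[order(-pi[cand], BASES[cand])]
        }
        best[s] <- cand[1]
    }
    if (nTies > 0L)
        message(nTies, " site(s) had tied reconstructions ",
                "(resolved by stationary frequency, then alphabetically)")
    out <- BASES[best]
    out[allGap | is.na(best)] <- "-"
    paste(out, collapse = "")
}

#' MRCA-based age estimate
#'
#' Counts substitutions between each copy and the (reconstructed) ancestor
#' as the raw per-site proportion (gaps excluded pairwise) and divides the
#' mean by the rate: T_mrca = d-bar_anc / r. A TN93-corrected mode is
#' available.
#'
#' @param aligned aligned element copies.
#' @param ancestor ancestor sequence of the same alignment length.
#' @param rate substitution rate r (> 0).
#' @param model "raw" (default) or "tn93" for corrected divergences.
#' @return estimated age in years, with attribute \code{meanAncestral}.
#' @export
mrcaAge <- function(aligned, ancestor, rate, model = c("raw", "tn93")) {
    model <- match.arg(model)
    if (rate <= 0) stop("rate must be > 0")
    aligned <- asAlignedSet(aligned)
    if (nchar(ancestor) != nchar(aligned[1]))
        stop("ancestor length must match the alignment")
    d <- if (model == "raw") rawDivergence(aligned, ancestor)
        else vapply(aligned, function(s) tn93Distance(s, ancestor),
                    numeric(1))
    dbar <- mean(d, na.rm = TRUE)
    structure(dbar / rate, meanAncestral = dbar)
}

#' Date a TE insertion with the star and MRCA estimators
#'
#' Calibrates the substitution rate from an ortholog pair at the midpoint
#' of the given species divergence range, computes the star-phylogeny
#' estimate (a lower bound: shared internal branches make pairwise
#' distances undershoot twice the age), reconstructs the ancestor on the
#' neighbor-joining tree of the copies and computes the MRCA estimate (an
#' upper bound: the MRCA predates the youngest common insertion). Reports
#' the range [T_star, T_mrca].
#'
#' @param aligned aligned element copies from the sampled accessions.
#' @param orthologPair two aligned orthologous sequences (list or character
#'   of length 2) used for rate calibration; alternatively supply
#'   \code{rate} directly.
#' @param tDivRange species divergence-time range in years; the midpoint is
#'   used (default c(3.5e6, 5.8e6), midpoint 4.65 MYA).
#' @param rate optional substitution rate overriding calibration.
#' @param orthologModel "tn93" (default) or "raw" divergence for the
#'   calibration.
#' @param params optional \linkS4class{TN93Params} for reconstruction.
#' @return a \linkS4class{DatingResult}.
#' @export
dateInsertion <- function(aligned, orthologPair = NULL,
                          tDivRange = c(3.5e6, 5.8e6), rate = NULL,
                          orthologModel = c("tn93", "raw"), params = NULL) {
    orthologModel <- match.arg(orthologModel)
    aligned <- asAlignedSet(aligned)
    tDiv <- mean(tDivRange)
    if (is.null(rate)) {
        if (is.null(orthologPair))
            stop("supply either orthologPair or rate")
        op <- asAlignedSet(as.character(unlist(orthologPair)))
        dOrth <- if (orthologModel == "tn93")
            tn93Distance(op[1], op[2])
        else {
            mm <- alignmentToMatrix(op)
            ok <- !is.na(mm[1, ]) & !is.na(mm[2, ])
            mean(mm[1, ok] != mm[2, ok])
        }
        if (is.na(dOrth)) stop("ortholog divergence undefined (saturated)")
        rate <- calibrateRate(dOrth, tDiv)
    }
    tStar <- starAge(aligned, rate)
    tree <- if (length(aligned) >= 3L) {
        D <- tn93DistanceMatrix(aligned)
        if (any(is.na(D))) NULL else njTree(D)
    } else NULL
    anc <- ancestralSequence(aligned, tree, params)
    tMrca <- mrcaAge(aligned, anc, rate)
    if (as.numeric(tStar) > as.numeric(tMrca))
        message("T_star exceeds T_mrca on these data (soft check)")
    new("DatingResult", rate = rate,
        meanPairwise = attr(tStar, "meanPairwise"),
        meanAncestral = attr(tMrca, "meanAncestral"),
        tStar = as.numeric(tStar), tMrca = as.numeric(tMrca),
        tDivUsed = tDiv, nSeqs = length(aligned))
}
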