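# Independent oracles, coded directly from first principles / textbook
# formulas; deliberately different code paths from the package internals.

# TN93 distance from explicit site classification with string vectors
oracleTN93 <- function(a, b) {
    x <- strsplit(a, "")[[1]]
    y <- strsplit(b, "")[[1]]
    ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    cnt <- table(factor(c(x, y), levels = c("A", "C", "G", "T")))
    gA <- cnt[["A"]] / (2 * n); gC <- cnt[["C"]] / (2 * n)
    gG <- cnt[["G"]] / (2 * n); gT <- cnt[["T"]] / (2 * n)
    gR <- gA + gG; gY <- gC + gT
    P1 <- mean((x == "A" & y == "G") | (x == "G" & y == "A"))
    P2 <- mean((x == "C" & y == "T") | (x == "T" & y == "C"))
    Q <- mean((x %in% c("A", "G")) != (y %in% c("A", "G")))
    k1 <- 2 * gA * gG / gR
    k2 <- 2 * gT * gC / gY
    k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
    -k1 * log(1 - P1 / k1 - Q / (2 * gR)) -
        k2 * log(1 - P2 / k2 - Q / (2 * gY)) -
        k3 * log(1 - Q / (2 * gR * gY))
}

# Jukes-Cantor distance
oracleJC <- function(p) -3 / 4 * log(1 - 4 * p / 3)

# two-sided Fisher exact p by full hypergeometric enumeration
oracleFisher <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(support, m, n, k)
    pObs <- stats::dhyper(tab[1, 1], m, n, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# two-sided rank-sum p by enumeration of all group assignments
oracleRankSum <- function(a, b) {
    n1 <- length(a); n <- n1 + length(b)
    r <- rank(c(a, b))
    wObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2      # Mann-Whitney U
    combs <- utils::combn(n, n1)
    ws <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    mu <- n1 * (n - n1) / 2
    mean(abs(ws - mu) >= abs(wObs - mu) - 1e-9)
}

# two-sided exact Spearman p by enumeration of all permutations (no ties)
oracleSpearmanExact <- function(x, y) {
    n <- length(x)
    rObs <- stats::cor(rank(x), rank(y))
    perms <- permutationsAll(n)
    rx <- rank(x)
    rs <- apply(perms, 1, function(p) stats::cor(rx, rank(y)[p]))
    list(rho = rObs, p = mean(abs(rs) >= abs(rObs) - 1e-9))
}

permutationsAll <- function(n) {
    if (n == 1) return(matrix(1))
    sub <- permutationsAll(n - 1)
    do.call(rbind, lapply(seq_len(n), function(i)
        cbind(i, sub + (sub >= i))))
}

# Welch t-test from the textbook formula
oracleWelch <- function(a, b) {
    va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# brute-force TSD: tries every substring length at the junction
oracleTSD <- function(refFlank, allele, te, maxTsd = 12) {
    t0 <- regexpr(te, allele, fixed = TRUE)
    if (t0 == -1) t0 <- regexpr(revcompOracle(te), allele, fixed = TRUE)
    stopifnot(t0 != -1)
    k <- nchar(te)
    best <- 0; bestSeq <- ""
    for (s in seq_len(maxTsd)) {
        left <- substring(allele, t0 - s, t0 - 1)
        right <- substring(allele, t0 + k, t0 + k + s - 1)
        if (nchar(left) == s && left == right) {
            junction <- paste0(substring(allele, max(1, t0 - s - 20), t0 - 1),
                               substring(allele, t0 + k + s))
            if (grepl(substring(junction, 1, 20 + s + 20), refFlank,
                      fixed = TRUE)) {
                best <- s; bestSeq <- left
            }
        }
    }
    list(tsdLength = best, tsdSeq = bestSeq)
}

revcompOracle <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

randomSeq <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tip-to-tip path-length matrix of a phylo tree, pure R (BFS per tip)
oracleCophenetic <- function(tr) {
    n <- length(tr$tip.label)
    N <- max(tr$edge)
    adj <- vector("list", N)
    for (e in seq_len(nrow(tr$edge))) {
        a <- tr$edge[e, 1]; b <- tr$edge[e, 2]; w <- tr$edge.length[e]
        adj[[a]] <- rbind(adj[[a]], c(b, w))
        adj[[b]] <- rbind(adj[[b]], c(a, w))
    }
    D <- matrix(0, n, n, dimnames = list(tr$tip.label, tr$tip.label))
    for (i in seq_len(n)) {
        dist <- rep(NA_real_, N)
        dist[i] <- 0
        queue <- i
        while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]
            am <- adj[[v]]
            for (r in seq_len(NROW(am))) {
                u <- am[r, 1]
                if (is.na(dist[u])) {
                    dist[u] <- dist[v] + am[r, 2]
                    queue <- c(queue, u)
                }
            }
        }
        D[i, ] <- dist[seq_len(n)]
    }
    D
}
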