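# constructs a pair of sequences with prescribed difference counts and a
# balanced base composition (300 of each base before substitution)
makeBalancedPair <- function(nAG, nCT, nTv, L = 1200L) {
    stopifnot(nTv %% 4 == 0, nAG %% 2 == 0, nCT %% 2 == 0)
    x <- rep(c("A", "C", "G", "T"), each = L / 4)
    y <- x
    idx <- split(seq_len(L), x)
    take <- function(base, n) {
        out <- idx[[base]][seq_len(n)]
        idx[[base]] <<- idx[[base]][-seq_len(n)]
        out
    }
    y[take("A", nAG / 2)] <- "G"; y[take("G", nAG / 2)] <- "A"
    y[take("C", nCT / 2)] <- "T"; y[take("T", nCT / 2)] <- "C"
    y[take("A", nTv / 4)] <- "C"; y[take("C", nTv / 4)] <- "A"
    y[take("G", nTv / 4)] <- "T"; y[take("T", nTv / 4)] <- "G"
    c(a = paste(x, collapse = ""), b = paste(y, collapse = ""))
}

test_that("TN93 distance matches the closed-form oracle and ape", {
    expect_equal(tn93Distance("ACGTACGT", "ACGTACGT"), 0)
    set.seed(201)
    for (i in 1:10) {
        a <- randomSeq(500)
        b <- strsplit(a, "")[[1]]
        swap <- sample(500, 25)
        b[swap] <- sample(c("A", "C", "G", "T"), 25, replace = TRUE)
        b <- paste(b, collapse = "")
        d <- tn93Distance(a, b)
        expect_equal(d, oracleTN93(a, b), tolerance = 1e-9)
        expect_equal(tn93Distance(b, a), d)            # symmetry
        expect_gte(d, 0)
    }
    # constructed pair with P1 = 0.02, P2 = 0.01, Q = 0.03 over 1200 sites
    pr <- makeBalancedPair(nAG = 24, nCT = 12, nTv = 36)
    expect_equal(tn93Distance(pr["a"], pr["b"]), oracleTN93(pr["a"], pr["b"]),
                 tolerance = 1e-12)
    # independent implementation from ape agrees
    mat <- do.call(rbind, strsplit(tolower(c(pr["a"], pr["b"])), ""))
    dApe <- ape::dist.dna(ape::as.DNAbin(mat), model = "TN93")
    expect_equal(tn93Distance(pr["a"], pr["b"]), as.numeric(dApe),
                 tolerance = 1e-6)
    # gaps/N excluded pairwise
    expect_equal(tn93Distance("ACGT-N", "ACGTAA"), 0)
})

test_that("TN93 reduces to Jukes-Cantor in the equal-rates limit", {
    # JC substitution pattern: P1 = P2 = p/6, Q = 2p/3, equal frequencies
    for (p12 in c(12L, 24L)) {
        pr <- makeBalancedPair(nAG = p12, nCT = p12, nTv = 4 * p12)
        p <- 6 * p12 / 1200
        expect_equal(tn93Distance(pr["a"], pr["b"]), oracleJC(p),
                     tolerance = 1e-9)
    }
})

test_that("distance matrix is symmetric, zero-diagonal, zero iff identical", {
    set.seed(202)
    s1 <- randomSeq(300)
    ch <- strsplit(s1, "")[[1]]
    ch[sample(300, 30)] <- sample(c("A", "C", "G", "T"), 30, replace = TRUE)
    seqs <- c(s1 = s1, s2 = paste(ch, collapse = ""), s3 = s1)
    D <- tn93DistanceMatrix(seqs)
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    expect_equal(D["s1", "s3"], 0)
    expect_gt(D["s1", "s2"], 0)
})

test_that("NJ reproduces three-point branch lengths exactly", {
    D <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
    tr <- njTree(D)
    bl <- stats::setNames(tr$edge.length,
                          tr$tip.label[tr$edge[, 2]])
    expect_equal(bl[["a"]], (0.2 + 0.3 - 0.4) / 2)
    expect_equal(bl[["b"]], (0.2 + 0.4 - 0.3) / 2)
    expect_equal(bl[["c"]], (0.3 + 0.4 - 0.2) / 2)
    expect_error(njTree(D[1:2, 1:2]), ">= 3 taxa")
})

test_that("NJ recovers every additive 4- and 5-taxon topology (brute force)", {
    set.seed(203)
    for (n in c(4L, 5L)) {
        topos <- phangorn::allTrees(n, rooted = FALSE,
                                    tip.label = letters[1:n])
        for (k in seq_along(topos)) {
            tp <- topos[[k]]      # [[ re-attaches compressed tip labels
            tp$edge.length <- stats::runif(nrow(tp$edge), 0.05, 0.5)
            D <- oracleCophenetic(tp)[letters[1:n], letters[1:n]]
            est <- njTree(D)
            # with strictly positive branch lengths, exact recovery of the
            # additive distances implies the correct topology
            expect_lt(max(abs(oracleCophenetic(est)[letters[1:n],
                                                    letters[1:n]] - D)),
                      1e-9)
        }
    }
})

test_that("ultrametric star distances give a star-like NJ tree", {
    D <- matrix(0.2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    diag(D) <- 0
    tr <- njTree(D)
    internal <- tr$edge.length[tr$edge[, 2] > length(tr$tip.label)]
    expect_true(all(abs(internal) < 1e-12))
})

test_that("rate calibration is d / (2T)", {
    expect_equal(calibrateRate(0, 5e6), 0)
    expect_equal(calibrateRate(0.068, 5e6), 6.8e-9)
    expect_error(calibrateRate(0.01, 0), "tDiv")
})

test_that("star and MRCA age estimators implement d/(2r) and d_anc/r", {
    anc <- makeElement(204, 2000L)
    same <- c(a = anc, b = anc, c = anc)
    expect_equal(as.numeric(starAge(same, 6.8e-9)), 0)
    expect_equal(as.numeric(mrcaAge(same, anc, 6.8e-9)), 0)
    ev <- evolveStar(anc, 10L, 4e5, 6.8e-9, seed = 205)
    tips <- as.character(ev$tips)
    ts <- starAge(tips, 6.8e-9)
    expect_equal(as.numeric(ts),
                 attr(ts, "meanPairwise") / (2 * 6.8e-9))
    tm <- mrcaAge(tips, anc, 6.8e-9)
    expect_equal(as.numeric(tm), attr(tm, "meanAncestral") / 6.8e-9)
    # spec-scale arithmetic: a mean pairwise distance of 0.005 at the
    # calibrated rate corresponds to ~3.68e5 years
    expect_equal(0.005 / (2 * 6.8e-9), 367647, tolerance = 1e-5)
    expect_error(starAge(tips, 0), "rate")
    expect_error(mrcaAge(tips, anc, -1), "rate")
    expect_error(mrcaAge(tips, substring(anc, 1, 100), 6.8e-9), "length")
})

test_that("ancestral reconstruction: identity, consensus and tie rule", {
    s <- randomSeq(400, seed = 206)
    expect_identical(ancestralSequence(c(a = s, b = s, c = s)), s)
    # low-divergence star data: agrees with per-site majority consensus
    anc <- makeElement(207, 3000L)
    ev <- evolveStar(anc, 30L, 5e5, 6.8e-9, seed = 208)  # d_anc ~ 0.0034
    tips <- as.character(ev$tips)
    rec <- ancestralSequence(tips)
    m <- do.call(rbind, strsplit(tips, ""))
    consensus <- apply(m, 2, function(col) {
        tb <- sort(table(col), decreasing = TRUE)
        names(tb)[1]
    })
    agree <- mean(strsplit(rec, "")[[1]] == consensus)
    expect_gte(agree, 0.999)
    # two tips, equal branches, A/G site: tie broken by higher frequency
    prm <- TN93Params(freqs = c(A = 0.4, C = 0.2, G = 0.1, T = 0.3))
    two <- c(x = "AAAAAAAAAA", y = "GAAAAAAAAA")
    star <- ape::read.tree(text = "(x:0.01,y:0.01);")
    got <- suppressMessages(ancestralSequence(two, star, prm))
    expect_identical(substring(got, 1, 1), "A")   # pi_A > pi_G
})

test_that("dating estimator bias shrinks with alignment length", {
    rate <- 6.8e-9; T <- 5e5
    errs <- vapply(c(1000L, 10000L), function(L) {
        anc <- makeElement(209, L)
        est <- vapply(1:3, function(i) {
            ev <- evolveStar(anc, 20L, T, rate, seed = 210 + i + L)
            as.numeric(starAge(as.character(ev$tips), rate))
        }, numeric(1))
        abs(mean(est) - T) / T
    }, numeric(1))
    expect_lt(errs[2], 0.08)      # long alignments pin the estimate down
})

test_that("dateInsertion integrates calibration and both estimators", {
    anc <- makeElement(211, 2000L)
    same <- c(a = anc, b = anc, c = anc)
    res0 <- suppressMessages(dateInsertion(same, rate = 6.8e-9))
    expect_equal(datingRange(res0), c(tStar = 0, tMrca = 0))
    ev <- evolveStar(anc, 12L, 5e5, 6.8e-9, seed = 212)
    orth <- evolveStar(makeElement(213, 2000L), 2L, 4.65e6, 6.8e-9,
                       seed = 214)
    res <- suppressMessages(dateInsertion(as.character(ev$tips),
        orthologPair = as.character(orth$tips)))
    expect_s4_class(res, "DatingResult")
    expect_equal(res@tDivUsed, 4.65e6)
    # calibrated rate recovers the simulated rate within Monte-Carlo error
    expect_lt(abs(res@rate - 6.8e-9) / 6.8e-9, 0.25)
    expect_lt(abs(res@tStar - 5e5) / 5e5, 0.35)
    expect_lt(abs(res@tMrca - 5e5) / 5e5, 0.35)
    expect_error(dateInsertion(same), "orthologPair or rate")
})
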