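test_that("makeReference hits the target composition and is reproducible", {
    g <- makeReference(1, c(chr1 = 200000L), gcFraction = 0.36)
    s <- as.character(genomeSeqs(g)[[1]])
    gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
    expect_gt(gc, 0.34)
    expect_lt(gc, 0.38)
    g2 <- makeReference(1, c(chr1 = 200000L), gcFraction = 0.36)
    expect_identical(as.character(genomeSeqs(g2)), as.character(genomeSeqs(g)))
    pure <- makeReference(2, c(chr1 = 1000L), gcFraction = 1)
    expect_match(as.character(genomeSeqs(pure)[[1]]), "^[GC]+$")
    expect_error(makeReference(1, c(chr1 = 500L)), "1 kb")
})

test_that("plantInsertion builds flank + TSD + element + TSD + flank", {
    g <- makeReference(3, c(chr1 = 5000L))
    te <- makeElement(4, 300L)
    src <- as.character(genomeSeqs(g)[[1]])

    plain <- plantInsertion(g, PlantedInsertion("chr1", 2000L, te))
    expect_equal(Biostrings::width(genomeSeqs(plain))[1], 5000L + 300L)

    ins <- PlantedInsertion("chr1", 2000L, te, tsdLength = 8L)
    der <- as.character(genomeSeqs(plantInsertion(g, ins))[[1]])
    tsd <- substring(src, 1993, 2000)            # bases [1992, 2000) 0-based
    expect_identical(substring(der, 1993, 2000), tsd)
    expect_identical(substring(der, 2001, 2300), te)
    expect_identical(substring(der, 2301, 2308), tsd)  # duplicated copy
    expect_identical(substring(der, 2309, 2400), substring(src, 2001, 2092))
    expect_equal(nchar(der), 5000 + 300 + 8)

    inv <- PlantedInsertion("chr1", 2000L, te, inverted = TRUE,
                            truncation = 50L)
    derInv <- as.character(genomeSeqs(plantInsertion(g, inv))[[1]])
    expected <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substring(te, 51))))
    expect_identical(substring(derInv, 2001, 2250), expected)

    expect_error(plantInsertion(g,
        PlantedInsertion("chr1", 5L, te, tsdLength = 10L)), "left flank")
})

test_that("simulateReadPairs delivers coverage, exact substrings, determinism", {
    g <- makeReference(5, c(chr1 = 100000L))
    rp <- simulateReadPairs(g, readLen = 150L, insertMean = 500,
                            insertSd = 50, coverage = 30, seed = 6)
    # coverage arithmetic: pairs = cov * L / (2 * readLen)
    expect_equal(length(rp$read1), 10000L)
    realized <- 2 * 150 * length(rp$read1) / 100000
    expect_lt(abs(realized - 30) / 30, 0.1)
    # error-free reads are exact substrings (mate 2 reverse-complemented)
    s <- as.character(genomeSeqs(g)[[1]])
    idx <- c(1L, 500L, 9999L)
    for (i in idx) {
        tr <- rp$truth[i, ]
        expect_identical(as.character(rp$read1[[i]]),
                         substring(s, tr$fragStart + 1, tr$fragStart + 150))
        expect_identical(as.character(Biostrings::reverseComplement(
                             rp$read2[[i]])),
                         substring(s, tr$fragEnd - 149, tr$fragEnd))
    }
    # outer distance is the fragment length, near the configured mean
    expect_lt(abs(mean(rp$truth$fragEnd - rp$truth$fragStart) - 500), 5)
    rp2 <- simulateReadPairs(g, readLen = 150L, insertMean = 500,
                             insertSd = 50, coverage = 30, seed = 6)
    expect_identical(as.character(rp2$read1), as.character(rp$read1))
    expect_error(simulateReadPairs(g, coverage = 0), "coverage")
    expect_error(simulateReadPairs(g, readLen = 300L, insertMean = 500),
                 "insertMean")
})

test_that("cytosineContexts matches a hand-worked example on both strands", {
    #         0123456789
    # plus:   CCGTACGGAC ; minus cytosines at plus-G positions
    g <- suppressWarnings(GenomeModel(c(chr1 = paste0(
        "CCGTACGGAC", randomSeq(990, seed = 1)))))
    cy <- cytosineContexts(g, "chr1", 0L, 10L)
    plus <- cy[cy$strand == "+", ]
    expect_identical(plus$pos[1:3], c(0L, 1L, 5L))
    expect_identical(plus$context[1:3], c("CHG", "CG", "CG"))
    minus <- cy[cy$strand == "-", ]
    # G at 2: downstream (leftwards) complement of "CC" -> GG -> context CG
    expect_identical(minus$context[minus$pos == 2L], "CG")
    # G at 7: left neighbours "CG" -> complement GC read 5'->3' = "CG"? no:
    # bases left of 7 are pos 6 = G, pos 5 = C -> complements C, G -> CHG
    expect_identical(minus$context[minus$pos == 7L], "CHG")
    # chromosome-end cytosines lacking context are skipped
    tail <- cytosineContexts(GenomeModel(c(c1 = "AAAAAAAACC")), "c1")
    expect_true(all(tail$pos + 2 < 10 | tail$strand == "-"))
})

test_that("bisulfite simulation respects state means and drops depth 0", {
    g <- makeReference(7, c(chr1 = 6000L))
    regions <- data.frame(chrom = "chr1", lo = c(0L, 3000L),
                          hi = c(2000L, 5000L),
                          state = c("unmethylated", "methylated"))
    cy <- simulateBisulfiteCalls(g, regions, depthMean = 50,
                                 conversionError = 0, seed = 8)
    expect_true(all(cy$count_total > 0L))
    expect_true(all(cy$count_methylated <= cy$count_total))
    un <- weightedLevel(cy, "chr1", 0L, 2000L)
    expect_lte(un$level, 0.05)
    me <- weightedLevel(cy, "chr1", 3000L, 5000L, "CG")
    expect_gt(me$level, 0.7)
    cy2 <- simulateBisulfiteCalls(g, regions, depthMean = 50,
                                  conversionError = 0, seed = 8)
    expect_identical(cy2, cy)
    expect_error(simulateBisulfiteCalls(g, regions, depthMean = 0), "depthMean")
})

test_that("F2 cross segregates 1:2:1 by genotype and 3:1 by dominant band", {
    cfg <- CrossConfig(data.frame(name = c("m1", "m2"), pos = c(0, 20)),
                       locusPos = 10, parentalStates = c("m", "u"))
    pop <- simulateCross(cfg, "F2", 8000L, seed = 9)
    gt <- locusGenotype(pop)
    freq <- table(gt) / length(gt)
    expect_lt(abs(freq[["mm"]] - 0.25), 0.02)
    expect_lt(abs(freq[["mu"]] - 0.50), 0.02)
    expect_lt(abs(freq[["uu"]] - 0.25), 0.02)
    band <- individuals(pop)$band
    expect_lt(abs(mean(band) - 0.75), 0.02)
    # each parental haplotype at 50% allele frequency at every marker
    af <- mean(c(individuals(pop)$m1.a, individuals(pop)$m1.b) == 1)
    expect_lt(abs(af - 0.5), 0.02)
    pop2 <- simulateCross(cfg, "F2", 8000L, seed = 9)
    expect_identical(individuals(pop2), individuals(pop))
    expect_error(simulateCross(cfg, "F2", 0L), "n must be")
})

test_that("epiallele states are stable in cis; ddm1 loss is irreversible", {
    # with epsilon = 0 there are zero state changes across 5 generations,
    # even in a ddm1 background: an all-methylated line stays methylated
    cfg0 <- CrossConfig(data.frame(name = "m1", pos = 0), locusPos = 5,
                        parentalStates = c("m", "m"), epsilon = 0)
    pop <- simulateCross(cfg0, "F2", 2000L, seed = 10, ddm1 = TRUE)
    for (i in 1:4) pop <- selfPopulation(pop, seed = 10 + i, ddm1 = TRUE)
    expect_true(all(individuals(pop)$locus.a == "m"))
    expect_true(all(individuals(pop)$locus.b == "m"))
    # with ddm1, the methylated-allele fraction decays ~ (1 - eps)^meioses
    cfgM <- CrossConfig(data.frame(name = "m1", pos = 0), locusPos = 5,
                        parentalStates = c("m", "m"), epsilon = 0.2)
    popM <- simulateCross(cfgM, "F1", 4000L, seed = 11, ddm1 = TRUE)
    fr1 <- mean(c(individuals(popM)$locus.a,
                  individuals(popM)$locus.b) == "m")
    expect_lt(abs(fr1 - 0.8), 0.03)               # one meiosis: 1 - eps
    popM2 <- selfPopulation(popM, seed = 12, ddm1 = TRUE)
    fr2 <- mean(c(individuals(popM2)$locus.a,
                  individuals(popM2)$locus.b) == "m")
    expect_lt(abs(fr2 - 0.64), 0.04)              # two meioses: (1 - eps)^2
})

test_that("cis inheritance without ddm1 never changes a state", {
    cfg <- CrossConfig(data.frame(name = "m1", pos = 0), locusPos = 5,
                       parentalStates = c("m", "u"), epsilon = 0.5)
    pop <- simulateCross(cfg, "F2", 500L, seed = 13, ddm1 = FALSE)
    # every allele must still carry a parental state; with parents m/u the
    # m alleles are exactly those inherited from parent 1 so frequencies
    # match Mendelian expectation
    m <- c(individuals(pop)$locus.a, individuals(pop)$locus.b)
    expect_true(all(m %in% c("m", "u")))
    expect_lt(abs(mean(m == "m") - 0.5), 0.07)
})

test_that("star evolution matches TN93 expectations", {
    anc <- makeElement(20, 3000L, gcFraction = 0.36)
    frozen <- evolveStar(anc, 5L, 0, 6.8e-9, seed = 21)
    expect_true(all(as.character(frozen$tips) == anc))

    ev <- evolveStar(anc, 50L, 5e5, 6.8e-9, seed = 22)
    tips <- as.character(ev$tips)
    dAnc <- mean(rawDivergence(tips, anc))
    expect_lt(abs(dAnc - 3.4e-3) / 3.4e-3, 0.15)   # E = rT
    D <- tn93DistanceMatrix(tips)
    expect_lt(abs(mean(D[upper.tri(D)]) - 6.8e-3) / 6.8e-3, 0.15)  # 2rT
    ev2 <- evolveStar(anc, 50L, 5e5, 6.8e-9, seed = 22)
    expect_identical(as.character(ev2$tips), tips)
    expect_error(evolveStar("", 5, 1, 1e-9), "zero-length")
})

test_that("long-time TN93 evolution converges to stationary frequencies", {
    anc <- paste(rep("A", 4000), collapse = "")   # far from stationarity
    prm <- TN93Params(freqs = c(A = 0.4, C = 0.1, G = 0.2, T = 0.3))
    ev <- evolveStar(anc, 4L, 1e10, 1e-8, params = prm, seed = 23)
    obs <- colMeans(Biostrings::alphabetFrequency(ev$tips)[, 1:4] / 4000)
    expect_lt(max(abs(obs - c(0.4, 0.1, 0.2, 0.3))), 0.02)
})

test_that("climate table has planted structure and multinomial group sizes", {
    tab <- simulateClimateTable(137L, bio9Effect = 0, seed = 24)
    expect_equal(nrow(tab), 137L)
    counts <- table(tab$group)
    expect_lt(abs(counts[["methylated"]] - 137 * 21 / 137), 15)
    expect_lt(abs(counts[["deletion"]] - 77), 18)
    # absent element -> methylation 0 by convention
    expect_true(all(tab$meth_total[tab$group == "deletion"] == 0))
    r <- spearmanAssoc(tab$meth_total, tab$bio9_present)
    expect_lt(abs(r$rho), 0.25)                    # null behaviour
    tab2 <- simulateClimateTable(137L, bio9Effect = 0, seed = 24)
    expect_identical(tab2, tab)
    expect_error(simulateClimateTable(10, groupProportions = c(0.5, 0.1)),
                 "sum to 1")
})
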