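# fixture shared across detection tests: one planted, truncated element
makeDetectionFixture <- function(seed, tsd = 7L, inverted = TRUE,
                                 coverage = 30, point = 30000L,
                                 genomeLen = 60000L) {
    g <- makeReference(seed, c(chr1 = genomeLen))
    te <- makeElement(seed + 1000L, 2500L)
    ins <- PlantedInsertion("chr1", point, te, inverted = inverted,
                            truncation = 500L, tsdLength = tsd)
    sample <- plantInsertion(g, ins)
    reads <- simulateReadPairs(sample, readLen = 100L, insertMean = 400,
                               insertSd = 40, coverage = coverage,
                               seed = seed + 2000L)
    teIns <- substring(te, 501L)
    if (inverted) teIns <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(teIns)))
    list(ref = g, sample = sample, te = te, teInserted = teIns,
         reads = reads, point = point, tsd = tsd, inverted = inverted)
}

test_that("naiveMap places unique reads and flags repeats and strands", {
    g <- GenomeModel(c(chr1 = paste0(randomSeq(300, seed = 1),
                                     randomSeq(100, seed = 2),
                                     randomSeq(300, seed = 3),
                                     randomSeq(100, seed = 2))))
    s <- as.character(genomeSeqs(g)[[1]])
    uniqueRead <- substring(s, 51, 100)
    repeatRead <- substring(s, 301, 350)           # occurs twice
    rcRead <- revcompOracle(substring(s, 151, 200))
    reads <- Biostrings::DNAStringSet(c("u/1" = uniqueRead,
                                        "r/1" = repeatRead,
                                        "c/1" = rcRead))
    al <- naiveMap(reads, g, Biostrings::DNAStringSet())
    u <- al[al$qname == "u", ]
    expect_equal(nrow(u), 1L)
    expect_equal(u$start, 50L)
    expect_true(u$unique)
    expect_identical(u$strand, "+")
    expect_false(any(al$unique[al$qname == "r"]))
    cc <- al[al$qname == "c", ]
    expect_identical(cc$strand[1], "-")
    expect_equal(cc$start[1], 150L)
    expect_error(naiveMap(reads, GenomeModel(Biostrings::DNAStringSet()),
                          Biostrings::DNAStringSet()), "non-empty|empty")
})

test_that("discordant pairs cluster per insertion; none without TE mates", {
    fx <- makeDetectionFixture(31)
    al <- naiveMap(fx$reads, fx$ref, c(TE = fx$te))
    cl <- findDiscordantPairs(al, "TE", 400, 40)
    expect_equal(length(cl), 1L)
    expect_setequal(unique(cl[[1]]$side), c("left", "right"))
    # anchors flank the planted point
    expect_true(any(cl[[1]]$end <= fx$point))
    expect_true(any(cl[[1]]$start >= fx$point - fx$tsd))
    # no TE-mapped mates at all -> empty
    expect_identical(findDiscordantPairs(al[!(al$ref == "TE"), ], "TE"),
                     list())
})

test_that("two insertions 100 kb apart give two clusters and two calls", {
    g <- makeReference(33, c(chr1 = 220000L))
    te <- makeElement(34, 2000L)
    s1 <- plantInsertion(g, PlantedInsertion("chr1", 50000L, te,
                                             tsdLength = 5L))
    s2 <- plantInsertion(s1, PlantedInsertion("chr1", 150000L, te,
                                              inverted = TRUE,
                                              tsdLength = 9L))
    reads <- simulateReadPairs(s2, readLen = 100L, insertMean = 400,
                               insertSd = 40, coverage = 30, seed = 35)
    det <- detectInsertions(reads, g, c(TE = te), 400, 40)
    expect_equal(length(det$calls), 2L)
    pts <- sort(vapply(det$calls, function(x) x@lo, integer(1)))
    expect_lt(abs(pts[1] - 50000), 400)
    # second call maps back to reference coordinates: planting happened at
    # 150000 of the once-derived genome, i.e. 150000 - 2005 of the reference
    expect_lt(abs(pts[2] - 147995), 400)
    ors <- vapply(det$calls, function(x) x@orientation, character(1))
    expect_setequal(ors, c("same", "inverted"))
})

test_that("callInsertion enforces min support and reports candidates", {
    fx <- makeDetectionFixture(36)
    al <- naiveMap(fx$reads, fx$ref, c(TE = fx$te))
    cl <- findDiscordantPairs(al, "TE", 400, 40)[[1]]
    thin <- rbind(cl[cl$side == "left", ][1:2, ], cl[cl$side == "right", ])
    res <- callInsertion(thin, 400, 40, minSupport = 3L)
    expect_s3_class(res, "TECandidate")
    expect_match(res$reason, "insufficient support")
    full <- callInsertion(cl, 400, 40, minSupport = 3L)
    expect_s4_class(full, "TEInsertionCall")
    expect_identical(full@orientation, "inverted")
    iv <- breakpointInterval(full)
    expect_lte(iv["lo"], fx$point)
    expect_gt(iv["hi"], fx$point)
    expect_lte(iv["hi"] - iv["lo"], 400)       # within one insert length
})

test_that("detectTSD is exact on planted junctions and matches brute force", {
    g <- makeReference(40, c(chr1 = 20000L))
    te <- makeElement(41, 600L)
    src <- as.character(genomeSeqs(g)[[1]])
    for (tsd in c(0L, 8L)) {
        ins <- PlantedInsertion("chr1", 9000L, te, tsdLength = tsd)
        der <- as.character(genomeSeqs(plantInsertion(g, ins))[[1]])
        refFlank <- substring(src, 8900, 9100)
        allele <- substring(der, 8900, 9800)
        got <- detectTSD(refFlank, allele, te)
        expect_equal(got$tsdLength, tsd)
        if (tsd > 0)
            expect_identical(got$tsdSeq, substring(src, 9000 - tsd + 1, 9000))
        else expect_identical(got$tsdSeq, "")
    }
    expect_error(detectTSD("ACGT", "ACGTACGT", "GGGGGGGG"), "not found")
    # brute-force all-substring oracle agreement for maxTsd <= 12
    for (rep in 1:20) {
        tsd <- sample(0:12, 1)
        p <- sample(5000:15000, 1)
        ins <- PlantedInsertion("chr1", p, te,
                                inverted = sample(c(TRUE, FALSE), 1),
                                tsdLength = tsd)
        der <- as.character(genomeSeqs(plantInsertion(g, ins))[[1]])
        refFlank <- substring(src, p - 80, p + 80)
        allele <- substring(der, p - 80, p + 600 + 160)
        got <- detectTSD(refFlank, allele,
                         if (ins@inverted) revcompOracle(te) else te,
                         maxTsd = 12L)
        want <- oracleTSD(refFlank, allele,
                          if (ins@inverted) revcompOracle(te) else te,
                          maxTsd = 12L)
        expect_equal(got$tsdLength, want$tsdLength)
        expect_identical(got$tsdSeq, want$tsdSeq)
    }
})

test_that("planted TSD lengths 0..30 are recovered exactly (property)", {
    g <- makeReference(42, c(chr1 = 30000L))
    te <- makeElement(43, 800L)
    src <- as.character(genomeSeqs(g)[[1]])
    for (tsd in 0:30) {
        p <- 10000L + 17L * tsd
        ins <- PlantedInsertion("chr1", p, te, tsdLength = as.integer(tsd))
        der <- as.character(genomeSeqs(plantInsertion(g, ins))[[1]])
        got <- detectTSD(substring(src, p - 100, p + 100),
                         substring(der, p - 100, p + 800 + 200), te)
        expect_equal(got$tsdLength, tsd)
    }
})

test_that("breakpoint interval contains the planted point across seeds", {
    for (seed in c(50, 51, 52)) {
        fx <- makeDetectionFixture(seed, tsd = sample(c(0L, 5L, 7L, 15L), 1),
                                   inverted = seed %% 2 == 0)
        det <- detectInsertions(fx$reads, fx$ref, c(TE = fx$te), 400, 40)
        expect_equal(length(det$calls), 1L)
        call <- det$calls[[1]]
        expect_lte(call@lo, fx$point)
        expect_gt(call@hi, fx$point)
        expect_identical(call@orientation,
                         if (fx$inverted) "inverted" else "same")
    }
})
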