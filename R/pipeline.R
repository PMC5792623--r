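# End-to-end orchestration of the synthetic study: one config, one seed,
# deterministic stage sub-seeds, provenance headers on every output.

PIPELINE_STAGES <- c("simulate", "detect-te", "methylation", "segregate",
                     "map-locus", "cosegregate", "date-insertion", "climate")

#' Default demonstration configuration
#'
#' A compact fully synthetic study: a 60 kb reference, a 2.5 kb truncated
#' inverted element planted with a 7 bp TSD, 30x 100 bp paired-end reads,
#' bisulfite calls over the element and a control flank, a 2,000-plant F2
#' with markers spanning the epiallele locus, a 20-copy star alignment for
#' dating, and a 137-accession climate table with a planted bio9 effect.
#'
#' @param seed global seed; every stochastic stage derives its own sub-seed
#'   from it deterministically.
#' @return a named list accepted by \code{\link{runPipeline}}.
#' @export
demoConfig <- function(seed = 1L) {
    list(
        seed = seed,
        stages = PIPELINE_STAGES,
        genome = list(chromLength = 60000L, gc = 0.36),
        te = list(length = 2500L, gc = 0.33),
        insertion = list(point = 30000L, tsdLength = 7L, inverted = TRUE,
                         truncation = 500L),
        reads = list(readLen = 100L, insertMean = 400, insertSd = 40,
                     coverage = 30, errorRate = 0),
        detect = list(minSupport = 3L, maxTsd = 30L),
        bisulfite = list(depthMean = 30, conversionError = 0.005),
        cross = list(n = 2000L, markerSpacing = 2, nMarkers = 11L,
                     epsilon = 0),
        dating = list(nTips = 20L, length = 1500L, rate = 6.8e-9,
                      ageYears = 5e5, tDivRange = c(3.5e6, 5.8e6)),
        climate = list(n = 137L, bio9Effect = 1, alpha = 0.05)
    )
}

validateConfig <- function(config) {
    required <- c("seed", "stages", "genome", "te", "insertion", "reads",
                  "detect", "bisulfite", "cross", "dating", "climate")
    missing <- setdiff(required, names(config))
    if (length(missing))
        stop("config is missing field: ", missing[1], call. = FALSE)
    bad <- setdiff(config$stages, PIPELINE_STAGES)
    if (length(bad))
        stop("unknown stage name in field 'stages': ", bad[1],
             call. = FALSE)
    invisible(config)
}

provenanceHeader <- function(config, stage) {
    cfgFile <- tempfile()
    yaml::write_yaml(config, cfgFile)
    hash <- unname(tools::md5sum(cfgFile))
    unlink(cfgFile)
    c(sprintf("epiline %s | stage %s",
              as.character(utils::packageVersion("epiline")), stage),
      sprintf("seed %d | config md5 %s", config$seed, hash))
}

#' Run the synthetic study end-to-end
#'
#' Executes the selected stages in dependency order on fully synthetic
#' inputs with known truth: genome + planted insertion simulation, TE
#' detection with TSD calling, methylation quantification, segregation
#' testing, recombinant-count locus mapping, co-segregation summaries,
#' insertion dating, and the climate scan. Every output file starts with a
#' provenance header (package version, stage, seed, config hash), and the
#' whole run is deterministic given the config.
#'
#' @param config a config list (see \code{\link{demoConfig}}) or the path
#'   of a YAML file holding one.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list of per-stage results (also written to
#'   \code{outDir}).
#' @export
runPipeline <- function(config = demoConfig(), outDir = tempfile("run")) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    validateConfig(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seed <- config$seed
    res <- list()

    ## -- simulate ---------------------------------------------------------
    ref <- makeReference(deriveSeed(seed, "reference"),
                         c(chr1 = config$genome$chromLength),
                         config$genome$gc)
    te <- makeElement(deriveSeed(seed, "element"), config$te$length,
                      config$te$gc)
    ins <- PlantedInsertion("chr1", config$insertion$point, te,
                            inverted = isTRUE(config$insertion$inverted),
                            truncation = config$insertion$truncation,
                            tsdLength = config$insertion$tsdLength)
    sampleGenome <- plantInsertion(ref, ins)
    reads <- simulateReadPairs(sampleGenome, config$reads$readLen,
        config$reads$insertMean, config$reads$insertSd,
        config$reads$coverage, config$reads$errorRate,
        seed = deriveSeed(seed, "reads"))
    if ("simulate" %in% config$stages) {
        writeFasta(genomeSeqs(ref), file.path(outDir, "reference.fasta"))
        writeFasta(stats::setNames(Biostrings::DNAStringSet(te), "TE"),
                   file.path(outDir, "element.fasta"))
        writeReadPairsFastq(reads, file.path(outDir, "reads"))
        writeTsv(reads$truth, file.path(outDir, "read_truth.tsv"),
                 provenanceHeader(config, "simulate"))
        res$simulate <- list(genome = ref, sample = sampleGenome, reads = reads)
    }

    ## -- detect-te --------------------------------------------------------
    if ("detect-te" %in% config$stages) {
        det <- detectInsertions(reads, ref,
            stats::setNames(c(TE = te), "TE"),
            config$reads$insertMean, config$reads$insertSd,
            config$detect$minSupport, config$detect$maxTsd)
        # TSD from the local insertion-allele sequence around the call
        teIns <- as.character(ins@teSeq)
        teIns <- substring(teIns, ins@truncation + 1L)
        if (ins@inverted) teIns <- revcompChar(teIns)
        for (i in seq_along(det$calls)) {
            call <- det$calls[[i]]
            pad <- config$detect$maxTsd + 20L
            refFlank <- subseq0(genomeSeqs(ref), call@chrom,
                max(call@lo - pad, 0L),
                min(call@hi + pad,
                    nchar(as.character(genomeSeqs(ref)[[call@chrom]]))))
            alleleLo <- max(call@lo - pad, 0L)
            alleleHi <- min(call@hi + nchar(teIns) + pad + 60L,
                nchar(as.character(genomeSeqs(sampleGenome)[[call@chrom]])))
            allele <- subseq0(genomeSeqs(sampleGenome), call@chrom, alleleLo,
                              alleleHi)
            tsd <- detectTSD(refFlank, allele, teIns, config$detect$maxTsd)
            call@tsdLength <- as.integer(tsd$tsdLength)
            call@tsdSeq <- tsd$tsdSeq
            det$calls[[i]] <- call
        }
        writeBedlike(det$calls, file.path(outDir, "insertions.tsv"),
                     provenanceHeader(config, "detect-te"))
        res$detect <- det
    }

    ## -- methylation ------------------------------------------------------
    if ("methylation" %in% config$stages) {
        p <- config$insertion$point
        teLen <- config$te$length - config$insertion$truncation
        regions <- data.frame(
            chrom = "chr1",
            lo = c(p, p - 5000L),
            hi = c(p + teLen, p - 1000L),
            state = c("methylated", "unmethylated"))
        cyto <- simulateBisulfiteCalls(sampleGenome, regions,
            config$bisulfite$depthMean, config$bisulfite$conversionError,
            seed = deriveSeed(seed, "bisulfite"))
        meth <- rbind(regionMethylation(cyto, "chr1", p, p + teLen),
                      regionMethylation(cyto, "chr1", p - 5000L, p - 1000L))
        meth$state <- regions$state
        writeCytosineTsv(cyto, file.path(outDir, "cytosines.tsv"),
                         provenanceHeader(config, "methylation"))
        writeTsv(meth, file.path(outDir, "region_methylation.tsv"),
                 provenanceHeader(config, "methylation"))
        res$methylation <- meth
    }

    ## -- cross-based stages -----------------------------------------------
    needCross <- any(c("segregate", "map-locus", "cosegregate") %in%
                     config$stages)
    if (needCross) {
        sp <- config$cross$markerSpacing
        nm <- config$cross$nMarkers
        markers <- data.frame(
            name = sprintf("mk%02d", seq_len(nm)),
            pos = seq(0, by = sp, length.out = nm))
        cfg <- CrossConfig(markers, locusPos = sp * (nm - 1) / 2 + 0.9,
                           parentalStates = c("m", "u"),
                           epsilon = config$cross$epsilon)
        pop <- simulateCross(cfg, "F2", config$cross$n,
                             seed = deriveSeed(seed, "cross"))
    }
    if ("segregate" %in% config$stages) {
        counts <- c(sum(individuals(pop)$band), sum(!individuals(pop)$band))
        seg <- segregationTest(counts, c(3, 1))
        writeTsv(data.frame(class = c("band", "no_band"),
                            observed = seg$observed,
                            expected = seg$expected,
                            chisq = seg$chisq, df = seg$df, p = seg$p),
                 file.path(outDir, "segregation.tsv"),
                 provenanceHeader(config, "segregate"))
        res$segregation <- seg
    }
    if ("map-locus" %in% config$stages) {
        lt <- linkageTable(pop)
        loc <- mapLocus(lt)
        writeTsv(lt, file.path(outDir, "linkage.tsv"),
                 provenanceHeader(config, "map-locus"))
        res$mapping <- list(linkage = lt, locus = loc)
    }
    if ("cosegregate" %in% config$stages) {
        set.seed(deriveSeed(seed, "cosegregate"))
        gt <- locusGenotype(pop)
        nMeth <- (gt == "mm") + 0.5 * (gt == "mu")
        expr <- pmax(stats::rnorm(length(gt), 1.4, 0.15) - 1.0 * nMeth, 0)
        chl <- pmax(stats::rnorm(length(gt), 0.45, 0.08) + 0.6 * nMeth, 0)
        cs <- cosegregationSummary(gt, expression = expr, chlorophyll = chl)
        writeTsv(cs$summary, file.path(outDir, "cosegregation.tsv"),
                 provenanceHeader(config, "cosegregate"))
        res$cosegregation <- cs
    }

    ## -- date-insertion ---------------------------------------------------
    if ("date-insertion" %in% config$stages) {
        dc <- config$dating
        anc <- makeElement(deriveSeed(seed, "ancestor"), dc$length, 0.36)
        ev <- evolveStar(anc, dc$nTips, dc$ageYears, dc$rate,
                         seed = deriveSeed(seed, "evolve"))
        # ortholog pair for calibration: two lineages split at the
        # midpoint of the species divergence range
        orth <- evolveStar(makeElement(deriveSeed(seed, "orthanc"),
                                       dc$length, 0.36),
                           2L, mean(dc$tDivRange), dc$rate,
                           seed = deriveSeed(seed, "ortholog"))
        dating <- dateInsertion(as.character(ev$tips),
                                orthologPair = as.character(orth$tips),
                                tDivRange = dc$tDivRange)
        writeTsv(data.frame(rate = dating@rate,
                            mean_pairwise = dating@meanPairwise,
                            mean_ancestral = dating@meanAncestral,
                            t_star = dating@tStar, t_mrca = dating@tMrca,
                            t_div_used = dating@tDivUsed,
                            n_seqs = dating@nSeqs),
                 file.path(outDir, "dating.tsv"),
                 provenanceHeader(config, "date-insertion"))
        D <- tn93DistanceMatrix(as.character(ev$tips))
        writeNewick(njTree(D), file.path(outDir, "copies.nwk"))
        res$dating <- dating
    }

    ## -- climate ----------------------------------------------------------
    if ("climate" %in% config$stages) {
        tab <- simulateClimateTable(config$climate$n,
            bio9Effect = config$climate$bio9Effect,
            seed = deriveSeed(seed, "climate"))
        grp <- assignGroups(tab)
        scan <- climateScan(grp$table, alpha = config$climate$alpha)
        writeTsv(scan$results, file.path(outDir, "climate_scan.tsv"),
                 provenanceHeader(config, "climate"))
        res$climate <- list(counts = grp$counts, scan = scan)
    }
    invisible(res)
}
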