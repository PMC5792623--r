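# Segregation tests, recombinant-count linkage mapping with methylation as
# the phenotype, and co-segregation summaries.

#' Chi-square segregation test against an expected ratio
#'
#' Pearson goodness-of-fit test of observed phenotype-class counts against
#' an expected ratio (e.g. 3:1 for a dominant band in an F2), without
#' continuity correction by default: the mapping populations this targets
#' are large. df = classes - 1.
#'
#' @param observed integer vector of class counts (total > 0).
#' @param expectedRatio positive weights, e.g. \code{c(3, 1)}.
#' @param yates apply the Yates correction (|O-E| - 0.5); default FALSE.
#' @return list: observed, expected, chisq, df, p.
#' @export
segregationTest <- function(observed, expectedRatio = c(3, 1),
                            yates = FALSE) {
    if (sum(observed) <= 0) stop("total count must be > 0")
    if (any(expectedRatio <= 0)) stop("expected class proportions must be > 0")
    if (length(observed) != length(expectedRatio))
        stop("observed and expectedRatio lengths differ")
    p <- expectedRatio / sum(expectedRatio)
    expected <- sum(observed) * p
    dev <- abs(observed - expected)
    if (yates) dev <- pmax(dev - 0.5, 0)
    chisq <- sum(dev^2 / expected)
    df <- length(observed) - 1L
    list(observed = observed, expected = expected, chisq = chisq, df = df,
         p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Count recombinant chromosomes at a marker among selected plants
#'
#' Recessive-selection mapping: individuals are pre-filtered to the
#' recessive phenotype class (both epiallele copies from the unmethylated
#' parent), so every one of their 2n chromosomes should carry the
#' unmethylated parent's marker allele under complete linkage. Each marker
#' allele inherited from the other (methylated) parent is one recombinant
#' chromosome. Individuals with a missing marker genotype are skipped.
#'
#' @param population a \linkS4class{CrossPopulation} (F2).
#' @param marker marker name.
#' @param selectedPhenotype phenotype used for selection; default
#'   "unmethylated" (band-absent class).
#' @return list: marker, pos, recombinants, chromosomes (2n), nSelected,
#'   nSkipped.
#' @export
countRecombinants <- function(population, marker,
                              selectedPhenotype = "unmethylated") {
    stopifnot(is(population, "CrossPopulation"))
    df <- population@individuals
    cfg <- population@config
    sel <- if (selectedPhenotype == "unmethylated") !df$band else df$band
    df <- df[sel, , drop = FALSE]
    ca <- df[[paste0(marker, ".a")]]
    cb <- df[[paste0(marker, ".b")]]
    if (is.null(ca)) stop("unknown marker: ", marker)
    ok <- !is.na(ca) & !is.na(cb)
    nSkipped <- sum(!ok)
    if (nSkipped > 0L)
        message(nSkipped, " individual(s) skipped for missing genotype at ",
                marker)
    ca <- ca[ok]; cb <- cb[ok]
    # the "wrong" parental allele: the one carried by the methylated parent
    wrong <- which(cfg@parentalStates == "m")
    rec <- sum(ca == wrong) + sum(cb == wrong)
    pos <- cfg@markers$pos[match(marker, cfg@markers$name)]
    list(marker = marker, pos = pos, recombinants = rec,
         chromosomes = 2L * sum(ok), nSelected = sum(ok),
         nSkipped = nSkipped)
}

#' Recombinant counts for every marker of a population
#'
#' @inheritParams countRecombinants
#' @return data.frame: marker, pos, recombinants, chromosomes.
#' @export
linkageTable <- function(population, selectedPhenotype = "unmethylated") {
    mk <- population@config@markers
    res <- lapply(mk$name, function(m)
        countRecombinants(population, m, selectedPhenotype))
    data.frame(marker = vapply(res, `[[`, character(1), "marker"),
               pos = vapply(res, `[[`, numeric(1), "pos"),
               recombinants = vapply(res, `[[`, numeric(1), "recombinants"),
               chromosomes = vapply(res, `[[`, numeric(1), "chromosomes"))
}

#' Localise a locus from a recombinant-count table
#'
#' Point estimate: the marker with the minimum recombinant count. Interval:
#' the nearest flanking markers with strictly more recombinants; ties on the
#' minimum widen the interval, and a monotone run to either end leaves that
#' side unbounded (flagged).
#'
#' @param linkage data.frame with columns marker, pos, recombinants (>= 3
#'   markers, sorted or sortable by pos).
#' @return list: marker (point estimate), pos, lo, hi (interval positions,
#'   -Inf/Inf when unbounded), loMarker, hiMarker, flagged, note.
#' @export
mapLocus <- function(linkage) {
    if (nrow(linkage) < 3L) stop("need >= 3 markers")
    linkage <- linkage[order(linkage$pos), , drop = FALSE]
    rec <- linkage$recombinants
    if (length(unique(rec)) == 1L)
        return(list(marker = NA_character_, pos = NA_real_,
                    lo = -Inf, hi = Inf, loMarker = NA, hiMarker = NA,
                    flagged = TRUE,
                    note = "all markers have equal counts; whole span"))
    minRec <- min(rec)
    hits <- which(rec == minRec)
    first <- hits[1]; last <- hits[length(hits)]
    below <- which(rec > minRec & seq_along(rec) < first)
    above <- which(rec > minRec & seq_along(rec) > last)
    lo <- if (length(below)) linkage$pos[max(below)] else -Inf
    hi <- if (length(above)) linkage$pos[min(above)] else Inf
    flagged <- !is.finite(lo) || !is.finite(hi)
    mid <- hits[ceiling(length(hits) / 2)]
    list(marker = linkage$marker[mid], pos = linkage$pos[mid],
         lo = lo, hi = hi,
         loMarker = if (is.finite(lo)) linkage$marker[max(below)] else NA,
         hiMarker = if (is.finite(hi)) linkage$marker[min(above)] else NA,
         flagged = flagged,
         note = if (flagged) "interval unbounded on one side" else "")
}

#' Co-segregation summary with Welch t-tests
#'
#' Groups same-plant measurements by Chop-PCR epiallele genotype (mm/mu/uu)
#' and, for each measurement, reports group means with standard errors and
#' a two-tailed Welch (unequal-variance) t-test between the two homozygous
#' classes. Groups with a single plant yield means only.
#'
#' @param genotype character vector ("mm", "mu", "uu"), one per plant.
#' @param ... named numeric vectors of per-plant measurements (e.g.
#'   \code{expression = }, \code{chlorophyll = }).
#' @return list with \code{summary} (data.frame genotype x measurement
#'   means/sem/n) and \code{tests} (data.frame measurement, t, df, p for
#'   mm vs uu; NA when a class has < 2 plants).
#' @export
cosegregationSummary <- function(genotype, ...) {
    meas <- list(...)
    stopifnot(length(meas) >= 1L, !is.null(names(meas)))
    genotype <- factor(genotype, levels = c("mm", "mu", "uu"))
    sem <- function(x) stats::sd(x) / sqrt(length(x))
    rows <- list(); tests <- list()
    for (nm in names(meas)) {
        v <- meas[[nm]]
        for (g in levels(genotype)) {
            x <- v[genotype == g & !is.na(genotype)]
            if (!length(x)) next
            rows[[length(rows) + 1L]] <- data.frame(
                measurement = nm, genotype = g, n = length(x),
                mean = mean(x), sem = if (length(x) > 1) sem(x) else NA_real_)
        }
        a <- v[genotype == "mm" & !is.na(genotype)]
        b <- v[genotype == "uu" & !is.na(genotype)]
        if (length(a) >= 2L && length(b) >= 2L) {
            if (stats::sd(a) == 0 && stats::sd(b) == 0 &&
                mean(a) == mean(b)) {
                tt <- list(statistic = 0, parameter = length(a) +
                           length(b) - 2, p.value = 1)
            } else tt <- stats::t.test(a, b)
            tests[[length(tests) + 1L]] <- data.frame(
                measurement = nm, t = unname(tt$statistic),
                df = unname(tt$parameter), p = tt$p.value)
        } else {
            tests[[length(tests) + 1L]] <- data.frame(
                measurement = nm, t = NA_real_, df = NA_real_, p = NA_real_)
        }
    }
    list(summary = do.call(rbind, rows), tests = do.call(rbind, tests))
}

#' Epiallele genotype of simulated individuals
#'
#' @param population a \linkS4class{CrossPopulation}.
#' @return character vector "mm"/"mu"/"uu" per individual.
#' @export
locusGenotype <- function(population) {
    df <- population@individuals
    nm <- (df$locus.a == "m") + (df$locus.b == "m")
    c("uu", "mu", "mm")[nm + 1L]
}
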