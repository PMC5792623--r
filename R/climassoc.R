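# Grouping of accessions by epiallele status and association of
# methylation, expression and senescence phenotypes with bioclimatic
# variables at two epochs.

#' Assign accessions to methylated / unmethylated / deletion groups
#'
#' Groups either from an existing \code{group} column, from an epiallele
#' \code{category} column (as produced by \code{\link{classifyAccession}};
#' NMR19-4m and NMR19-4m/16m count as methylated, NMR19-4u as unmethylated,
#' everything without the 4.45 Mb element as deletion), or from
#' \code{presence4} + \code{meth_CG} columns.
#'
#' @param table accession data.frame.
#' @param methThreshold CG-level threshold when deriving status from levels.
#' @return list: table (with a \code{group} factor column), counts (named
#'   integer vector; always partitions the table).
#' @export
assignGroups <- function(table, methThreshold = 0.2) {
    lv <- c("methylated", "unmethylated", "deletion")
    if (!is.null(table$group)) {
        grp <- as.character(table$group)
    } else if (!is.null(table$category)) {
        grp <- ifelse(table$category %in% c("NMR19-4m", "NMR19-4m/16m"),
                      "methylated",
               ifelse(table$category == "NMR19-4u", "unmethylated",
                      "deletion"))
    } else if (!is.null(table$presence4)) {
        grp <- ifelse(!table$presence4, "deletion",
               ifelse(!is.na(table$meth_CG) &
                          table$meth_CG >= methThreshold,
                      "methylated", "unmethylated"))
    } else stop("need a group, category or presence4 column")
    if (!all(grp %in% lv)) stop("unknown category in table")
    table$group <- factor(grp, levels = lv)
    counts <- table(table$group)
    list(table = table, counts = stats::setNames(as.integer(counts), lv))
}

#' Spearman rank correlation with exact small-sample p
#'
#' rho is computed on average (tie-adjusted) ranks. The p-value uses the
#' exact permutation null for n <= 10 without ties, and the t
#' approximation otherwise. Missing values are removed pairwise; constant
#' input is undefined.
#'
#' @param x,y numeric vectors.
#' @return list: rho, p, n, defined.
#' @export
spearmanAssoc <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 4L) stop("need n >= 4 after pairwise deletion")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(list(rho = NA_real_, p = NA_real_, n = n, defined = FALSE))
    ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
        exact = (n <= 10L && !ties)))
    list(rho = unname(ct$estimate), p = min(ct$p.value, 1), n = n,
         defined = TRUE)
}

#' Wilcoxon test between two groups or paired epochs
#'
#' Rank-sum (unpaired) or signed-rank (paired) Wilcoxon test, two-sided:
#' exact null when the combined sample is <= 20 and untied, normal
#' approximation (tie-corrected, no continuity correction) otherwise.
#' All-zero paired differences are degenerate: p = 1.
#'
#' @param values numeric vector (unpaired mode) or first member of each
#'   pair (paired mode).
#' @param groups two-level factor/character (unpaired mode), or the second
#'   member of each pair (paired mode).
#' @param paired logical; default FALSE.
#' @return list: p, statistic, method, degenerate.
#' @export
wilcoxonGroups <- function(values, groups, paired = FALSE) {
    if (paired) {
        y <- as.numeric(groups)
        stopifnot(length(values) == length(y))
        d <- values - y
        d <- d[!is.na(d)]
        if (!length(d)) stop("no complete pairs")
        if (all(d == 0))
            return(list(p = 1, statistic = NA_real_,
                        method = "signed-rank", degenerate = TRUE))
        exact <- length(d) <= 20L && !anyDuplicated(abs(d[d != 0])) &&
            all(d != 0)
        wt <- suppressWarnings(stats::wilcox.test(values, y, paired = TRUE,
            exact = exact, correct = FALSE))
        return(list(p = wt$p.value, statistic = unname(wt$statistic),
                    method = "signed-rank", degenerate = FALSE))
    }
    g <- factor(groups)
    if (nlevels(g) != 2L) stop("need exactly two groups")
    a <- values[g == levels(g)[1]]
    b <- values[g == levels(g)[2]]
    if (!length(a) || !length(b)) stop("group of size 0")
    if (length(unique(c(a, b))) == 1L)
        return(list(p = 1, statistic = length(a) * length(b) / 2,
                    method = "rank-sum", degenerate = TRUE))
    exact <- (length(a) + length(b)) <= 20L && !anyDuplicated(c(a, b))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = FALSE))
    list(p = wt$p.value, statistic = unname(wt$statistic),
         method = "rank-sum", degenerate = FALSE)
}

#' Scan 19 bioclimatic variables at two epochs for associations
#'
#' Computes the Spearman correlation of each phenotype (total methylation,
#' the three context levels, PPH expression, chlorophyll) against each of
#' the 19 bioclim variables at each epoch (present, LIG). A variable counts
#' as associated in an epoch when the total-methylation correlation has
#' raw p < alpha (no multiple-testing correction, mirroring how such scans
#' are usually reported; Benjamini-Hochberg is available via
#' \code{adjust = "BH"}, applied per epoch).
#'
#' @param table accession table as from \code{\link{simulateClimateTable}}
#'   (methylation set to 0 where the element is absent).
#' @param alpha significance level; default 0.05.
#' @param adjust "none" (default) or "BH".
#' @param phenotypes phenotype columns to scan; default all of meth_total,
#'   meth_CG, meth_CHG, meth_CHH, pph, chl that are present.
#' @return list: results (data.frame phenotype, variable, epoch, rho, p, n,
#'   significant), significantCounts (per-epoch count of associated
#'   variables), alpha.
#' @export
climateScan <- function(table, alpha = 0.05, adjust = c("none", "BH"),
                        phenotypes = NULL) {
    adjust <- match.arg(adjust)
    phen <- c("meth_total", "meth_CG", "meth_CHG", "meth_CHH", "pph", "chl")
    if (!is.null(phenotypes)) phen <- phenotypes
    phen <- phen[phen %in% names(table)]
    if (!length(phen)) stop("no phenotype columns found")
    rows <- list()
    for (epoch in c("present", "LIG")) {
        for (b in 1:19) {
            v <- table[[paste0("bio", b, "_", epoch)]]
            if (is.null(v)) stop("missing column bio", b, "_", epoch)
            for (ph in phen) {
                res <- spearmanAssoc(table[[ph]], v)
                rows[[length(rows) + 1L]] <- data.frame(
                    phenotype = ph, variable = paste0("bio", b),
                    epoch = epoch, rho = res$rho, p = res$p, n = res$n)
            }
        }
    }
    out <- do.call(rbind, rows)
    if (adjust == "BH") {
        for (epoch in c("present", "LIG")) {
            sel <- out$epoch == epoch
            out$p.adj[sel] <- stats::p.adjust(out$p[sel], "BH")
        }
        pUse <- out$p.adj
    } else pUse <- out$p
    out$significant <- !is.na(pUse) & pUse < alpha
    keyPhen <- if ("meth_total" %in% phen) "meth_total" else phen[1]
    tot <- out[out$phenotype == keyPhen, ]
    counts <- vapply(c(present = "present", LIG = "LIG"), function(ep)
        sum(tot$significant[tot$epoch == ep]), integer(1))
    list(results = out, significantCounts = counts, alpha = alpha)
}
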