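#' @importFrom stats pt t.test var setNames quantile
NULL

.CONDITIONS <- c("control", "A", "B", "AB")

#' Read a dual-luciferase reporter table
#'
#' @param path TSV with header columns construct, condition, replicate,
#'   firefly, renilla; conditions must be control, A, B, AB.
#' @return validated data.frame.
#' @export
readReporterTable <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
        stringsAsFactors = FALSE)
    need <- c("construct", "condition", "replicate", "firefly", "renilla")
    if (!all(need %in% names(tab)))
        stop("reporter table must have columns: ",
            paste(need, collapse = ", "))
    if (!all(tab$condition %in% .CONDITIONS))
        stop("conditions must be among: ",
            paste(.CONDITIONS, collapse = ", "))
    tab[need]
}

#' Normalise dual-luciferase readings
#'
#' Per well, the firefly/renilla ratio; per construct, each ratio divided by
#' the mean control ratio, so the control condition has mean relative output
#' 1 by construction.
#'
#' @param table reporter data.frame (see [readReporterTable()]).
#' @return the table with added columns `ratio` and `relative`.
#' @export
normalizeReporter <- function(table) {
    if (any(table$renilla <= 0))
        stop("renilla readings must be positive")
    if (any(table$firefly <= 0))
        stop("firefly readings must be positive")
    table$ratio <- table$firefly / table$renilla
    table$relative <- NA_real_
    for (cst in unique(table$construct)) {
        rows <- table$construct == cst
        ctrl <- table$ratio[rows & table$condition == "control"]
        if (!length(ctrl))
            stop("no control condition for construct ", cst)
        table$relative[rows] <- table$ratio[rows] / mean(ctrl)
    }
    table
}

# delta-method variance/df of AB - A - B (ratio scale) divided by control mean
.deltaSynergy <- function(tab) {
    g <- split(tab$ratio, factor(tab$condition, .CONDITIONS))
    n <- vapply(g, length, 1L)
    mns <- vapply(g, mean, 1)
    vs <- vapply(g, stats::var, 1)
    cbar <- mns[["control"]]
    D <- mns[["AB"]] - mns[["A"]] - mns[["B"]]
    excess <- D / cbar + 1
    # variance components of g = D / cbar + 1
    comp <- c(vs[["AB"]] / n[["AB"]], vs[["A"]] / n[["A"]],
        vs[["B"]] / n[["B"]]) / cbar^2
    compC <- D^2 * vs[["control"]] / n[["control"]] / cbar^4
    V <- sum(comp) + compC
    dfDen <- sum(comp^2 / (n[c("AB", "A", "B")] - 1)) +
        compC^2 / (n[["control"]] - 1)
    df <- if (dfDen > 0) V^2 / dfDen else Inf
    tstat <- if (V > 0) excess / sqrt(V) else
        if (excess > 0) Inf else if (excess < 0) -Inf else 0
    list(excess = excess, statistic = tstat, df = df,
        p = stats::pt(tstat, df, lower.tail = FALSE))
}

#' Test reporter output for synergy (super-additivity)
#'
#' On the control-normalised scale the additive expectation for the combined
#' condition is \code{mean(A) + mean(B) - 1} (the shared baseline subtracted
#' once); synergy is a significant positive excess of \code{mean(AB)} over
#' that expectation.  The default delta method forms a Welch-type t statistic
#' with variance propagated from the AB, A, B and control replicate means and
#' Welch-Satterthwaite degrees of freedom; the bootstrap alternative
#' resamples replicates within each condition and reports the fraction of
#' resampled excesses at or below zero.
#'
#' @param table a normalised reporter data.frame (see [normalizeReporter()];
#'   an un-normalised table is normalised on the fly).
#' @param construct which construct to test (default: each in turn).
#' @param method \code{"delta"} or \code{"bootstrap"}.
#' @param nBoot bootstrap resamples (>= 1000; default 10000).
#' @param seed RNG seed for the bootstrap.
#' @param comparisons also attach the pairwise Welch tests of
#'   [conditionComparisons()].
#' @return a [SynergyStat-class], or a named list of them when several
#'   constructs are present.
#' @export
synergyTest <- function(table, construct = NULL, method = c("delta",
        "bootstrap"), nBoot = 10000L, seed = 1L, comparisons = TRUE) {
    method <- match.arg(method)
    if (is.null(table$relative))
        table <- normalizeReporter(table)
    if (is.null(construct)) {
        csts <- unique(table$construct)
        if (length(csts) > 1L) {
            res <- lapply(csts, function(cst) synergyTest(table, cst,
                method = method, nBoot = nBoot, seed = seed,
                comparisons = comparisons))
            return(stats::setNames(res, csts))
        }
        construct <- csts
    }
    tab <- table[table$construct == construct, , drop = FALSE]
    missing <- setdiff(.CONDITIONS, tab$condition)
    if (length(missing))
        stop("construct ", construct, " lacks condition(s): ",
            paste(missing, collapse = ", "))
    nRep <- table(factor(tab$condition, .CONDITIONS))
    if (any(nRep < 2L))
        stop("need >= 2 replicates per condition for construct ", construct)
    relMeans <- vapply(split(tab$relative, factor(tab$condition,
        .CONDITIONS)), mean, 1)
    expectedAdd <- relMeans[["A"]] + relMeans[["B"]] - 1
    if (method == "delta") {
        d <- .deltaSynergy(tab)
        stat <- d$statistic; df <- d$df; p <- d$p
        excess <- relMeans[["AB"]] - expectedAdd
    } else {
        nBoot <- assertCount(nBoot, "nBoot", min = 1000L)
        set.seed(as.integer(seed))
        g <- split(tab$ratio, factor(tab$condition, .CONDITIONS))
        boots <- vapply(seq_len(nBoot), function(i) {
            m <- vapply(g, function(x)
                mean(x[sample.int(length(x), replace = TRUE)]), 1)
            (m[["AB"]] - m[["A"]] - m[["B"]]) / m[["control"]] + 1
        }, numeric(1))
        excess <- relMeans[["AB"]] - expectedAdd
        p <- (1 + sum(boots <= 0)) / (1 + nBoot)
        stat <- NA_real_; df <- NA_real_
    }
    cmp <- if (comparisons) conditionComparisons(tab) else
        data.frame()
    new("SynergyStat", construct = as.character(construct),
        conditionMeans = relMeans, expectedAdditive = expectedAdd,
        excess = unname(excess), statistic = unname(stat), df = unname(df),
        pSynergy = unname(p), method = method, comparisons = cmp)
}

#' Pairwise Welch comparisons between reporter conditions
#'
#' Two-sided Welch t tests on the relative outputs for each condition versus
#' control and for AB versus each single factor, with significance tiers at
#' strict 0.05 / 0.01 / 0.001 thresholds.  A pair of zero-variance groups is
#' reported as p = 1 when their means are equal and p = 0 otherwise, with a
#' warning.
#'
#' @param table a normalised reporter data.frame for a single construct (or
#'   with a `construct` column restricted beforehand).
#' @return data.frame: comparison, estimate (difference of means), p, tier
#'   (one of "", "*", "**", "***").
#' @export
conditionComparisons <- function(table) {
    if (is.null(table$relative))
        table <- normalizeReporter(table)
    pairs <- list(c("A", "control"), c("B", "control"), c("AB", "control"),
        c("AB", "A"), c("AB", "B"))
    rows <- lapply(pairs, function(pr) {
        x <- table$relative[table$condition == pr[1L]]
        y <- table$relative[table$condition == pr[2L]]
        if (length(x) < 2L || length(y) < 2L)
            stop("need >= 2 replicates per condition (", pr[1L], " vs ",
                pr[2L], ")")
        if (stats::var(x) == 0 && stats::var(y) == 0) {
            warning("zero-variance comparison ", pr[1L], " vs ", pr[2L])
            p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
        } else {
            p <- stats::t.test(x, y)$p.value
        }
        tier <- if (p < 0.001) "***" else if (p < 0.01) "**" else
            if (p < 0.05) "*" else ""
        data.frame(comparison = paste(pr, collapse = "_vs_"),
            estimate = mean(x) - mean(y), p = p, tier = tier,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
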