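#' Pooled two-sample Student's t-test from summary statistics
#'
#' The classic equal-variance Student's t-test, computed from per-condition
#' means, sample standard deviations and replicate counts (so it can be run
#' from printed summary tables as well as from raw replicate values):
#' \deqn{s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}, \quad
#'       t = \frac{m_1 - m_2}{s_p\sqrt{1/n_1 + 1/n_2}}}
#' with a two-tailed p-value from the t distribution on \eqn{n_1+n_2-2}
#' degrees of freedom. Welch's unequal-variance form is available via
#' \code{welch = TRUE}.
#'
#' Degenerate pooled variance is handled explicitly: with equal means the
#' test returns \eqn{t = 0, p = 1}; with unequal means it returns
#' \eqn{p = 0} with a degeneracy warning.
#'
#' @param a,b [SummaryStats-class] objects (see [summaryStats()]).
#' @param welch use the Welch-Satterthwaite form instead of pooling.
#' @return A [TTestResult-class].
#' @examples
#' pooledTTestSummary(summaryStats(3050.30, 421.88, 3),
#'                    summaryStats(1869.77, 122.47, 3))
#' @export
pooledTTestSummary <- function(a, b, welch = FALSE) {
    stopifnot(is(a, "SummaryStats"), is(b, "SummaryStats"))
    validObject(a); validObject(b)
    diff <- a@mean - b@mean
    if (welch) {
        v1 <- a@sd^2 / a@n
        v2 <- b@sd^2 / b@n
        se <- sqrt(v1 + v2)
        df <- (v1 + v2)^2 / (v1^2 / (a@n - 1) + v2^2 / (b@n - 1))
        df <- as.integer(floor(df))
    } else {
        sp2 <- ((a@n - 1) * a@sd^2 + (b@n - 1) * b@sd^2) / (a@n + b@n - 2L)
        se <- sqrt(sp2) * sqrt(1 / a@n + 1 / b@n)
        df <- a@n + b@n - 2L
    }
    if (se == 0) {
        if (diff == 0)
            return(new("TTestResult", t = 0, df = df, p = 1,
                       meanDifference = 0))
        warning("zero pooled variance with unequal means; p = 0",
                call. = FALSE)
        return(new("TTestResult", t = sign(diff) * Inf, df = df, p = 0,
                   meanDifference = diff))
    }
    t <- diff / se
    p <- 2 * pt(-abs(t), df)
    new("TTestResult", t = t, df = df, p = p, meanDifference = diff)
}

#' Compare symbiont protein content between two conditions
#'
#' Computes a per-sample symbiont quantity -- either the symbiont fraction of
#' holobiont nSpC (default) or the summed symbiont nSpC total -- summarizes
#' it per condition (mean, sample sd, n) and tests the two conditions
#' against each other with the pooled Student's t-test. The output mirrors
#' the usual printed comparison table: one column per condition plus the
#' p-value.
#'
#' @param x a [QuantMatrix-class], or a data frame with columns
#'   \code{sample_id} and \code{value} holding a precomputed per-sample
#'   quantity.
#' @param design data frame with columns \code{sample_id} and
#'   \code{condition} (a \code{replicate} column is accepted and ignored).
#'   Exactly two conditions, each with at least two replicates.
#' @param metric \code{"fraction"} (symbiont share of holobiont nSpC) or
#'   \code{"nspc_total"} (summed symbiont nSpC on the matrix scale). Ignored
#'   when \code{x} is already a per-sample value table.
#' @param welch passed to [pooledTTestSummary()].
#' @return A list with \code{summary} (per-condition data frame:
#'   \code{condition}, \code{mean}, \code{sd}, \code{n}), \code{test} (a
#'   [TTestResult-class]) and \code{values} (the per-sample quantities
#'   used).
#' @examples
#' vals <- data.frame(sample_id = paste0("s", 1:6),
#'                    value = c(0.30, 0.29, 0.31, 0.18, 0.19, 0.20))
#' design <- data.frame(sample_id = paste0("s", 1:6),
#'                      condition = rep(c("fresh", "starved"), each = 3))
#' compareConditions(vals, design)$test
#' @export
compareConditions <- function(x, design, metric = c("fraction", "nspc_total"),
                              welch = FALSE) {
    metric <- match.arg(metric)
    stopifnot(all(c("sample_id", "condition") %in% colnames(design)))
    if (is(x, "QuantMatrix")) {
        if (metric == "fraction") {
            tf <- taxonFractions(x)
            values <- data.frame(sample_id = tf$sample_id,
                                 value = tf$fraction)
        } else {
            rd <- SummarizedExperiment::rowData(x)
            m <- nspc(x)
            values <- data.frame(
                sample_id = colnames(m),
                value = colSums(m[rd$taxon == "symbiont", , drop = FALSE]))
        }
    } else {
        stopifnot(all(c("sample_id", "value") %in% colnames(x)))
        values <- x[, c("sample_id", "value")]
    }
    values <- merge(values, design[, c("sample_id", "condition")],
                    by = "sample_id", sort = FALSE)
    conds <- unique(as.character(design$condition))
    if (length(conds) != 2L)
        stop("exactly two conditions required, got: ",
             paste(conds, collapse = ", "))
    perCond <- split(values$value, factor(values$condition, levels = conds))
    small <- conds[vapply(perCond, length, integer(1)) < 2L]
    if (length(small))
        stop("fewer than 2 replicates in condition '", small[1L], "'")
    stats <- lapply(perCond, function(v)
        summaryStats(mean(v), stats::sd(v), length(v)))
    res <- pooledTTestSummary(stats[[1L]], stats[[2L]], welch = welch)
    summary <- data.frame(
        condition = conds,
        mean = vapply(stats, function(s) s@mean, numeric(1)),
        sd = vapply(stats, function(s) s@sd, numeric(1)),
        n = vapply(stats, function(s) s@n, integer(1)),
        row.names = NULL)
    list(summary = summary, test = res, values = values)
}
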