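#' Normalized spectral counts (nSpC) from balanced counts
#'
#' Converts balanced spectral counts to normalized spectral counts, the
#' length-corrected relative abundance measure derived from normalized
#' spectral abundance factors: for group \eqn{i} with balanced count
#' \eqn{SpC_i} and seed length \eqn{L_i},
#' \eqn{SAF_i = SpC_i / L_i} and \eqn{nSpC_i = SAF_i / \sum_j SAF_j}, the
#' sum running over the chosen normalization universe in the same sample.
#' On the \code{"per_10000"} scale values are multiplied by 10,000, so host
#' protein tables normalized on the host universe sum to 10,000 per sample.
#' Groups outside the universe are reported on the same scale factor.
#'
#' @param counts numeric matrix of balanced spectral counts, protein groups
#'   x samples, with row and column names.
#' @param seedLengths named numeric vector of seed lengths (residues) for
#'   every row of \code{counts}; by default taken from \code{groups}.
#' @param taxon named character vector of per-group taxon labels
#'   (\code{host}/\code{symbiont}/\code{contaminant}); by default from
#'   \code{groups}.
#' @param groups optional [ProteinGroupSet-class] supplying lengths and
#'   taxa.
#' @param universe normalization universe: \code{"holobiont"} (host +
#'   symbiont, contaminants excluded; the default used for host-vs-symbiont
#'   fractions), \code{"host"} (reproduces the host-table sums-to-10,000
#'   convention), \code{"symbiont"}, or \code{"all"} rows.
#' @param scale \code{"per_10000"} (default, matching printed abundance
#'   tables) or \code{"fraction"}.
#' @param colData optional \code{DataFrame}/data.frame of sample annotations
#'   (e.g. condition, replicate) matching the columns of \code{counts}.
#' @return A [QuantMatrix-class].
#' @examples
#' cnt <- matrix(c(10, 20), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' qm <- computeNSpC(cnt, seedLengths = c(g1 = 100, g2 = 400),
#'                   taxon = c(g1 = "host", g2 = "host"), universe = "all",
#'                   scale = "fraction")
#' nspc(qm)  # SAF 0.1 and 0.05 -> 2/3 and 1/3
#' @export
computeNSpC <- function(counts, seedLengths = NULL, taxon = NULL,
                        groups = NULL,
                        universe = c("holobiont", "host", "symbiont", "all"),
                        scale = c("per_10000", "fraction"),
                        colData = NULL) {
    universe <- match.arg(universe)
    scale <- match.arg(scale)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("'counts' needs row (group) and column (sample) names")
    if (!is.null(groups)) {
        if (is.null(seedLengths)) seedLengths <- seedLengths(groups)
        if (is.null(taxon)) taxon <- groupTaxa(groups)
    }
    if (is.null(seedLengths) || is.null(taxon))
        stop("provide 'seedLengths' and 'taxon', or a ProteinGroupSet")
    ids <- rownames(counts)
    seedLengths <- seedLengths[ids]
    taxon <- taxon[ids]
    if (anyNA(seedLengths) || any(seedLengths <= 0))
        stop("every group needs a positive seed length")

    inUniverse <- switch(universe,
        all = rep(TRUE, length(ids)),
        holobiont = taxon %in% c("host", "symbiont"),
        host = taxon == "host",
        symbiont = taxon == "symbiont")
    inUniverse[is.na(inUniverse)] <- FALSE

    saf <- counts / seedLengths
    denom <- colSums(saf[inUniverse, , drop = FALSE])
    zero <- denom <= 0
    if (any(zero)) {
        warning("zero total SAF over the '", universe, "' universe in ",
                sum(zero), " sample(s); emitting zeros", call. = FALSE)
        denom[zero] <- 1
        saf[, zero] <- 0
    }
    scaleFactor <- if (scale == "per_10000") 10000 else 1
    mat <- sweep(saf, 2L, denom, "/") * scaleFactor

    rd <- DataFrame(group_id = ids, taxon = unname(taxon),
                    seed_length = unname(as.numeric(seedLengths)),
                    in_universe = unname(inUniverse), row.names = ids)
    cd <- if (is.null(colData)) {
        DataFrame(sample_id = colnames(counts), row.names = colnames(counts))
    } else {
        cd <- DataFrame(colData)
        rownames(cd) <- colnames(counts)
        if (!"sample_id" %in% colnames(cd)) cd$sample_id <- colnames(counts)
        cd
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(nspc = mat, spc = counts),
        rowData = rd, colData = cd,
        metadata = list(universe = universe, scale = scale))
    new("QuantMatrix", se)
}

#' Per-sample host and symbiont abundance fractions
#'
#' Computes, for every sample, the symbiont share of total holobiont protein
#' on the length-corrected nSpC scale: the summed symbiont nSpC divided by
#' the summed host-plus-symbiont nSpC. Contaminant groups are excluded. The
#' ratio is invariant to the quantification scale and normalization universe
#' since the per-sample normalization factor cancels.
#'
#' @param quant a [QuantMatrix-class].
#' @return Data frame with columns \code{sample_id} and \code{fraction}
#'   (symbiont fraction in \[0, 1\]; \code{NA} where a sample has no
#'   holobiont signal). Sample annotations from \code{colData} are carried
#'   along.
#' @examples
#' cnt <- matrix(c(8, 2), 2, 1, dimnames = list(c("h", "s"), "s1"))
#' qm <- computeNSpC(cnt, seedLengths = c(h = 100, s = 100),
#'                   taxon = c(h = "host", s = "symbiont"))
#' taxonFractions(qm)$fraction  # 0.2
#' @export
taxonFractions <- function(quant) {
    stopifnot(is(quant, "QuantMatrix"))
    rd <- SummarizedExperiment::rowData(quant)
    m <- nspc(quant)
    sym <- colSums(m[rd$taxon == "symbiont", , drop = FALSE])
    hst <- colSums(m[rd$taxon == "host", , drop = FALSE])
    tot <- sym + hst
    frac <- ifelse(tot > 0, sym / tot, NA_real_)
    if (anyNA(frac))
        warning(sum(is.na(frac)),
                " sample(s) without holobiont signal; fraction undefined",
                call. = FALSE)
    out <- data.frame(sample_id = colnames(m), fraction = unname(frac),
                      row.names = NULL)
    cd <- as.data.frame(SummarizedExperiment::colData(quant))
    extra <- setdiff(colnames(cd), colnames(out))
    if (length(extra)) out <- cbind(out, cd[out$sample_id, extra, drop = FALSE],
                                    row.names = NULL)
    out
}
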