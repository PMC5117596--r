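#' Count spectra per peptide per sample
#'
#' @param psms PSM data frame with \code{sample_id} and \code{peptide}
#'   columns (typically the filtered target PSMs).
#' @return Data frame with columns \code{peptide}, \code{sample_id},
#'   \code{count}.
#' @export
countPeptideSpectra <- function(psms) {
    stopifnot(all(c("sample_id", "peptide") %in% colnames(psms)))
    if (!nrow(psms))
        return(data.frame(peptide = character(), sample_id = character(),
                          count = numeric()))
    tab <- as.data.frame(table(peptide = psms$peptide,
                               sample_id = psms$sample_id),
                         stringsAsFactors = FALSE)
    names(tab)[3L] <- "count"
    tab[tab$count > 0, , drop = FALSE]
}

#' End-to-end spectral-count quantification
#'
#' Runs the full post-search quantification chain on a PSM table and its
#' target protein database: target-decoy q-values, identification
#' filtering, greedy identity grouping, peptide uniqueness re-assessment,
#' shared-spectra balancing and nSpC normalization. Groups failing the
#' evidence filters are dropped before normalization, so the normalization
#' universe consists of the retained identified groups.
#'
#' @param psms PSM data frame (\code{sample_id}, \code{spectrum_id},
#'   \code{peptide}, \code{score}, \code{is_decoy}); q-values are computed
#'   if missing.
#' @param database target protein \code{AAStringSet} with taxon labels in
#'   \code{mcols} (decoys live only in the PSM table's \code{is_decoy}
#'   flag).
#' @param identityThreshold grouping threshold (default 0.9).
#' @param policy a [FilterPolicy-class].
#' @param universe,scale passed to [computeNSpC()].
#' @param balanceMethod passed to [balanceSpectra()].
#' @param design optional per-sample annotation data frame with a
#'   \code{sample_id} column, stored in the result's \code{colData}.
#' @return A [QuantMatrix-class]; its \code{metadata} additionally carries
#'   the [filterIdentifications()] report (\code{filterReport}) and the
#'   [ProteinGroupSet-class] (\code{groups}).
#' @examples
#' cfg <- generatorConfig(nHostProteins = 6, nSymbiontProteins = 4,
#'                        nVariantFamilies = 0, spectraPerSample = 2000)
#' db <- generateDatabase(cfg)
#' sim <- simulatePSMs(db$database, db$truth, cfg)
#' qm <- quantifyHolobiont(sim$psms, db$database)
#' taxonFractions(qm)
#' @export
quantifyHolobiont <- function(psms, database, identityThreshold = 0.9,
                              policy = filterPolicy(),
                              universe = c("holobiont", "host", "symbiont",
                                           "all"),
                              scale = c("per_10000", "fraction"),
                              balanceMethod = c("spectra", "peptides"),
                              design = NULL) {
    universe <- match.arg(universe)
    scale <- match.arg(scale)
    balanceMethod <- match.arg(balanceMethod)
    database <- .asAAStringSet(database)
    if (!"q_value" %in% colnames(psms))
        psms <- computeQvalues(psms)
    groups <- greedyCluster(database, threshold = identityThreshold)
    filt <- filterIdentifications(psms, groups, policy)

    pepCounts <- countPeptideSpectra(filt$psms)
    keepPep <- filt$uniqueness$status != "orphan"
    balanced <- balanceSpectra(pepCounts, filt$uniqueness[keepPep, ],
                               method = balanceMethod)
    samples <- unique(as.character(psms$sample_id))
    full <- matrix(0, length(filt$retainedGroups), length(samples),
                   dimnames = list(filt$retainedGroups, samples))
    common <- intersect(rownames(balanced), filt$retainedGroups)
    full[common, colnames(balanced)] <- balanced[common, , drop = FALSE]

    cd <- if (!is.null(design)) {
        stopifnot("sample_id" %in% colnames(design))
        design[match(samples, design$sample_id), , drop = FALSE]
    } else NULL
    qm <- computeNSpC(full, groups = groups, universe = universe,
                      scale = scale, colData = cd)
    metadata(qm)$filterReport <- filt$report
    metadata(qm)$groups <- groups
    qm
}
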