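#' Target-decoy q-value estimation for PSMs
#'
#' Sorts peptide-spectrum matches by score (higher is better) and estimates,
#' at every score threshold, the false-discovery rate as the number of decoy
#' matches at or above the threshold divided by the number of target matches
#' at or above it (capped at 1). The q-value of a PSM is the minimum FDR over
#' all thresholds that would accept it, i.e. the running minimum of the FDR
#' from the worst score upward; tied scores are processed as one block and
#' share the block's q-value. q-values are therefore non-increasing in score.
#'
#' @param psms data frame with at least \code{score} (numeric) and
#'   \code{is_decoy} (logical or 0/1) columns.
#' @return The input with a \code{q_value} column added (rows unchanged).
#' @examples
#' psms <- data.frame(score = c(10, 9, 8, 7),
#'                    is_decoy = c(FALSE, FALSE, FALSE, TRUE))
#' computeQvalues(psms)$q_value  # 0 0 0 1/3
#' @export
computeQvalues <- function(psms) {
    stopifnot(all(c("score", "is_decoy") %in% colnames(psms)))
    n <- nrow(psms)
    if (n == 0L) {
        psms$q_value <- numeric(0)
        return(psms)
    }
    if (anyNA(psms$score) || anyNA(psms$is_decoy))
        stop("every PSM needs a score and a decoy label")
    o <- order(psms$score, decreasing = TRUE)
    s <- psms$score[o]
    d <- as.logical(psms$is_decoy[o])
    cumD <- cumsum(d)
    cumT <- cumsum(!d)
    # tie blocks share the cumulative counts at the end of the block
    blockLen <- rle(s)$lengths
    blockEnd <- cumsum(blockLen)
    blockIdx <- rep(seq_along(blockEnd), blockLen)
    fdr <- pmin(1, cumD[blockEnd][blockIdx] / pmax(1, cumT[blockEnd][blockIdx]))
    q <- rev(cummin(rev(fdr)))
    psms$q_value <- NA_real_
    psms$q_value[o] <- q
    psms
}

#' Apply identification filters to PSMs and protein groups
#'
#' Implements the post-search identification policy: PSMs above the q-value
#' cutoff are discarded; a protein group is retained only with at least
#' \code{minSpectraPerProtein} supporting spectra, at least two distinct
#' peptides and at least one peptide unique to the group (thresholds taken
#' from \code{policy}). The same rules are applied to the mirrored decoy
#' groups (reversed decoy peptides mapped against reversed groups) to
#' estimate a protein-level FDR, which is flagged when it exceeds the
#' report threshold.
#'
#' @param psms data frame with columns \code{sample_id}, \code{peptide},
#'   \code{score}, \code{is_decoy} and \code{q_value} (see
#'   [computeQvalues()]).
#' @param groups a [ProteinGroupSet-class] built over the target database.
#' @param policy a [FilterPolicy-class].
#' @return A list with elements \code{psms} (retained target PSMs),
#'   \code{retainedGroups} (ids), \code{uniqueness} (the
#'   [reassessUniqueness()] table for observed target peptides),
#'   \code{groupStats} (per-group spectra / distinct / unique counts with
#'   the retention decision) and \code{report} (PSM and group tallies,
#'   protein-level FDR and its flag).
#' @export
filterIdentifications <- function(psms, groups, policy = filterPolicy()) {
    stopifnot(is(groups, "ProteinGroupSet"), is(policy, "FilterPolicy"))
    validObject(policy)
    if (!"q_value" %in% colnames(psms))
        stop("assign q-values with computeQvalues() before filtering")

    keep <- psms$q_value <= policy@maxQ
    passing <- psms[keep, , drop = FALSE]
    tgt <- passing[!as.logical(passing$is_decoy), , drop = FALSE]
    dcy <- passing[as.logical(passing$is_decoy), , drop = FALSE]

    uniq <- reassessUniqueness(unique(tgt$peptide), groups)
    orphans <- uniq$peptide[uniq$status == "orphan"]
    tgt <- tgt[!tgt$peptide %in% orphans, , drop = FALSE]

    minDistinct <- max(policy@minDistinctPeptides,
                       policy@minGroupDistinctPeptides)
    gsT <- .groupEvidence(tgt$peptide, uniq, groups)
    gsT$retained <- gsT$spectra >= policy@minSpectraPerProtein &
        gsT$distinct_peptides >= minDistinct &
        gsT$unique_peptides >= policy@minGroupUniquePeptides

    # decoy side: reversed peptides against the (reversed) target groups
    nDecoyPass <- 0L
    if (nrow(dcy)) {
        revPep <- .reverseStrings(dcy$peptide)
        uniqD <- suppressWarnings(reassessUniqueness(unique(revPep), groups))
        keepD <- !revPep %in% uniqD$peptide[uniqD$status == "orphan"]
        gsD <- .groupEvidence(revPep[keepD], uniqD, groups)
        nDecoyPass <- sum(gsD$spectra >= policy@minSpectraPerProtein &
                          gsD$distinct_peptides >= minDistinct &
                          gsD$unique_peptides >= policy@minGroupUniquePeptides)
    }
    nTargetPass <- sum(gsT$retained)
    proteinFdr <- nDecoyPass / max(1L, nTargetPass)

    report <- list(
        n_psms_in = nrow(psms),
        n_psms_passing_q = nrow(passing),
        n_target_psms_retained = nrow(tgt),
        n_orphan_peptides = length(orphans),
        n_groups_with_evidence = nrow(gsT),
        n_groups_retained = nTargetPass,
        n_decoy_groups_passing = nDecoyPass,
        protein_fdr = proteinFdr,
        protein_fdr_flagged = proteinFdr > policy@proteinFdrReportThreshold)
    if (report$protein_fdr_flagged)
        warning(sprintf("protein-level FDR %.3f exceeds %.3f",
                        proteinFdr, policy@proteinFdrReportThreshold),
                call. = FALSE)

    list(psms = tgt, retainedGroups = gsT$group_id[gsT$retained],
         uniqueness = uniq, groupStats = gsT, report = report)
}

# Per-group evidence from a vector of (non-distinct) observed peptides:
# spectra touching the group (shared spectra count for every sharing group),
# distinct peptides, and peptides unique to the group.
.groupEvidence <- function(peptideVec, uniqueness, groups) {
    ids <- groupIds(groups)
    idIndex <- setNames(seq_along(ids), ids)
    grpIdx <- lapply(as.list(uniqueness$groups),
                     function(g) unname(idIndex[g]))
    spectra <- numeric(length(ids))
    distinctP <- integer(length(ids))
    uniqueP <- integer(length(ids))
    if (length(peptideVec)) {
        cnt <- as.numeric(table(factor(peptideVec,
                                       levels = uniqueness$peptide)))
        isUnique <- uniqueness$status == "unique"
        for (i in seq_len(nrow(uniqueness))) {
            if (cnt[i] == 0) next
            gs <- grpIdx[[i]]
            if (!length(gs)) next
            spectra[gs] <- spectra[gs] + cnt[i]
            distinctP[gs] <- distinctP[gs] + 1L
            if (isUnique[i])
                uniqueP[gs] <- uniqueP[gs] + 1L
        }
    }
    data.frame(group_id = ids, spectra = spectra,
               distinct_peptides = distinctP,
               unique_peptides = uniqueP,
               row.names = NULL)
}

.reverseStrings <- function(x) {
    vapply(strsplit(x, "", fixed = TRUE),
           function(ch) paste(rev(ch), collapse = ""), character(1))
}
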