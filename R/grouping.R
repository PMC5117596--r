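#' Greedy centroid clustering of protein sequences
#'
#' Clusters proteins into groups at a global-alignment identity threshold
#' (default 0.9), the post-search grouping step that collapses
#' near-redundant database entries (assembly isoforms, fragments, strain
#' variants) into single quantifiable units. Records are visited sorted by
#' length descending (ties broken by identifier); each record joins the
#' first existing seed it matches at or above the threshold (seeds tried in
#' creation order), otherwise it founds a new group with itself as seed.
#' The seed is therefore always the longest member.
#'
#' @param records named character vector or \code{AAStringSet}. A
#'   \code{taxon} column in \code{mcols(records)} is propagated to the
#'   groups (a group carries its seed's taxon).
#' @param threshold identity threshold in (0, 1].
#' @param gapOpening,gapExtension alignment gap penalties, as in
#'   [pairwiseIdentity()].
#' @return A [ProteinGroupSet-class].
#' @examples
#' seqs <- c(A = "MKAAAECDEFGHIKLMNPQRSTVWY", B = "MKAAAECDEFGHIKLMNPQRSTVWF",
#'           C = "MWNCYPRDSTHHGAEIKLVQMFTGA")
#' greedyCluster(seqs, threshold = 0.9)
#' @export
greedyCluster <- function(records, threshold = 0.9, gapOpening = 10,
                          gapExtension = 1) {
    if (threshold <= 0 || threshold > 1)
        stop("'threshold' must lie in (0, 1]")
    if (is.character(records)) {
        taxon <- NULL
        records <- Biostrings::AAStringSet(records)
    } else {
        records <- .asAAStringSet(records)
        taxon <- mcols(records)$taxon
    }
    n <- length(records)
    if (n == 0L)
        return(.newProteinGroupSet(list(), records, NULL, threshold))
    if (is.null(names(records)) || anyDuplicated(names(records)))
        stop("'records' must carry unique names")
    if (is.null(taxon)) taxon <- rep(NA_character_, n)
    names(taxon) <- names(records)

    ord <- order(-Biostrings::width(records),
                 names(records), method = "radix")
    seedIdx <- integer()          # indices (into records) of seeds, creation order
    assignment <- integer(n)      # per record: seed rank in seedIdx
    for (i in ord) {
        hit <- 0L
        if (length(seedIdx)) {
            ident <- .alignBatch(records[seedIdx], records[[i]],
                                 gapOpening, gapExtension)$matches /
                pmin(Biostrings::width(records)[seedIdx],
                     Biostrings::width(records)[i])
            ok <- which(ident >= threshold)
            if (length(ok)) hit <- ok[1L]
        }
        if (hit == 0L) {
            seedIdx <- c(seedIdx, i)
            hit <- length(seedIdx)
        }
        assignment[i] <- hit
    }

    memberList <- split(names(records), assignment)[as.character(seq_along(seedIdx))]
    .newProteinGroupSet(memberList, records, taxon, threshold,
                        seedIds = names(records)[seedIdx])
}

# Build a ProteinGroupSet from a list of member-id vectors. Seeds default to
# the longest member (ties by id) of each group.
.newProteinGroupSet <- function(memberList, records, taxon, threshold,
                                seedIds = NULL) {
    if (!length(memberList)) {
        groups <- DataFrame(group_id = character(), seed_id = character(),
                            seed_length = integer(), taxon = character(),
                            n_members = integer())
        return(new("ProteinGroupSet", groups = groups,
                   members = CharacterList(), sequences = records,
                   threshold = threshold))
    }
    w <- setNames(Biostrings::width(records), names(records))
    if (is.null(seedIds))
        seedIds <- vapply(memberList, function(m)
            m[order(-w[m], m, method = "radix")][1L], character(1))
    groups <- DataFrame(
        group_id = unname(seedIds),
        seed_id = unname(seedIds),
        seed_length = unname(as.integer(w[seedIds])),
        taxon = if (is.null(taxon)) rep(NA_character_, length(seedIds))
                else unname(taxon[seedIds]),
        n_members = unname(lengths(memberList)))
    members <- CharacterList(unname(memberList))
    new("ProteinGroupSet", groups = groups, members = members,
        sequences = records, threshold = threshold)
}

#' Map peptides to protein groups and re-assess uniqueness
#'
#' After grouping, a peptide is unique when every database protein that
#' contains it (as an exact substring) belongs to a single protein group; it
#' is shared when its occurrences span several groups. Peptides matching no
#' database protein are flagged as orphans (with a warning) and must be
#' excluded downstream.
#'
#' @param peptides character vector of distinct peptide sequences.
#' @param groups a [ProteinGroupSet-class].
#' @return A \code{DataFrame} with columns \code{peptide}, \code{status}
#'   (\code{unique}/\code{shared}/\code{orphan}) and \code{groups}
#'   (\code{CharacterList} of group ids containing the peptide).
#' @examples
#' grp <- greedyCluster(c(A = "MSAMPLEKAAAQRTT", B = "MWNCYPKDSTHHGAEIK"))
#' reassessUniqueness(c("AAAQR", "DSTHHGAEIK"), grp)
#' @export
reassessUniqueness <- function(peptides, groups) {
    stopifnot(is(groups, "ProteinGroupSet"))
    peptides <- as.character(peptides)
    seqs <- as.character(groups@sequences)
    protIds <- names(groups@sequences)
    memberToGroup <- setNames(
        rep(groups@groups$group_id, lengths(groups@members)),
        unlist(groups@members))
    grpPerPep <- lapply(peptides, function(p) {
        hit <- grepl(p, seqs, fixed = TRUE)
        unique(unname(memberToGroup[protIds[hit]]))
    })
    status <- vapply(grpPerPep, function(g)
        if (length(g) == 0L) "orphan" else if (length(g) == 1L) "unique"
        else "shared", character(1))
    nOrphan <- sum(status == "orphan")
    if (nOrphan)
        warning(nOrphan, " peptide(s) match no database protein; ",
                "flagged as orphans and excluded downstream", call. = FALSE)
    DataFrame(peptide = peptides, status = status,
              groups = CharacterList(grpPerPep))
}

#' Balance shared spectral counts across protein groups
#'
#' Distributes each shared peptide's spectral counts among the protein groups
#' sharing it, proportionally to each group's unique evidence in the same
#' sample: with unique spectral counts \eqn{U_g}, group \eqn{g} receives the
#' fraction \eqn{U_g / \sum_h U_h} of the shared count (equal split when all
#' sharing groups lack unique evidence). A group's balanced count is its
#' unique count plus all its allocations; per sample the balanced counts
#' conserve the raw spectral total exactly.
#'
#' @param peptideCounts data frame with columns \code{peptide},
#'   \code{sample_id} and \code{count} (spectra per peptide per sample).
#' @param uniqueness result of [reassessUniqueness()] covering every peptide
#'   in \code{peptideCounts}; orphan peptides are ignored.
#' @param method \code{"spectra"} weighs sharing groups by their unique
#'   spectral counts (default); \code{"peptides"} weighs them by the number
#'   of distinct unique peptide species observed in the sample.
#' @return Numeric matrix of balanced counts, protein groups x samples.
#' @examples
#' grp <- greedyCluster(c(A = "MSSSSKAAAQRLLLLK", B = "MTTTTKAAAQRVVVVK"),
#'                      threshold = 0.99)
#' pc <- data.frame(peptide = c("LLLLK", "VVVVK", "AAAQR"),
#'                  sample_id = "s1", count = c(2, 1, 6))
#' balanceSpectra(pc, reassessUniqueness(pc$peptide, grp))
#' @export
balanceSpectra <- function(peptideCounts, uniqueness,
                           method = c("spectra", "peptides")) {
    method <- match.arg(method)
    stopifnot(all(c("peptide", "sample_id", "count") %in%
                  colnames(peptideCounts)))
    if (any(peptideCounts$count < 0))
        stop("spectral counts must be >= 0")
    pepIdx <- match(as.character(peptideCounts$peptide), uniqueness$peptide)
    if (anyNA(pepIdx))
        stop("peptides without a uniqueness assessment: ",
             paste(utils::head(unique(
                 peptideCounts$peptide[is.na(pepIdx)]), 3), collapse = ", "))

    grpList <- as.list(uniqueness$groups)
    allGroups <- unique(unlist(grpList, use.names = FALSE))
    samples <- unique(as.character(peptideCounts$sample_id))
    if (!length(allGroups) || !length(samples))
        return(matrix(0, 0, 0))
    # integer indices throughout: name lookups are quadratic at PSM scale
    grpIdx <- lapply(grpList, function(g) match(g, allGroups))
    U <- matrix(0, length(allGroups), length(samples),
                dimnames = list(allGroups, samples))
    uSpecies <- U

    smpIdx <- match(as.character(peptideCounts$sample_id), samples)
    cnt <- as.numeric(peptideCounts$count)
    st <- uniqueness$status[pepIdx]

    for (k in which(st == "unique")) {
        g <- grpIdx[[pepIdx[k]]][1L]
        U[g, smpIdx[k]] <- U[g, smpIdx[k]] + cnt[k]
        if (cnt[k] > 0)
            uSpecies[g, smpIdx[k]] <- uSpecies[g, smpIdx[k]] + 1
    }
    weightsOf <- if (method == "spectra") U else uSpecies

    balanced <- U
    for (k in which(st == "shared")) {
        gs <- grpIdx[[pepIdx[k]]]
        w <- weightsOf[gs, smpIdx[k]]
        w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(gs), length(gs))
        balanced[gs, smpIdx[k]] <- balanced[gs, smpIdx[k]] + cnt[k] * w
    }
    balanced
}
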