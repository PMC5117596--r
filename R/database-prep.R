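#' @importFrom Biostrings DNAString DNAStringSet reverseComplement translate
#'   subseq
NULL

#' Six-frame open reading frame extraction
#'
#' Scans all six reading frames of one or more nucleotide contigs and
#' translates every maximal stop-free region (between stop codons or the
#' sequence ends) of at least \code{minLength} residues, using the standard
#' genetic code -- the stop-to-stop convention of classic ORF finders.
#' Codons containing \code{N} translate to \code{X}. Coordinates of
#' reverse-frame ORFs are reported on the forward strand.
#'
#' @param contigs nucleotide sequences over \code{A,C,G,T,N}: a character
#'   vector, \code{DNAString} or \code{DNAStringSet} (names become contig
#'   ids).
#' @param minLength minimum ORF length in residues (default 40).
#' @param requireStart if \code{TRUE}, each region is trimmed to begin at
#'   its first methionine (ATG-initiated mode); regions without one are
#'   dropped.
#' @return Data frame with columns \code{contig}, \code{frame} (+1..+3,
#'   -1..-3), \code{start}, \code{end} (1-based inclusive forward-strand
#'   nucleotide coordinates; the stop codon is excluded) and
#'   \code{protein}.
#' @examples
#' extractOrfs("ATGAAATAA", minLength = 1)  # frame +1: "MK"
#' @export
extractOrfs <- function(contigs, minLength = 40L, requireStart = FALSE) {
    if (minLength < 1L)
        stop("'minLength' must be >= 1")
    if (is(contigs, "DNAString"))
        contigs <- DNAStringSet(list(contigs))
    else if (is.character(contigs))
        contigs <- tryCatch(DNAStringSet(toupper(contigs)),
                            error = function(e)
                                stop("non-nucleotide characters in contig",
                                     call. = FALSE))
    if (!is(contigs, "DNAStringSet"))
        stop("'contigs' must be character, DNAString or DNAStringSet")
    if (any(grepl("[^ACGTN]", as.character(contigs))))
        stop("non-nucleotide characters in contig (A,C,G,T,N only)")
    if (is.null(names(contigs)))
        names(contigs) <- sprintf("contig_%d", seq_along(contigs))

    out <- list()
    for (ci in seq_along(contigs)) {
        fwd <- contigs[[ci]]
        L <- length(fwd)
        for (strand in c(1L, -1L)) {
            s <- if (strand == 1L) fwd else reverseComplement(fwd)
            for (off in 0:2) {
                nCod <- (L - off) %/% 3L
                if (nCod < 1L) next
                aa <- as.character(translate(subseq(s, off + 1L, off + 3L * nCod),
                                             if.fuzzy.codon = "X"))
                runs <- gregexpr("[^*]+", aa)[[1L]]
                if (runs[1L] == -1L) next
                lens <- attr(runs, "match.length")
                for (k in seq_along(runs)) {
                    aaStart <- as.integer(runs[k])
                    aaLen <- lens[k]
                    prot <- substr(aa, aaStart, aaStart + aaLen - 1L)
                    if (requireStart) {
                        mPos <- regexpr("M", prot, fixed = TRUE)
                        if (mPos == -1L) next
                        aaStart <- aaStart + as.integer(mPos) - 1L
                        aaLen <- aaLen - as.integer(mPos) + 1L
                        prot <- substr(prot, mPos, nchar(prot))
                    }
                    if (aaLen < minLength) next
                    cs <- off + (aaStart - 1L) * 3L + 1L
                    ce <- off + (aaStart + aaLen - 1L) * 3L
                    if (strand == 1L) {
                        startF <- cs; endF <- ce
                    } else {
                        startF <- L - ce + 1L; endF <- L - cs + 1L
                    }
                    out[[length(out) + 1L]] <- data.frame(
                        contig = names(contigs)[ci],
                        frame = strand * (off + 1L),
                        start = startF, end = endF,
                        protein = prot, stringsAsFactors = FALSE)
                }
            }
        }
    }
    if (!length(out))
        return(data.frame(contig = character(), frame = integer(),
                          start = integer(), end = integer(),
                          protein = character(), stringsAsFactors = FALSE))
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Reversed-sequence decoys
#'
#' Builds one decoy per target by reversing the amino-acid sequence and
#' prefixing the identifier with a reserved tag; input order is preserved.
#' Palindromic sequences whose decoy equals the target are reported in a
#' warning, since such decoys are uninformative for FDR estimation.
#'
#' @param targets named character vector or \code{AAStringSet} with unique
#'   ids.
#' @param prefix reserved decoy id prefix (default \code{"rev_"}).
#' @return An \code{AAStringSet} of decoys, same length and order as
#'   \code{targets}.
#' @examples
#' as.character(makeDecoys(c(p1 = "ACDEF")))  # "FEDCA"
#' @export
makeDecoys <- function(targets, prefix = "rev_") {
    targets <- .asAAStringSet(targets)
    if (length(targets) == 0L)
        stop("'targets' must be non-empty")
    if (is.null(names(targets)) || anyDuplicated(names(targets)))
        stop("duplicate or missing target ids")
    rev <- Biostrings::reverse(targets)
    names(rev) <- paste0(prefix, names(targets))
    pal <- as.character(rev) == as.character(targets)
    if (any(pal))
        warning("decoy equals target for palindromic sequence(s): ",
                paste(names(targets)[pal], collapse = ", "), call. = FALSE)
    mcols(rev) <- NULL
    rev
}

#' Remove redundant sequences by identity clustering
#'
#' Collapses a sequence set at an identity threshold via [greedyCluster()]
#' and keeps each cluster's seed (its longest member) as the
#' representative -- the redundancy-removal step applied to predicted coding
#' sequences before a proteomic search.
#'
#' @param records named character vector or \code{AAStringSet}.
#' @param identityThreshold clustering threshold in (0, 1] (default 0.9).
#' @return List with \code{representatives} (an \code{AAStringSet} of
#'   seeds) and \code{membership} (data frame \code{member_id},
#'   \code{seed_id}).
#' @examples
#' dd <- deduplicate(c(a = "MKLVNNPQRSTWYAECDGHI", b = "MKLVNNPQRSTWYAECDGHI"))
#' length(dd$representatives)  # 1
#' @export
deduplicate <- function(records, identityThreshold = 0.9) {
    records <- .asAAStringSet(records)
    if (length(records) == 0L)
        return(list(representatives = records,
                    membership = data.frame(member_id = character(),
                                            seed_id = character())))
    grp <- greedyCluster(records, threshold = identityThreshold)
    membership <- data.frame(
        member_id = unlist(grp@members, use.names = FALSE),
        seed_id = rep(grp@groups$seed_id, lengths(grp@members)),
        stringsAsFactors = FALSE)
    reps <- records[grp@groups$seed_id]
    list(representatives = reps, membership = membership)
}

#' Assemble a target-decoy search database
#'
#' Concatenates target proteins with optional contaminant entries (e.g.
#' human keratin and trypsin supplied by the user) and appends one
#' reversed-sequence decoy per target and contaminant.
#'
#' @param targets named \code{AAStringSet} or character vector; a
#'   \code{taxon} column in \code{mcols} is preserved.
#' @param contaminants optional named \code{AAStringSet}/character vector;
#'   records are labeled with taxon \code{"contaminant"}.
#' @param decoyPrefix reserved decoy id prefix.
#' @return A [SearchDatabase-class].
#' @export
buildSearchDatabase <- function(targets, contaminants = NULL,
                                decoyPrefix = "rev_") {
    targets <- .asAAStringSet(targets)
    if (length(targets) == 0L)
        stop("'targets' must be non-empty")
    if (is.null(mcols(targets)$taxon))
        mcols(targets)$taxon <- rep(NA_character_, length(targets))
    if (is.null(contaminants))
        contaminants <- Biostrings::AAStringSet()
    else {
        contaminants <- Biostrings::AAStringSet(contaminants)
        mcols(contaminants)$taxon <- rep("contaminant", length(contaminants))
    }
    all <- c(targets, contaminants)
    decoys <- suppressWarnings(makeDecoys(all, prefix = decoyPrefix))
    new("SearchDatabase", targets = targets, contaminants = contaminants,
        decoys = decoys, decoyPrefix = decoyPrefix)
}
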