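#' @importFrom Biostrings pairwiseAlignment alignedPattern alignedSubject
NULL

# Lazily fetched copy of the BLOSUM62 matrix shipped with Biostrings.
.blosum62 <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            e <- new.env()
            utils::data("BLOSUM62", package = "Biostrings", envir = e)
            cache <<- e$BLOSUM62
        }
        cache
    }
})

.asAAStringSet <- function(x) {
    if (is(x, "AAStringSet")) x else Biostrings::AAStringSet(x)
}

.checkAminoAcid <- function(x, what = "sequence") {
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYXBZU*-]", toupper(x))
    if (any(bad))
        stop("non-amino-acid characters in ", what, call. = FALSE)
    invisible(TRUE)
}

# Align a set of patterns against one subject and return, per pattern, the
# number of identically aligned residue pairs (X never counts as a match).
# Single Needleman-Wunsch batch call; aligned strings are extracted only on
# demand (or when X residues force a corrected match count) because that
# extraction dominates the runtime of large batches.
.alignBatch <- function(patterns, subject, gapOpening = 10, gapExtension = 1,
                        aligned = FALSE) {
    if (!is.null(mcols(patterns))) mcols(patterns) <- NULL
    pa <- pairwiseAlignment(patterns, subject, type = "global",
                            substitutionMatrix = .blosum62(),
                            gapOpening = gapOpening,
                            gapExtension = gapExtension)
    hasX <- any(grepl("X", as.character(patterns), fixed = TRUE)) ||
        grepl("X", as.character(subject), fixed = TRUE)
    ap <- as_ <- NULL
    if (aligned || hasX) {
        ap <- as.character(alignedPattern(pa))
        as_ <- as.character(alignedSubject(pa))
        matches <- mapply(function(p, s) {
            pc <- strsplit(p, "", fixed = TRUE)[[1L]]
            sc <- strsplit(s, "", fixed = TRUE)[[1L]]
            sum(pc == sc & pc != "-" & pc != "X")
        }, ap, as_, USE.NAMES = FALSE)
    } else {
        matches <- Biostrings::nmatch(pa)
    }
    list(matches = matches, alignedPattern = ap, alignedSubject = as_)
}

#' Pairwise global sequence identity
#'
#' Global (Needleman-Wunsch) alignment under BLOSUM62 with affine gap costs;
#' identity is the number of identically aligned residues divided by the
#' length of the shorter sequence (the centroid-clustering convention, so a
#' sequence contained in a longer one scores 1). \code{X} residues never
#' count as matches. The measure is symmetric.
#'
#' @param a character vector of one or more query sequences.
#' @param b a single subject sequence.
#' @param gapOpening,gapExtension affine gap penalties (defaults 10 and 1).
#' @return Numeric vector of identities in \[0, 1\], one per element of
#'   \code{a}.
#' @examples
#' pairwiseIdentity("ACDEFGHIK", "ACDEFGHIR")  # 8/9
#' pairwiseIdentity("ACDEF", "ACDEFGGGGG")     # contained: 1
#' @export
pairwiseIdentity <- function(a, b, gapOpening = 10, gapExtension = 1) {
    a <- toupper(as.character(a))
    b <- toupper(as.character(b))
    if (length(b) != 1L)
        stop("'b' must be a single sequence")
    if (any(!nzchar(a)) || !nzchar(b))
        stop("sequences must be non-empty")
    .checkAminoAcid(c(a, b))
    res <- .alignBatch(Biostrings::AAStringSet(a), Biostrings::AAString(b),
                       gapOpening, gapExtension)
    res$matches / pmin(nchar(a), nchar(b))
}

#' Map reference positions onto a query via global alignment
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps) of a query
#' against a reference, returning for every reference position the aligned
#' 1-based query position, or \code{NA} where the reference residue falls
#' opposite an alignment gap. Mapped query positions increase strictly with
#' reference position.
#'
#' @param query,reference amino-acid sequences (character or
#'   \code{AAString}).
#' @param gapOpening,gapExtension affine gap penalties.
#' @return Integer vector of length \code{nchar(reference)}.
#' @examples
#' alignPositions("MKAEFG", "MKACDEFG")  # positions 4 and 5 are NA
#' @export
alignPositions <- function(query, reference, gapOpening = 10,
                           gapExtension = 1) {
    query <- toupper(as.character(query))
    reference <- toupper(as.character(reference))
    if (!nzchar(query) || !nzchar(reference))
        stop("sequences must be non-empty")
    .checkAminoAcid(c(query, reference))
    res <- .alignBatch(Biostrings::AAStringSet(query),
                       Biostrings::AAString(reference),
                       gapOpening, gapExtension, aligned = TRUE)
    qc <- strsplit(res$alignedPattern[1L], "", fixed = TRUE)[[1L]]
    rc <- strsplit(res$alignedSubject[1L], "", fixed = TRUE)[[1L]]
    qpos <- cumsum(qc != "-")
    keep <- rc != "-"
    map <- ifelse(qc[keep] != "-", qpos[keep], NA_integer_)
    as.integer(map)
}
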