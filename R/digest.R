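#' In-silico tryptic digestion
#'
#' Cleaves a protein after every lysine or arginine not followed by proline
#' and enumerates all fully-tryptic peptides spanning at most
#' \code{missedCleavages} internal cleavage sites. Both peptide termini are
#' either cleavage products or the protein's ends.
#'
#' @param protein a single amino-acid sequence.
#' @param missedCleavages maximum internal cleavage sites per peptide
#'   (default 2, the usual search-engine setting).
#' @param minLength minimum peptide length in residues (default 5; shorter
#'   peptides are rarely informative in a database search).
#' @param unique drop duplicate peptide strings (default \code{TRUE});
#'   set \code{FALSE} to obtain the positional fragment series, whose
#'   zero-missed-cleavage concatenation reconstructs the protein.
#' @return Character vector of peptides ordered by start position, then span.
#' @examples
#' digestProtein("MKRAAAKGGG", missedCleavages = 0, minLength = 1)
#' digestProtein("MKPAAA", missedCleavages = 0, minLength = 1)  # KP: no cut
#' @export
digestProtein <- function(protein, missedCleavages = 2L, minLength = 5L,
                          unique = TRUE) {
    if (missedCleavages < 0L)
        stop("'missedCleavages' must be >= 0")
    protein <- toupper(as.character(protein))
    if (!nzchar(protein))
        return(character())
    chars <- strsplit(protein, "", fixed = TRUE)[[1L]]
    n <- length(chars)
    sites <- which(chars %in% c("K", "R"))
    sites <- sites[sites < n & chars[sites + 1L] != "P"]
    bounds <- c(0L, sites, n)            # fragment i spans bounds[i]+1..bounds[i+1]
    m <- length(bounds) - 1L
    out <- character()
    for (i in seq_len(m)) {
        jmax <- min(i + missedCleavages, m)
        for (j in i:jmax) {
            start <- bounds[i] + 1L
            end <- bounds[j + 1L]
            if (end - start + 1L >= minLength)
                out <- c(out, substr(protein, start, end))
        }
    }
    if (unique) unique(out) else out
}
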