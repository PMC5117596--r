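# Shared fixtures and independent oracles for the test suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randomProteinSeq <- function(len) {
    paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# n random proteins, optionally with planted >= `identity` variants of the
# first `nVariants` sequences (substitution-only, so identity is exact).
randomProteinSet <- function(n, lenRange = c(30, 60), nVariants = 0,
                             identity = 0.95) {
    lens <- sample(seq(lenRange[1], lenRange[2]), n, replace = TRUE)
    seqs <- vapply(lens, randomProteinSeq, character(1))
    names(seqs) <- sprintf("p%02d", seq_len(n))
    if (nVariants > 0) {
        for (i in seq_len(min(nVariants, n))) {
            ch <- strsplit(seqs[[i]], "")[[1]]
            nSub <- max(1, round((1 - identity) * length(ch)))
            pos <- sample(length(ch), nSub)
            ch[pos] <- vapply(ch[pos], function(o)
                sample(setdiff(AA20, o), 1), character(1))
            seqs[[paste0(names(seqs)[i], "v")]] <- paste(ch, collapse = "")
        }
    }
    seqs
}

# Brute-force greedy clustering oracle: explicit all-pairs identity lookups
# and a plain assignment loop under the same ordering rules (length
# descending, ties by id in C locale; seeds tried in creation order).
oracleGreedyCluster <- function(seqs, threshold) {
    ids <- names(seqs)
    ord <- order(-nchar(seqs), ids, method = "radix")
    seeds <- character(0)
    assign <- setNames(character(length(seqs)), ids)
    for (id in ids[ord]) {
        placed <- NA_character_
        if (length(seeds)) {
            # identity of this record to every existing seed, seeds in
            # creation order; first at/above threshold wins
            idents <- pairwiseIdentity(unname(seqs[seeds]), seqs[[id]])
            hit <- which(idents >= threshold)
            if (length(hit))
                placed <- seeds[hit[1L]]
        }
        if (is.na(placed)) {
            seeds <- c(seeds, id)
            placed <- id
        }
        assign[[id]] <- placed
    }
    assign
}

# Member -> seed map from a ProteinGroupSet, for comparison with the oracle.
membershipMap <- function(groups) {
    m <- memberIds(groups)
    setNames(rep(seedIds(groups), lengths(m)), unlist(m, use.names = FALSE))
}

# Exhaustive q-value oracle: evaluate the decoy/target FDR at every distinct
# score threshold and take, per PSM, the minimum over all thresholds that
# would accept it.
oracleQvalues <- function(score, is_decoy) {
    thr <- sort(unique(score))
    fdr <- vapply(thr, function(t) {
        above <- score >= t
        min(1, sum(is_decoy[above]) / max(1, sum(!is_decoy[above])))
    }, numeric(1))
    vapply(score, function(s) min(fdr[thr <= s]), numeric(1))
}

# Small two-protein database whose tryptic peptides are known by hand:
# shared peptide AAAQR, unique peptides per protein.
twoProteinDb <- function() {
    c(protA = "MSSSSKAAAQRLLLLK", protB = "MTTTTKAAAQRVVVVK")
}

makePsms <- function(peptides, scores = NULL, decoy = NULL,
                     sample_id = "s1") {
    n <- length(peptides)
    data.frame(
        sample_id = rep_len(sample_id, n),
        spectrum_id = sprintf("scan%04d", seq_len(n)),
        peptide = peptides,
        score = if (is.null(scores)) rep(10, n) else scores,
        is_decoy = if (is.null(decoy)) rep(FALSE, n) else decoy,
        stringsAsFactors = FALSE)
}

tinyConfig <- function(rngSeed = 11L, ...) {
    generatorConfig(nHostProteins = 6, nSymbiontProteins = 4,
                    nVariantFamilies = 2, variantIdentity = 0.95,
                    proteinLengthRange = c(60, 120),
                    spectraPerSample = 2000, rngSeed = rngSeed, ...)
}
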