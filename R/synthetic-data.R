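.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.randomProtein <- function(len) {
    paste(sample(.AA20, len, replace = TRUE), collapse = "")
}

# Length-corrected (nSpC-scale) symbiont fraction implied by the abundance
# model at symbiont spectral fraction p: spectra go to protein i of taxon T
# with probability p_T * w_i L_i / sum_T(wL), so the expected SAF of taxon T
# totals p_T * sum_T(w) / sum_T(wL).
.nspcScaleFraction <- function(p, weights) {
    sym <- weights$taxon == "symbiont"
    hst <- weights$taxon == "host"
    A <- sum(weights$weight[sym]) /
        sum(weights$weight[sym] * weights$length[sym])
    B <- sum(weights$weight[hst]) /
        sum(weights$weight[hst] * weights$length[hst])
    p * A / (p * A + (1 - p) * B)
}

#' Generate a synthetic two-taxon protein database with ground truth
#'
#' Draws host and symbiont base proteins uniformly over the 20-letter
#' amino-acid alphabet, then adds one near-identical variant to each of
#' \code{nVariantFamilies} randomly chosen base proteins by point-substituting
#' a \code{1 - variantIdentity} fraction of positions -- the redundancy that
#' protein grouping must collapse. Per-protein abundance weights are drawn
#' log-normally within taxon; spectra are later allocated proportionally to
#' weight x length, the premise of NSAF length correction. Everything is
#' deterministic given the config's seed.
#'
#' @param config a [GeneratorConfig-class].
#' @return A list with \code{database} (an \code{AAStringSet} whose
#'   \code{mcols} carry the \code{taxon} label) and \code{truth} (a
#'   [GroundTruth-class]).
#' @examples
#' db <- generateDatabase(generatorConfig(nHostProteins = 5,
#'     nSymbiontProteins = 3, nVariantFamilies = 0))
#' table(S4Vectors::mcols(db$database)$taxon)
#' @export
generateDatabase <- function(config) {
    stopifnot(is(config, "GeneratorConfig"))
    validObject(config)
    set.seed(config@rngSeed)

    nH <- config@nHostProteins
    nS <- config@nSymbiontProteins
    ids <- c(sprintf("host_%04d", seq_len(nH)),
             sprintf("sym_%04d", seq_len(nS)))
    taxon <- c(rep("host", nH), rep("symbiont", nS))
    lens <- sample(seq(config@proteinLengthRange[1L],
                       config@proteinLengthRange[2L]),
                   nH + nS, replace = TRUE)
    seqs <- vapply(lens, .randomProtein, character(1))

    famBase <- character(0)
    if (config@nVariantFamilies > 0L) {
        famBase <- sample(ids, config@nVariantFamilies)
        for (b in famBase) {
            k <- match(b, ids)
            L <- lens[k]
            nSub <- if (config@variantIdentity >= 1) 0L else
                max(1L, round((1 - config@variantIdentity) * L))
            v <- strsplit(seqs[k], "", fixed = TRUE)[[1L]]
            if (nSub > 0L) {
                pos <- sample(L, nSub)
                v[pos] <- vapply(v[pos], function(old)
                    sample(setdiff(.AA20, old), 1L), character(1))
            }
            ids <- c(ids, paste0(b, "_v1"))
            taxon <- c(taxon, taxon[k])
            lens <- c(lens, L)
            seqs <- c(seqs, paste(v, collapse = ""))
        }
    }

    database <- Biostrings::AAStringSet(setNames(seqs, ids))
    mcols(database)$taxon <- taxon

    weights <- DataFrame(protein_id = ids, taxon = taxon,
                         length = as.integer(lens),
                         weight = rlnorm(length(ids), 0, 1))
    probs <- vapply(config@conditions, function(p)
        .samplingProbs(p, weights), numeric(length(ids)))
    rownames(probs) <- ids

    truth <- new("GroundTruth", weights = weights, probs = probs,
                 samples = DataFrame(), familyMap = DataFrame(
                     variant_id = if (length(famBase))
                         paste0(famBase, "_v1") else character(),
                     base_id = famBase))
    list(database = database, truth = truth)
}

# Spectrum-sampling probabilities at symbiont fraction p: taxon first, then
# protein within taxon proportional to weight * length.
.samplingProbs <- function(p, weights) {
    w <- weights$weight * weights$length
    pr <- numeric(nrow(weights))
    sym <- weights$taxon == "symbiont"
    if (any(sym) && sum(w[sym]) > 0)
        pr[sym] <- p * w[sym] / sum(w[sym])
    if (any(!sym) && sum(w[!sym]) > 0)
        pr[!sym] <- (1 - p) * w[!sym] / sum(w[!sym])
    pr / sum(pr)
}

#' Simulate peptide-spectrum-match tables for every sample
#'
#' For each sample, the configured symbiont spectral fraction is perturbed
#' by multiplicative Gaussian replicate noise (clamped to \[0, 1\]), the
#' number of symbiont spectra is drawn binomially, spectra are allocated to
#' proteins within taxon proportionally to abundance weight x length, and
#' each spectrum is assigned a fully-tryptic peptide (length >= 5, up to 2
#' missed cleavages) of its protein uniformly at random. Target scores are
#' Gaussian; decoy matches (reversed peptides, scores shifted two standard
#' deviations down, which yields monotone q-values) are appended so that
#' they make up \code{decoyFractionOfMatches} of the final table.
#'
#' @param database \code{AAStringSet} with taxon labels in \code{mcols}, as
#'   returned by [generateDatabase()].
#' @param truth the matching [GroundTruth-class].
#' @param config the [GeneratorConfig-class] used for the database.
#' @param seed integer seed for the spectrum-sampling stage; defaults to
#'   \code{rngSeed(config) + 1} so that database and spectra draw from
#'   distinct streams.
#' @return A list with \code{psms} (data frame: \code{sample_id},
#'   \code{spectrum_id}, \code{peptide}, \code{score}, \code{is_decoy}) and
#'   \code{truth} (updated with the per-sample table: perturbed and
#'   realized symbiont spectral fractions and the implied nSpC-scale
#'   fraction).
#' @export
simulatePSMs <- function(database, truth, config, seed = NULL) {
    stopifnot(is(truth, "GroundTruth"), is(config, "GeneratorConfig"))
    if (length(database) == 0L)
        stop("empty protein database")
    taxon <- mcols(database)$taxon
    if (is.null(taxon))
        stop("database must carry taxon labels in mcols()")
    for (cond in names(config@conditions)) {
        p <- config@conditions[[cond]]
        if (p > 0 && !any(taxon == "symbiont"))
            stop("condition '", cond, "' has symbiont fraction > 0 ",
                 "but the database has no symbiont proteins")
        if (p < 1 && !any(taxon == "host"))
            stop("condition '", cond, "' has host fraction > 0 ",
                 "but the database has no host proteins")
    }
    if (is.null(seed)) seed <- config@rngSeed + 1L
    set.seed(seed)

    weights <- truth@weights
    ids <- weights$protein_id
    stopifnot(identical(ids, names(database)))
    pepSets <- lapply(as.character(database), digestProtein,
                      missedCleavages = 2L, minLength = 5L)
    empty <- lengths(pepSets) == 0L
    if (any(empty)) {
        warning(sum(empty), " protein(s) yield no observable peptide; ",
                "their abundance is set to zero", call. = FALSE)
        weights$weight[empty] <- 0
    }
    allPeptides <- unique(unlist(pepSets, use.names = FALSE))

    N <- config@spectraPerSample
    nRep <- config@nReplicates
    sampleRows <- list()
    psmRows <- list()
    probList <- list()
    for (cond in names(config@conditions)) {
        p0 <- config@conditions[[cond]]
        for (r in seq_len(nRep)) {
            sid <- sprintf("%s_r%d", cond, r)
            pPert <- min(1, max(0, p0 * (1 + rnorm(1, 0, config@replicateNoiseSd))))
            nSym <- rbinom(1L, N, pPert)
            counts <- integer(length(ids))
            for (tx in c("symbiont", "host")) {
                sel <- weights$taxon == tx
                nTx <- if (tx == "symbiont") nSym else N - nSym
                if (nTx == 0L || !any(sel)) next
                wl <- weights$weight[sel] * weights$length[sel]
                if (sum(wl) <= 0)
                    stop("taxon '", tx, "' has positive demand but zero weight")
                counts[sel] <- as.integer(rmultinom(1L, nTx, wl))
            }
            pepVec <- character(N)
            off <- 0L
            for (k in which(counts > 0L)) {
                pepVec[(off + 1L):(off + counts[k])] <-
                    sample(pepSets[[k]], counts[k], replace = TRUE)
                off <- off + counts[k]
            }
            f <- config@decoyFractionOfMatches
            nDecoy <- if (f > 0) as.integer(round(N * f / (1 - f))) else 0L
            decoyPep <- if (nDecoy)
                .reverseStrings(sample(allPeptides, nDecoy, replace = TRUE))
                else character()
            psmRows[[sid]] <- data.frame(
                sample_id = sid,
                spectrum_id = sprintf("%s_scan%06d", sid, seq_len(N + nDecoy)),
                peptide = c(pepVec, decoyPep),
                score = c(rnorm(N, 8, 1), rnorm(nDecoy, 6, 1)),
                is_decoy = rep(c(FALSE, TRUE), c(N, nDecoy)),
                stringsAsFactors = FALSE)
            sampleRows[[sid]] <- DataFrame(
                sample_id = sid, condition = cond, replicate = r,
                configured_fraction = p0, perturbed_fraction = pPert,
                realized_fraction = nSym / N,
                nspc_fraction = .nspcScaleFraction(pPert, weights))
            probList[[sid]] <- .samplingProbs(pPert, weights)
        }
    }
    psms <- do.call(rbind, c(psmRows, list(make.row.names = FALSE)))
    truth@samples <- do.call(rbind, unname(sampleRows))
    truth@probs <- do.call(cbind, probList)
    rownames(truth@probs) <- ids
    validObject(truth)
    list(psms = psms, truth = truth)
}

#' Fast path: realized per-sample symbiont spectral fractions
#'
#' Draws only the per-sample realized symbiont spectral fractions -- the
#' multiplicative replicate noise followed by binomial spectrum sampling --
#' without materializing PSM tables. The draw is identical in distribution
#' to counting symbiont-assigned spectra in [simulatePSMs()] output, which
#' makes this the tool for calibration studies that need thousands of
#' seeded repetitions (e.g. type-I-error panels for [compareConditions()]).
#'
#' @param config a [GeneratorConfig-class].
#' @param seed integer seed (default \code{rngSeed(config) + 1}, matching
#'   [simulatePSMs()]).
#' @return Data frame with columns \code{sample_id}, \code{condition},
#'   \code{replicate} and \code{fraction}.
#' @examples
#' simulateRealizedFractions(generatorConfig(spectraPerSample = 1000))
#' @export
simulateRealizedFractions <- function(config, seed = NULL) {
    stopifnot(is(config, "GeneratorConfig"))
    validObject(config)
    if (is.null(seed)) seed <- config@rngSeed + 1L
    set.seed(seed)
    N <- config@spectraPerSample
    out <- list()
    for (cond in names(config@conditions)) {
        p0 <- config@conditions[[cond]]
        for (r in seq_len(config@nReplicates)) {
            pPert <- min(1, max(0, p0 * (1 + rnorm(1, 0, config@replicateNoiseSd))))
            out[[length(out) + 1L]] <- data.frame(
                sample_id = sprintf("%s_r%d", cond, r),
                condition = cond, replicate = r,
                fraction = rbinom(1L, N, pPert) / N)
        }
    }
    do.call(rbind, out)
}
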