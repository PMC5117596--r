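#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges CharacterList
#' @importFrom Biostrings AAStringSet AAString
NULL

.TAXA <- c("host", "symbiont", "contaminant")
.ROLES <- c("active_site", "binding_groove", "sulfide_cysteine",
            "conserved_disulfide_cysteine")

## ---------------------------------------------------------------------------
## GeneratorConfig
## ---------------------------------------------------------------------------

#' Configuration for the synthetic holobiont generator
#'
#' Bundles every tunable of the synthetic two-taxon (host + symbiont)
#' metaproteome generator: database composition, near-redundant variant
#' families, the per-condition symbiont spectral fraction, replicate
#' structure, sampling depth, replicate noise and the decoy contamination
#' of the simulated search results.
#'
#' @slot nHostProteins number of host base proteins.
#' @slot nSymbiontProteins number of symbiont base proteins.
#' @slot nVariantFamilies number of base proteins that receive one
#'   additional near-identical variant (a redundancy family).
#' @slot variantIdentity target sequence identity of a variant to its base
#'   protein, as a fraction in \[0, 1\].
#' @slot proteinLengthRange minimum and maximum protein length in residues.
#' @slot conditions named numeric vector; names are condition labels and
#'   values the symbiont spectral fraction of total matched spectra.
#' @slot nReplicates biological replicates per condition.
#' @slot spectraPerSample target (non-decoy) spectra drawn per sample.
#' @slot replicateNoiseSd standard deviation of the multiplicative Gaussian
#'   perturbation applied to a replicate's symbiont fraction.
#' @slot decoyFractionOfMatches fraction of the final PSM table made up of
#'   decoy matches, in \[0, 1).
#' @slot rngSeed integer seed making the whole simulation deterministic.
#' @seealso [generatorConfig()], [generateDatabase()], [simulatePSMs()]
#' @export
setClass("GeneratorConfig",
    representation(
        nHostProteins = "integer",
        nSymbiontProteins = "integer",
        nVariantFamilies = "integer",
        variantIdentity = "numeric",
        proteinLengthRange = "integer",
        conditions = "numeric",
        nReplicates = "integer",
        spectraPerSample = "integer",
        replicateNoiseSd = "numeric",
        decoyFractionOfMatches = "numeric",
        rngSeed = "integer"
    )
)

setValidity("GeneratorConfig", function(object) {
    msg <- character()
    chkCount <- function(x, field, minimum = 1L) {
        if (length(x) != 1L || is.na(x) || x < minimum)
            sprintf("'%s' must be a single count >= %d", field, minimum)
        else character()
    }
    msg <- c(msg,
        chkCount(object@nHostProteins, "nHostProteins"),
        chkCount(object@nSymbiontProteins, "nSymbiontProteins"),
        chkCount(object@nVariantFamilies, "nVariantFamilies", 0L),
        chkCount(object@nReplicates, "nReplicates"),
        chkCount(object@spectraPerSample, "spectraPerSample"),
        chkCount(object@rngSeed, "rngSeed", minimum = -.Machine$integer.max))
    if (length(object@variantIdentity) != 1L ||
        object@variantIdentity < 0 || object@variantIdentity > 1)
        msg <- c(msg, "'variantIdentity' must be a fraction in [0, 1]")
    if (length(object@proteinLengthRange) != 2L ||
        any(is.na(object@proteinLengthRange)) ||
        object@proteinLengthRange[1L] < 20L ||
        diff(object@proteinLengthRange) < 0L)
        msg <- c(msg, paste0("'proteinLengthRange' must be (min, max) with ",
                             "min >= 20 residues and max >= min"))
    if (length(object@conditions) < 1L || is.null(names(object@conditions)) ||
        any(!nzchar(names(object@conditions))) ||
        anyDuplicated(names(object@conditions)))
        msg <- c(msg, "'conditions' must be a named vector of unique condition labels")
    if (any(object@conditions < 0 | object@conditions > 1))
        msg <- c(msg, "'conditions' fractions must lie in [0, 1]")
    if (length(object@replicateNoiseSd) != 1L || object@replicateNoiseSd < 0)
        msg <- c(msg, "'replicateNoiseSd' must be a single fraction >= 0")
    if (length(object@decoyFractionOfMatches) != 1L ||
        object@decoyFractionOfMatches < 0 || object@decoyFractionOfMatches >= 1)
        msg <- c(msg, "'decoyFractionOfMatches' must lie in [0, 1)")
    if (object@nVariantFamilies > object@nHostProteins + object@nSymbiontProteins)
        msg <- c(msg, "'nVariantFamilies' cannot exceed the number of base proteins")
    if (length(msg)) msg else TRUE
})

#' Create a generator configuration
#'
#' The defaults emulate the study design the package was validated against: a
#' two-condition ("fresh" vs "starved") holobiont proteome with three
#' biological replicates per condition, in which the symbiont share of
#' matched spectra drops from 29.5% in fresh to 18.7% in starved animals,
#' with 3% multiplicative replicate noise on that share.
#'
#' @param nHostProteins,nSymbiontProteins base proteins per taxon.
#' @param nVariantFamilies how many base proteins also get a near-identical
#'   (>= 90% identity) variant, creating the redundancy that protein grouping
#'   must collapse.
#' @param variantIdentity identity of a variant to its base protein.
#' @param proteinLengthRange length range (residues) for base proteins.
#' @param conditions named numeric vector of per-condition symbiont spectral
#'   fractions.
#' @param nReplicates replicates per condition.
#' @param spectraPerSample target spectra per sample.
#' @param replicateNoiseSd sd of the multiplicative replicate noise.
#' @param decoyFractionOfMatches decoy share of the final PSM table.
#' @param rngSeed integer seed.
#' @return A [GeneratorConfig-class] object.
#' @examples
#' cfg <- generatorConfig(nHostProteins = 5, nSymbiontProteins = 3,
#'                        nVariantFamilies = 0, spectraPerSample = 500)
#' cfg
#' @export
generatorConfig <- function(nHostProteins = 30L,
                            nSymbiontProteins = 20L,
                            nVariantFamilies = 6L,
                            variantIdentity = 0.95,
                            proteinLengthRange = c(150L, 450L),
                            conditions = c(fresh = 0.295, starved = 0.187),
                            nReplicates = 3L,
                            spectraPerSample = 50000L,
                            replicateNoiseSd = 0.03,
                            decoyFractionOfMatches = 0.1,
                            rngSeed = 1L) {
    new("GeneratorConfig",
        nHostProteins = as.integer(nHostProteins),
        nSymbiontProteins = as.integer(nSymbiontProteins),
        nVariantFamilies = as.integer(nVariantFamilies),
        variantIdentity = as.numeric(variantIdentity),
        proteinLengthRange = as.integer(proteinLengthRange),
        conditions = conditions,
        nReplicates = as.integer(nReplicates),
        spectraPerSample = as.integer(spectraPerSample),
        replicateNoiseSd = as.numeric(replicateNoiseSd),
        decoyFractionOfMatches = as.numeric(decoyFractionOfMatches),
        rngSeed = as.integer(rngSeed))
}

#' @describeIn GeneratorConfig-class the configured RNG seed.
#' @param x a \code{GeneratorConfig}.
#' @export
setMethod("rngSeed", "GeneratorConfig", function(x) x@rngSeed)

setMethod("show", "GeneratorConfig", function(object) {
    cat("GeneratorConfig\n")
    cat("  proteins: ", object@nHostProteins, " host + ",
        object@nSymbiontProteins, " symbiont (",
        object@nVariantFamilies, " variant families at ",
        object@variantIdentity, " identity)\n", sep = "")
    cat("  conditions:",
        paste(sprintf("%s=%.3f", names(object@conditions), object@conditions),
              collapse = ", "),
        sprintf("x %d replicates", object@nReplicates), "\n")
    cat("  spectra/sample:", object@spectraPerSample,
        " noise sd:", object@replicateNoiseSd,
        " decoy fraction:", object@decoyFractionOfMatches,
        " seed:", object@rngSeed, "\n")
})

## ---------------------------------------------------------------------------
## GroundTruth
## ---------------------------------------------------------------------------

#' Ground truth of a synthetic holobiont simulation
#'
#' Records everything the generator knows and the analysis is supposed to
#' recover: per-protein abundance weights, per-condition sampling
#' probabilities, the per-sample perturbed and realized symbiont spectral
#' fractions, the per-sample length-corrected (nSpC-scale) symbiont fraction
#' implied by the drawn weights, and the variant-family membership map.
#'
#' The sample table is empty until [simulatePSMs()] has been run; the
#' simulation returns an updated \code{GroundTruth} with it filled in.
#'
#' @slot weights \code{DataFrame} with one row per database protein:
#'   \code{protein_id}, \code{taxon}, \code{length}, \code{weight} (log-normal
#'   abundance weight within taxon).
#' @slot probs matrix of per-condition spectrum-sampling probabilities
#'   (proteins x conditions); each column sums to 1.
#' @slot samples \code{DataFrame} with one row per simulated sample:
#'   condition, replicate, configured/perturbed/realized symbiont spectral
#'   fraction and the implied nSpC-scale symbiont fraction.
#' @slot familyMap \code{DataFrame} mapping each variant protein to its base
#'   protein (\code{variant_id}, \code{base_id}).
#' @export
setClass("GroundTruth",
    representation(
        weights = "DataFrame",
        probs = "matrix",
        samples = "DataFrame",
        familyMap = "DataFrame"
    )
)

setValidity("GroundTruth", function(object) {
    msg <- character()
    need <- c("protein_id", "taxon", "length", "weight")
    if (!all(need %in% colnames(object@weights)))
        msg <- c(msg, "weights must have columns protein_id, taxon, length, weight")
    if (ncol(object@probs) > 0L) {
        s <- colSums(object@probs)
        if (any(abs(s - 1) > 1e-8))
            msg <- c(msg, "each probs column must sum to 1")
    }
    if (nrow(object@samples) > 0L) {
        fr <- object@samples$realized_fraction
        if (any(fr < 0 | fr > 1, na.rm = TRUE))
            msg <- c(msg, "realized fractions must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn GroundTruth-class per-sample truth table (empty before
#'   simulation).
#' @param x a \code{GroundTruth}.
#' @export
setMethod("truthSamples", "GroundTruth", function(x) x@samples)

#' @describeIn GroundTruth-class per-protein abundance weights.
#' @export
setMethod("truthWeights", "GroundTruth", function(x) x@weights)

#' @describeIn GroundTruth-class variant-to-base family membership map.
#' @export
setMethod("familyMap", "GroundTruth", function(x) x@familyMap)

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", nrow(object@weights), "proteins,",
        nrow(object@familyMap), "variant families,",
        nrow(object@samples), "simulated samples\n")
})

## ---------------------------------------------------------------------------
## SearchDatabase
## ---------------------------------------------------------------------------

#' Target-decoy search database
#'
#' Container for a concatenated proteomic search database: target proteins
#' (with host/symbiont taxon labels in \code{mcols}), optional contaminant
#' proteins, and one reversed-sequence decoy per target and contaminant.
#' Decoy identifiers carry a reserved prefix (default \code{"rev_"}).
#'
#' @slot targets,contaminants,decoys \code{AAStringSet}s.
#' @slot decoyPrefix reserved identifier prefix of decoy records.
#' @seealso [buildSearchDatabase()], [makeDecoys()]
#' @export
setClass("SearchDatabase",
    representation(
        targets = "AAStringSet",
        contaminants = "AAStringSet",
        decoys = "AAStringSet",
        decoyPrefix = "character"
    )
)

setValidity("SearchDatabase", function(object) {
    msg <- character()
    if (length(object@decoys) !=
        length(object@targets) + length(object@contaminants))
        msg <- c(msg, "need exactly one decoy per target and contaminant")
    if (length(object@decoys) &&
        !all(startsWith(names(object@decoys), object@decoyPrefix)))
        msg <- c(msg, sprintf("all decoy ids must start with '%s'",
                              object@decoyPrefix))
    ids <- c(names(object@targets), names(object@contaminants),
             names(object@decoys))
    if (anyDuplicated(ids))
        msg <- c(msg, "identifier collision between database records")
    if (length(object@targets) &&
        any(startsWith(names(object@targets), object@decoyPrefix)))
        msg <- c(msg, sprintf("target ids may not use the reserved prefix '%s'",
                              object@decoyPrefix))
    if (length(msg)) msg else TRUE
})

#' @describeIn SearchDatabase-class target protein sequences.
#' @param x a \code{SearchDatabase}.
#' @export
setMethod("targets", "SearchDatabase", function(x) x@targets)

#' @describeIn SearchDatabase-class reversed decoy sequences.
#' @export
setMethod("decoys", "SearchDatabase", function(x) x@decoys)

#' @describeIn SearchDatabase-class contaminant sequences.
#' @export
setMethod("contaminants", "SearchDatabase", function(x) x@contaminants)

#' @describeIn SearchDatabase-class reserved decoy identifier prefix.
#' @export
setMethod("decoyPrefix", "SearchDatabase", function(x) x@decoyPrefix)

setMethod("show", "SearchDatabase", function(object) {
    cat("SearchDatabase:", length(object@targets), "targets,",
        length(object@contaminants), "contaminants,",
        length(object@decoys), "decoys (prefix '",
        object@decoyPrefix, "')\n", sep = " ")
})

## ---------------------------------------------------------------------------
## ProteinGroupSet
## ---------------------------------------------------------------------------

#' Greedy sequence-identity protein groups
#'
#' Result of greedy centroid clustering of database proteins at a sequence
#' identity threshold (default 90%). Each group is represented by its longest
#' member, the seed; every member aligns to the seed at or above the
#' threshold; the group is quantified as one unit downstream.
#'
#' @slot groups \code{DataFrame} with one row per group: \code{group_id}
#'   (equal to the seed id), \code{seed_id}, \code{seed_length},
#'   \code{taxon} (the seed's taxon, \code{NA} if unlabeled), and
#'   \code{n_members}.
#' @slot members \code{CharacterList} of member ids, parallel to
#'   \code{groups}.
#' @slot sequences \code{AAStringSet} of every clustered record (needed for
#'   substring-based peptide-to-group mapping).
#' @slot threshold identity threshold used.
#' @seealso [greedyCluster()], [reassessUniqueness()]
#' @export
setClass("ProteinGroupSet",
    representation(
        groups = "DataFrame",
        members = "CharacterList",
        sequences = "AAStringSet",
        threshold = "numeric"
    )
)

setValidity("ProteinGroupSet", function(object) {
    msg <- character()
    g <- object@groups
    need <- c("group_id", "seed_id", "seed_length", "taxon", "n_members")
    if (!all(need %in% colnames(g)))
        return("groups must have columns group_id, seed_id, seed_length, taxon, n_members")
    if (length(object@members) != nrow(g))
        msg <- c(msg, "one member list per group required")
    if (nrow(g)) {
        seedInMembers <- mapply(function(s, m) s %in% m,
                                g$seed_id, as.list(object@members))
        if (!all(seedInMembers))
            msg <- c(msg, "each seed must be a member of its own group")
        w <- setNames(Biostrings::width(object@sequences),
                      names(object@sequences))
        maxMember <- vapply(as.list(object@members),
                            function(m) max(w[m]), numeric(1))
        if (any(maxMember > g$seed_length))
            msg <- c(msg, "no member may be longer than its seed")
    }
    if (length(object@threshold) != 1L ||
        object@threshold <= 0 || object@threshold > 1)
        msg <- c(msg, "threshold must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' @describeIn ProteinGroupSet-class group identifiers (seed ids).
#' @param x a \code{ProteinGroupSet}.
#' @export
setMethod("groupIds", "ProteinGroupSet", function(x) x@groups$group_id)

#' @describeIn ProteinGroupSet-class seed (longest member) identifiers.
#' @export
setMethod("seedIds", "ProteinGroupSet", function(x) x@groups$seed_id)

#' @describeIn ProteinGroupSet-class member ids per group.
#' @export
setMethod("memberIds", "ProteinGroupSet", function(x)
    setNames(x@members, x@groups$group_id))

#' @describeIn ProteinGroupSet-class seed lengths in residues.
#' @export
setMethod("seedLengths", "ProteinGroupSet", function(x)
    setNames(x@groups$seed_length, x@groups$group_id))

#' @describeIn ProteinGroupSet-class taxon label of each group's seed.
#' @export
setMethod("groupTaxa", "ProteinGroupSet", function(x)
    setNames(x@groups$taxon, x@groups$group_id))

#' @describeIn ProteinGroupSet-class the identity threshold used.
#' @export
setMethod("identityThreshold", "ProteinGroupSet", function(x) x@threshold)

#' @describeIn ProteinGroupSet-class number of groups.
#' @export
setMethod("length", "ProteinGroupSet", function(x) nrow(x@groups))

setMethod("show", "ProteinGroupSet", function(object) {
    cat("ProteinGroupSet:", nrow(object@groups), "groups over",
        length(object@sequences), "proteins at identity >=",
        object@threshold, "\n")
    if (nrow(object@groups)) {
        sz <- object@groups$n_members
        cat("  group sizes: ", paste(range(sz), collapse = "-"),
            " (multi-member: ", sum(sz > 1L), ")\n", sep = "")
    }
})

## ---------------------------------------------------------------------------
## FilterPolicy
## ---------------------------------------------------------------------------

#' Identification filter policy
#'
#' Thresholds applied after target-decoy scoring: the PSM q-value cutoff, the
#' minimum spectra per protein group, the minimum distinct peptides required
#' for an identification, the group-level evidence rule (at least two
#' distinct peptides, at least one of them unique to the group), and the
#' protein-level FDR above which the filter report raises a flag.
#'
#' @slot maxQ maximum PSM q-value retained (default 0.02).
#' @slot minSpectraPerProtein minimum spectra per retained group (default 2).
#' @slot minDistinctPeptides minimum distinct peptides per identification
#'   (default 1, permitting short/fragmented proteins at the PSM stage).
#' @slot minGroupDistinctPeptides group-level distinct-peptide rule
#'   (default 2).
#' @slot minGroupUniquePeptides group-level unique-peptide rule (default 1).
#' @slot proteinFdrReportThreshold protein-level FDR that triggers a warning
#'   flag in the report (default 0.03).
#' @seealso [filterPolicy()], [filterIdentifications()]
#' @export
setClass("FilterPolicy",
    representation(
        maxQ = "numeric",
        minSpectraPerProtein = "integer",
        minDistinctPeptides = "integer",
        minGroupDistinctPeptides = "integer",
        minGroupUniquePeptides = "integer",
        proteinFdrReportThreshold = "numeric"
    )
)

setValidity("FilterPolicy", function(object) {
    vals <- c(object@maxQ, object@minSpectraPerProtein,
              object@minDistinctPeptides, object@minGroupDistinctPeptides,
              object@minGroupUniquePeptides, object@proteinFdrReportThreshold)
    if (any(is.na(vals)) || any(vals < 0))
        "all filter thresholds must be >= 0"
    else TRUE
})

#' Create an identification filter policy
#'
#' @param maxQ,minSpectraPerProtein,minDistinctPeptides,minGroupDistinctPeptides,minGroupUniquePeptides,proteinFdrReportThreshold
#'   see [FilterPolicy-class].
#' @return A [FilterPolicy-class] object.
#' @examples
#' filterPolicy()
#' filterPolicy(maxQ = 0.01)
#' @export
filterPolicy <- function(maxQ = 0.02,
                         minSpectraPerProtein = 2L,
                         minDistinctPeptides = 1L,
                         minGroupDistinctPeptides = 2L,
                         minGroupUniquePeptides = 1L,
                         proteinFdrReportThreshold = 0.03) {
    new("FilterPolicy",
        maxQ = as.numeric(maxQ),
        minSpectraPerProtein = as.integer(minSpectraPerProtein),
        minDistinctPeptides = as.integer(minDistinctPeptides),
        minGroupDistinctPeptides = as.integer(minGroupDistinctPeptides),
        minGroupUniquePeptides = as.integer(minGroupUniquePeptides),
        proteinFdrReportThreshold = as.numeric(proteinFdrReportThreshold))
}

setMethod("show", "FilterPolicy", function(object) {
    cat("FilterPolicy: q <=", object@maxQ,
        "| spectra >=", object@minSpectraPerProtein,
        "| distinct >=", max(object@minDistinctPeptides,
                             object@minGroupDistinctPeptides),
        "| unique >=", object@minGroupUniquePeptides,
        "| FDR flag >", object@proteinFdrReportThreshold, "\n")
})

## ---------------------------------------------------------------------------
## QuantMatrix
## ---------------------------------------------------------------------------

#' Protein-group x sample matrix of normalized spectral counts
#'
#' A \code{SummarizedExperiment} holding the \code{"nspc"} assay (normalized
#' spectral counts) and the \code{"spc"} assay (balanced spectral counts).
#' Rows are protein groups with taxon label, seed length and a flag marking
#' membership in the normalization universe; columns are samples. The
#' normalization guarantees that, per sample, nSpC summed over the universe
#' equals 1 (\code{"fraction"} scale) or 10,000 (\code{"per_10000"} scale).
#'
#' @seealso [computeNSpC()], [taxonFractions()]
#' @export
setClass("QuantMatrix", contains = "SummarizedExperiment")

setValidity("QuantMatrix", function(object) {
    msg <- character()
    if (!"nspc" %in% SummarizedExperiment::assayNames(object))
        return("assay 'nspc' is required")
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("taxon", "seed_length", "in_universe") %in% colnames(rd)))
        return("rowData needs columns taxon, seed_length, in_universe")
    md <- metadata(object)
    if (is.null(md$scale) || !md$scale %in% c("fraction", "per_10000"))
        msg <- c(msg, "metadata scale must be 'fraction' or 'per_10000'")
    else {
        expectedSum <- if (md$scale == "per_10000") 10000 else 1
        m <- SummarizedExperiment::assay(object, "nspc")
        if (nrow(m) && ncol(m)) {
            s <- colSums(m[rd$in_universe, , drop = FALSE])
            bad <- s > 0 & abs(s - expectedSum) > 1e-9 * expectedSum
            if (any(bad))
                msg <- c(msg, "per-sample nSpC over the universe must sum to the scale value")
        }
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn QuantMatrix-class the normalized spectral count matrix.
#' @param x a \code{QuantMatrix}.
#' @export
setMethod("nspc", "QuantMatrix", function(x)
    SummarizedExperiment::assay(x, "nspc"))

#' @describeIn QuantMatrix-class the balanced spectral count matrix.
#' @export
setMethod("spectralCounts", "QuantMatrix", function(x)
    SummarizedExperiment::assay(x, "spc"))

#' @describeIn QuantMatrix-class reporting scale ("fraction" or "per_10000").
#' @export
setMethod("quantScale", "QuantMatrix", function(x) metadata(x)$scale)

#' @describeIn QuantMatrix-class normalization universe label.
#' @export
setMethod("quantUniverse", "QuantMatrix", function(x) metadata(x)$universe)

setMethod("show", "QuantMatrix", function(object) {
    rd <- SummarizedExperiment::rowData(object)
    cat("QuantMatrix:", nrow(object), "protein groups x", ncol(object),
        "samples\n")
    cat("  universe:", metadata(object)$universe,
        "| scale:", metadata(object)$scale, "\n")
    cat("  taxa:", paste(sprintf("%s=%d", names(table(rd$taxon)),
                                 as.integer(table(rd$taxon))),
                         collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## AnnotatedReference
## ---------------------------------------------------------------------------

#' Reference protein with annotated functional positions
#'
#' A reference sequence whose functionally relevant residue positions are
#' known: amidase active-site residues, peptidoglycan binding-groove residues
#' that set stem-peptide specificity, the sulfide-binding cysteine position of
#' annelid A2 hemoglobin chains, and conserved disulfide-bonded cysteines.
#' Queries are screened against it with [screenSites()].
#'
#' @slot id reference identifier.
#' @slot sequence amino-acid sequence (character).
#' @slot annotations \code{DataFrame} with columns \code{position} (1-based
#'   residue index), \code{role} (one of \code{active_site},
#'   \code{binding_groove}, \code{sulfide_cysteine},
#'   \code{conserved_disulfide_cysteine}) and \code{expected} (string of
#'   amino acids accepted at that position).
#' @seealso [annotatedReference()], [screenSites()], [readAnnotationTable()]
#' @export
setClass("AnnotatedReference",
    representation(
        id = "character",
        sequence = "character",
        annotations = "DataFrame"
    )
)

setValidity("AnnotatedReference", function(object) {
    msg <- character()
    ann <- object@annotations
    if (!all(c("position", "role", "expected") %in% colnames(ann)))
        return("annotations must have columns position, role, expected")
    if (nrow(ann)) {
        if (any(ann$position < 1L | ann$position > nchar(object@sequence)))
            msg <- c(msg, "annotated positions must lie within the reference sequence")
        if (!all(ann$role %in% .ROLES))
            msg <- c(msg, paste("roles must be one of:",
                                paste(.ROLES, collapse = ", ")))
        if (any(!nzchar(ann$expected)))
            msg <- c(msg, "each annotation needs a non-empty expected residue set")
    }
    if (length(msg)) msg else TRUE
})

#' Create an annotated reference protein
#'
#' @param id reference identifier.
#' @param sequence amino-acid sequence (character or \code{AAString}).
#' @param annotations data frame with columns \code{position}, \code{role}
#'   and \code{expected} (see [AnnotatedReference-class]).
#' @return An [AnnotatedReference-class] object.
#' @examples
#' ref <- annotatedReference("refA", "MHACDEYKLC",
#'     data.frame(position = c(2, 7), role = "active_site",
#'                expected = c("H", "Y")))
#' ref
#' @export
annotatedReference <- function(id, sequence, annotations) {
    ann <- DataFrame(position = as.integer(annotations$position),
                     role = as.character(annotations$role),
                     expected = toupper(as.character(annotations$expected)))
    new("AnnotatedReference", id = as.character(id),
        sequence = toupper(as.character(sequence)), annotations = ann)
}

setMethod("show", "AnnotatedReference", function(object) {
    cat("AnnotatedReference '", object@id, "': ",
        nchar(object@sequence), " aa, ",
        nrow(object@annotations), " annotated positions (",
        paste(unique(object@annotations$role), collapse = ", "), ")\n",
        sep = "")
})

## ---------------------------------------------------------------------------
## ScreenReport
## ---------------------------------------------------------------------------

#' Residue-screen report for one query protein
#'
#' Produced by [screenSites()]. Per annotation role it records how many
#' positions could be read in the query and how many matched the expected
#' residues, and derives the biological calls: whether the query retains a
#' complete amidase active site, whether its binding groove favors DAP-type
#' peptidoglycan, and whether a free (non-disulfide) cysteine sits at the
#' sulfide-binding position.
#'
#' A call is \code{"indeterminate"} exactly when at least one of its
#' positions is unmapped (falls in an alignment gap).
#'
#' @slot queryId query identifier.
#' @slot roleCounts \code{DataFrame}: per role, \code{matched},
#'   \code{mapped} and \code{total} position counts.
#' @slot amidaseCall \code{"active"}, \code{"inactive"} or
#'   \code{"indeterminate"}.
#' @slot grooveCall \code{"DAP_type"}, \code{"other"} or
#'   \code{"indeterminate"}.
#' @slot freeCysteine logical; \code{NA} when the sulfide position is
#'   unmapped.
#' @slot unmappedPositions number of annotated positions without a query
#'   residue.
#' @export
setClass("ScreenReport",
    representation(
        queryId = "character",
        roleCounts = "DataFrame",
        amidaseCall = "character",
        grooveCall = "character",
        freeCysteine = "logical",
        unmappedPositions = "integer"
    )
)

setValidity("ScreenReport", function(object) {
    rc <- object@roleCounts
    if (nrow(rc) && any(rc$matched > rc$total))
        "matched counts cannot exceed totals"
    else TRUE
})

setMethod("show", "ScreenReport", function(object) {
    cat("ScreenReport '", object@queryId, "': amidase=", object@amidaseCall,
        ", groove=", object@grooveCall,
        ", free cysteine=", object@freeCysteine,
        " (", object@unmappedPositions, " unmapped positions)\n", sep = "")
})

## ---------------------------------------------------------------------------
## SummaryStats / TTestResult
## ---------------------------------------------------------------------------

#' Per-condition summary statistics
#'
#' Mean, sample standard deviation (n-1 denominator) and replicate count, as
#' printed in condition-comparison tables; sufficient for the pooled
#' Student's t-test.
#'
#' @slot mean,sd,n summary values; \code{sd >= 0}, \code{n >= 2}.
#' @seealso [summaryStats()], [pooledTTestSummary()]
#' @export
setClass("SummaryStats",
    representation(mean = "numeric", sd = "numeric", n = "integer"))

setValidity("SummaryStats", function(object) {
    msg <- character()
    if (length(object@sd) != 1L || is.na(object@sd) || object@sd < 0)
        msg <- c(msg, "sd must be a single value >= 0")
    if (length(object@n) != 1L || is.na(object@n) || object@n < 2L)
        msg <- c(msg, "n must be >= 2")
    if (length(msg)) msg else TRUE
})

#' Create summary statistics for one condition
#'
#' @param mean condition mean.
#' @param sd sample standard deviation (n-1 denominator).
#' @param n number of replicates (>= 2).
#' @return A [SummaryStats-class] object.
#' @examples
#' summaryStats(3050.30, 421.88, 3)
#' @export
summaryStats <- function(mean, sd, n) {
    new("SummaryStats", mean = as.numeric(mean), sd = as.numeric(sd),
        n = as.integer(n))
}

setMethod("show", "SummaryStats", function(object) {
    cat(sprintf("SummaryStats: mean=%g sd=%g n=%d\n",
                object@mean, object@sd, object@n))
})

#' Two-sample pooled t-test result
#'
#' @slot t the t statistic.
#' @slot df degrees of freedom (n1 + n2 - 2).
#' @slot p two-tailed p-value.
#' @slot meanDifference difference of means (first minus second condition).
#' @seealso [pooledTTestSummary()], [compareConditions()]
#' @export
setClass("TTestResult",
    representation(t = "numeric", df = "integer", p = "numeric",
                   meanDifference = "numeric"))

setValidity("TTestResult", function(object) {
    if (length(object@p) == 1L && !is.na(object@p) &&
        (object@p < 0 || object@p > 1))
        "p must lie in [0, 1]"
    else TRUE
})

setMethod("show", "TTestResult", function(object) {
    cat(sprintf("Student's t-test: t=%.4f df=%d p=%.5g (mean difference %.4g)\n",
                object@t, object@df, object@p, object@meanDifference))
})
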