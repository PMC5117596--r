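#' @importFrom Biostrings writeXStringSet readAAStringSet
#' @importFrom jsonlite write_json read_json
NULL

#' Write / read a taxon-labeled protein FASTA
#'
#' Headers follow the \code{id|taxon} convention; on reading, the taxon (if
#' present in the header) is restored into \code{mcols}.
#'
#' @param x an \code{AAStringSet} with an optional \code{taxon} column in
#'   \code{mcols}.
#' @param path FASTA file path.
#' @return \code{writeProteinFasta} returns \code{path} invisibly;
#'   \code{readProteinFasta} returns an \code{AAStringSet}.
#' @export
writeProteinFasta <- function(x, path) {
    x <- .asAAStringSet(x)
    if (length(x) == 0L)
        stop("refusing to write an empty protein database")
    taxon <- mcols(x)$taxon
    out <- x
    if (!is.null(taxon) && !all(is.na(taxon)))
        names(out) <- paste(names(x), taxon, sep = "|")
    writeXStringSet(out, path)
    invisible(path)
}

#' @rdname writeProteinFasta
#' @export
readProteinFasta <- function(path) {
    x <- readAAStringSet(path)
    parts <- strsplit(names(x), "|", fixed = TRUE)
    if (all(lengths(parts) == 2L)) {
        names(x) <- vapply(parts, `[`, character(1), 1L)
        mcols(x)$taxon <- vapply(parts, `[`, character(1), 2L)
    }
    x
}

#' Write a synthetic fixture bundle to disk
#'
#' Materializes one simulated experiment as plain-text files: the protein
#' database FASTA (\code{id|taxon} headers), the PSM table TSV, the sample
#' design TSV, the protein-to-taxon map TSV and the ground truth JSON.
#' Scores are serialized at full double precision so that re-reading the
#' bundle reproduces the in-memory objects exactly.
#'
#' @param database taxon-labeled \code{AAStringSet}.
#' @param psms PSM data frame from [simulatePSMs()].
#' @param truth the matching [GroundTruth-class].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a named vector of the file paths written.
#' @seealso [readFixtureBundle()]
#' @export
writeFixtureBundle <- function(database, psms, truth, outdir) {
    if (length(database) == 0L)
        stop("refusing to write an empty protein database")
    stopifnot(is(truth, "GroundTruth"))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(outdir))
        stop("cannot create output directory: ", outdir)
    paths <- c(
        database = file.path(outdir, "database.faa"),
        psms = file.path(outdir, "psms.tsv"),
        design = file.path(outdir, "design.tsv"),
        taxon_map = file.path(outdir, "taxon_map.tsv"),
        truth = file.path(outdir, "truth.json"))

    writeProteinFasta(database, paths[["database"]])

    p <- psms
    p$score <- sprintf("%.17g", p$score)
    p$is_decoy <- as.integer(p$is_decoy)
    write.table(p, paths[["psms"]], sep = "\t", quote = FALSE,
                row.names = FALSE)

    smp <- as.data.frame(truth@samples)
    write.table(smp[, c("sample_id", "condition", "replicate")],
                paths[["design"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(protein_id = names(database),
                           taxon = mcols(database)$taxon),
                paths[["taxon_map"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_json(list(weights = as.data.frame(truth@weights),
                    samples = smp,
                    probs = as.data.frame(truth@probs),
                    family_map = as.data.frame(truth@familyMap)),
               paths[["truth"]], digits = NA, auto_unbox = TRUE)
    invisible(paths)
}

#' Read a fixture bundle written by [writeFixtureBundle()]
#'
#' @param outdir the bundle directory.
#' @return List with \code{database} (taxon-labeled \code{AAStringSet}),
#'   \code{psms}, \code{design}, \code{taxonMap} (data frames) and
#'   \code{truth} (a [GroundTruth-class]).
#' @export
readFixtureBundle <- function(outdir) {
    database <- readProteinFasta(file.path(outdir, "database.faa"))
    psms <- read.delim(file.path(outdir, "psms.tsv"),
                       stringsAsFactors = FALSE,
                       colClasses = c(score = "numeric"))
    psms$is_decoy <- as.logical(psms$is_decoy)
    design <- read.delim(file.path(outdir, "design.tsv"),
                         stringsAsFactors = FALSE)
    taxonMap <- read.delim(file.path(outdir, "taxon_map.tsv"),
                           stringsAsFactors = FALSE)
    tr <- read_json(file.path(outdir, "truth.json"), simplifyVector = TRUE)
    probs <- as.matrix(tr$probs)
    rownames(probs) <- tr$weights$protein_id
    truth <- new("GroundTruth",
                 weights = DataFrame(tr$weights),
                 probs = probs,
                 samples = DataFrame(tr$samples),
                 familyMap = if (length(tr$family_map))
                     DataFrame(tr$family_map)
                 else DataFrame(variant_id = character(),
                                base_id = character()))
    list(database = database, psms = psms, design = design,
         taxonMap = taxonMap, truth = truth)
}

#' Export tables
#'
#' \code{writeGroupTable} writes one row per protein group (group id, seed,
#' members, seed length, taxon); \code{writeQuantTable} writes the nSpC
#' matrix with its row annotations.
#'
#' @param groups a [ProteinGroupSet-class].
#' @param quant a [QuantMatrix-class].
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
writeGroupTable <- function(groups, path) {
    stopifnot(is(groups, "ProteinGroupSet"))
    g <- as.data.frame(groups@groups)
    g$members <- vapply(as.list(groups@members), paste,
                        character(1), collapse = ",")
    write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeGroupTable
#' @export
writeQuantTable <- function(quant, path) {
    stopifnot(is(quant, "QuantMatrix"))
    rd <- as.data.frame(SummarizedExperiment::rowData(quant))
    out <- cbind(rd[, c("group_id", "taxon", "seed_length")],
                 as.data.frame(nspc(quant)))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
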