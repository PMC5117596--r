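#' Screen a query protein against an annotated reference
#'
#' Aligns a query to an annotated reference (Needleman-Wunsch, BLOSUM62) and
#' reads off the query residues at the annotated functional positions. From
#' them it derives: the amidase call (\code{"active"} only when every
#' active-site position matches its expected residues -- loss of a single
#' active-site residue abolishes amidase activity), the binding-groove call
#' (\code{"DAP_type"} when all groove positions carry the residues favoring
#' DAP-type peptidoglycan of gram-negative bacteria), and the free-cysteine
#' flag (a cysteine at the sulfide-binding position that is not itself a
#' conserved disulfide position -- the configuration associated with
#' reversible sulfide binding in annelid hemoglobins). Any call whose
#' positions include an unmapped one (alignment gap in the query, e.g. an
#' insertion disrupting the groove region or a truncated sequence) is
#' \code{"indeterminate"}.
#'
#' @param query a single amino-acid sequence (character or \code{AAString});
#'   a name, if present, becomes the report's query id.
#' @param reference an [AnnotatedReference-class].
#' @param map optional precomputed reference-to-query position map from
#'   [alignPositions()]; computed internally when missing.
#' @param queryId identifier used in the report (defaults to the name of
#'   \code{query} or \code{"query"}).
#' @param gapOpening,gapExtension alignment penalties, as in
#'   [alignPositions()].
#' @return A [ScreenReport-class].
#' @examples
#' ref <- annotatedReference("ref", "MHACDEYKLCWWTTGGHH",
#'     data.frame(position = c(2, 7), role = "active_site",
#'                expected = c("H", "Y")))
#' screenSites("MHACDEYKLCWWTTGGHH", ref)  # identical query: active
#' @export
screenSites <- function(query, reference, map = NULL, queryId = NULL,
                        gapOpening = 10, gapExtension = 1) {
    stopifnot(is(reference, "AnnotatedReference"))
    validObject(reference)
    if (is.null(queryId))
        queryId <- if (!is.null(names(query))) names(query)[1L] else "query"
    query <- toupper(as.character(query))
    if (is.null(map))
        map <- alignPositions(query, reference@sequence,
                              gapOpening = gapOpening,
                              gapExtension = gapExtension)
    if (length(map) != nchar(reference@sequence))
        stop("position map must cover the whole reference")

    ann <- reference@annotations
    qChars <- strsplit(query, "", fixed = TRUE)[[1L]]
    qPos <- map[ann$position]
    residue <- ifelse(is.na(qPos), NA_character_, qChars[qPos])
    expectedSets <- strsplit(ann$expected, "", fixed = TRUE)
    matched <- mapply(function(r, ex) !is.na(r) && r %in% ex,
                      residue, expectedSets)

    roleCall <- function(role) {
        sel <- ann$role == role
        if (!any(sel)) return("indeterminate")
        if (any(is.na(residue[sel]))) return("indeterminate")
        if (all(matched[sel])) "all_matched" else "mismatch"
    }
    amidase <- switch(roleCall("active_site"),
                      all_matched = "active", mismatch = "inactive",
                      indeterminate = "indeterminate")
    groove <- switch(roleCall("binding_groove"),
                     all_matched = "DAP_type", mismatch = "other",
                     indeterminate = "indeterminate")

    sulfSel <- ann$role == "sulfide_cysteine"
    disulfPos <- ann$position[ann$role == "conserved_disulfide_cysteine"]
    freeCys <- FALSE
    if (any(sulfSel)) {
        if (any(is.na(residue[sulfSel])))
            freeCys <- NA
        else
            freeCys <- all(residue[sulfSel] == "C" &
                           !(ann$position[sulfSel] %in% disulfPos))
    }

    rc <- do.call(rbind, lapply(unique(ann$role), function(role) {
        sel <- ann$role == role
        DataFrame(role = role,
                  matched = sum(matched[sel] & !is.na(residue[sel])),
                  mapped = sum(!is.na(residue[sel])),
                  total = sum(sel))
    }))
    if (is.null(rc))
        rc <- DataFrame(role = character(), matched = integer(),
                        mapped = integer(), total = integer())

    new("ScreenReport", queryId = as.character(queryId), roleCounts = rc,
        amidaseCall = amidase, grooveCall = groove,
        freeCysteine = freeCys,
        unmappedPositions = sum(is.na(qPos)))
}

#' Screen many queries and tabulate the calls
#'
#' Convenience wrapper running [screenSites()] for every query and returning
#' one row per query.
#'
#' @param queries named character vector or \code{AAStringSet}.
#' @param reference an [AnnotatedReference-class].
#' @param ... passed to [screenSites()].
#' @return Data frame with columns \code{query_id}, \code{amidase},
#'   \code{groove}, \code{free_cysteine} and \code{unmapped_positions}.
#' @export
screenQueries <- function(queries, reference, ...) {
    queries <- as.character(Biostrings::AAStringSet(queries))
    if (is.null(names(queries)))
        names(queries) <- sprintf("query_%d", seq_along(queries))
    reports <- lapply(names(queries), function(id)
        screenSites(queries[[id]], reference, queryId = id, ...))
    data.frame(
        query_id = vapply(reports, function(r) r@queryId, character(1)),
        amidase = vapply(reports, function(r) r@amidaseCall, character(1)),
        groove = vapply(reports, function(r) r@grooveCall, character(1)),
        free_cysteine = vapply(reports, function(r) r@freeCysteine, logical(1)),
        unmapped_positions = vapply(reports, function(r)
            r@unmappedPositions, integer(1)),
        stringsAsFactors = FALSE)
}

#' Read a residue-annotation table
#'
#' Reads a tab-separated annotation file with columns \code{ref_id},
#' \code{position}, \code{role} and \code{expected_residues} and builds one
#' [AnnotatedReference-class] per reference sequence. Annotation files are
#' user data: the functionally validated positions come from curated
#' alignments of experimentally characterized proteins, and the package
#' ships only synthetic examples for testing and documentation.
#'
#' @param path annotation TSV.
#' @param references named character vector or \code{AAStringSet} of
#'   reference sequences covering every \code{ref_id} in the file.
#' @return Named list of [AnnotatedReference-class] objects.
#' @export
readAnnotationTable <- function(path, references) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("ref_id", "position", "role", "expected_residues")
    if (!all(need %in% colnames(tab)))
        stop("annotation table needs columns: ", paste(need, collapse = ", "))
    references <- as.character(Biostrings::AAStringSet(references))
    missing <- setdiff(unique(tab$ref_id), names(references))
    if (length(missing))
        stop("no reference sequence for: ", paste(missing, collapse = ", "))
    lapply(split(tab, tab$ref_id), function(d)
        annotatedReference(d$ref_id[1L], references[[d$ref_id[1L]]],
                           data.frame(position = d$position, role = d$role,
                                      expected = d$expected_residues)))
}
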