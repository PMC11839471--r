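#' Read a GCT 1.2 expression matrix
#'
#' Parses the two-header-line GCT dialect used by the CCLE RPKM release:
#' line 1 the version token `#1.2`, line 2 the row/column counts, then a
#' table with `Name` and `Description` columns followed by one column per
#' sample.  `Description` is taken as the gene symbol (empty -> `NA`).
#' GCT 1.3 and any other version token are rejected.
#'
#' @param path path to a GCT 1.2 file.
#' @param scaleTag scale of the stored values; the CCLE file is raw RPKM
#'   (the default).
#' @return an [ExpressionMatrix-class].
#' @seealso [writeGCT()]
#' @export
readGCT <- function(path, scaleTag = "rpkm") {
    if (!file.exists(path)) stop("GCT file not found: ", path)
    head2 <- readLines(path, n = 2L)
    if (length(head2) < 2L)
        stop("not a GCT file (fewer than 2 header lines): ", path)
    version <- trimws(head2[1L])
    if (!identical(version, "#1.2"))
        stop("unsupported GCT version token ", sQuote(version),
             "; only GCT 1.2 is supported (1.3 is rejected)")
    dims <- suppressWarnings(as.integer(strsplit(head2[2L], "\t")[[1]][1:2]))
    if (any(is.na(dims)) || any(dims < 0))
        stop("malformed GCT dimensions line: ", sQuote(head2[2L]))
    tab <- utils::read.delim(path, skip = 2L, header = TRUE,
                             check.names = FALSE, quote = "",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    if (!all(c("Name", "Description") %in% colnames(tab)[1:2]))
        stop("GCT data header must start with Name and Description columns")
    if (nrow(tab) != dims[1L])
        stop(sprintf("GCT declares %d rows but body has %d", dims[1L],
                     nrow(tab)))
    if (ncol(tab) - 2L != dims[2L])
        stop(sprintf("GCT declares %d samples but body has %d", dims[2L],
                     ncol(tab) - 2L))
    if (anyDuplicated(tab$Name))
        stop("duplicate feature ids in GCT: ",
             paste(unique(tab$Name[duplicated(tab$Name)]), collapse = ", "))
    vals <- as.matrix(tab[, -(1:2), drop = FALSE])
    suppressWarnings(storage.mode(vals) <- "double")
    if (anyNA(vals) )
        stop("non-numeric expression values in GCT body")
    rownames(vals) <- tab$Name
    sym <- tab$Description
    sym[!nzchar(sym)] <- NA_character_
    ExpressionMatrix(vals, scaleTag = scaleTag, geneSymbols = sym)
}

#' Write an ExpressionMatrix as GCT 1.2
#'
#' Inverse of [readGCT()]; feature order, sample order and values (to full
#' double precision) round-trip.
#'
#' @param m an [ExpressionMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGCT <- function(m, path) {
    stopifnot(methods::is(m, "ExpressionMatrix"))
    v <- exprValues(m)
    sym <- geneSymbols(m)
    sym[is.na(sym)] <- ""
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t")), con)
    tab <- data.frame(Name = rownames(v), Description = sym, v,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a cell-line annotation table
#'
#' Tab-delimited with a header; column names are configurable because
#' annotation releases differ.  Rows duplicated with the same label are
#' deduplicated; the same cell line with conflicting labels is an error.
#'
#' @param path path to the annotation TSV.
#' @param idColumn,typeColumn header names of the cell-line-id and
#'   cancer-type columns.
#' @return named character vector: sample id -> cancer type.
#' @export
readLabels <- function(path, idColumn = "cell_line",
                       typeColumn = "cancer_type") {
    if (!file.exists(path)) stop("annotation file not found: ", path)
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             quote = "", stringsAsFactors = FALSE)
    for (col in c(idColumn, typeColumn))
        if (!col %in% colnames(tab))
            stop("annotation table lacks column ", sQuote(col))
    tab <- unique(tab[, c(idColumn, typeColumn)])
    dup <- tab[[idColumn]][duplicated(tab[[idColumn]])]
    if (length(dup))
        stop("conflicting cancer-type labels for: ",
             paste(unique(dup), collapse = ", "))
    lab <- stats::setNames(as.character(tab[[typeColumn]]),
                           as.character(tab[[idColumn]]))
    if (any(is.na(lab) | !nzchar(lab)))
        stop("empty cancer-type labels for: ",
             paste(names(lab)[is.na(lab) | !nzchar(lab)], collapse = ", "))
    lab
}

#' Read a GMT gene-set file
#'
#' One pathway per line: name, description, then one or more gene symbols,
#' tab-separated.  Symbols are upper-cased.
#'
#' @param path path to a GMT file.
#' @return a [PathwayDB-class].
#' @export
readGMT <- function(path) {
    if (!file.exists(path)) stop("GMT file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short))
        stop("GMT lines with fewer than 3 fields: line ",
             paste(short, collapse = ", "))
    ids <- vapply(fields, `[[`, character(1), 1L)
    if (anyDuplicated(ids))
        stop("duplicate pathway ids in GMT: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    sets <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
    names(sets) <- ids
    PathwayDB(sets, vapply(fields, `[[`, character(1), 2L))
}

#' Write a PathwayDB as GMT
#'
#' @param db a [PathwayDB-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(db, path) {
    stopifnot(methods::is(db, "PathwayDB"))
    lines <- vapply(pathwayIds(db), function(id)
        paste(c(id, db@descriptions[[id]], db@sets[[id]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a long-format drug-target table
#'
#' Two named columns (drug id, target gene symbol); multiple rows per drug
#' accumulate into its target set.  Concatenations of several sources are
#' fine: duplicate (drug, gene) pairs are collapsed.
#'
#' @param path path to the TSV.
#' @param drugColumn,geneColumn header names.
#' @return a [DrugTargetMap-class].
#' @export
readDrugTargets <- function(path, drugColumn = "drug_id",
                            geneColumn = "gene_symbol") {
    if (!file.exists(path)) stop("drug-target file not found: ", path)
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             quote = "", stringsAsFactors = FALSE)
    for (col in c(drugColumn, geneColumn))
        if (!col %in% colnames(tab))
            stop("drug-target table lacks column ", sQuote(col))
    DrugTargetMap(split(as.character(tab[[geneColumn]]),
                        as.character(tab[[drugColumn]])))
}

#' Read an mnAUC table
#'
#' mnAUC is the mean normalized area under the dose-response curve: the
#' average fraction of cells surviving drug exposure across cell lines
#' (lower = more potent).  One row per drug.
#'
#' @param path path to the TSV.
#' @param drugColumn,valueColumn header names.
#' @return named numeric vector: drug id -> mnAUC.
#' @export
readMnAUC <- function(path, drugColumn = "drug_id", valueColumn = "mnauc") {
    if (!file.exists(path)) stop("mnAUC file not found: ", path)
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             quote = "", stringsAsFactors = FALSE)
    for (col in c(drugColumn, valueColumn))
        if (!col %in% colnames(tab))
            stop("mnAUC table lacks column ", sQuote(col))
    val <- suppressWarnings(as.numeric(tab[[valueColumn]]))
    bad <- is.na(val) & !is.na(tab[[valueColumn]])
    if (any(bad) || anyNA(val))
        stop("non-numeric mnAUC values for: ",
             paste(tab[[drugColumn]][is.na(val)], collapse = ", "))
    if (anyDuplicated(tab[[drugColumn]]))
        stop("duplicate drug ids in mnAUC table")
    stats::setNames(val, as.character(tab[[drugColumn]]))
}

#' Read an approved drug--cancer-type table
#'
#' @param path path to the TSV.
#' @param drugColumn,typeColumn header names.
#' @return data.frame with columns `drug_id`, `cancer_type` (unique pairs).
#' @export
readApprovedPairs <- function(path, drugColumn = "drug_id",
                              typeColumn = "cancer_type") {
    if (!file.exists(path)) stop("approved-pairs file not found: ", path)
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             quote = "", stringsAsFactors = FALSE)
    for (col in c(drugColumn, typeColumn))
        if (!col %in% colnames(tab))
            stop("approved-pairs table lacks column ", sQuote(col))
    out <- unique(data.frame(drug_id = as.character(tab[[drugColumn]]),
                             cancer_type = as.character(tab[[typeColumn]]),
                             stringsAsFactors = FALSE))
    rownames(out) <- NULL
    out
}

#' Read a log2 protein quantification matrix
#'
#' Tab-delimited: first column the protein identifier (a gene symbol), the
#' remaining columns one per cell line.  Values are already log2 scale;
#' empty fields or `NA` are stored as missing and excluded pairwise by the
#' statistics downstream.
#'
#' @param path path to the TSV.
#' @return a log2-scale [ExpressionMatrix-class] whose gene symbols are the
#'   (upper-cased) row identifiers.
#' @export
readProteinMatrix <- function(path) {
    if (!file.exists(path)) stop("protein matrix file not found: ", path)
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             quote = "", stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
    ids <- as.character(tab[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate protein ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    suppressWarnings(storage.mode(vals) <- "double")
    rownames(vals) <- ids
    ExpressionMatrix(vals, scaleTag = "log2", geneSymbols = ids)
}

# Align a label map to a matrix's samples; unlabelled samples are reported
# (warning) and dropped rather than silently ignored.
alignLabels <- function(m, labels) {
    ids <- colnames(m)
    missing <- setdiff(ids, names(labels))
    if (length(missing))
        warning("samples without a cancer-type label (dropped): ",
                paste(missing, collapse = ", "))
    keep <- intersect(ids, names(labels))
    if (!length(keep)) stop("no labelled samples in the matrix")
    labels[keep]
}
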