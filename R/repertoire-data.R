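#' Read an AIRR-style rearrangement table
#'
#' Reads a delimited rearrangement file (one row per sequence or clone, header
#' row with named columns such as \code{v_call}, \code{d_call}, \code{j_call})
#' and keeps the repertoire identifier column plus the requested gene-call
#' columns. Rows with empty feature values are retained; they are filtered
#' during tabulation.
#'
#' @param path path to the file.
#' @param idColumn name of the column holding the repertoire/sample id.
#' @param featureColumns character vector of gene-call columns to keep.
#' @param delim field delimiter; tab by default, per AIRR rearrangement
#'   conventions.
#' @return a \code{data.frame} (all character columns) with \code{idColumn}
#'   first and the requested feature columns; attribute \code{"idColumn"}
#'   records the id column name.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("repertoire_id\tv_call",
#'              "s1\tIGHV1-2*02",
#'              "s2\tIGHV3-23*01"), tsv)
#' readAIRR(tsv)
#' @export
readAIRR <- function(path, idColumn = "repertoire_id",
                     featureColumns = "v_call", delim = "\t") {
    if (!file.exists(path))
        stop("input file not found: ", path)
    nf <- count.fields(path, sep = delim, quote = "", comment.char = "")
    nf <- nf[!is.na(nf)]
    if (length(nf) && length(unique(nf)) > 1L) {
        bad <- which(nf != nf[1L])[1L]
        stop("ragged row in ", path, ": line ", bad, " has ", nf[bad],
             " fields, expected ", nf[1L])
    }
    tab <- read.delim(path, sep = delim, header = TRUE,
        colClasses = "character", check.names = FALSE, quote = "",
        comment.char = "", stringsAsFactors = FALSE)
    missing <- setdiff(c(idColumn, featureColumns), names(tab))
    if (length(missing))
        stop("column(s) not present in ", path, ": ",
             paste(missing, collapse = ", "))
    if (any(!nzchar(tab[[idColumn]])))
        stop("empty repertoire id in column '", idColumn, "'")
    out <- tab[, c(idColumn, featureColumns), drop = FALSE]
    attr(out, "idColumn") <- idColumn
    out
}

#' Collapse IMGT-style gene calls to allele, gene or family level
#'
#' Normalizes raw gene-call strings such as \code{"IGHV1-2*02"} before
#' tabulation. At \code{"allele"} level the call is returned unchanged; at
#' \code{"gene"} level the allele suffix (\code{*NN}) is stripped; at
#' \code{"family"} level the text up to the first \code{"-"} of the gene token
#' is kept (the whole gene token if it has no \code{"-"}). Multi-assignment
#' strings (comma-separated candidates) resolve to the first listed call when
#' all candidates agree after collapsing; when the candidates disagree at the
#' requested level the call is ambiguous and \code{NA} is returned, so that
#' downstream counts stay integral. Empty or whitespace input gives \code{NA}.
#'
#' @param calls character vector of raw calls.
#' @param level \code{"allele"}, \code{"gene"} or \code{"family"}.
#' @return character vector of collapsed calls, \code{NA} where unresolvable.
#' @examples
#' collapseGeneCall("IGHV1-2*02", "gene")                  # "IGHV1-2"
#' collapseGeneCall("IGHV1-2*02,IGHV1-2*04", "gene")       # "IGHV1-2"
#' collapseGeneCall("IGHV1-2*02,IGHV3-23*01", "gene")      # NA (ambiguous)
#' collapseGeneCall("TRBV5-1*01", "family")                # "TRBV5"
#' @export
collapseGeneCall <- function(calls, level = c("allele", "gene", "family")) {
    level <- match.arg(level)
    vapply(as.character(calls), function(call) {
        if (is.na(call)) return(NA_character_)
        cands <- trimws(strsplit(call, ",", fixed = TRUE)[[1L]])
        cands <- cands[nzchar(cands)]
        if (!length(cands)) return(NA_character_)
        collapsed <- vapply(cands, .collapseOne, character(1L), level = level)
        if (length(unique(collapsed)) > 1L) return(NA_character_)
        collapsed[[1L]]
    }, character(1L), USE.NAMES = FALSE)
}

.collapseOne <- function(call, level) {
    if (level == "allele") return(call)
    gene <- sub("\\*.*$", "", call)
    if (level == "gene") return(gene)
    sub("-.*$", "", gene)
}

#' Tabulate per-repertoire feature counts
#'
#' Collapses the gene calls of an annotation table at the requested level and
#' counts, for every repertoire, how many records carry each collapsed
#' feature. Records whose call is unresolvable (ambiguous multi-assignment or
#' empty) are dropped. The feature universe is the union of features observed
#' across all repertoires, sorted lexicographically; a feature absent from a
#' repertoire is an explicit zero.
#'
#' @param table a \code{data.frame} as returned by \code{\link{readAIRR}}.
#' @param featureColumn name of the gene-call column to tabulate.
#' @param level collapsing level, see \code{\link{collapseGeneCall}}.
#' @param idColumn repertoire id column; defaults to the attribute recorded by
#'   \code{\link{readAIRR}}, falling back to \code{"repertoire_id"}.
#' @return a \code{\linkS4class{RepertoireCounts}} object. A repertoire with
#'   no usable record is retained as an all-zero column with a warning (it is
#'   rejected later by \code{\link{calcRDI}}).
#' @examples
#' tab <- data.frame(repertoire_id = c("a", "a", "a", "b"),
#'     v_call = c("V1*01", "V1*02", "V2*01", "V2*01"))
#' featureCounts(tabulateFeatures(tab, "v_call", level = "gene"))
#' @export
tabulateFeatures <- function(table, featureColumn = "v_call",
                             level = c("gene", "allele", "family"),
                             idColumn = NULL) {
    level <- match.arg(level)
    if (is.null(idColumn))
        idColumn <- attr(table, "idColumn")
    if (is.null(idColumn))
        idColumn <- "repertoire_id"
    if (!featureColumn %in% names(table))
        stop("feature column '", featureColumn, "' not present")
    if (!idColumn %in% names(table))
        stop("id column '", idColumn, "' not present")
    ids <- as.character(table[[idColumn]])
    feats <- collapseGeneCall(table[[featureColumn]], level)
    keep <- !is.na(feats)
    repLevels <- unique(ids)
    featLevels <- sort(unique(feats[keep]))
    if (!length(featLevels))
        featLevels <- character(0)
    counts <- table(factor(feats[keep], levels = featLevels),
                    factor(ids[keep], levels = repLevels))
    counts <- matrix(as.integer(counts), nrow = length(featLevels),
        dimnames = list(featLevels, repLevels))
    zero <- colSums(counts) == 0L
    if (any(zero))
        warning("repertoire(s) with no resolvable ", featureColumn,
                " call: ", paste(repLevels[zero], collapse = ", "))
    RepertoireCounts(counts,
        featureName = paste(sub("_call$", "", featureColumn), level,
                            sep = "_"))
}

#' Read and write the count-table interchange CSV
#'
#' The interchange format is a CSV with \code{repertoire_id} as first column
#' and one column per feature label, one row per repertoire.
#'
#' @param x a \code{\linkS4class{RepertoireCounts}} object.
#' @param path output (or input) file path.
#' @param featureName feature-axis label to record when reading.
#' @return \code{writeFeatureCounts} returns \code{path} invisibly;
#'   \code{readFeatureCounts} returns a \code{RepertoireCounts}.
#' @export
writeFeatureCounts <- function(x, path) {
    m <- t(featureCounts(x))
    df <- data.frame(repertoire_id = rownames(m), m, check.names = FALSE,
        row.names = NULL)
    write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeFeatureCounts
#' @export
readFeatureCounts <- function(path, featureName = "feature") {
    if (!file.exists(path))
        stop("input file not found: ", path)
    df <- read.delim(path, sep = ",", header = TRUE, check.names = FALSE,
        stringsAsFactors = FALSE)
    if (names(df)[1L] != "repertoire_id")
        stop("first column of ", path, " must be 'repertoire_id'")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$repertoire_id
    RepertoireCounts(m, featureName = featureName, repertoiresAsRows = TRUE)
}
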