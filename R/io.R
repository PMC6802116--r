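#' Read a non-negative features x samples matrix
#'
#' Supported dialects: \code{tsv} (first column = feature identifiers,
#' header row = sample identifiers), \code{gct} (GCT 1.2, read-only)
#' and \code{mtx} (MatrixMarket triplets with sidecar identifier files
#' \code{<prefix>.rows.txt} / \code{<prefix>.cols.txt}, one identifier
#' per line). Negative entries, duplicated identifiers and empty
#' matrices are rejected.
#'
#' @param path path to the matrix file.
#' @param format one of \code{"tsv"}, \code{"gct"}, \code{"mtx"};
#'   guessed from the file extension by default.
#' @return A numeric matrix with feature row names and sample column
#'   names.
#' @seealso [writeMatrix()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6, 3, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' writeMatrix(m, f)
#' all.equal(readMatrix(f), m + 0)
readMatrix <- function(path, format = c("auto", "tsv", "gct", "mtx")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, gct = "gct", mtx = "mtx", "tsv")
    }
    m <- switch(format,
        tsv = readTsvMatrix(path),
        gct = readGctMatrix(path),
        mtx = readMtxMatrix(path))
    validateNonNegative(m, what = basename(path))
    m
}

readTsvMatrix <- function(path) {
    d <- read.delim(path, header = TRUE, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(d) < 2L) stop("TSV must have a feature-id column plus data")
    ids <- as.character(d[[1L]])
    if (anyDuplicated(ids))
        stop(basename(path), " has duplicated feature identifiers")
    m <- as.matrix(d[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    # [.data.frame silently uniquifies duplicated sample names;
    # restore the originals so validation can reject them
    colnames(m) <- colnames(d)[-1L]
    rownames(m) <- ids
    m
}

readGctMatrix <- function(path) {
    lines <- readLines(path, n = 2L)
    if (!grepl("^#1\\.2", lines[1L]))
        stop("only GCT 1.2 is supported")
    d <- read.delim(path, skip = 2L, header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(d[[1L]])
    if (anyDuplicated(ids))
        stop(basename(path), " has duplicated feature identifiers")
    m <- as.matrix(d[, -(1:2), drop = FALSE])
    storage.mode(m) <- "double"
    colnames(m) <- colnames(d)[-(1:2)]
    rownames(m) <- ids
    m
}

readMtxMatrix <- function(path) {
    prefix <- sub("\\.mtx$", "", path)
    rf <- paste0(prefix, ".rows.txt")
    cf <- paste0(prefix, ".cols.txt")
    if (!file.exists(rf) || !file.exists(cf))
        stop("mtx sidecar files not found: ", rf, " / ", cf)
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(rf)
    colnames(m) <- readLines(cf)
    m
}

#' Write a matrix as TSV
#'
#' Writes with feature identifiers in the first column (named
#' \code{feature}) and sample identifiers as the header.
#' \code{digits = NA} writes full \code{\%.17g} precision so the
#' values round-trip bit-exactly through [readMatrix()].
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param digits significant digits, or \code{NA} for full precision.
#' @return Invisibly, \code{path}.
#' @export
writeMatrix <- function(m, path, digits = NA) {
    stopifnot(is.matrix(m))
    if (is.null(rownames(m)))
        rownames(m) <- paste0("f", seq_len(nrow(m)))
    if (is.null(colnames(m)))
        colnames(m) <- paste0("s", seq_len(ncol(m)))
    fmt <- if (is.na(digits)) "%.17g" else paste0("%.", digits, "g")
    txt <- apply(m, 1L, function(r) paste(sprintf(fmt, r),
                                          collapse = "\t"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("feature", colnames(m)), collapse = "\t"), con)
    writeLines(paste(rownames(m), txt, sep = "\t"), con)
    invisible(path)
}

#' Read and write GMT gene-set files
#'
#' One set per line: name, description, then member genes,
#' tab-separated.
#'
#' @param path GMT file path.
#' @return \code{readGmt}: a named list of character vectors.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(strsplit(lines, "\t"), function(x) unique(x[-(1:2)]))
    names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1L)
    sets
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], descriptions[i], sets[[i]]),
              collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}
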