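#' Read a gene-expression matrix from delimited text
#'
#' Expects a header row of condition names and a first column of gene
#' identifiers.  The matrix must have at least 2 genes and at least 3
#' conditions (3 conditions are the minimum for the pair-column
#' combinatorics of the behavior matrix to be non-degenerate), and
#' identifiers must be unique.  Values must be finite numbers; with
#' \code{impute = TRUE} missing or non-numeric cells are replaced by the
#' mean of the remaining finite values in their row.
#'
#' @param path path to the TSV/CSV file.
#' @param sep field separator; tab by default.
#' @param impute replace non-finite cells by the row mean instead of
#'   raising an error.
#' @return numeric matrix with gene identifiers as rownames and condition
#'   identifiers as colnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tc1\tc2\tc3", "g1\t1\t2\t3", "g2\t3\t1\t2"), tf)
#' M <- readExpressionMatrix(tf)
#' dim(M)
#' @export
readExpressionMatrix <- function(path, sep = "\t", impute = FALSE) {
  if (!file.exists(path))
    stop("expression matrix file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L)
    stop("dimension error: expected a gene-id column plus condition columns")
  geneIds <- df[[1L]]
  condIds <- colnames(df)[-1L]
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df)))
  )
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L)
  dimnames(vals) <- list(geneIds, condIds)
  if (impute) {
    bad <- !is.finite(vals)
    if (any(bad)) {
      rm <- rowMeans(vals, na.rm = TRUE)
      if (any(!is.finite(rm[rowSums(bad) > 0])))
        stop("parse error: a row has no finite values to impute from")
      vals[bad] <- rm[row(vals)[bad]]
    }
  } else if (!all(is.finite(vals))) {
    stop("parse error: non-numeric or missing cell ",
         "(use impute = TRUE for row-mean imputation)")
  }
  validateExpressionMatrix(vals)
}

#' Validate an expression matrix
#'
#' Checks the invariants required by the PDNS pipeline: a numeric matrix
#' with n >= 2 genes, m >= 3 conditions, unique row and column
#' identifiers and no non-finite entries.
#'
#' @param M numeric matrix with rownames (gene ids) and colnames
#'   (condition ids).
#' @return \code{M}, invisibly unchanged, if valid; otherwise an error.
#' @export
validateExpressionMatrix <- function(M) {
  if (!is.matrix(M) || !is.numeric(M))
    stop("format error: expression data must be a numeric matrix")
  if (nrow(M) < 2L)
    stop("dimension error: need at least 2 genes, got ", nrow(M))
  if (ncol(M) < 3L)
    stop("dimension error: need at least 3 conditions, got ", ncol(M))
  if (is.null(rownames(M)) || is.null(colnames(M)))
    stop("format error: gene and condition identifiers are required")
  if (anyDuplicated(rownames(M)))
    stop("format error: duplicate gene identifier")
  if (anyDuplicated(colnames(M)))
    stop("format error: duplicate condition identifier")
  if (!all(is.finite(M)))
    stop("format error: non-finite entries in expression matrix")
  M
}

#' Construct a bicluster from index vectors
#'
#' @param genes integer vector of gene row indices.
#' @param conditions integer vector of condition column indices.
#' @param asr optional ASR score in [-1, 1]; \code{NA} when unscored.
#' @return a [Bicluster-class]
#' @export
bicluster <- function(genes, conditions, asr = NA_real_) {
  new("Bicluster",
      genes = sort(unique(as.integer(genes))),
      conditions = sort(unique(as.integer(conditions))),
      asr = as.numeric(asr))
}

.resolveIds <- function(ids, universe, what) {
  idx <- match(ids, universe)
  if (anyNA(idx))
    stop("resolution error: unknown ", what, ": ",
         paste(ids[is.na(idx)], collapse = ", "))
  sort(unique(idx))
}

#' Write biclusters to JSON or BicAT-like text
#'
#' JSON output is an array of records with \code{gene_ids},
#' \code{condition_ids}, \code{asr} and a \code{provenance} block.  The
#' BicAT-like text format emits, per bicluster, one line of
#' space-separated gene ids, one line of condition ids, and a blank
#' separator line.
#'
#' @param biclusters list of [Bicluster-class] objects (may be empty).
#' @param path output file path.
#' @param M the expression matrix the indices refer to (for identifier
#'   resolution).
#' @param format `"json"` or `"bicat"`.
#' @param provenance named list recorded verbatim in each JSON record
#'   (typically seed and parameters).
#' @return invisibly, \code{path}.
#' @export
writeBiclusters <- function(biclusters, path, M,
                            format = c("json", "bicat"),
                            provenance = list()) {
  format <- match.arg(format)
  stopifnot(is.list(biclusters))
  if (format == "json") {
    recs <- lapply(biclusters, function(b) {
      list(
        gene_ids = rownames(M)[b@genes],
        condition_ids = colnames(M)[b@conditions],
        asr = if (is.na(b@asr)) NULL else b@asr,
        provenance = provenance
      )
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (b in biclusters) {
      writeLines(paste(rownames(M)[b@genes], collapse = " "), con)
      writeLines(paste(colnames(M)[b@conditions], collapse = " "), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Read a bicluster seed from file
#'
#' Accepts either the JSON schema written by [writeBiclusters()] (the
#' first record is used) or a two-line plain-text format: first line
#' space-separated gene ids, second line space-separated condition ids.
#' Identifiers are resolved against \code{M}; unknown identifiers are an
#' error.
#'
#' @param path input file.
#' @param M expression matrix used to resolve identifiers to indices.
#' @return a [Bicluster-class]
#' @export
readBicluster <- function(path, M) {
  if (!file.exists(path))
    stop("bicluster file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  first <- trimws(txt[nzchar(trimws(txt))][1])
  if (startsWith(first, "[") || startsWith(first, "{")) {
    recs <- jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
    if (length(recs) == 0L)
      stop("format error: empty bicluster JSON")
    rec <- if (!is.null(recs$gene_ids)) recs else recs[[1L]]
    geneIds <- unlist(rec$gene_ids)
    condIds <- unlist(rec$condition_ids)
  } else {
    lines <- txt[nzchar(trimws(txt))]
    if (length(lines) < 2L)
      stop("format error: expected a gene-id line and a condition-id line")
    geneIds <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
    condIds <- strsplit(trimws(lines[2L]), "[[:space:]]+")[[1L]]
  }
  bicluster(.resolveIds(geneIds, rownames(M), "gene identifier"),
            .resolveIds(condIds, colnames(M), "condition identifier"))
}
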