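## File I/O: tab-separated matrices and tables, BED/GFF3 intervals.
## Internal coordinates are 0-based half-open; BED shares that convention,
## GFF3 is converted from/to 1-based closed on the way in/out.

#' Read a tab-separated numeric matrix
#'
#' First column holds row ids, remaining columns are numeric; `NA` encodes
#' missing.
#'
#' @param path File path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1L]]
  m
}

#' Write a matrix as a tab-separated file
#'
#' @param m Matrix with dimnames.
#' @param path File path.
#' @param id_name Header for the row-id column.
#' @export
write_matrix_tsv <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a plain tab-separated table
#'
#' @param path File path.
#' @return Data.frame.
#' @export
read_tsv_table <- function(path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)

#' @rdname read_tsv_table
#' @param df Data.frame to write.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read interval annotations from BED or GFF3
#'
#' BED is kept 0-based half-open as-is; GFF3 start coordinates are shifted
#' to the internal 0-based half-open convention. GFF3 attributes `ID` (or
#' `Name`) populate the id column.
#'
#' @param path File path ending in `.bed`, `.gff`, `.gff3` or `.gtf`.
#' @param id_name Name for the id column of the result (e.g. `"te_id"`).
#' @return Data.frame with `<id_name>`, `contig`, `start`, `end`, `strand`.
#' @export
read_intervals <- function(path, id_name = "id") {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    out <- data.frame(id = if (ncol(df) >= 4) df[[4L]] else
                        sprintf("feat_%05d", seq_len(nrow(df))),
                      contig = df[[1L]], start = df[[2L]], end = df[[3L]],
                      strand = if (ncol(df) >= 6) df[[6L]] else ".",
                      stringsAsFactors = FALSE)
  } else if (ext %in% c("gff", "gff3", "gtf")) {
    gr <- rtracklayer::import(path)
    md <- S4Vectors::mcols(gr)
    id <- if (!is.null(md$ID)) as.character(md$ID)
          else if (!is.null(md$Name)) as.character(md$Name)
          else sprintf("feat_%05d", seq_along(gr))
    out <- data.frame(id = id,
                      contig = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
    out$strand[out$strand == "*"] <- "."
  } else stop("unsupported interval format: .", ext, call. = FALSE)
  names(out)[1L] <- id_name
  out
}

#' Write intervals as BED
#'
#' @param df Data.frame with `contig`, `start`, `end`, an id column and
#'   optionally `strand`.
#' @param path Output path.
#' @param id_col Name of the id column.
#' @export
write_bed <- function(df, path, id_col = "id") {
  bed <- data.frame(df$contig, df$start, df$end, df[[id_col]], 0L,
                    if (!is.null(df$strand)) df$strand else ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
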