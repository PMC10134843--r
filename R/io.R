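# Plain-text table and FASTA I/O used by every stage. All tables are
# tab-separated with a header row and no quoting or row names.

#' Read and write pipeline tables
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_tsv()` returns a data.frame.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

# matrix <-> table with an id first column
.write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), as.data.frame(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  write_tsv(df, path)
}

.read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
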