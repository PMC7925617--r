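#' Count matrix with sample metadata
#'
#' Light container pairing a genes x samples integer count matrix with its
#' sample metadata (cell line, condition, replicate). Sample names follow
#' the `<line>_<condition>_<rep>` convention.
#'
#' @param counts Integer matrix, genes as rows (rownames = gene IDs),
#'   samples as columns.
#' @param meta Data frame with columns `sample`, `line`,
#'   `condition` (one of `"unstim"`, `"stim"`) and `replicate`, one row per
#'   column of `counts`, in column order.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  obj <- structure(list(counts = counts, meta = as.data.frame(meta)),
                   class = "count_matrix")
  validate_count_matrix(obj)
  obj
}

validate_count_matrix <- function(x) {
  if (is.null(rownames(x$counts))) stopf("counts must carry gene IDs as rownames")
  if (any(x$counts < 0, na.rm = TRUE)) stopf("counts must be non-negative")
  need <- c("sample", "line", "condition", "replicate")
  if (!all(need %in% names(x$meta))) {
    stopf("meta must have columns: %s", paste(need, collapse = ", "))
  }
  if (!identical(as.character(x$meta$sample), colnames(x$counts))) {
    stopf("meta rows must match count columns in order")
  }
  if (!all(x$meta$condition %in% c("unstim", "stim"))) {
    stopf("condition must be 'unstim' or 'stim'")
  }
  invisible(x)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d lines)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$meta$line))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read / write a count matrix as TSV
#'
#' The counts TSV has genes as rows with the gene ID in the first column
#' (`gene`); the metadata TSV has one row per sample.
#'
#' @param counts_file,meta_file Paths to the two TSV files.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_file, meta_file) {
  tab <- read.delim(counts_file, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  meta <- read.delim(meta_file, stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

#' @rdname read_counts
#' @param x A `count_matrix`.
#' @export
write_counts <- function(x, counts_file, meta_file) {
  validate_count_matrix(x)
  tab <- data.frame(gene = rownames(x$counts), x$counts, check.names = FALSE)
  write.table(tab, counts_file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$meta, meta_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts_file, meta_file))
}
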