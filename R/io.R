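#' Count dataset container
#'
#' A gene x sample matrix of non-negative integer counts plus the per-sample
#' design (condition, time in hours, replicate).
#'
#' @param counts integer matrix, genes in rows (rownames = gene IDs),
#'   samples in columns (colnames = sample IDs).
#' @param design data frame with columns `sample`, `condition`, `time_h`,
#'   `replicate`, one row per sample, in column order of `counts`.
#' @return An object of class `count_dataset`.
#' @export
count_dataset <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("duplicate gene or sample IDs", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  need <- c("sample", "condition", "time_h", "replicate")
  if (!all(need %in% names(design))) {
    stop("design must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  design <- as.data.frame(design)[, need]
  if (!identical(as.character(design$sample), colnames(counts))) {
    m <- match(colnames(counts), design$sample)
    if (anyNA(m)) stop("design does not cover every sample", call. = FALSE)
    design <- design[m, , drop = FALSE]
  }
  rownames(design) <- NULL
  structure(list(counts = counts, design = design), class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("count_dataset: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$design$condition), collapse = " / ")))
  invisible(x)
}

#' Read and write count matrices and sample metadata as TSV
#'
#' The counts file is gene x sample with the gene ID in the first column;
#' the metadata file has columns `sample`, `condition`, `time_h`,
#' `replicate`.
#'
#' @param counts_path,metadata_path file paths.
#' @param data a [count_dataset()].
#' @return `read_count_dataset()` returns a `count_dataset`;
#'   the writers return their path invisibly.
#' @export
read_count_dataset <- function(counts_path, metadata_path) {
  tab <- read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- as.character(tab[[1]])
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  count_dataset(counts, meta)
}

#' @rdname read_count_dataset
#' @export
write_count_dataset <- function(data, counts_path, metadata_path) {
  stopifnot(inherits(data, "count_dataset"))
  tab <- data.frame(gene = rownames(data$counts), data$counts,
                    check.names = FALSE)
  write.table(tab, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data$design, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(counts_path)
}
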