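#' Construct a read-count table
#'
#' The central data container of the package: a samples x OTUs matrix of
#' non-negative integer read counts together with per-sample metadata
#' (rookery label, negative-control flag, assay type). On disk the table is
#' stored OTUs-as-rows (the usual VSEARCH/QIIME orientation, see
#' [read_otu_table()]); in memory it is sample-major so that per-sample
#' statistics are row operations.
#'
#' @param counts integer matrix, samples in rows, OTUs in columns. Must have
#'   row and column names (sample ids / OTU ids).
#' @param meta data.frame with columns `sample_id`, `rookery`,
#'   `is_negative_control` (logical) and `assay` (one of `"blocking"`,
#'   `"no_blocking"`, `"pooled"`). One row per sample of `counts`.
#' @return An object of class `read_count_table`: a list with elements
#'   `counts` and `meta` (meta rows aligned with count rows).
#' @examples
#' m <- matrix(c(3L, 1L, 0L, 2L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("OTU_1", "OTU_2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), rookery = c("A", "B"),
#'                    is_negative_control = FALSE, assay = "pooled")
#' read_count_table(m, meta)
#' @export
read_count_table <- function(counts, meta) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry sample ids as rownames and OTU ids as colnames")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("sample_id", "rookery", "is_negative_control", "assay")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$rookery <- as.character(meta$rookery)
  meta$rookery[is.na(meta$rookery)] <- ""
  meta$is_negative_control <- as.logical(meta$is_negative_control)
  meta$assay <- as.character(meta$assay)
  obj <- structure(list(counts = counts, meta = meta),
                   class = "read_count_table")
  validate_read_count_table(obj)
}

validate_read_count_table <- function(x) {
  counts <- x$counts
  meta <- x$meta
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(counts < 0L)) {
    bad <- which(counts < 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count (%d) at sample '%s', OTU '%s'",
                 counts[bad[1], bad[2]],
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids in count matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids in count matrix")
  absent <- setdiff(rownames(counts), meta$sample_id)
  if (length(absent))
    stop("sample(s) present in counts but missing from metadata: ",
         paste(absent, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata")
  # align metadata rows with count rows and drop metadata-only samples
  x$meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  rownames(x$meta) <- NULL
  if (any(x$meta$is_negative_control & nzchar(x$meta$rookery)))
    stop("negative controls must not carry a rookery label")
  bad_assay <- setdiff(unique(x$meta$assay), c("blocking", "no_blocking", "pooled"))
  if (length(bad_assay))
    stop("unknown assay label(s): ", paste(bad_assay, collapse = ", "))
  x
}

#' @export
print.read_count_table <- function(x, ...) {
  n_ctrl <- sum(x$meta$is_negative_control)
  cat(sprintf("read_count_table: %d samples x %d OTUs (%d negative control%s)\n",
              nrow(x$counts), ncol(x$counts), n_ctrl, if (n_ctrl == 1) "" else "s"))
  rk <- table(x$meta$rookery[!x$meta$is_negative_control &
                               nzchar(x$meta$rookery)])
  if (length(rk))
    cat("rookeries:", paste(sprintf("%s (%d)", names(rk), rk), collapse = ", "), "\n")
  cat(sprintf("total reads: %s\n", format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' @export
dim.read_count_table <- function(x) dim(x$counts)

#' Subset a read-count table by sample and/or OTU
#'
#' @param x a `read_count_table`
#' @param samples,otus character or logical selectors; `NULL` keeps all.
#' @return a `read_count_table`
#' @export
subset_table <- function(x, samples = NULL, otus = NULL) {
  stopifnot(inherits(x, "read_count_table"))
  counts <- x$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(otus)) counts <- counts[, otus, drop = FALSE]
  meta <- x$meta[match(rownames(counts), x$meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta), class = "read_count_table")
}

sample_totals <- function(x) {
  if (inherits(x, "read_count_table")) rowSums(x$counts) else rowSums(x)
}

negative_control_ids <- function(x) {
  x$meta$sample_id[x$meta$is_negative_control]
}
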