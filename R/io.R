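#' Read an OTU read-count table and its sample metadata
#'
#' The on-disk dialect stores OTUs as rows and samples as columns (the usual
#' orientation of VSEARCH/QIIME OTU tables): a TSV whose header is
#' `otu_id<TAB>sample1<TAB>...`, with integer cells. Sample metadata lives in
#' a second TSV with columns `sample_id`, `rookery`, `is_negative_control`
#' (0/1) and `assay` (`blocking`, `no_blocking` or `pooled`). The returned
#' object is transposed to the in-memory samples x OTUs orientation.
#'
#' Parsing is strict: any non-integer or negative cell is an error naming the
#' offending OTU and sample; a sample present in the table but absent from
#' the metadata is an error. All text I/O is UTF-8 with "." as the decimal
#' point.
#'
#' @param path path to the OTU-table TSV.
#' @param metadata_path path to the sample-metadata TSV.
#' @return a [read_count_table()].
#' @seealso [write_otu_table()]
#' @export
read_otu_table <- function(path, metadata_path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8", comment.char = "")
  if (names(raw)[1] != "otu_id")
    stop("OTU table must have 'otu_id' as its first column, found '",
         names(raw)[1], "'")
  otu_ids <- raw[[1]]
  sample_ids <- names(raw)[-1]
  mat <- matrix(0L, nrow = length(sample_ids), ncol = length(otu_ids),
                dimnames = list(sample_ids, otu_ids))
  for (j in seq_along(sample_ids)) {
    cells <- raw[[j + 1L]]
    ok <- grepl("^[0-9]+$", cells)
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop(sprintf("malformed count '%s' at OTU '%s', sample '%s'",
                   cells[bad], otu_ids[bad], sample_ids[j]))
    }
    mat[j, ] <- as.integer(cells)
  }
  meta <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                            quote = "", stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8", comment.char = "",
                            colClasses = "character")
  meta$is_negative_control <- meta$is_negative_control %in% c("1", "TRUE", "true")
  if (!"rookery" %in% names(meta)) meta$rookery <- ""
  meta$rookery[is.na(meta$rookery)] <- ""
  read_count_table(mat, meta)
}

#' Write an OTU read-count table (and optionally its metadata)
#'
#' Inverse of [read_otu_table()]: emits the OTUs-as-rows TSV dialect.
#' `write_otu_table(...)` followed by `read_otu_table(...)` reproduces the
#' table exactly, including row/column order.
#'
#' @param x a [read_count_table()].
#' @param path output TSV path.
#' @param metadata_path optional path for the sample-metadata TSV.
#' @export
write_otu_table <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "read_count_table"))
  df <- data.frame(otu_id = colnames(x$counts),
                   t(x$counts), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(metadata_path)) {
    meta <- x$meta
    meta$is_negative_control <- as.integer(meta$is_negative_control)
    utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

hit_lineage_ranks <- c("species", "genus", "family", "order", "class")

#' Read per-OTU best-hit taxonomy records
#'
#' Tab-separated, one best hit per OTU, an outfmt-6-like layout with appended
#' lineage columns: `otu_id`, `taxon`, `percent_identity`, `e_value`, then
#' `species`, `genus`, `family`, `order`, `class`. Missing lineage ranks are
#' empty strings. OTUs absent from the file are treated downstream as
#' "no hit".
#'
#' @param path path to the hits TSV (with header).
#' @return data.frame of hit records, one row per OTU.
#' @export
read_hits <- function(path) {
  cols <- c("otu_id", "taxon", "percent_identity", "e_value", hit_lineage_ranks)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0)
    return(empty_hits())
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          comment.char = "", colClasses = "character")
  if (nrow(df) == 0) return(empty_hits())
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop("hits file missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[cols]
  df$percent_identity <- as.numeric(df$percent_identity)
  df$e_value <- as.numeric(df$e_value)
  if (anyDuplicated(df$otu_id))
    stop("duplicated otu_id in hits file: ",
         paste(unique(df$otu_id[duplicated(df$otu_id)]), collapse = ", "))
  bad <- which(is.na(df$percent_identity) | df$percent_identity < 0 |
                 df$percent_identity > 100)
  if (length(bad))
    stop(sprintf("percent_identity out of [0,100] for OTU '%s'",
                 df$otu_id[bad[1]]))
  if (any(!is.na(df$e_value) & df$e_value < 0))
    stop("negative e_value in hits file")
  df
}

empty_hits <- function() {
  data.frame(otu_id = character(), taxon = character(),
             percent_identity = numeric(), e_value = numeric(),
             species = character(), genus = character(), family = character(),
             order = character(), class = character(),
             stringsAsFactors = FALSE)
}

#' @rdname read_hits
#' @param hits data.frame as returned by `read_hits`.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

habitat_classes <- c("epipelagic", "mesopelagic", "bathypelagic",
                     "rocky_bottom", "rocky_bottom_deep")

#' Read a prey trait table
#'
#' CSV with columns `taxon`, `habitat_class`, `trophic_level`. Habitat must
#' be one of the five habitat categories used throughout
#' (epipelagic 0-200 m, mesopelagic 200-1000 m, bathypelagic 1000-3000 m,
#' rocky bottom 0-200 m, rocky bottom-deep >200 m); trophic level must lie
#' in [2, 5].
#'
#' @param path CSV path.
#' @return data.frame keyed by `taxon`.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(c("taxon", "habitat_class", "trophic_level"), names(df))
  if (length(missing_cols))
    stop("trait table missing column(s): ", paste(missing_cols, collapse = ", "))
  validate_traits(df)
}

validate_traits <- function(df) {
  bad <- setdiff(unique(df$habitat_class), habitat_classes)
  if (length(bad))
    stop("unknown habitat class(es) ", paste(sQuote(bad), collapse = ", "),
         "; allowed values: ", paste(habitat_classes, collapse = ", "))
  df$trophic_level <- as.numeric(df$trophic_level)
  out <- which(is.na(df$trophic_level) | df$trophic_level < 2 |
                 df$trophic_level > 5)
  if (length(out))
    stop("trophic_level outside [2,5] for taxon '", df$taxon[out[1]], "'")
  if (anyDuplicated(df$taxon))
    stop("duplicated taxon in trait table")
  df
}

#' @rdname read_traits
#' @param traits data.frame as returned by `read_traits`.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}

#' Read a regional species checklist
#'
#' One taxon name per line; membership tests are case-insensitive
#' ([in_checklist()]).
#'
#' @param path text file path.
#' @return character vector of names (as written in the file).
#' @export
read_checklist <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x[nzchar(x)]
}

#' @rdname read_checklist
#' @param checklist character vector of names.
#' @export
write_checklist <- function(checklist, path) {
  writeLines(checklist, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname read_checklist
#' @param name taxon name(s) to test.
#' @export
in_checklist <- function(name, checklist) {
  tolower(trimws(name)) %in% tolower(trimws(checklist))
}

#' Write a statistic result object to JSON
#'
#' Serialises permutation-test results (statistic, df, p, n_permutations,
#' seed, ...) to a JSON file for machine-readable pipeline output.
#'
#' @param x a list or result object.
#' @param path output path.
#' @export
write_result_json <- function(x, path) {
  x <- unclass(x)
  keep <- !vapply(x, is.function, logical(1))
  jsonlite::write_json(x[keep], path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
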