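#' Configuration of the decontamination cascade
#'
#' Collects every threshold of the OTU-table filtering cascade. Defaults
#' follow the published workflow: a tag-switch relative-abundance floor
#' derived from negative controls, removal of OTUs with no hit or identity
#' below 70%, predator and obvious (non-marine) contaminant removal,
#' negative-control-based cell nullification, a per-sample 1% minor-OTU rule
#' with singleton removal, exclusion of samples with fewer than 2 prey reads
#' and of the lowest quartile of per-sample prey reads, and a 100-read
#' minimum for the inferential subset.
#'
#' @param tag_switch_floor proportion in `[0,1]`, or `NULL` to derive it from
#'   the negative controls via [compute_tag_switch_floor()].
#' @param min_identity OTUs with best-hit identity strictly below this are
#'   removed (percent).
#' @param blacklist taxa treated as obvious non-marine contaminants.
#' @param predator_taxa names (binomials or genera) identifying the predator.
#' @param per_sample_min_fraction cells below this fraction of their sample's
#'   reads are nullified (strict `<`).
#' @param drop_singletons remove OTUs whose dataset-wide total is one read.
#' @param singleton_definition `"reads"` (total abundance 1, the default
#'   metabarcoding usage) or `"samples"` (present in exactly one sample).
#' @param control_filter_stat `"max"` (default) or `"sum"`: statistic of an
#'   OTU's reads across negative controls used by the control-based cell
#'   filter.
#' @param min_sample_reads_absolute samples with fewer prey reads than this
#'   are excluded (default 2: "zero or one prey reads").
#' @param lowest_quartile_exclusion drop samples strictly below the 25th
#'   percentile of per-sample prey reads.
#' @param quartile_cutoff explicit cutoff overriding the derived quartile
#'   (used when re-executing a recorded run).
#' @param inferential_min_reads minimum prey reads for the inferential
#'   subset ([subset_inferential()]).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(tag_switch_floor = NULL,
                          min_identity = 70,
                          blacklist = character(),
                          predator_taxa = c("Zalophus", "Zalophus wollebaeki",
                                            "Zalophus californianus",
                                            "Otariidae"),
                          per_sample_min_fraction = 0.01,
                          drop_singletons = TRUE,
                          singleton_definition = c("reads", "samples"),
                          control_filter_stat = c("max", "sum"),
                          min_sample_reads_absolute = 2,
                          lowest_quartile_exclusion = TRUE,
                          quartile_cutoff = NULL,
                          inferential_min_reads = 100) {
  if (!is.null(tag_switch_floor) &&
      (tag_switch_floor < 0 || tag_switch_floor > 1))
    stop("tag_switch_floor must lie in [0,1]")
  stopifnot(min_identity >= 0, per_sample_min_fraction >= 0,
            min_sample_reads_absolute >= 0, inferential_min_reads >= 0)
  structure(list(tag_switch_floor = tag_switch_floor,
                 min_identity = min_identity,
                 blacklist = blacklist,
                 predator_taxa = predator_taxa,
                 per_sample_min_fraction = per_sample_min_fraction,
                 drop_singletons = drop_singletons,
                 singleton_definition = match.arg(singleton_definition),
                 control_filter_stat = match.arg(control_filter_stat),
                 min_sample_reads_absolute = min_sample_reads_absolute,
                 lowest_quartile_exclusion = lowest_quartile_exclusion,
                 quartile_cutoff = quartile_cutoff,
                 inferential_min_reads = inferential_min_reads),
            class = "filter_config")
}

#' Pool assay replicates per scat
#'
#' Blocking and no-blocking PCR replicates of the same scat are summed into
#' one pooled sample before any threshold is applied. Replicates are tied
#' together by the `scat_id` metadata column when present, otherwise by the
#' sample id with a trailing `.<assay>` suffix stripped. Negative controls
#' are passed through unchanged.
#'
#' @param table a [read_count_table()].
#' @return a [read_count_table()] with one row per scat (assay = "pooled").
#' @export
pool_assays <- function(table) {
  stopifnot(inherits(table, "read_count_table"))
  meta <- table$meta
  scat <- if ("scat_id" %in% names(meta)) meta$scat_id
          else sub("\\.(blocking|no_blocking|pooled)$", "", meta$sample_id)
  scat[meta$is_negative_control] <- meta$sample_id[meta$is_negative_control]
  if (!anyDuplicated(scat)) {
    out_meta <- meta
    out_meta$sample_id <- scat
    out_meta$assay <- ifelse(out_meta$is_negative_control,
                             out_meta$assay, "pooled")
    counts <- table$counts
    rownames(counts) <- scat
    return(read_count_table(counts, out_meta))
  }
  keys <- unique(scat)
  counts <- rowsum(table$counts, group = factor(scat, levels = keys))
  first <- match(keys, scat)
  out_meta <- data.frame(sample_id = keys,
                         rookery = meta$rookery[first],
                         is_negative_control = meta$is_negative_control[first],
                         assay = ifelse(meta$is_negative_control[first],
                                        meta$assay[first], "pooled"),
                         stringsAsFactors = FALSE)
  if ("scat_id" %in% names(meta)) out_meta$scat_id <- keys
  read_count_table(counts, out_meta)
}

#' Tag-switch relative-abundance floor from negative controls
#'
#' The floor is the maximum, over negative controls, of the predator-OTU
#' read fraction (predator reads in the control divided by total reads in
#' the control). Controls without reads, or without predator reads,
#' contribute 0.
#'
#' @param table a [read_count_table()] containing at least one negative
#'   control.
#' @param predator_otus OTU ids counted as predator.
#' @return a proportion in `[0,1]`.
#' @export
compute_tag_switch_floor <- function(table, predator_otus) {
  stopifnot(inherits(table, "read_count_table"))
  ctrl <- negative_control_ids(table)
  if (!length(ctrl))
    stop("table has no negative controls; supply tag_switch_floor explicitly")
  pred <- intersect(predator_otus, colnames(table$counts))
  if (!length(pred)) return(0)
  sub <- table$counts[ctrl, , drop = FALSE]
  tot <- rowSums(sub)
  frac <- ifelse(tot > 0, rowSums(sub[, pred, drop = FALSE]) / tot, 0)
  max(frac, 0)
}

#' Nullify cells below a relative-abundance floor
#'
#' Any cell whose count is strictly less than `floor` times its sample's
#' total reads (totals taken before nullification) is set to 0.
#'
#' @param table a [read_count_table()].
#' @param floor proportion in `[0,1]`.
#' @return the filtered [read_count_table()].
#' @export
nullify_below_floor <- function(table, floor) {
  stopifnot(inherits(table, "read_count_table"), floor >= 0, floor <= 1)
  if (floor == 0) return(table)
  counts <- table$counts
  tot <- rowSums(counts)
  rel <- counts / ifelse(tot > 0, tot, 1)
  counts[rel < floor] <- 0L
  table$counts <- counts
  table
}

# obvious-contaminant OTU ids given hits and a blacklist of taxa
match_blacklist <- function(hits, blacklist) {
  if (!length(blacklist)) return(character())
  bl <- tolower(blacklist)
  hit_genus <- tolower(vapply(strsplit(hits$taxon, " "), `[`, "", 1))
  hits$otu_id[tolower(hits$taxon) %in% bl | hit_genus %in% bl |
                tolower(hits$genus) %in% bl]
}

match_predator <- function(hits, predator_taxa) {
  pt <- tolower(predator_taxa)
  hit_genus <- tolower(vapply(strsplit(hits$taxon, " "), `[`, "", 1))
  hits$otu_id[tolower(hits$taxon) %in% pt | hit_genus %in% pt |
                tolower(hits$genus) %in% pt | tolower(hits$family) %in% pt]
}

#' OTU-level screening against taxonomy hits
#'
#' Removes whole OTU columns: OTUs with no hit record, identity strictly
#' below `min_identity` (default 70%), predator (otariid) OTUs, and obvious
#' contaminants matching the blacklist. Removal reasons are returned.
#'
#' @param table a [read_count_table()].
#' @param hits data.frame from [read_hits()]; OTUs absent from it count as
#'   "no hit".
#' @param config a [filter_config()].
#' @param drop_contaminants if `FALSE`, blacklist OTUs are reported but their
#'   columns are kept (the cascade defers their removal to
#'   [control_based_filters()], which needs their read proportions).
#' @return list with `table` and `removals` (data.frame otu_id, reason).
#' @export
screen_otus <- function(table, hits, config, drop_contaminants = TRUE) {
  stopifnot(inherits(table, "read_count_table"))
  otus <- colnames(table$counts)
  idx <- match(otus, hits$otu_id)
  reason <- rep(NA_character_, length(otus))
  reason[is.na(idx)] <- "no_hit"
  ok <- !is.na(idx)
  low <- ok & hits$percent_identity[idx] < config$min_identity
  reason[low & is.na(reason)] <- "low_identity"
  pred_otus <- match_predator(hits, config$predator_taxa)
  reason[otus %in% pred_otus & is.na(reason)] <- "predator"
  contam_otus <- match_blacklist(hits, config$blacklist)
  reason[otus %in% contam_otus & is.na(reason)] <- "contaminant"
  removals <- data.frame(otu_id = otus[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  drop <- removals$otu_id
  if (!drop_contaminants)
    drop <- setdiff(drop, removals$otu_id[removals$reason == "contaminant"])
  keep <- setdiff(otus, drop)
  list(table = subset_table(table, otus = keep), removals = removals)
}

#' Negative-control-based cell filters
#'
#' Two steps of the cross-contamination correction. Step 1: a sample cell is
#' nullified when its count is less than or equal to the maximum count of
#' that OTU across the negative controls (statistic configurable to the sum).
#' Step 2: for every sample, `c` = reads of obvious-contaminant OTUs divided
#' by total reads in the sample; any OTU with within-sample relative
#' abundance strictly below `c` is nullified; the contaminant columns are
#' then dropped.
#'
#' @param table a [read_count_table()] (controls may be absent, in which case
#'   step 1 is a no-op).
#' @param obvious_contaminant_otus OTU ids of the obvious contaminants still
#'   present in the table.
#' @param control_filter_stat `"max"` or `"sum"`.
#' @return the filtered [read_count_table()].
#' @export
control_based_filters <- function(table, obvious_contaminant_otus = character(),
                                  control_filter_stat = "max") {
  stopifnot(inherits(table, "read_count_table"))
  counts <- table$counts
  ctrl <- negative_control_ids(table)
  real <- setdiff(rownames(counts), ctrl)
  if (length(ctrl)) {
    sub <- counts[ctrl, , drop = FALSE]
    lim <- if (control_filter_stat == "sum") colSums(sub)
           else apply(sub, 2, max)
    if (any(lim > 0)) {
      block <- counts[real, , drop = FALSE]
      block[sweep(block, 2, lim, `<=`) & block > 0L] <- 0L
      counts[real, ] <- block
    }
  }
  contam <- intersect(obvious_contaminant_otus, colnames(counts))
  if (length(contam)) {
    block <- counts[real, , drop = FALSE]
    tot <- rowSums(block)
    c_frac <- ifelse(tot > 0,
                     rowSums(block[, contam, drop = FALSE]) / tot, 0)
    rel <- block / ifelse(tot > 0, tot, 1)
    block[rel < c_frac] <- 0L      # strict <, per-sample threshold
    counts[real, ] <- block
    counts <- counts[, setdiff(colnames(counts), contam), drop = FALSE]
  }
  table$counts <- counts
  validate_read_count_table(table)
}

#' Per-sample minor-OTU rule and singleton removal
#'
#' Nullifies cells representing strictly less than `per_sample_min_fraction`
#' (default 1%) of their sample's reads, then removes singleton OTUs
#' (dataset-wide total of one read, or present in exactly one sample under
#' the alternative definition).
#'
#' @param table a [read_count_table()].
#' @param config a [filter_config()].
#' @return the filtered [read_count_table()].
#' @export
minor_otu_filter <- function(table, config) {
  stopifnot(inherits(table, "read_count_table"))
  counts <- table$counts
  if (config$per_sample_min_fraction > 0 && nrow(counts)) {
    tot <- rowSums(counts)
    rel <- counts / ifelse(tot > 0, tot, 1)
    counts[rel < config$per_sample_min_fraction] <- 0L
  }
  if (config$drop_singletons && ncol(counts)) {
    singleton <- if (config$singleton_definition == "reads")
      colSums(counts) == 1L else colSums(counts > 0L) == 1L
    counts <- counts[, !singleton, drop = FALSE]
  }
  table$counts <- counts
  validate_read_count_table(table)
}

#' Exclude low-coverage samples
#'
#' Drops negative controls, then samples with fewer than
#' `min_sample_reads_absolute` prey reads (default: "zero or one"), then —
#' when enabled — samples strictly below the 25th percentile (linear
#' interpolation) of the remaining per-sample totals. Samples exactly at the
#' cutoff are retained. With fewer than 4 samples remaining the quartile step
#' is skipped with a warning.
#'
#' @param table a [read_count_table()] after the OTU-level filters.
#' @param config a [filter_config()].
#' @return list with `table`, `excluded` (data.frame sample_id, reason) and
#'   `quartile_cutoff` (NA when the step did not run).
#' @export
exclude_samples <- function(table, config) {
  stopifnot(inherits(table, "read_count_table"))
  excluded <- data.frame(sample_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  ctrl <- negative_control_ids(table)
  if (length(ctrl))
    excluded <- rbind(excluded, data.frame(sample_id = ctrl,
                                           reason = "negative_control"))
  table <- subset_table(table,
                        samples = setdiff(rownames(table$counts), ctrl))
  tot <- sample_totals(table)
  low <- names(tot)[tot < config$min_sample_reads_absolute]
  if (length(low))
    excluded <- rbind(excluded, data.frame(sample_id = low,
                                           reason = "below_absolute_minimum"))
  table <- subset_table(table, samples = setdiff(rownames(table$counts), low))
  cutoff <- NA_real_
  if (config$lowest_quartile_exclusion) {
    tot <- sample_totals(table)
    if (!is.null(config$quartile_cutoff)) {
      cutoff <- config$quartile_cutoff
    } else if (length(tot) < 4) {
      warning("fewer than 4 samples remain; lowest-quartile step skipped")
    } else {
      cutoff <- unname(stats::quantile(tot, 0.25, type = 7))
    }
    if (!is.na(cutoff)) {
      drop <- names(tot)[tot < cutoff]   # strict: samples at the cutoff stay
      if (length(drop))
        excluded <- rbind(excluded, data.frame(sample_id = drop,
                                               reason = "lowest_quartile"))
      table <- subset_table(table,
                            samples = setdiff(rownames(table$counts), drop))
    }
  }
  list(table = table, excluded = excluded, quartile_cutoff = cutoff)
}

#' Run the full decontamination cascade
#'
#' Applies, in order: assay pooling, the tag-switch floor (derived from the
#' negative controls unless supplied), OTU-level screening, the
#' negative-control-based cell filters, the minor-OTU rule, sample
#' exclusion, and a final cleanup dropping all-zero OTU columns plus
#' singletons created by the sample exclusion. Every step is monotone: no
#' cell ever increases and no OTU or sample is ever added.
#'
#' Data-derived thresholds (floor, quartile cutoff) are recorded in the
#' report; re-running the cascade on its own output with those recorded
#' thresholds frozen into the config removes nothing.
#'
#' @param table raw [read_count_table()] (assay replicates plus controls).
#' @param hits taxonomy hit records ([read_hits()]).
#' @param config a [filter_config()].
#' @return list with `table` (filtered, pooled, controls dropped) and
#'   `report` (class `filter_report`).
#' @export
run_filter_cascade <- function(table, hits, config = filter_config()) {
  stopifnot(inherits(table, "read_count_table"))
  report <- list(steps = list(), derived = list())
  dims <- function(t) c(samples = nrow(t$counts), otus = ncol(t$counts),
                        reads = sum(as.numeric(t$counts)))
  log_step <- function(name, before, after, detail = NULL) {
    report$steps[[name]] <<- list(
      before = as.list(before), after = as.list(after),
      otus_removed = unname(before["otus"] - after["otus"]),
      samples_removed = unname(before["samples"] - after["samples"]),
      reads_removed = unname(before["reads"] - after["reads"]),
      detail = detail)
  }

  d0 <- dims(table)
  table <- pool_assays(table)
  log_step("pool_assays", d0, dims(table))

  floor <- config$tag_switch_floor
  if (is.null(floor)) {
    if (length(negative_control_ids(table))) {
      pred_otus <- match_predator(hits, config$predator_taxa)
      floor <- compute_tag_switch_floor(table, pred_otus)
    } else {
      warning("no negative controls and no explicit tag_switch_floor; ",
              "using 0")
      floor <- 0
    }
  }
  report$derived$tag_switch_floor <- floor
  d <- dims(table)
  table <- nullify_below_floor(table, floor)
  log_step("tag_switch_floor", d, dims(table), detail = list(floor = floor))

  d <- dims(table)
  scr <- screen_otus(table, hits, config, drop_contaminants = FALSE)
  table <- scr$table
  contam_otus <- scr$removals$otu_id[scr$removals$reason == "contaminant"]
  log_step("screen_otus", d, dims(table),
           detail = list(removals = scr$removals))

  d <- dims(table)
  table <- control_based_filters(table, contam_otus,
                                 config$control_filter_stat)
  log_step("control_based_filters", d, dims(table),
           detail = list(contaminant_otus = contam_otus))

  d <- dims(table)
  table <- minor_otu_filter(table, config)
  log_step("minor_otu_filter", d, dims(table))

  d <- dims(table)
  ex <- exclude_samples(table, config)
  table <- ex$table
  report$derived$quartile_cutoff <- ex$quartile_cutoff
  log_step("exclude_samples", d, dims(table),
           detail = list(excluded = ex$excluded,
                         quartile_cutoff = ex$quartile_cutoff))

  # final cleanup: all-zero columns, and singletons re-created by the
  # sample exclusion (keeps the cascade a fixed point for the OTU rules)
  d <- dims(table)
  keep <- colSums(table$counts) > 0L
  if (config$drop_singletons) {
    singleton <- if (config$singleton_definition == "reads")
      colSums(table$counts) == 1L else colSums(table$counts > 0L) == 1L
    keep <- keep & !singleton
  }
  table <- subset_table(table, otus = colnames(table$counts)[keep])
  log_step("drop_empty_otus", d, dims(table))

  class(report) <- "filter_report"
  list(table = table, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report\n")
  if (!is.null(x$derived$tag_switch_floor))
    cat(sprintf("  derived tag-switch floor: %.6g\n",
                x$derived$tag_switch_floor))
  if (!is.null(x$derived$quartile_cutoff) &&
      !is.na(x$derived$quartile_cutoff))
    cat(sprintf("  derived quartile cutoff: %.6g reads\n",
                x$derived$quartile_cutoff))
  for (nm in names(x$steps)) {
    s <- x$steps[[nm]]
    cat(sprintf("  %-22s -%3d OTUs  -%3d samples  -%8d reads\n", nm,
                s$otus_removed, s$samples_removed, round(s$reads_removed)))
  }
  invisible(x)
}

#' Inferential subset: samples with at least `min_reads` prey reads
#'
#' @param table filtered [read_count_table()].
#' @param min_reads inclusive minimum (default 100).
#' @return a [read_count_table()].
#' @export
subset_inferential <- function(table, min_reads = 100) {
  stopifnot(inherits(table, "read_count_table"))
  tot <- sample_totals(table)
  subset_table(table, samples = names(tot)[tot >= min_reads])
}
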