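#' Configuration for a full pipeline run
#'
#' Bundles inputs, filter settings, taxonomy bands, statistics selection and
#' the seed for one reproducible end-to-end run. Exactly one of `inputs`
#' (paths to the on-disk formats) or `simulate` (a [sim_config()]) must be
#' given. The seed is mandatory: every permutation test and simulation draw
#' derives its stream from it, and rerunning the same configuration
#' reproduces identical outputs.
#'
#' @param inputs named list of paths: `otu_table`, `metadata`, `hits`,
#'   `traits`, `checklist`.
#' @param simulate a [sim_config()] to generate the inputs instead.
#' @param filter a [filter_config()].
#' @param bands an [identity_bands()] vector.
#' @param stats character subset of
#'   `c("permanova", "permdisp", "nmds", "schoener", "indval")`.
#' @param n_perm permutations for every permutation test.
#' @param inferential_min_reads prey-read minimum for the inferential subset.
#' @param rarefaction_n sample-based rarefaction size; default the smallest
#'   rookery.
#' @param seed integer, required.
#' @param out_dir output directory (created); `NULL` for in-memory only.
#' @return list of class `run_config`.
#' @export
run_config <- function(inputs = NULL, simulate = NULL,
                       filter = filter_config(), bands = identity_bands(),
                       stats = c("permanova", "permdisp", "nmds",
                                 "schoener", "indval"),
                       n_perm = 999, inferential_min_reads = 100,
                       rarefaction_n = NULL, seed = NULL, out_dir = NULL) {
  if (is.null(inputs) == is.null(simulate))
    stop("give exactly one of 'inputs' or 'simulate'")
  stats <- match.arg(stats, several.ok = TRUE)
  if (is.null(seed))
    stop("a seed is required: permutation/simulation steps are seeded")
  structure(list(inputs = inputs, simulate = simulate, filter = filter,
                 bands = bands, stats = stats, n_perm = n_perm,
                 inferential_min_reads = inferential_min_reads,
                 rarefaction_n = rarefaction_n,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full diet-metabarcoding pipeline
#'
#' Orchestrates simulate/load -> decontamination cascade -> taxonomy
#' assignment -> diet summaries -> community statistics, writing every stage
#' output plus a machine-readable provenance record (configuration, seeds,
#' derived thresholds, per-stage sample/OTU accounting) sufficient to
#' re-execute the identical run. Stage errors abort with a stage-tagged
#' message; outputs written so far are retained.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `tables` (filtered and inferential
#'   read-count tables), `report`, `assignments`, `entities`, `summaries`,
#'   `stats`, and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  emit <- function(name, writer) {
    if (!is.null(out)) writer(file.path(out, name))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }

  # -- inputs ---------------------------------------------------------------
  sim_truth <- NULL
  data <- stage("input", {
    if (!is.null(config$simulate)) {
      sim <- simulate_experiment(config$simulate)
      sim_truth <- sim$truth
      emit("otu_table.tsv", function(p)
        write_otu_table(sim$table, p, file.path(out, "metadata.tsv")))
      emit("hits.tsv", function(p) write_hits(sim$hits, p))
      emit("traits.csv", function(p) write_traits(sim$traits, p))
      emit("checklist.txt", function(p) write_checklist(sim$checklist, p))
      emit("ground_truth.json", function(p)
        jsonlite::write_json(list(
          occurrence = sim$truth$occurrence,
          contaminant_otus = sim$truth$contaminant_otus,
          predator_otu = sim$truth$predator_otu), p, auto_unbox = TRUE))
      sim[c("table", "hits", "traits", "checklist")]
    } else {
      list(table = read_otu_table(config$inputs$otu_table,
                                  config$inputs$metadata),
           hits = read_hits(config$inputs$hits),
           traits = read_traits(config$inputs$traits),
           checklist = read_checklist(config$inputs$checklist))
    }
  })

  # -- decontamination cascade ----------------------------------------------
  filt <- stage("filter",
                run_filter_cascade(data$table, data$hits, config$filter))
  emit("filtered_table.tsv", function(p)
    write_otu_table(filt$table, p, file.path(out, "filtered_metadata.tsv")))
  emit("filter_report.json", function(p) write_result_json(filt$report, p))

  # -- taxonomy ---------------------------------------------------------------
  assignments <- stage("assign", {
    retained <- data$hits[data$hits$otu_id %in% colnames(filt$table$counts), ,
                          drop = FALSE]
    assign_taxonomy(retained, data$checklist, config$bands)
  })
  entities <- collapse_entities(assignments)
  emit("assignments.csv", function(p)
    utils::write.csv(assignments, p, row.names = FALSE))
  emit("entities.csv", function(p)
    utils::write.csv(entities$entities, p, row.names = FALSE))

  # -- diet summaries ---------------------------------------------------------
  summaries <- stage("summarize", {
    occ_otu <- to_occurrence(filt$table)
    occ_ent <- collapse_occurrence(occ_otu, assignments)
    # entity names carry a " (rank)" suffix; traits are keyed by taxon name
    bare <- sub(" \\((species|genus|family|order|class)\\)$", "",
                colnames(occ_ent$matrix))
    cats <- categorize_prey(bare, data$traits)
    cats$item <- colnames(occ_ent$matrix)
    poo_items <- poo_summary(occ_ent, "items")
    poo_hab <- poo_summary(occ_ent, "habitat", cats)
    poo_troph <- poo_summary(occ_ent, "trophic_bin", cats)
    rich <- richness_summary(occ_otu)
    n_rare <- config$rarefaction_n
    if (is.null(n_rare)) n_rare <- min(table(occ_otu$rookery))
    rare <- do.call(rbind, lapply(unique(occ_otu$rookery), function(rk) {
      sub <- occ_otu$matrix[occ_otu$rookery == rk, , drop = FALSE]
      est <- rarefy_samples(sub, min(n_rare, nrow(sub)))
      data.frame(rookery = rk, n = est$n, expected = est$expected,
                 ci_lower = est$ci_lower, ci_upper = est$ci_upper)
    }))
    list(occ_otu = occ_otu, occ_ent = occ_ent, categories = cats,
         poo_items = poo_items, poo_habitat = poo_hab,
         poo_trophic = poo_troph, richness = rich, rarefaction = rare)
  })
  emit("poo_items.csv", function(p)
    utils::write.csv(summaries$poo_items, p, row.names = FALSE))
  emit("poo_habitat.csv", function(p)
    utils::write.csv(summaries$poo_habitat, p, row.names = FALSE))
  emit("poo_trophic.csv", function(p)
    utils::write.csv(summaries$poo_trophic, p, row.names = FALSE))
  emit("richness.csv", function(p)
    utils::write.csv(summaries$richness$per_rookery, p, row.names = FALSE))
  emit("rarefaction.csv", function(p)
    utils::write.csv(summaries$rarefaction, p, row.names = FALSE))

  # -- inferential statistics -------------------------------------------------
  inferential <- subset_inferential(filt$table, config$inferential_min_reads)
  stat_results <- stage("compare", {
    res <- list()
    if (length(config$stats) && nrow(inferential$counts) >= 4) {
      occ <- to_occurrence(inferential)
      d <- jaccard_distances(occ)
      groups <- factor(occ$rookery)
      reads <- sample_totals(inferential)[rownames(occ$matrix)]
      if ("permanova" %in% config$stats) {
        res$permanova <- permanova(
          d, data.frame(rookery = groups, reads = as.numeric(reads)),
          n_perm = config$n_perm, seed = config$seed)
        res$pairwise_permanova <- pairwise_permanova(
          d, groups, n_perm = config$n_perm, seed = config$seed)
      }
      if ("permdisp" %in% config$stats)
        res$permdisp <- permdisp(d, groups, n_perm = config$n_perm,
                                 seed = config$seed)
      if ("nmds" %in% config$stats)
        res$nmds <- nmds(d, k = 3, seed = config$seed)
      if ("schoener" %in% config$stats) {
        occ_ent_inf <- collapse_occurrence(occ, assignments)
        res$schoener <- schoener_matrix(poo_summary(occ_ent_inf, "items"))
      }
      if ("indval" %in% config$stats)
        res$indval <- indval(occ, groups, n_perm = config$n_perm,
                             seed = config$seed)
    }
    res
  })
  if (!is.null(stat_results$permanova))
    emit("permanova.json", function(p)
      write_result_json(list(aov_table = stat_results$permanova$aov_table,
                             n_permutations = config$n_perm,
                             seed = config$seed), p))
  if (!is.null(stat_results$permdisp))
    emit("permdisp.json", function(p)
      write_result_json(stat_results$permdisp[
        c("group_means", "F", "df", "p", "pairwise",
          "n_permutations", "seed")], p))
  if (!is.null(stat_results$nmds))
    emit("nmds_points.csv", function(p)
      utils::write.csv(data.frame(sample_id = rownames(
        stat_results$nmds$points), stat_results$nmds$points,
        stress = stat_results$nmds$stress), p, row.names = FALSE))
  if (!is.null(stat_results$schoener))
    emit("schoener.csv", function(p)
      utils::write.csv(stat_results$schoener, p))
  if (!is.null(stat_results$indval))
    emit("indval.csv", function(p)
      utils::write.csv(stat_results$indval, p, row.names = FALSE))

  provenance <- list(
    package_version = as.character(utils::packageVersion("scatdiet")),
    seed = config$seed,
    n_permutations = config$n_perm,
    derived_thresholds = filt$report$derived,
    counts = list(
      samples_in = nrow(data$table$counts),
      otus_in = ncol(data$table$counts),
      samples_filtered = nrow(filt$table$counts),
      otus_filtered = ncol(filt$table$counts),
      samples_inferential = nrow(inferential$counts),
      entities = entities$n_entities,
      rank_tally = as.list(entities$rank_tally)),
    config = serialize_config(config))
  emit("provenance.json", function(p)
    jsonlite::write_json(provenance, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null"))

  invisible(list(tables = list(filtered = filt$table,
                               inferential = inferential),
                 report = filt$report, assignments = assignments,
                 entities = entities, summaries = summaries,
                 stats = stat_results, provenance = provenance,
                 truth = sim_truth))
}

# flatten the run configuration for the provenance record; the output
# directory is a location, not part of the run's identity
serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$filter <- unclass(cfg$filter)
  if (!is.null(cfg$simulate)) cfg$simulate <- unclass(cfg$simulate)
  cfg$bands <- as.list(cfg$bands)
  cfg
}

#' Collapse an OTU-level occurrence matrix to taxonomic entities
#'
#' A sample contains an entity when it contains any of the entity's OTUs.
#'
#' @param occ an `occurrence_matrix` over OTUs.
#' @param assignments data.frame from [assign_taxonomy()].
#' @return an `occurrence_matrix` over entity names.
#' @export
collapse_occurrence <- function(occ, assignments) {
  occ <- as_occurrence(occ)
  idx <- match(colnames(occ$matrix), assignments$otu_id)
  if (anyNA(idx))
    stop("assignments missing for OTU(s): ",
         paste(colnames(occ$matrix)[is.na(idx)], collapse = ", "))
  entity <- sprintf("%s (%s)", assignments$assigned_name[idx],
                    assignments$assigned_rank[idx])
  levels <- unique(entity)
  m <- vapply(levels, function(e)
    as.integer(rowSums(occ$matrix[, entity == e, drop = FALSE]) > 0),
    integer(nrow(occ$matrix)))
  m <- matrix(m, nrow = nrow(occ$matrix),
              dimnames = list(rownames(occ$matrix), levels))
  occurrence_matrix(m, occ$rookery)
}
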