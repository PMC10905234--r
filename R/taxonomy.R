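#' Identity bands for above-species taxonomic ranking
#'
#' OTUs matching below the species threshold are ranked by configurable
#' identity bands (an offline, reproducible stand-in for manual tree-based
#' placement): identity at or above the `genus` band is assigned at genus
#' level, at or above the `family` band at family level, and below that at
#' order level.
#'
#' @param species species-level threshold (checklist-confirmed, default 96).
#' @param genus,family lower band edges (defaults 92 and 85).
#' @return named numeric vector.
#' @export
identity_bands <- function(species = 96, genus = 92, family = 85) {
  stopifnot(species >= genus, genus >= family)
  c(species = species, genus = genus, family = family)
}

trophic_bin_labels <- c("2.0-2.5", "2.6-3.0", "3.1-3.5", "3.6-4.0", "4.1-4.5")
# printed bins leave one-decimal gaps (2.5-2.6 etc.); gap values go to the
# nearest bin, ties rounding up
trophic_bin_breaks <- c(-Inf, 2.55, 3.05, 3.55, 4.05, Inf)

#' Assign final taxonomy to hit records
#'
#' Implements the species-assignment rule: an OTU whose best hit has
#' percent identity at or above the species band (default 96) is assigned to
#' that species *provided* the species is on the regional checklist;
#' otherwise it escalates to genus (unconfirmed). Hits below the species
#' band are ranked by identity bands (genus/family/order). An empty lineage
#' at the required rank escalates to the next available higher rank with a
#' warning.
#'
#' @param hits data.frame of hit records ([read_hits()]).
#' @param checklist character vector of regional taxa (case-insensitive
#'   matching on the binomial).
#' @param bands an [identity_bands()] vector.
#' @return data.frame with columns `otu_id`, `assigned_name`,
#'   `assigned_rank`, `percent_identity`, `checklist_confirmed`.
#' @export
assign_taxonomy <- function(hits, checklist, bands = identity_bands()) {
  n <- nrow(hits)
  rank <- character(n)
  confirmed <- logical(n)
  id <- hits$percent_identity
  sp_name <- ifelse(nzchar(hits$species), hits$species, hits$taxon)
  listed <- in_checklist(sp_name, checklist)
  rank[id >= bands[["species"]] & listed] <- "species"
  confirmed[id >= bands[["species"]] & listed] <- TRUE
  rank[id >= bands[["species"]] & !listed] <- "genus"
  sub <- !nzchar(rank) & id >= bands[["genus"]]
  rank[sub] <- "genus"
  sub <- !nzchar(rank) & id >= bands[["family"]]
  rank[sub] <- "family"
  rank[!nzchar(rank)] <- "order"

  rank_order <- c("species", "genus", "family", "order", "class")
  name <- character(n)
  for (i in seq_len(n)) {
    r <- match(rank[i], rank_order)
    repeat {
      cand <- switch(rank_order[r],
                     species = sp_name[i],
                     genus = hits$genus[i],
                     family = hits$family[i],
                     order = hits$order[i],
                     class = hits$class[i])
      if (!is.na(cand) && nzchar(cand)) break
      if (r == length(rank_order))
        stop("OTU '", hits$otu_id[i], "' has an entirely empty lineage")
      r <- r + 1L
    }
    if (rank_order[r] != rank[i]) {
      warning(sprintf("OTU '%s': no %s name in lineage; escalated to %s",
                      hits$otu_id[i], rank[i], rank_order[r]))
      rank[i] <- rank_order[r]
      confirmed[i] <- FALSE
    }
    name[i] <- cand
  }
  data.frame(otu_id = hits$otu_id, assigned_name = name,
             assigned_rank = rank, percent_identity = id,
             checklist_confirmed = confirmed, stringsAsFactors = FALSE)
}

#' Collapse OTUs to unique taxonomic entities
#'
#' Groups OTUs sharing the same assigned name and rank into one entity
#' (e.g. two OTUs both assigned to the same genus are one entity) and
#' tallies assignments per rank.
#'
#' @param assignments data.frame from [assign_taxonomy()].
#' @return list with `entities` (data.frame entity, assigned_name,
#'   assigned_rank, n_otus, otu_ids), `n_entities`, and `rank_tally`
#'   (named OTU counts for species/genus/family/order).
#' @export
collapse_entities <- function(assignments) {
  key <- paste(assignments$assigned_name, assignments$assigned_rank,
               sep = " | ")
  groups <- split(assignments$otu_id, factor(key, levels = unique(key)))
  first <- match(names(groups), key)
  entities <- data.frame(
    entity = sprintf("%s (%s)", assignments$assigned_name[first],
                     assignments$assigned_rank[first]),
    assigned_name = assignments$assigned_name[first],
    assigned_rank = assignments$assigned_rank[first],
    n_otus = lengths(groups),
    otu_ids = vapply(groups, paste, "", collapse = ";"),
    stringsAsFactors = FALSE, row.names = NULL)
  ranks <- c("species", "genus", "family", "order")
  tally <- vapply(ranks, function(r) sum(assignments$assigned_rank == r),
                  integer(1))
  list(entities = entities, n_entities = nrow(entities), rank_tally = tally)
}

#' Habitat and trophic categorisation of prey items
#'
#' Attaches the five-class habitat and the half-unit trophic bin to each
#' prey item. Trophic bins are closed at their printed endpoints
#' (2.0-2.5, 2.6-3.0, 3.1-3.5, 3.6-4.0, 4.1-4.5); values falling in the
#' one-decimal gaps between bins go to the nearest bin (ties round up).
#' Guild is planktivore for bins up to 3.0 and carnivore above. Items
#' without a trait record are flagged uncategorised (they stay in item-level
#' summaries but are excluded from category summaries).
#'
#' @param items character vector of prey taxon names.
#' @param traits trait table ([read_traits()]).
#' @return data.frame with columns `item`, `habitat_class`, `trophic_level`,
#'   `trophic_bin`, `guild`, `categorized`.
#' @export
categorize_prey <- function(items, traits) {
  idx <- match(tolower(items), tolower(traits$taxon))
  tl <- traits$trophic_level[idx]
  bin_i <- findInterval(tl, trophic_bin_breaks, left.open = FALSE)
  bin <- trophic_bin_labels[pmin(bin_i, 5L)]
  data.frame(item = items,
             habitat_class = traits$habitat_class[idx],
             trophic_level = tl,
             trophic_bin = bin,
             guild = ifelse(bin_i <= 2, "planktivore", "carnivore"),
             categorized = !is.na(idx),
             stringsAsFactors = FALSE)
}
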