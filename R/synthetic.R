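#' Configuration for the synthetic scat-metabarcoding generator
#'
#' Builds the parameter set for [simulate_experiment()]. Defaults emulate the
#' structure of a five-rookery sea lion scat study: per-sample predator-read
#' dominance with two PCR assays per scat (a blocking-primer assay that
#' suppresses predator DNA and a no-blocking assay that does not),
#' rookery-structured multinomial prey compositions, sparse per-sample prey
#' richness (mean about 2.7 items), tag-switch read leakage across samples,
#' non-marine contaminant OTUs, and negative controls carrying predator and
#' contaminant reads.
#'
#' @param n_rookeries number of rookeries.
#' @param samples_per_rookery integer vector (recycled) of scats per rookery.
#' @param rookery_names labels; defaults to the five southeastern Galapagos
#'   rookeries.
#' @param n_negative_controls number of extraction/PCR blanks.
#' @param global_prey_pool total number of prey OTUs available to the system.
#' @param prey_pool_size number of prey OTUs available within each rookery.
#' @param dirichlet_concentration sharpness of each rookery's prey-frequency
#'   vector (smaller = a few dominant prey; larger = even diets).
#' @param mean_items_per_sample mean prey items per scat (zero-truncated
#'   Poisson; must exceed 1).
#' @param reads_per_sample_range integer range of sequencing depth per assay
#'   replicate.
#' @param predator_read_fraction named numeric, fraction of reads that are
#'   predator (host) DNA per assay; `blocking` must not exceed `no_blocking`.
#' @param tag_switch_rate per-read probability of misassignment to a
#'   uniformly random other sample (index hopping).
#' @param contaminant_otus number of non-marine contaminant OTUs.
#' @param contaminant_read_fraction fraction of each sample's reads drawn
#'   from contaminant OTUs.
#' @param control_reads_range depth range for negative controls (controls are
#'   empty when both contamination sources are 0).
#' @param control_predator_fraction relative abundance of predator reads in
#'   negative controls; this is what the tag-switch floor estimates.
#' @param n_low_identity_otus prey-like OTUs planted with BLAST identity
#'   below 70 (exercises the identity filter).
#' @param n_nohit_otus OTUs planted with no BLAST hit at all.
#' @param n_nonchecklist_otus prey OTUs whose species is absent from the
#'   regional checklist (exercises the genus-escalation rule).
#' @param seed integer; fixes all randomness. Component draws use
#'   independent derived streams, so e.g. changing the number of controls
#'   does not perturb the sample-level draws.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_rookeries = 5,
                       samples_per_rookery = c(36, 23, 22, 20, 23),
                       rookery_names = c("Malecon", "PuntaPitt", "SantaFe",
                                         "Floreana", "Espanola"),
                       n_negative_controls = 3,
                       global_prey_pool = 98,
                       prey_pool_size = 40,
                       dirichlet_concentration = 0.4,
                       mean_items_per_sample = 2.7,
                       reads_per_sample_range = c(500, 5000),
                       predator_read_fraction = c(blocking = 0.55,
                                                  no_blocking = 0.90),
                       tag_switch_rate = 5e-4,
                       contaminant_otus = 4,
                       contaminant_read_fraction = 0.02,
                       control_reads_range = c(2000, 20000),
                       control_predator_fraction = 0.000514,
                       n_low_identity_otus = 3,
                       n_nohit_otus = 2,
                       n_nonchecklist_otus = 4,
                       seed = 1L) {
  cfg <- list(n_rookeries = as.integer(n_rookeries),
              samples_per_rookery = rep_len(as.integer(samples_per_rookery),
                                            n_rookeries),
              rookery_names = rep_len(as.character(rookery_names), n_rookeries),
              n_negative_controls = as.integer(n_negative_controls),
              global_prey_pool = as.integer(global_prey_pool),
              prey_pool_size = as.integer(prey_pool_size),
              dirichlet_concentration = dirichlet_concentration,
              mean_items_per_sample = mean_items_per_sample,
              reads_per_sample_range = as.integer(reads_per_sample_range),
              predator_read_fraction = predator_read_fraction,
              tag_switch_rate = tag_switch_rate,
              contaminant_otus = as.integer(contaminant_otus),
              contaminant_read_fraction = contaminant_read_fraction,
              control_reads_range = as.integer(control_reads_range),
              control_predator_fraction = control_predator_fraction,
              n_low_identity_otus = as.integer(n_low_identity_otus),
              n_nohit_otus = as.integer(n_nohit_otus),
              n_nonchecklist_otus = as.integer(n_nonchecklist_otus),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  props <- c(cfg$tag_switch_rate, cfg$contaminant_read_fraction,
             cfg$control_predator_fraction, cfg$predator_read_fraction)
  if (any(props < 0 | props > 1))
    stop("all proportions must lie in [0,1]")
  if (cfg$predator_read_fraction[["blocking"]] >
      cfg$predator_read_fraction[["no_blocking"]])
    stop("predator_read_fraction must satisfy blocking <= no_blocking")
  if (sum(cfg$predator_read_fraction[["no_blocking"]],
          cfg$contaminant_read_fraction) >= 1)
    stop("predator + contaminant fractions leave no room for prey reads")
  if (cfg$mean_items_per_sample <= 1)
    stop("mean_items_per_sample must exceed 1 (zero-truncated Poisson)")
  if (cfg$prey_pool_size > cfg$global_prey_pool)
    stop("prey_pool_size cannot exceed global_prey_pool")
  if (cfg$mean_items_per_sample >= cfg$prey_pool_size)
    stop("infeasible config: prey pool smaller than mean items per sample")
  if (any(cfg$reads_per_sample_range <= 0) ||
      diff(cfg$reads_per_sample_range) < 0)
    stop("reads_per_sample_range must be a positive non-decreasing pair")
  if (is.na(cfg$seed)) stop("seed is required")
  cfg
}

# Independent per-component sub-seeds derived from the master seed, so that
# draws for one component (e.g. negative controls) do not shift another's.
derive_streams <- function(seed, components) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, length(components))
  names(s) <- components
  s
}

# zero-truncated Poisson with a given mean (> 1): solve for lambda, then
# sample by inversion on the truncated distribution
ztp_lambda <- function(mean) {
  stats::uniroot(function(l) l / (1 - exp(-l)) - mean,
                 interval = c(1e-9, 1e3), tol = 1e-12)$root
}

rztpois <- function(n, lambda) {
  stats::qpois(stats::runif(n, stats::dpois(0, lambda), 1), lambda)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

# integer allocation of `total` over `shares` by largest-remainder rounding
allocate_reads <- function(total, shares) {
  if (total == 0) return(integer(length(shares)))
  raw <- shares / sum(shares) * total
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Simulate a scat-metabarcoding experiment with known ground truth
#'
#' Generates a full synthetic dataset: a raw OTU read-count table with two
#' assay replicates per scat plus negative controls, the matching BLAST-style
#' hit records, a prey trait table, a regional checklist, and a ground-truth
#' object recording which prey items truly occurred in which scat.
#'
#' Per scat, the number of prey items is zero-truncated Poisson with the
#' configured mean; items are drawn without replacement using the rookery's
#' Dirichlet prey-frequency vector. Each assay replicate's reads are split
#' between predator, contaminants and prey; prey reads are allocated over the
#' scat's items by largest-remainder rounding of Dirichlet-mixture shares
#' floored at 30% of uniform, so that every true item receives more than 1%
#' of the prey reads and occurrence is in principle recoverable. Tag-switch
#' leakage then moves each read to a uniformly random other sample with the
#' configured probability (conserving each OTU's total reads).
#'
#' @param config a [sim_config()].
#' @return list with elements `table` (a [read_count_table()], including a
#'   `scat_id` metadata column tying assay replicates together), `truth`
#'   (list: `occurrence` binary scats x prey-OTU matrix, `prey_otus`,
#'   `predator_otu`, `contaminant_otus`, `rookery_frequencies`), `hits`,
#'   `traits`, `checklist`, and `config`.
#' @examples
#' sim <- simulate_experiment(sim_config(samples_per_rookery = 4, seed = 7))
#' sim$table
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  streams <- derive_streams(cfg$seed,
                            c("pool", "items", "depths", "alloc",
                              "switch", "controls", "hits", "traits"))

  n_prey <- cfg$global_prey_pool
  prey_otus <- sprintf("OTU_p%03d", seq_len(n_prey))
  predator_otu <- "OTU_zalophus"
  contam_otus <- if (cfg$contaminant_otus > 0)
    sprintf("OTU_c%02d", seq_len(cfg$contaminant_otus)) else character()
  all_otus <- c(prey_otus, predator_otu, contam_otus)

  # --- rookery prey pools and Dirichlet frequency vectors ------------------
  set.seed(streams[["pool"]])
  rook_pool <- rook_freq <- vector("list", cfg$n_rookeries)
  names(rook_pool) <- names(rook_freq) <- cfg$rookery_names
  for (r in seq_len(cfg$n_rookeries)) {
    pool <- sort(sample.int(n_prey, cfg$prey_pool_size))
    f <- rdirichlet1(rep(cfg$dirichlet_concentration, cfg$prey_pool_size))
    rook_pool[[r]] <- pool
    rook_freq[[r]] <- stats::setNames(f, prey_otus[pool])
  }

  scat_ids <- unlist(lapply(seq_len(cfg$n_rookeries), function(r)
    sprintf("%s_%02d", cfg$rookery_names[r],
            seq_len(cfg$samples_per_rookery[r]))))
  scat_rook <- rep(cfg$rookery_names, cfg$samples_per_rookery)
  n_scat <- length(scat_ids)

  # --- true per-scat prey items and within-scat read shares ----------------
  set.seed(streams[["items"]])
  lambda <- ztp_lambda(cfg$mean_items_per_sample)
  occurrence <- matrix(0L, n_scat, n_prey,
                       dimnames = list(scat_ids, prey_otus))
  scat_items <- scat_shares <- vector("list", n_scat)
  for (s in seq_len(n_scat)) {
    pool <- rook_pool[[scat_rook[s]]]
    freq <- rook_freq[[scat_rook[s]]]
    k <- min(rztpois(1, lambda), length(pool))
    items <- sample(pool, k, prob = freq)
    occurrence[s, items] <- 1L
    dir <- rdirichlet1(rep(2, k))
    scat_items[[s]] <- items
    scat_shares[[s]] <- 0.7 * dir + 0.3 / k   # floor: every item > 1% of prey reads
  }

  # --- assay replicate read depths and allocation --------------------------
  assays <- c("blocking", "no_blocking")
  rep_ids <- as.vector(t(outer(scat_ids, assays, paste, sep = ".")))
  set.seed(streams[["depths"]])
  depths <- sample(cfg$reads_per_sample_range[1]:cfg$reads_per_sample_range[2],
                   length(rep_ids), replace = TRUE)
  set.seed(streams[["alloc"]])
  counts <- matrix(0L, length(rep_ids), length(all_otus),
                   dimnames = list(rep_ids, all_otus))
  for (i in seq_along(rep_ids)) {
    s <- (i + 1L) %/% 2L
    assay <- assays[2L - i %% 2L]
    d <- depths[i]
    n_pred <- as.integer(round(d * cfg$predator_read_fraction[[assay]]))
    n_cont <- as.integer(round(d * cfg$contaminant_read_fraction))
    n_prey_reads <- d - n_pred - n_cont
    counts[i, predator_otu] <- n_pred
    if (n_cont > 0 && length(contam_otus))
      counts[i, contam_otus] <- allocate_reads(n_cont,
                                               rep(1, length(contam_otus)))
    counts[i, prey_otus[scat_items[[s]]]] <-
      allocate_reads(n_prey_reads, scat_shares[[s]])
  }

  # --- negative controls ----------------------------------------------------
  set.seed(streams[["controls"]])
  ctrl_ids <- if (cfg$n_negative_controls > 0)
    sprintf("NTC_%02d", seq_len(cfg$n_negative_controls)) else character()
  ctrl_counts <- matrix(0L, length(ctrl_ids), length(all_otus),
                        dimnames = list(ctrl_ids, all_otus))
  clean_blanks <- cfg$contaminant_read_fraction == 0 &&
    cfg$control_predator_fraction == 0
  for (i in seq_along(ctrl_ids)) {
    if (clean_blanks) next
    d <- sample(cfg$control_reads_range[1]:cfg$control_reads_range[2], 1)
    n_pred <- if (cfg$control_predator_fraction > 0)
      max(1L, as.integer(round(d * cfg$control_predator_fraction))) else 0L
    ctrl_counts[i, predator_otu] <- n_pred
    if (length(contam_otus) && cfg$contaminant_read_fraction > 0)
      ctrl_counts[i, contam_otus] <- allocate_reads(d - n_pred,
                                                    rep(1, length(contam_otus)))
  }
  counts <- rbind(counts, ctrl_counts)

  # --- tag-switch leakage: per-OTU uniform read misassignment ---------------
  set.seed(streams[["switch"]])
  if (cfg$tag_switch_rate > 0 && nrow(counts) > 1) {
    n <- nrow(counts)
    for (j in seq_len(ncol(counts))) {
      col <- counts[, j]
      src <- which(col > 0L)
      moved <- stats::rbinom(length(src), col[src], cfg$tag_switch_rate)
      for (k in seq_along(src)) {
        if (moved[k] == 0L) next
        dest <- sample.int(n - 1L, moved[k], replace = TRUE)
        dest <- ifelse(dest >= src[k], dest + 1L, dest)
        col[src[k]] <- col[src[k]] - moved[k]
        tab <- tabulate(dest, nbins = n)
        col <- col + tab
      }
      counts[, j] <- as.integer(col)
    }
  }

  meta <- data.frame(
    sample_id = rownames(counts),
    rookery = c(rep(scat_rook, each = 2L), rep("", length(ctrl_ids))),
    is_negative_control = c(rep(FALSE, length(rep_ids)),
                            rep(TRUE, length(ctrl_ids))),
    assay = c(rep(assays, n_scat), rep("pooled", length(ctrl_ids))),
    scat_id = c(rep(scat_ids, each = 2L), ctrl_ids),
    stringsAsFactors = FALSE)
  table <- read_count_table(counts, meta)

  # --- taxonomy hits, traits, checklist -------------------------------------
  set.seed(streams[["hits"]])
  species <- synthetic_species_names(n_prey)
  # plant identity bands and awkward cases at the tail of the pool
  identity <- round(stats::runif(n_prey, 96.1, 100), 1)
  n_band <- min(n_prey %/% 10, 9)
  if (n_band >= 3) {
    band_idx <- seq_len(n_band)
    identity[band_idx] <- round(c(
      stats::runif(ceiling(n_band / 3), 92, 95.9),
      stats::runif(ceiling(n_band / 3), 85, 91.9),
      stats::runif(n_band - 2 * ceiling(n_band / 3), 70, 84.9)
    ), 1)
  }
  lowid_otus <- nohit_otus <- nonck_otus <- character()
  if (cfg$n_low_identity_otus > 0) {
    lowid_otus <- sprintf("OTU_low%02d", seq_len(cfg$n_low_identity_otus))
  }
  if (cfg$n_nohit_otus > 0) {
    nohit_otus <- sprintf("OTU_nohit%02d", seq_len(cfg$n_nohit_otus))
  }
  if (cfg$n_nonchecklist_otus > 0) {
    nonck_otus <- prey_otus[sample.int(n_prey, cfg$n_nonchecklist_otus)]
  }
  hits <- data.frame(
    otu_id = prey_otus,
    taxon = species$species,
    percent_identity = identity,
    e_value = signif(10^stats::runif(n_prey, -80, -45), 3),
    species = species$species, genus = species$genus,
    family = species$family, order = species$order,
    class = "Actinopterygii",
    stringsAsFactors = FALSE)
  hits <- rbind(hits, data.frame(
    otu_id = predator_otu, taxon = "Zalophus wollebaeki",
    percent_identity = 99.6, e_value = 1e-100,
    species = "Zalophus wollebaeki", genus = "Zalophus",
    family = "Otariidae", order = "Carnivora", class = "Mammalia",
    stringsAsFactors = FALSE))
  if (length(contam_otus)) {
    contam_species <- c("Homo sapiens", "Gallus gallus", "Bos taurus",
                        "Canis lupus", "Sus scrofa", "Rattus rattus")
    cs <- rep_len(contam_species, length(contam_otus))
    hits <- rbind(hits, data.frame(
      otu_id = contam_otus, taxon = cs, percent_identity = 99,
      e_value = 1e-90, species = cs,
      genus = vapply(strsplit(cs, " "), `[`, "", 1),
      family = "", order = "", class = "Mammalia",
      stringsAsFactors = FALSE))
  }
  if (length(lowid_otus)) {
    hits <- rbind(hits, data.frame(
      otu_id = lowid_otus, taxon = "Incertae sedis",
      percent_identity = round(stats::runif(length(lowid_otus), 50, 69.9), 1),
      e_value = 1e-5, species = "", genus = "", family = "", order = "",
      class = "", stringsAsFactors = FALSE))
  }
  # low-identity and no-hit OTUs get a sprinkling of reads in a few samples
  extra <- c(lowid_otus, nohit_otus)
  if (length(extra)) {
    extra_counts <- matrix(0L, nrow(table$counts), length(extra),
                           dimnames = list(rownames(table$counts), extra))
    non_ctrl <- which(!table$meta$is_negative_control)
    for (j in seq_along(extra)) {
      pick <- sample(non_ctrl, min(3, length(non_ctrl)))
      extra_counts[pick, j] <- sample(20:200, length(pick), replace = TRUE)
    }
    table <- read_count_table(cbind(table$counts, extra_counts), table$meta)
  }

  set.seed(streams[["traits"]])
  uniq_sp <- unique(species$species)
  traits <- data.frame(
    taxon = uniq_sp,
    habitat_class = sample(habitat_classes, length(uniq_sp), replace = TRUE),
    trophic_level = round(stats::runif(length(uniq_sp), 2.0, 4.5), 1),
    stringsAsFactors = FALSE)
  checklist <- setdiff(uniq_sp, unique(hits$taxon[hits$otu_id %in% nonck_otus]))
  checklist <- c(checklist, "Octopus oculifer")

  truth <- list(occurrence = occurrence,
                prey_otus = prey_otus,
                predator_otu = predator_otu,
                contaminant_otus = contam_otus,
                planted_low_identity = lowid_otus,
                planted_no_hit = nohit_otus,
                planted_non_checklist = nonck_otus,
                rookery_frequencies = rook_freq)
  list(table = table, truth = truth, hits = hits, traits = traits,
       checklist = checklist, config = cfg)
}

# fake but well-formed binomials; roughly every third OTU shares a genus and
# some OTUs share a species so entity collapsing has work to do
synthetic_species_names <- function(n) {
  genus_pool <- sprintf("Pseudopiscis%02d", seq_len(ceiling(n / 3)))
  genus <- rep(genus_pool, each = 3, length.out = n)
  epithet <- sprintf("sp%03d", seq_len(n))
  # every 8th OTU duplicates the previous species name (same entity)
  dup <- which(seq_len(n) %% 8 == 0 & seq_len(n) > 1)
  epithet[dup] <- epithet[dup - 1]
  genus[dup] <- genus[dup - 1]
  species <- paste(genus, epithet)
  family <- sprintf("Fam%02didae", (match(genus, genus_pool) - 1) %/% 3 + 1)
  order <- sprintf("Ord%02diformes", (match(genus, genus_pool) - 1) %/% 9 + 1)
  list(species = species, genus = genus, family = family, order = order)
}

#' Simulate a grouped occurrence matrix with a known between-group shift
#'
#' Test harness for the community statistics: draws binary samples x items
#' matrices where one group's item-occurrence probabilities are shifted away
#' from the common baseline by `effect_size`. At `effect_size = 0` all groups
#' are exchangeable (type-I calibration); large values give high power.
#'
#' @param config a [sim_config()]; rookery count/sizes and prey pool size are
#'   used, plus its `seed` unless `seed` is given.
#' @param effect_size non-negative; 0 means no group signal. The shifted
#'   group's probabilities are mixed with a permuted copy:
#'   `p' = (1-e)*p + e*p[perm]` truncated to `[0.02, 0.98]`.
#' @param seed optional integer overriding `config$seed`.
#' @return list with `occurrence` (binary matrix, no all-zero rows) and
#'   `groups` (factor of group labels).
#' @export
simulate_group_shift <- function(config, effect_size, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), effect_size >= 0)
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  n_items <- config$prey_pool_size
  k <- config$n_rookeries
  sizes <- config$samples_per_rookery
  base_freq <- rdirichlet1(rep(config$dirichlet_concentration, n_items))
  p <- pmin(pmax(base_freq * config$mean_items_per_sample, 0.02), 0.98)
  perm <- sample.int(n_items)
  p_shift <- pmin(pmax((1 - effect_size) * p + effect_size * p[perm],
                       0.02), 0.98)
  groups <- factor(rep(config$rookery_names, sizes),
                   levels = config$rookery_names)
  n <- sum(sizes)
  occ <- matrix(0L, n, n_items,
                dimnames = list(sprintf("s%03d", seq_len(n)),
                                sprintf("item%02d", seq_len(n_items))))
  shifted_group <- config$rookery_names[k]
  for (i in seq_len(n)) {
    pr <- if (groups[i] == shifted_group && effect_size > 0) p_shift else p
    repeat {
      row <- stats::rbinom(n_items, 1L, pr)
      if (sum(row) > 0) break
    }
    occ[i, ] <- row
  }
  list(occurrence = occ, groups = groups)
}
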