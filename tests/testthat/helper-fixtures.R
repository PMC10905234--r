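# in-code fixture builders shared across test files

make_table <- function(counts, rookery = NULL, negatives = NULL,
                       assay = "pooled") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("s%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("OTU_%02d", seq_len(ncol(counts)))
  n <- nrow(counts)
  if (is.null(rookery)) rookery <- rep("A", n)
  if (is.null(negatives)) negatives <- rep(FALSE, n)
  rookery[negatives] <- ""
  read_count_table(counts, data.frame(
    sample_id = rownames(counts), rookery = rookery,
    is_negative_control = negatives, assay = rep_len(assay, n),
    stringsAsFactors = FALSE))
}

make_hits <- function(otu_id, taxon, identity, species = taxon,
                      genus = vapply(strsplit(taxon, " "), `[`, "", 1),
                      family = "Famidae", order = "Ordiformes",
                      class = "Actinopterygii") {
  data.frame(otu_id = otu_id, taxon = taxon, percent_identity = identity,
             e_value = 1e-50, species = species, genus = genus,
             family = family, order = order, class = class,
             stringsAsFactors = FALSE)
}

# noise-free simulation: every filtering step should be a no-op apart from
# predator removal, so the cascade must recover the truth exactly
noise_free_config <- function(seed = 42, samples = c(8, 8, 8, 8, 8)) {
  sim_config(samples_per_rookery = samples, tag_switch_rate = 0,
             contaminant_read_fraction = 0, control_predator_fraction = 0,
             n_low_identity_otus = 0, n_nohit_otus = 0, seed = seed)
}

occurrence_equal <- function(occ, truth) {
  truth <- truth[, colSums(truth) > 0, drop = FALSE]
  m <- if (inherits(occ, "occurrence_matrix")) occ$matrix else occ
  if (!setequal(rownames(m), rownames(truth))) return(FALSE)
  if (!setequal(colnames(m), colnames(truth))) return(FALSE)
  all(m[rownames(truth), colnames(truth)] == truth)
}

# independent one-way PERMANOVA route: sums of squared distances within
# groups (Anderson 2001), no Gower centering involved
permanova_f_direct <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- factor(groups)
  ss_total <- sum(d[lower.tri(d)]^2) / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    sub <- d[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  ss_a <- ss_total - ss_within
  k <- nlevels(groups)
  (ss_a / (k - 1)) / (ss_within / (n - k))
}
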