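test_that("tag-switch floor is the max predator fraction over controls", {
  # two controls engineered to predator fractions 0.000514 and 0.0003
  counts <- rbind(c(514L, 999486L), c(3L, 9997L), c(500L, 500L))
  dimnames(counts) <- list(c("ntc1", "ntc2", "samp"), c("pred", "prey"))
  tb <- make_table(counts, negatives = c(TRUE, TRUE, FALSE))
  expect_equal(compute_tag_switch_floor(tb, "pred"), 0.000514)

  # hand arithmetic: 2/1000 vs 1/4000
  counts2 <- rbind(c(2L, 998L), c(1L, 3999L), c(10L, 10L))
  dimnames(counts2) <- list(c("a", "b", "samp"), c("pred", "prey"))
  tb2 <- make_table(counts2, negatives = c(TRUE, TRUE, FALSE))
  expect_equal(compute_tag_switch_floor(tb2, "pred"), 0.002)

  # controls without predator reads give 0; no controls is an error
  counts3 <- rbind(c(0L, 100L), c(5L, 5L))
  dimnames(counts3) <- list(c("ntc", "samp"), c("pred", "prey"))
  expect_equal(compute_tag_switch_floor(
    make_table(counts3, negatives = c(TRUE, FALSE)), "pred"), 0)
  expect_error(compute_tag_switch_floor(make_table(counts3), "pred"),
               "no negative controls")
})

test_that("floor nullification is strict and uses pre-nullification totals", {
  counts <- matrix(c(5L, 6L, 9989L), 1, 3,
                   dimnames = list("s1", c("low", "edge", "big")))
  tb <- make_table(counts)
  out <- nullify_below_floor(tb, 0.000514)
  expect_equal(unname(out$counts["s1", ]), c(0L, 6L, 9989L))  # 5/10000 < T
  expect_identical(nullify_below_floor(tb, 0)$counts, tb$counts)
})

test_that("OTU screening applies the 70% boundary, predator and blacklist rules", {
  counts <- matrix(10L, 1, 5, dimnames = list("s1", paste0("o", 1:5)))
  tb <- make_table(counts)
  hits <- make_hits(c("o1", "o2", "o3", "o4"),
                    c("Fishus one", "Fishus two", "Zalophus wollebaeki",
                      "Gallus gallus"),
                    c(69.9, 70.0, 99.6, 99.0))
  cfg <- filter_config(blacklist = "Gallus gallus")
  res <- screen_otus(tb, hits, cfg)
  expect_setequal(colnames(res$table$counts), "o2")   # 70.0 retained
  expect_equal(res$removals$reason[res$removals$otu_id == "o1"],
               "low_identity")
  expect_equal(res$removals$reason[res$removals$otu_id == "o3"], "predator")
  expect_equal(res$removals$reason[res$removals$otu_id == "o4"],
               "contaminant")
  expect_equal(res$removals$reason[res$removals$otu_id == "o5"], "no_hit")
  # cascade mode keeps contaminant columns for the control-based step
  res2 <- screen_otus(tb, hits, cfg, drop_contaminants = FALSE)
  expect_true("o4" %in% colnames(res2$table$counts))
})

test_that("control-based filters: 'equal or less' boundary and sample threshold", {
  counts <- rbind(ntc = c(10L, 0L, 0L),
                  s1 = c(10L, 50L, 0L),
                  s2 = c(11L, 60L, 0L))
  colnames(counts) <- c("oA", "oB", "oC")
  tb <- make_table(counts, negatives = c(TRUE, FALSE, FALSE))
  out <- control_based_filters(tb)
  expect_equal(out$counts["s1", "oA"], 0L)   # 10 <= 10 nullified
  expect_equal(out$counts["s2", "oA"], 11L)  # 11 > 10 kept

  # contaminant share 200/1000 = 0.2: rel 0.19 nullified, 0.21 kept
  counts2 <- rbind(s1 = c(200L, 190L, 210L, 400L))
  colnames(counts2) <- c("cont", "p19", "p21", "rest")
  tb2 <- make_table(counts2)
  out2 <- control_based_filters(tb2, obvious_contaminant_otus = "cont")
  expect_false("cont" %in% colnames(out2$counts))
  expect_equal(out2$counts["s1", "p19"], 0L)
  expect_equal(out2$counts["s1", "p21"], 210L)

  # no controls, no contaminants: identity
  tb3 <- make_table(matrix(c(5L, 7L), 1, 2))
  expect_identical(control_based_filters(tb3)$counts, tb3$counts)
})

test_that("minor-OTU rule is strict at 1% and singletons are removed", {
  counts <- rbind(s1 = c(9L, 10L, 981L),
                  s2 = c(0L, 0L, 500L))
  colnames(counts) <- c("p09", "p10", "big")
  tb <- make_table(counts)
  out <- minor_otu_filter(tb, filter_config())
  expect_equal(out$counts["s1", "p09"], 0L)    # 0.9% < 1%
  expect_equal(out$counts["s1", "p10"], 10L)   # exactly 1% kept

  # a sample with a single OTU keeps it (100%)
  tb2 <- make_table(matrix(3L, 1, 1))
  expect_identical(minor_otu_filter(tb2, filter_config())$counts, tb2$counts)

  # dataset-wide singleton removed under the reads definition
  counts3 <- rbind(s1 = c(1L, 50L), s2 = c(0L, 50L))
  colnames(counts3) <- c("single", "keep")
  tb3 <- make_table(counts3)
  out3 <- minor_otu_filter(tb3, filter_config(per_sample_min_fraction = 0))
  expect_false("single" %in% colnames(out3$counts))
  out4 <- minor_otu_filter(tb3, filter_config(
    per_sample_min_fraction = 0, singleton_definition = "samples"))
  expect_false("single" %in% colnames(out4$counts))
  expect_true("keep" %in% colnames(out4$counts))   # present in 2 samples
})

test_that("sample exclusion drops <2-read samples then the lowest quartile", {
  totals <- c(1L, 10L, 40L, 50L, 60L, 80L)
  counts <- matrix(totals, 6, 1,
                   dimnames = list(sprintf("s%d", 1:6), "o1"))
  tb <- make_table(counts)
  ex <- exclude_samples(tb, filter_config())
  expect_equal(ex$quartile_cutoff, 40)
  expect_setequal(rownames(ex$table$counts), c("s3", "s4", "s5", "s6"))
  expect_setequal(
    ex$excluded$reason[ex$excluded$sample_id %in% c("s1", "s2")],
    c("below_absolute_minimum", "lowest_quartile"))

  # equal totals: nothing dropped by the quartile
  tbe <- make_table(matrix(50L, 5, 1))
  exe <- exclude_samples(tbe, filter_config())
  expect_equal(nrow(exe$table$counts), 5)

  # < 4 samples: quartile skipped with a warning
  tbs <- make_table(matrix(c(10L, 20L, 30L), 3, 1))
  expect_warning(exs <- exclude_samples(tbs, filter_config()),
                 "fewer than 4")
  expect_equal(nrow(exs$table$counts), 3)
})

test_that("assay pooling sums replicate counts per scat before thresholds", {
  counts <- rbind(a.blocking = c(3L, 0L), a.no_blocking = c(2L, 5L),
                  ntc = c(0L, 1L))
  colnames(counts) <- c("o1", "o2")
  tb <- read_count_table(counts, data.frame(
    sample_id = rownames(counts), rookery = c("R", "R", ""),
    is_negative_control = c(FALSE, FALSE, TRUE),
    assay = c("blocking", "no_blocking", "pooled"),
    scat_id = c("a", "a", "ntc")))
  pooled <- pool_assays(tb)
  expect_equal(unname(pooled$counts["a", ]), c(5L, 5L))
  expect_equal(unname(pooled$counts["ntc", ]), c(0L, 1L))
  expect_equal(pooled$meta$assay[pooled$meta$sample_id == "a"], "pooled")
})

test_that("noise-free cascade recovers the ground truth exactly", {
  sim <- simulate_experiment(noise_free_config())
  res <- run_filter_cascade(sim$table, sim$hits,
                            filter_config(lowest_quartile_exclusion = FALSE))
  occ <- to_occurrence(res$table)
  expect_true(occurrence_equal(occ, sim$truth$occurrence))
  # report accounting: no contaminant-step removals on clean data
  expect_equal(res$report$steps$control_based_filters$reads_removed, 0)
  expect_equal(res$report$derived$tag_switch_floor, 0)
})

test_that("cascade is idempotent (derived thresholds frozen on re-run)", {
  sim <- simulate_experiment(sim_config(seed = 11))
  cfg <- filter_config(blacklist = c("Homo sapiens", "Gallus gallus",
                                     "Bos taurus", "Canis lupus"))
  first <- run_filter_cascade(sim$table, sim$hits, cfg)
  frozen <- filter_config(
    tag_switch_floor = first$report$derived$tag_switch_floor,
    blacklist = cfg$blacklist,
    quartile_cutoff = first$report$derived$quartile_cutoff)
  again <- run_filter_cascade(first$table, sim$hits, frozen)
  expect_identical(again$table$counts, first$table$counts)

  # strict re-application idempotence with the quartile step disabled
  cfg2 <- filter_config(blacklist = cfg$blacklist,
                        lowest_quartile_exclusion = FALSE)
  a <- run_filter_cascade(sim$table, sim$hits, cfg2)
  b <- suppressWarnings(run_filter_cascade(a$table, sim$hits, cfg2))
  expect_identical(b$table$counts, a$table$counts)
})

test_that("every cascade step is monotone and accounting is consistent", {
  sim <- simulate_experiment(sim_config(seed = 5,
                                        samples_per_rookery = c(6, 6, 6)))
  cfg <- filter_config(blacklist = c("Homo sapiens", "Gallus gallus",
                                     "Bos taurus", "Canis lupus"))
  res <- run_filter_cascade(sim$table, sim$hits, cfg)
  steps <- res$report$steps
  for (nm in names(steps)) {
    s <- steps[[nm]]
    expect_gte(s$otus_removed, 0)
    expect_gte(s$samples_removed, 0)
    if (nm != "pool_assays") expect_gte(s$reads_removed, 0)
    # removed + retained = input, per dimension
    expect_equal(s$before$samples - s$samples_removed, s$after$samples)
    expect_equal(s$before$otus - s$otus_removed, s$after$otus)
  }
  # with all thresholds off, cascade = pooled input minus controls
  # (and minus nothing else)
  off <- filter_config(tag_switch_floor = 0, min_identity = 0,
                       predator_taxa = character(),
                       per_sample_min_fraction = 0, drop_singletons = FALSE,
                       min_sample_reads_absolute = 0,
                       lowest_quartile_exclusion = FALSE)
  sim2 <- simulate_experiment(noise_free_config(seed = 9,
                                                samples = c(4, 4, 4, 4, 4)))
  res2 <- run_filter_cascade(sim2$table, sim2$hits, off)
  pooled <- pool_assays(sim2$table)
  keep <- setdiff(rownames(pooled$counts), negative_control_ids(pooled))
  nonzero <- colSums(pooled$counts[keep, , drop = FALSE]) > 0
  expect_identical(res2$table$counts,
                   pooled$counts[keep, nonzero, drop = FALSE])
})

test_that("inferential subset keeps samples with at least 100 reads", {
  counts <- matrix(c(99L, 100L, 101L), 3, 1,
                   dimnames = list(c("a", "b", "c"), "o1"))
  tb <- make_table(counts)
  expect_setequal(rownames(subset_inferential(tb)$counts), c("b", "c"))
  all_hi <- make_table(matrix(500L, 3, 1))
  expect_identical(subset_inferential(all_hi)$counts, all_hi$counts)
})
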