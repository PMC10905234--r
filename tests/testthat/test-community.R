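test_that("Jaccard distances: hand values and metric properties", {
  m <- rbind(s1 = c(1, 1, 0), s2 = c(0, 1, 1), s3 = c(1, 1, 0))
  d <- jaccard_distances(m)
  expect_equal(d["s1", "s3"], 0)           # identical rows
  expect_equal(d["s1", "s2"], 1 - 1 / 3)   # {A,B} vs {B,C}
  disj <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(jaccard_distances(disj)["a", "b"], 1)
  expect_error(jaccard_distances(rbind(c(1, 0), c(0, 0))), "no items")

  # triangle inequality on random binary matrices
  set.seed(8)
  for (rep in 1:5) {
    mm <- matrix(rbinom(80, 1, 0.5), 8, 10)
    mm[rowSums(mm) == 0, 1] <- 1
    dd <- jaccard_distances(mm)
    for (i in 1:8) for (j in 1:8) for (k in 1:8)
      expect_lte(dd[i, j], dd[i, k] + dd[k, j] + 1e-12)
    expect_equal(dd, t(dd))
  }
})

test_that("PERMANOVA on a 2x2 toy matches hand computation and exhaustive permutation", {
  # two groups of 2, within-distance 0, between-distance 1
  d <- matrix(1, 4, 4) - diag(4)
  d[1, 2] <- d[2, 1] <- 0
  d[3, 4] <- d[4, 3] <- 0
  dimnames(d) <- list(letters[1:4], letters[1:4])
  groups <- factor(c("g1", "g1", "g2", "g2"))
  # hand: SS_total = (sum d^2 over pairs)/n = 4/4 = 1; SS_within = 0
  # => SS_A = 1, F = (1/1)/(0/2) = Inf; use a perturbed version instead
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.1
  all_perms <- scatdiet:::all_permutations(4)
  fit <- permanova(d, groups, permutations = all_perms, seed = 1)
  ss_total <- sum(d[lower.tri(d)]^2) / 4
  ss_within <- (0.1^2) / 2 + (0.1^2) / 2
  ss_a <- ss_total - ss_within
  expect_equal(fit$aov_table$SS[1], ss_a, tolerance = 1e-12)
  expect_equal(fit$aov_table$SS[3], ss_total, tolerance = 1e-12)
  f_direct <- permanova_f_direct(d, groups)
  expect_equal(fit$aov_table$F[1], f_direct, tolerance = 1e-12)
  # exhaustive-permutation p: brute-force oracle over all 4! relabelings
  f_perms <- apply(all_perms, 1, function(p)
    permanova_f_direct(d[p, p], groups))
  p_oracle <- (1 + sum(f_perms >= f_direct - 1e-12)) / (1 + nrow(all_perms))
  expect_equal(fit$aov_table$p[1], p_oracle)
})

test_that("PERMANOVA equals the brute-force route on a 7-sample toy", {
  set.seed(21)
  m <- matrix(rbinom(42, 1, 0.5), 7, 6)
  m[rowSums(m) == 0, 1] <- 1
  d <- jaccard_distances(m)
  groups <- factor(rep(c("x", "y"), c(4, 3)))
  all_perms <- scatdiet:::all_permutations(7)
  fit <- permanova(d, groups, permutations = all_perms, seed = 1)
  f_direct <- permanova_f_direct(d, groups)
  expect_equal(fit$aov_table$F[1], f_direct, tolerance = 1e-10)
  f_perms <- apply(all_perms, 1, function(p)
    permanova_f_direct(d[p, p], groups))
  p_oracle <- (1 + sum(f_perms >= f_direct - 1e-10)) / (1 + nrow(all_perms))
  expect_equal(fit$aov_table$p[1], p_oracle, tolerance = 1e-12)
})

test_that("sequential decomposition is additive and matches classical ANOVA", {
  # Euclidean distances on univariate data: PERMANOVA SS = classical SS
  set.seed(5)
  y <- rnorm(12)
  g <- factor(rep(letters[1:3], each = 4))
  d <- as.matrix(dist(y))
  fit <- permanova(d, g, n_perm = 99, seed = 1)
  av <- anova(lm(y ~ g))
  expect_equal(fit$aov_table$SS[1], av$`Sum Sq`[1], tolerance = 1e-10)
  expect_equal(fit$aov_table$SS[2], av$`Sum Sq`[2], tolerance = 1e-10)
  expect_equal(fit$aov_table$F[1], av$`F value`[1], tolerance = 1e-10)
  # additivity with a covariate term
  x <- rnorm(12)
  fit2 <- permanova(d, data.frame(g = g, x = x), n_perm = 49, seed = 1)
  tab <- fit2$aov_table
  expect_equal(sum(tab$SS[1:3]), tab$SS[4], tolerance = 1e-10)
  expect_equal(sum(tab$df[c(1, 2, 3)]), 11)
  expect_equal(tab$R2[1:3], (tab$SS / tab$SS[4])[1:3])
  expect_error(permanova(d, data.frame(g = g, g2 = g), n_perm = 9),
               "collinear")
})

test_that("pairwise PERMANOVA applies Holm over pairs and flags tiny groups", {
  set.seed(3)
  sh <- simulate_group_shift(sim_config(n_rookeries = 3,
                                        samples_per_rookery = c(6, 6, 6),
                                        prey_pool_size = 15, seed = 3),
                             effect_size = 0.8)
  d <- jaccard_distances(sh$occurrence)
  pw <- pairwise_permanova(d, sh$groups, n_perm = 99, seed = 1)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_adj >= pw$p))
  expect_equal(pw$p_adj, holm_adjust(pw$p))
  tiny <- factor(c(rep("a", 17), "b"))
  expect_warning(expect_error(pairwise_permanova(d, tiny, n_perm = 9),
                              "no testable pairs"),
                 "skipped")
})

test_that("PERMDISP distances equal point-to-centroid distances in Euclidean space", {
  # points on a line: group1 {0,2}, group2 {0,6} -> z = (1,1,3,3); both
  # groups are internally constant, so separation is complete (F infinite)
  pts <- c(0, 2, 0, 6)
  d <- as.matrix(dist(pts))
  groups <- factor(c("g1", "g1", "g2", "g2"))
  pd <- permdisp(d, groups, n_perm = 99, seed = 1)
  expect_equal(unname(pd$z), c(1, 1, 3, 3), tolerance = 1e-10)
  expect_true(is.infinite(pd$F))
  expect_equal(pd$n_clamped, 0)
  # non-degenerate line configuration: F matches the closed-form ANOVA
  pts2 <- c(0, 2, 6, 0, 6, 7)
  g3 <- factor(rep(c("g1", "g2"), each = 3))
  pd2 <- permdisp(as.matrix(dist(pts2)), g3, n_perm = 99, seed = 1)
  z_hand <- c(abs(c(0, 2, 6) - 8 / 3), abs(c(0, 6, 7) - 13 / 3))
  expect_equal(unname(pd2$z), z_hand, tolerance = 1e-10)
  expect_equal(pd2$F, anova(lm(z_hand ~ g3))$`F value`[1],
               tolerance = 1e-10)

  # general Euclidean configuration: z from the PCoA embedding must match
  # direct distances to group centroids
  set.seed(12)
  X <- matrix(rnorm(30), 10, 3)
  g2 <- factor(rep(c("a", "b"), each = 5))
  pdX <- permdisp(as.matrix(dist(X)), g2, n_perm = 49, seed = 1)
  direct <- numeric(10)
  for (gg in levels(g2)) {
    idx <- g2 == gg
    cen <- colMeans(X[idx, ])
    direct[idx] <- sqrt(rowSums(sweep(X[idx, , drop = FALSE], 2, cen)^2))
  }
  expect_equal(unname(pdX$z), direct, tolerance = 1e-10)
})

test_that("mirrored point sets give no dispersion difference", {
  # second group is a shifted copy of the first: within-group z patterns
  # are identical, so the between-group dispersion SS is exactly zero
  X <- rbind(c(0, 0), c(2, 0), c(0, 2), c(6, 5))
  pts <- rbind(X, X + 100)
  d <- as.matrix(dist(pts))
  groups <- factor(rep(c("a", "b"), each = 4))
  pd <- permdisp(d, groups, n_perm = 199, seed = 1)
  expect_equal(unname(pd$z[1:4]), unname(pd$z[5:8]), tolerance = 1e-8)
  expect_lt(pd$F, 1e-12)
  expect_gt(pd$p, 0.9)
})

test_that("PERMDISP on non-Euclidean distances matches an independent PCoA oracle", {
  set.seed(31)
  m <- matrix(rbinom(70, 1, 0.5), 10, 7)
  m[rowSums(m) == 0, 1] <- 1
  d <- jaccard_distances(m)
  g <- factor(rep(c("a", "b"), each = 5))
  pd <- permdisp(d, g, n_perm = 49, seed = 1)
  # oracle: squared distance to centroid from the Gower matrix directly,
  # d_i^2 = G_ii - 2 mean_j G_ij + mean_jk G_jk over the group
  G <- scatdiet:::gower_matrix(d)
  z2 <- numeric(10)
  for (gg in levels(g)) {
    idx <- which(g == gg)
    for (i in idx)
      z2[i] <- G[i, i] - 2 * mean(G[i, idx]) + mean(G[idx, idx])
  }
  expect_equal(unname(pd$z), sqrt(pmax(z2, 0)), tolerance = 1e-8)
})

test_that("NMDS recovers configurations that embed exactly", {
  set.seed(2)
  for (k in c(2, 3)) {
    X <- matrix(rnorm(18 * k), 18, k)
    d <- as.matrix(dist(X))
    fit <- nmds(d, k = k, n_starts = 8, seed = 4)
    expect_lt(fit$stress, 1e-3)
  }
})

test_that("NMDS stress does not increase with k", {
  set.seed(14)
  m <- matrix(rbinom(120, 1, 0.4), 15, 8)
  m[rowSums(m) == 0, 1] <- 1
  d <- jaccard_distances(m)
  s2 <- nmds(d, k = 2, n_starts = 10, seed = 6)$stress
  s3 <- nmds(d, k = 3, n_starts = 10, seed = 6)$stress
  expect_lte(s3, s2 + 1e-6)
  expect_true(s3 >= 0 && s3 <= 1)
})

test_that("Schoener overlap: symmetry, bounds, and hand values", {
  expect_equal(schoener_overlap(c(a = 60, b = 40), c(a = 60, b = 40)), 1)
  expect_equal(schoener_overlap(c(a = 100), c(b = 100)), 0)
  x <- c(a = 0.5, b = 0.3, c = 0.2)
  y <- c(a = 0.2, b = 0.2, d = 0.6)
  expect_equal(schoener_overlap(x, y), schoener_overlap(y, x))
  expect_equal(schoener_overlap(x, y),
               1 - 0.5 * (0.3 + 0.1 + 0.2 + 0.6))
  # matrix version agrees with pairwise calls on POO profiles
  m <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  colnames(m) <- c("x", "y", "z")
  occ <- occurrence_matrix(m, c("A", "A", "B", "B"))
  prof <- poo_summary(occ)
  sm <- schoener_matrix(prof)
  pa <- prof[prof$rookery == "A", ]
  pb <- prof[prof$rookery == "B", ]
  expect_equal(sm["A", "B"],
               schoener_overlap(setNames(pa$poo, pa$item),
                                setNames(pb$poo, pb$item)))
})

test_that("IndVal components and best combinations match hand computation", {
  # item present in 3 of 4 sites of group 1, nowhere else: A=1, B=0.75
  m <- matrix(0, 8, 1, dimnames = list(sprintf("s%d", 1:8), "item"))
  m[1:3, 1] <- 1
  g <- factor(rep(c("g1", "g2"), each = 4))
  iv <- indval(m, g, n_perm = 199, seed = 1)
  expect_equal(iv$A, 1)
  expect_equal(iv$B, 0.75)
  expect_equal(iv$indval, sqrt(0.75), tolerance = 1e-12)
  expect_equal(iv$combination, "g1")

  # perfect indicator: IndVal exactly 1
  m2 <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 8, 1)
  iv2 <- indval(m2, g, n_perm = 99, seed = 1)
  expect_equal(iv2$indval, 1)

  # a combination of two groups can beat single groups
  m3 <- matrix(0, 9, 1)
  g3 <- factor(rep(c("a", "b", "c"), each = 3))
  m3[1:6, 1] <- 1   # all of a and b, none of c
  iv3 <- indval(m3, g3, n_perm = 99, seed = 1)
  expect_equal(iv3$combination, "a+b")
  expect_equal(iv3$indval, 1)
})

test_that("IndVal is invariant to replicating all sites of every group", {
  set.seed(9)
  m <- matrix(rbinom(36, 1, 0.5), 12, 3)
  m[, colSums(m) == 0] <- 1
  g <- factor(rep(c("a", "b", "c"), each = 4))
  iv1 <- indval(m, g, n_perm = 49, seed = 1)
  iv2 <- indval(rbind(m, m), factor(c(as.character(g), as.character(g))),
                n_perm = 49, seed = 1)
  expect_equal(iv1$A, iv2$A)
  expect_equal(iv1$indval, iv2$indval)
})

test_that("Spearman correlation: exact enumeration and tie handling", {
  r <- rank_correlation(1:6, c(2, 4, 6, 8, 10, 12))
  expect_equal(r$rho, 1)
  expect_equal(r$p, 2 / factorial(6))  # only identity and reversal reach |1|
  # oracle: enumeration p equals the proportion of |rho| >= observed
  x <- c(3, 1, 4, 1.5, 5)
  y <- c(2, 7, 1, 8, 3)
  r2 <- rank_correlation(x, y)
  perms <- scatdiet:::all_permutations(5)
  rhos <- apply(perms, 1, function(p) cor(rank(x), rank(y)[p]))
  expect_equal(r2$p, mean(abs(rhos) >= abs(r2$rho) - 1e-12))
  expect_error(rank_correlation(rep(1, 5), 1:5), "constant")
})

test_that("Kruskal-Wallis: separated two-group ranks give H = 3.857", {
  g <- group_rank_test(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(g$chi2, 3.857142857, tolerance = 1e-8)
  expect_equal(g$df, 1)
  expect_equal(g$p, stats::pchisq(g$chi2, 1, lower.tail = FALSE))
  # enumeration oracle: exact distribution of H over all rank splits
  splits <- utils::combn(6, 3)
  hs <- apply(splits, 2, function(s) {
    lab <- rep("b", 6); lab[s] <- "a"
    suppressWarnings(stats::kruskal.test(1:6, factor(lab))$statistic)
  })
  expect_equal(mean(hs >= g$chi2 - 1e-12), 2 / 20)   # exact p = .1
  expect_error(group_rank_test(rep(1, 6), rep(c("a", "b"), 3)),
               "identical")
})

test_that("paired Wilcoxon matches sign-assignment enumeration", {
  p6 <- paired_rank_test(c(2, 3, 4, 5, 6, 7), c(1, 1, 1, 1, 1, 1))
  expect_equal(p6$p, 2 / 64)
  expect_equal(p6$method, "exact")
  # single non-zero pair: two-sided p = 1
  expect_equal(paired_rank_test(c(1, 2, 9), c(1, 2, 3))$p, 1)
  expect_error(paired_rank_test(1:4, 1:4), "zero")
  # enumeration oracle for n = 5 distinct differences
  d <- c(0.8, -1.6, 2.4, 3.1, 4.7)
  res <- paired_rank_test(d + 10, rep(10, 5))
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 5)))
  v_all <- as.vector(signs %*% r)   # V over all 2^5 sign assignments
  v_obs <- sum(r[d > 0])
  p_exact <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
  expect_equal(res$p, p_exact, tolerance = 1e-12)
})

test_that("Holm adjustment follows the step-down rule", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  set.seed(2)
  p <- runif(10)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "0,1")
})

test_that("permutation p-values are seed-stable in distribution", {
  set.seed(99)
  sh <- simulate_group_shift(sim_config(n_rookeries = 2,
                                        samples_per_rookery = c(8, 8),
                                        prey_pool_size = 15, seed = 99),
                             effect_size = 0.4)
  d <- jaccard_distances(sh$occurrence)
  ps <- vapply(1:8, function(s)
    permanova(d, sh$groups, n_perm = 999, seed = s)$aov_table$p[1],
    numeric(1))
  # binomial Monte-Carlo error at n_perm=999: spread stays within ~4 SE
  se <- sqrt(mean(ps) * (1 - mean(ps)) / 999)
  expect_lt(max(ps) - min(ps), 8 * se + 1e-6)
})
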