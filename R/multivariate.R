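#' Jaccard distances among samples
#'
#' d(x, y) = 1 - |intersection| / |union| on the item sets of two samples of
#' a presence/absence matrix.
#'
#' @param occ an `occurrence_matrix` or binary matrix; all-zero rows are an
#'   error naming the sample.
#' @return symmetric distance matrix with zero diagonal.
#' @export
jaccard_distances <- function(occ) {
  m <- if (inherits(occ, "occurrence_matrix")) occ$matrix else as.matrix(occ)
  m <- (m > 0) * 1
  rs <- rowSums(m)
  if (any(rs == 0))
    stop("sample(s) with no items: ",
         paste(rownames(m)[rs == 0], collapse = ", "))
  shared <- tcrossprod(m)
  union <- outer(rs, rs, `+`) - shared
  d <- 1 - shared / union
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

# Gower-centered inner-product matrix from squared distances
gower_matrix <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  cm <- diag(n) - matrix(1 / n, n, n)
  cm %*% a %*% cm
}

# sequential hat matrices for an ordered list of terms (with intercept)
sequential_hats <- function(rhs, n) {
  if (is.null(dim(rhs))) rhs <- data.frame(groups = rhs)
  rhs <- as.data.frame(rhs, stringsAsFactors = TRUE)
  rhs[] <- lapply(rhs, function(col)
    if (is.character(col)) factor(col) else col)
  if (nrow(rhs) != n) stop("terms do not align with the distance matrix")
  hats <- list()
  ranks <- integer()
  X <- matrix(1, n, 1)
  prev_rank <- 1L
  for (j in seq_along(rhs)) {
    Xj <- stats::model.matrix(~., rhs[seq_len(j)])
    qrj <- qr(Xj)
    if (qrj$rank <= prev_rank)
      stop("singular design: term '", names(rhs)[j],
           "' is collinear with preceding terms")
    Q <- qr.Q(qrj)[, seq_len(qrj$rank), drop = FALSE]
    hats[[j]] <- tcrossprod(Q)
    ranks[j] <- qrj$rank
    prev_rank <- qrj$rank
  }
  list(hats = hats, ranks = ranks, term_names = names(rhs))
}

#' Permutational multivariate analysis of variance (PERMANOVA / ADONIS)
#'
#' Partitions the total sum of squared interpoint distances by sequential
#' (type-I) projections on the Gower-centered matrix: for ordered terms,
#' SS_term = tr((H_j - H_{j-1}) G), pseudo-F = (SS_term/df_term) /
#' (SS_res/df_res) and R^2 = SS_term / SS_total. Significance is assessed by
#' whole-sample label permutation; p = (1 + #(F_perm >= F_obs)) /
#' (1 + n_perm), so p is never zero.
#'
#' @param d distance matrix (e.g. from [jaccard_distances()]).
#' @param rhs ordered model terms: a factor/vector (single term) or a
#'   data.frame whose columns are the terms in sequential order (factors
#'   and/or numeric covariates).
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed for the permutation stream.
#' @param permutations optional matrix of permutation indices (one row per
#'   permutation) overriding the random stream — used for exhaustive
#'   enumeration on small problems.
#' @return object of class `permanova`: data.frame `aov_table` with df, SS,
#'   R2, pseudo-F and permutation p per term plus residual and total rows;
#'   `n_permutations`; `seed`.
#' @export
permanova <- function(d, rhs, n_perm = 9999, seed = 1L, permutations = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  G <- gower_matrix(d)
  ss_total <- sum(diag(G))
  sh <- sequential_hats(rhs, n)
  k <- length(sh$hats)
  # difference projectors per term, shared by observed and permuted stats
  Hd <- vector("list", k)
  prev <- matrix(1 / n, n, n)   # intercept hat
  for (j in seq_len(k)) {
    Hd[[j]] <- sh$hats[[j]] - prev
    prev <- sh$hats[[j]]
  }
  H_last <- sh$hats[[k]]
  df_terms <- diff(c(1L, sh$ranks))
  df_res <- n - sh$ranks[k]
  if (df_res <= 0) stop("no residual degrees of freedom")

  stat <- function(Gp) {
    ss <- vapply(Hd, function(H) sum(H * Gp), numeric(1))
    ss_res <- ss_total - sum(H_last * Gp)
    f <- (ss / df_terms) / (ss_res / df_res)
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- stat(G)

  if (is.null(permutations)) {
    set.seed(seed)
    permutations <- t(replicate(n_perm, sample.int(n)))
  }
  n_perm <- nrow(permutations)
  exceed <- numeric(k)
  eps <- sqrt(.Machine$double.eps)
  for (i in seq_len(n_perm)) {
    p <- permutations[i, ]
    fp <- stat(G[p, p, drop = FALSE])$f
    exceed <- exceed + (fp >= obs$f - eps)
  }
  pvals <- (1 + exceed) / (1 + n_perm)

  aov_table <- data.frame(
    term = c(sh$term_names, "Residual", "Total"),
    df = c(df_terms, df_res, n - 1L),
    SS = c(obs$ss, obs$ss_res, ss_total),
    R2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    F = c(obs$f, NA, NA),
    p = c(pvals, NA, NA),
    stringsAsFactors = FALSE)
  structure(list(aov_table = aov_table, n_permutations = n_perm,
                 seed = seed),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (%d permutations)\n", x$n_permutations))
  tab <- x$aov_table
  tab$SS <- round(tab$SS, 4); tab$R2 <- round(tab$R2, 4)
  tab$F <- round(tab$F, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Pairwise PERMANOVA with Holm correction
#'
#' One single-factor PERMANOVA per pair of groups on the corresponding
#' sub-matrix; p-values are Holm-adjusted over all pairs. Pairs where a
#' group has fewer than 2 samples are skipped with a warning.
#'
#' @inheritParams permanova
#' @param groups factor of group labels aligned with `d`.
#' @return data.frame with group pair, pseudo-F, R2, raw and Holm-adjusted p.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 9999, seed = 1L) {
  d <- as.matrix(d)
  groups <- factor(groups)
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2)
  rows <- vector("list", ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    sel <- groups %in% c(g1, g2)
    if (sum(groups == g1) < 2 || sum(groups == g2) < 2) {
      warning("pair ", g1, " vs ", g2, " skipped: a group has < 2 samples")
      next
    }
    fit <- permanova(d[sel, sel, drop = FALSE], droplevels(groups[sel]),
                     n_perm = n_perm, seed = seed + i)
    tab <- fit$aov_table
    rows[[i]] <- data.frame(group1 = g1, group2 = g2,
                            F = tab$F[1], R2 = tab$R2[1], p = tab$p[1],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable pairs")
  out$p_adj <- holm_adjust(out$p)
  rownames(out) <- NULL
  out
}

# principal-coordinate embedding retaining positive- and negative-eigenvalue
# axes; distances to group centroids as sqrt(d+^2 - d-^2) (Anderson 2006)
dist_to_centroids <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  G <- gower_matrix(d)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * sqrt(.Machine$double.eps)
  pos <- e$values > tol
  neg <- e$values < -tol
  Xp <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  Xn <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-e$values[neg]), sum(neg))
  groups <- factor(groups)
  z <- numeric(n)
  clamped <- 0L
  for (g in levels(groups)) {
    idx <- which(groups == g)
    cp <- colMeans(Xp[idx, , drop = FALSE])
    cn <- colMeans(Xn[idx, , drop = FALSE])
    d2 <- rowSums(sweep(Xp[idx, , drop = FALSE], 2, cp)^2) -
      rowSums(sweep(Xn[idx, , drop = FALSE], 2, cn)^2)
    clamped <- clamped + sum(d2 < 0)
    z[idx] <- sqrt(pmax(d2, 0))
  }
  names(z) <- rownames(d)
  list(z = z, groups = groups, n_clamped = clamped)
}

anova_f <- function(z, groups) {
  groups <- factor(groups)
  n <- length(z)
  k <- nlevels(groups)
  gm <- tapply(z, groups, mean)
  ng <- tabulate(groups)
  ss_b <- sum(ng * (gm - mean(z))^2)
  ss_w <- sum((z - gm[as.integer(groups)])^2)
  (ss_b / (k - 1)) / (ss_w / (n - k))
}

#' Multivariate homogeneity of group dispersions (PERMDISP)
#'
#' Embeds the distance matrix by principal coordinates (keeping both
#' positive- and negative-eigenvalue axes), computes each sample's distance
#' to its group centroid as sqrt(d+^2 - d-^2) (negative radicands clamped to
#' 0 and counted), then tests equality of mean dispersions with a one-way
#' ANOVA F whose significance comes from permuting group labels of the
#' distances. Pairwise comparisons use Tukey HSD on the dispersions,
#' Holm-adjusted.
#'
#' @inheritParams pairwise_permanova
#' @return object of class `permdisp`: `z` (distances to centroid),
#'   `group_means`, `F`, `df`, `p` (permutation), `pairwise` (data.frame with
#'   Tukey and Holm-adjusted p), `n_clamped`, `n_permutations`, `seed`.
#' @export
permdisp <- function(d, groups, n_perm = 9999, seed = 1L) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  dc <- dist_to_centroids(d, groups)
  z <- dc$z
  f_obs <- anova_f(z, groups)
  set.seed(seed)
  exceed <- 0L
  eps <- sqrt(.Machine$double.eps)
  for (i in seq_len(n_perm)) {
    fp <- anova_f(z, groups[sample.int(length(z))])
    exceed <- exceed + (fp >= f_obs - eps)
  }
  p <- (1 + exceed) / (1 + n_perm)
  fit <- stats::aov(z ~ groups)
  tk <- stats::TukeyHSD(fit)$groups
  pair_names <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairwise <- data.frame(
    group1 = vapply(pair_names, `[`, "", 2),
    group2 = vapply(pair_names, `[`, "", 1),
    diff = tk[, "diff"], p_tukey = tk[, "p adj"],
    p_adj = holm_adjust(tk[, "p adj"]),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(z = z, groups = groups,
                 group_means = tapply(z, groups, mean),
                 F = f_obs,
                 df = c(nlevels(groups) - 1L, length(z) - nlevels(groups)),
                 p = p, pairwise = pairwise, n_clamped = dc$n_clamped,
                 n_permutations = n_perm, seed = seed),
            class = "permdisp")
}

#' @export
print.permdisp <- function(x, ...) {
  cat(sprintf("PERMDISP: F(%d,%d) = %.4f, permutation p = %.4g (%d perms)\n",
              x$df[1], x$df[2], x$F, x$p, x$n_permutations))
  cat("group mean dispersions:\n")
  print(round(x$group_means, 4))
  invisible(x)
}

# lower-triangle pair indices matching our delta vector layout
lower_pairs <- function(n) {
  j <- rep(seq_len(n - 1), times = (n - 1):1)
  i <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  cbind(i = i, j = j)
}

kruskal_stress <- function(dvec, theta) {
  s <- sum(dvec^2)
  if (s == 0) return(0)
  sqrt(sum((dvec - theta)^2) / s)
}

#' Nonmetric multidimensional scaling (Kruskal stress-1)
#'
#' Finds a k-dimensional configuration whose interpoint distances are, as
#' nearly as possible, a monotone function of the observed dissimilarities.
#' Stress-1 = sqrt(sum (d - theta)^2 / sum d^2), with theta the isotonic
#' (pool-adjacent-violators) fit of configuration distances to the
#' dissimilarity order; ties are handled by the primary approach (no order
#' constraint within tie blocks). Optimisation alternates the isotonic fit
#' (disparities rescaled to the configuration's scale) with a Guttman
#' transform update; the best of one metric-MDS start plus `n_starts - 1`
#' random starts is returned.
#'
#' @param d distance matrix.
#' @param k number of dimensions (default 3).
#' @param n_starts number of initialisations (default 20).
#' @param max_iter iteration cap per start (default 1000).
#' @param tol stress-change convergence tolerance (default 1e-9).
#' @param seed integer seed for random starts.
#' @return object of class `nmds`: `points` (n x k, centred and rotated to
#'   principal axes), `stress`, `k`, `n_starts`, `best_start`, `converged`,
#'   `seed`.
#' @export
nmds <- function(d, k = 3, n_starts = 20, max_iter = 1000, tol = 1e-9,
                 seed = 1L) {
  stopifnot(k >= 1, n_starts >= 1)
  d <- as.matrix(d)
  n <- nrow(d)
  pairs <- lower_pairs(n)
  delta <- d[pairs]
  set.seed(seed)
  best <- list(stress = Inf, points = NULL, start = NA, converged = FALSE)
  for (s in seq_len(n_starts)) {
    X <- if (s == 1) {
      cmd <- suppressWarnings(stats::cmdscale(d, k = k))
      if (ncol(cmd) < k)
        cmd <- cbind(cmd, matrix(stats::rnorm(n * (k - ncol(cmd)), sd = 1e-4),
                                 n))
      cmd
    } else {
      matrix(stats::runif(n * k, -1, 1), n, k)
    }
    res <- nmds_one_start(X, delta, pairs, n, max_iter, tol)
    if (res$stress < best$stress)
      best <- list(stress = res$stress, points = res$X, start = s,
                   converged = res$converged)
  }
  X <- scale(best$points, center = TRUE, scale = FALSE)
  X <- X %*% svd(X, nu = 0)$v   # rotate to principal axes
  rownames(X) <- rownames(d)
  structure(list(points = X, stress = best$stress, k = k,
                 n_starts = n_starts, best_start = best$start,
                 converged = best$converged, seed = seed),
            class = "nmds")
}

nmds_one_start <- function(X, delta, pairs, n, max_iter, tol) {
  stress_prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    diffs <- X[pairs[, 1], , drop = FALSE] - X[pairs[, 2], , drop = FALSE]
    dvec <- sqrt(rowSums(diffs^2))
    # primary tie approach: within delta ties, order by current distances
    ord <- order(delta, dvec)
    theta <- numeric(length(dvec))
    theta[ord] <- stats::isoreg(dvec[ord])$yf
    ssd <- sum(dvec^2)
    if (ssd == 0) return(list(X = X, stress = 0, converged = TRUE))
    theta <- theta * sqrt(ssd / max(sum(theta^2), .Machine$double.xmin))
    stress <- kruskal_stress(dvec, theta)
    if (abs(stress_prev - stress) < tol) {
      converged <- TRUE
      break
    }
    stress_prev <- stress
    # Guttman transform
    ratio <- ifelse(dvec > 0, theta / dvec, 0)
    B <- matrix(0, n, n)
    B[pairs] <- -ratio
    B[pairs[, c(2, 1)]] <- -ratio
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
  }
  list(X = X, stress = stress, converged = converged)
}

#' @export
print.nmds <- function(x, ...) {
  cat(sprintf("NMDS: k = %d, stress-1 = %.4f (best of %d starts%s)\n",
              x$k, x$stress, x$n_starts,
              if (x$converged) "" else "; not converged"))
  invisible(x)
}

#' @export
plot.nmds <- function(x, groups = NULL, dims = c(1, 2), ...) {
  pts <- x$points[, dims, drop = FALSE]
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  plot(pts, col = col, pch = 19,
       xlab = paste0("NMDS", dims[1]), ylab = paste0("NMDS", dims[2]), ...)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_len(nlevels(factor(groups))), pch = 19,
                     bty = "n")
  invisible(x)
}
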