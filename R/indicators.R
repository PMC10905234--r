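#' Schoener diet overlap index
#'
#' D = 1 - 0.5 * sum_i |p_x,i - p_y,i| over diet proportion vectors taken on
#' the union of items; 0 means no shared items, 1 identical diets. Inputs
#' are renormalised to proportions, so POO percentages and FOO proportions
#' are both acceptable.
#'
#' @param x,y named numeric vectors of diet proportions (item -> value).
#' @return Schoener's D in `[0, 1]`.
#' @examples
#' schoener_overlap(c(a = 50, b = 50), c(a = 50, b = 50))  # 1
#' schoener_overlap(c(a = 100), c(b = 100))                # 0
#' @export
schoener_overlap <- function(x, y) {
  items <- union(names(x), names(y))
  px <- stats::setNames(numeric(length(items)), items)
  py <- px
  px[names(x)] <- x
  py[names(y)] <- y
  if (sum(px) <= 0 || sum(py) <= 0) stop("profiles must have positive totals")
  px <- px / sum(px)
  py <- py / sum(py)
  1 - 0.5 * sum(abs(px - py))
}

#' Pairwise Schoener overlap among rookeries
#'
#' @param profile a `diet_profile` from [poo_summary()].
#' @param measure `"poo"` (default) or `"foo"`: which proportion vector to
#'   overlap.
#' @return symmetric matrix of Schoener's D.
#' @export
schoener_matrix <- function(profile, measure = c("poo", "foo")) {
  measure <- match.arg(measure)
  rookeries <- unique(profile$rookery)
  vecs <- lapply(rookeries, function(rk) {
    sub <- profile[profile$rookery == rk, ]
    stats::setNames(sub[[measure]], sub$item)
  })
  names(vecs) <- rookeries
  k <- length(vecs)
  m <- matrix(1, k, k, dimnames = list(rookeries, rookeries))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    m[i, j] <- m[j, i] <- schoener_overlap(vecs[[i]], vecs[[j]])
  m
}

# indicator matrix of all non-trivial group combinations (sizes 1..K-1),
# or singletons only
combination_matrix <- function(k, allow_combinations) {
  sizes <- if (allow_combinations) seq_len(k - 1) else 1L
  combos <- do.call(rbind, lapply(sizes, function(s) {
    cs <- utils::combn(k, s)
    t(apply(cs, 2, function(idx) as.integer(seq_len(k) %in% idx)))
  }))
  combos
}

#' Indicator species analysis (IndVal) with site-group combinations
#'
#' For every item and every non-trivial combination C of site groups,
#' specificity A_C is the summed group-mean occurrence of the groups in C
#' over the summed group means of all groups (group-size independent),
#' fidelity B_C is the fraction of C's sites occupied, and
#' IndVal_C = sqrt(A_C * B_C). The best combination per item is reported;
#' its significance comes from permuting site labels and comparing the
#' permuted maximum IndVal to the observed one:
#' p = (1 + #(max_perm >= obs)) / (1 + n_perm).
#'
#' @param occ an `occurrence_matrix` or binary matrix.
#' @param groups factor of site groups (taken from the occurrence matrix's
#'   rookery labels when omitted).
#' @param allow_combinations consider unions of up to K-1 groups (default)
#'   or single groups only.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return data.frame of class `indval`: one row per item with
#'   `combination`, `A`, `B`, `indval`, `p`; items absent everywhere are
#'   skipped. Attributes `n_permutations` and `seed`.
#' @export
indval <- function(occ, groups = NULL, allow_combinations = TRUE,
                   n_perm = 9999, seed = 1L) {
  m <- if (inherits(occ, "occurrence_matrix")) occ$matrix else as.matrix(occ)
  if (is.null(groups) && inherits(occ, "occurrence_matrix"))
    groups <- occ$rookery
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  m <- (m > 0) * 1
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("item%02d", seq_len(ncol(m)))
  present <- colSums(m) > 0
  if (!all(present)) m <- m[, present, drop = FALSE]
  k <- nlevels(groups)
  combos <- combination_matrix(k, allow_combinations)
  combo_names <- apply(combos, 1, function(row)
    paste(levels(groups)[row == 1], collapse = "+"))
  ng <- tabulate(groups, nbins = k)
  sites_in_combo <- as.numeric(combos %*% ng)

  indval_stats <- function(glab) {
    gm <- rowsum(m, glab, reorder = TRUE) / ng          # K x items group means
    a_num <- combos %*% gm
    a <- a_num / rep(colSums(gm), each = nrow(combos))  # combos x items
    occ_g <- rowsum(m, glab, reorder = TRUE)            # occupied per group
    b <- (combos %*% occ_g) / sites_in_combo
    sqrt(a * b)
  }
  iv_obs <- indval_stats(groups)
  best <- apply(iv_obs, 2, which.max)
  obs_max <- apply(iv_obs, 2, max)

  set.seed(seed)
  exceed <- numeric(ncol(m))
  eps <- sqrt(.Machine$double.eps)
  for (i in seq_len(n_perm)) {
    ivp <- indval_stats(groups[sample.int(length(groups))])
    exceed <- exceed + (apply(ivp, 2, max) >= obs_max - eps)
  }
  pvals <- (1 + exceed) / (1 + n_perm)

  idx <- cbind(best, seq_len(ncol(m)))
  gm <- rowsum(m, groups, reorder = TRUE) / ng
  a_all <- (combos %*% gm) / rep(colSums(gm), each = nrow(combos))
  b_all <- (combos %*% rowsum(m, groups, reorder = TRUE)) / sites_in_combo
  out <- data.frame(item = colnames(m),
                    combination = combo_names[best],
                    A = a_all[idx], B = b_all[idx],
                    indval = obs_max, p = pvals,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_permutations") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("indval", "data.frame")
  out
}

#' Spearman rank correlation
#'
#' rho on midranks; two-sided p by exact enumeration of all permutations for
#' n <= 8 in the untied case, otherwise by the t approximation
#' t = rho sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom (the standard
#' approximation when ties are present).
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return list with `rho`, `p`, `n`, `method`.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("rho undefined for a constant vector")
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  if (n <= 8 && !ties) {
    a <- rx - mean(rx)
    perms <- all_permutations(n)
    b <- matrix((ry - mean(ry))[perms], nrow(perms))
    rhos <- (b %*% a) / sqrt(sum(a^2) * sum((ry - mean(ry))^2))
    p <- mean(abs(rhos) >= abs(rho) - sqrt(.Machine$double.eps))
    method <- "exact enumeration"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.xmin))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

# all permutations of 1..n as an n! x n matrix (n <= 8)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (pos in seq_len(n)) {
    rows <- (pos - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, pos] <- n
    out[rows, -pos] <- sub
  }
  out
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' H statistic with midrank tie correction; p from the chi-square
#' approximation on K-1 degrees of freedom (via [stats::kruskal.test()]).
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return list with `chi2`, `df`, `p`.
#' @export
group_rank_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(unique(values)) == 1)
    stop("statistic undefined: all values identical")
  kt <- stats::kruskal.test(values, groups)
  list(chi2 = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided; zero differences are dropped. Exact when 25 or fewer non-zero
#' differences without ties in their magnitudes, otherwise the normal
#' approximation with tie correction (via [stats::wilcox.test()]).
#'
#' @param a,b paired numeric vectors.
#' @return list with `V`, `n` (non-zero pairs), `p`, `method`.
#' @export
paired_rank_test <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero")
  exact <- length(d) <= 25 && !anyDuplicated(abs(d))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                            correct = !exact))
  list(V = unname(wt$statistic), n = length(d), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Holm step-down p-value adjustment
#'
#' @param p vector of p-values in `[0, 1]` (NA passed through).
#' @return adjusted p-values (>= raw, <= 1), order preserved.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "holm")
}
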