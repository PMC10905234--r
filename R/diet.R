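#' Convert a filtered read-count table to a presence/absence matrix
#'
#' Any positive cell becomes 1; OTU columns with no occurrences are dropped.
#' Presence/absence is the conservative representation for diet data since
#' read counts are a biased proxy for biomass.
#'
#' @param table a filtered [read_count_table()] (or a plain counts matrix).
#' @return object of class `occurrence_matrix`: list with `matrix` (binary,
#'   samples x items) and `rookery` (named character vector).
#' @export
to_occurrence <- function(table) {
  if (inherits(table, "read_count_table")) {
    counts <- table$counts
    rookery <- stats::setNames(table$meta$rookery, table$meta$sample_id)
  } else {
    counts <- as.matrix(table)
    rookery <- stats::setNames(rep("", nrow(counts)), rownames(counts))
  }
  occ <- (counts > 0) * 1L
  occ <- occ[, colSums(occ) > 0, drop = FALSE]
  structure(list(matrix = occ, rookery = rookery[rownames(occ)]),
            class = "occurrence_matrix")
}

#' Construct an occurrence matrix from a plain binary matrix
#'
#' @param m binary samples x items matrix with dimnames.
#' @param rookery character vector of group labels, one per row.
#' @return an `occurrence_matrix`.
#' @export
occurrence_matrix <- function(m, rookery) {
  m <- as.matrix(m)
  stopifnot(all(m %in% c(0, 1)), length(rookery) == nrow(m))
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("item%02d", seq_len(ncol(m)))
  structure(list(matrix = m, rookery = stats::setNames(as.character(rookery),
                                                       rownames(m))),
            class = "occurrence_matrix")
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf("occurrence_matrix: %d samples x %d prey items\n",
              nrow(x$matrix), ncol(x$matrix)))
  rk <- table(x$rookery[nzchar(x$rookery)])
  if (length(rk))
    cat("rookeries:", paste(sprintf("%s (%d)", names(rk), rk),
                            collapse = ", "), "\n")
  invisible(x)
}

as_occurrence <- function(x) {
  if (inherits(x, "occurrence_matrix")) return(x)
  occurrence_matrix(x, rookery = rep("all", nrow(as.matrix(x))))
}

#' Frequency and percent of occurrence per rookery
#'
#' For every rookery, FOO_i is the fraction of the rookery's samples that
#' contain item i, and POO_i = 100 * FOO_i / sum_j FOO_j, so each rookery's
#' POO vector sums to 100. With `grouping = "habitat"` or `"trophic_bin"`,
#' items are first mapped to their category (a sample "contains" a category
#' when it contains at least one item of that category); uncategorised items
#' are excluded from category summaries but retained in item summaries.
#'
#' @param occ an `occurrence_matrix` (items must be taxon names for category
#'   groupings, e.g. after collapsing OTUs to entities).
#' @param grouping `"items"`, `"habitat"` or `"trophic_bin"`.
#' @param categories a [categorize_prey()] data.frame (required for category
#'   groupings).
#' @return data.frame of class `diet_profile` with columns `rookery`,
#'   `item`, `foo`, `poo`.
#' @export
poo_summary <- function(occ, grouping = c("items", "habitat", "trophic_bin"),
                        categories = NULL) {
  occ <- as_occurrence(occ)
  grouping <- match.arg(grouping)
  m <- occ$matrix
  if (grouping != "items") {
    if (is.null(categories))
      stop("category grouping requires a categorize_prey() table")
    col <- if (grouping == "habitat") "habitat_class" else "trophic_bin"
    idx <- match(colnames(m), categories$item)
    cat_of <- categories[[col]][idx]
    keep <- !is.na(idx) & categories$categorized[idx]
    m <- m[, keep, drop = FALSE]
    cat_of <- cat_of[keep]
    levels <- unique(cat_of)
    agg <- vapply(levels, function(cl)
      as.integer(rowSums(m[, cat_of == cl, drop = FALSE]) > 0),
      integer(nrow(m)))
    m <- matrix(agg, nrow = nrow(occ$matrix),
                dimnames = list(rownames(occ$matrix), levels))
  }
  rookeries <- unique(occ$rookery)
  out <- do.call(rbind, lapply(rookeries, function(rk) {
    rows <- occ$rookery == rk
    if (!sum(rows)) {
      warning("rookery '", rk, "' has no samples; excluded")
      return(NULL)
    }
    foo <- colMeans(m[rows, , drop = FALSE])
    poo <- if (sum(foo) > 0) 100 * foo / sum(foo) else foo
    data.frame(rookery = rk, item = colnames(m), foo = unname(foo),
               poo = unname(poo), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("diet_profile", "data.frame")
  out
}

#' Prey richness per rookery and per sample
#'
#' @param occ an `occurrence_matrix`.
#' @return list with `per_rookery` (rookery, n_samples, richness, mean,
#'   median, min and max per-individual richness) and `per_sample` (named
#'   integer vector of row sums).
#' @export
richness_summary <- function(occ) {
  occ <- as_occurrence(occ)
  if (!nrow(occ$matrix)) stop("empty occurrence matrix")
  per_sample <- rowSums(occ$matrix)
  rookeries <- unique(occ$rookery)
  per_rookery <- do.call(rbind, lapply(rookeries, function(rk) {
    rows <- occ$rookery == rk
    sub <- occ$matrix[rows, , drop = FALSE]
    rs <- per_sample[rows]
    data.frame(rookery = rk, n_samples = sum(rows),
               richness = sum(colSums(sub) > 0),
               mean_per_individual = mean(rs),
               median_per_individual = stats::median(rs),
               min_per_individual = min(rs), max_per_individual = max(rs),
               stringsAsFactors = FALSE)
  }))
  rownames(per_rookery) <- NULL
  list(per_rookery = per_rookery, per_sample = per_sample)
}

# log-scale "choose(N - f, n) / choose(N, n)": probability that an item
# present in f of N samples is absent from a random subsample of size n
absent_prob <- function(f, N, n) {
  ifelse(N - f < n, 0, exp(lchoose(N - f, n) - lchoose(N, n)))
}

#' Sample-based (incidence) rarefaction
#'
#' Expected richness in a random subsample of `n` of the `N` samples:
#' E[S_n] = sum_i (1 - C(N - f_i, n) / C(N, n)) with f_i the number of
#' samples containing item i. The variance is the exact
#' incidence-based form including pairwise joint-absence terms, and the 95%
#' CI is the normal approximation E +/- 1.96 sd. At n = N the estimate
#' equals observed richness with zero variance.
#'
#' @param occ binary samples x items matrix (or `occurrence_matrix`; use one
#'   rookery's rows for per-rookery curves).
#' @param n subsample size, 1 <= n <= N.
#' @return list of class `rarefaction_estimate`: `n`, `expected`,
#'   `variance`, `ci_lower`, `ci_upper`.
#' @export
rarefy_samples <- function(occ, n) {
  m <- if (inherits(occ, "occurrence_matrix")) occ$matrix else as.matrix(occ)
  m <- (m > 0) * 1L
  N <- nrow(m)
  if (n < 1 || n > N) stop("n must lie in [1, ", N, "]")
  f <- colSums(m)
  f <- f[f > 0]
  m <- m[, colSums(m) > 0, drop = FALSE]
  q <- absent_prob(f, N, n)
  expected <- sum(1 - q)
  # pairwise joint absences: u_ij = samples containing item i or item j
  both <- crossprod(m)
  u <- outer(f, f, `+`) - both
  qq <- matrix(absent_prob(u, N, n), ncol(m), ncol(m))
  cov_term <- qq - outer(q, q)
  variance <- sum(q * (1 - q)) + 2 * sum(cov_term[upper.tri(cov_term)])
  variance <- max(variance, 0)
  sd <- sqrt(variance)
  structure(list(n = n, expected = expected, variance = variance,
                 ci_lower = expected - 1.96 * sd,
                 ci_upper = expected + 1.96 * sd),
            class = "rarefaction_estimate")
}

#' @export
print.rarefaction_estimate <- function(x, ...) {
  cat(sprintf("rarefied richness at n=%d: %.2f (95%% CI %.2f-%.2f)\n",
              x$n, x$expected, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Read-based (individual) rarefaction curve
#'
#' Hypergeometric expectation of the number of OTUs detected in a random
#' subsample of reads from the pooled per-rookery counts:
#' E[S_m] = sum_i (1 - C(N - n_i, m) / C(N, m)). Also reports the read
#' depth at which the curve stabilises, defined as the smallest grid depth
#' where the coefficient of variation (sd/mean) of the estimate drops to
#' 0.05 or below.
#'
#' @param counts named vector of pooled per-OTU read counts (or a
#'   [read_count_table()] together with `rookery`).
#' @param rookery when `counts` is a table: pool the samples of this rookery.
#' @param grid read depths to evaluate; values beyond the total are dropped
#'   with a warning. Default: 25 log-spaced depths up to the total.
#' @return data.frame of class `rarefaction_curve` with columns `reads`,
#'   `expected`, `sd`; attribute `stabilization_depth`.
#' @export
rarefy_reads <- function(counts, rookery = NULL, grid = NULL) {
  if (inherits(counts, "read_count_table")) {
    rows <- if (is.null(rookery)) !counts$meta$is_negative_control
            else counts$meta$rookery == rookery
    counts <- colSums(counts$counts[rows, , drop = FALSE])
  }
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (is.null(grid))
    grid <- unique(round(exp(seq(log(1), log(N), length.out = 25))))
  if (any(grid > N)) {
    warning("grid depths beyond total reads (", N, ") dropped")
    grid <- grid[grid <= N]
  }
  est <- vapply(grid, function(m) {
    q <- absent_prob(counts, N, m)
    e <- sum(1 - q)
    qq_u <- outer(counts, counts, `+`)
    qq <- matrix(absent_prob(qq_u, N, m), length(counts), length(counts))
    cv <- qq - outer(q, q)
    v <- max(sum(q * (1 - q)) + 2 * sum(cv[upper.tri(cv)]), 0)
    c(e, sqrt(v))
  }, numeric(2))
  out <- data.frame(reads = grid, expected = est[1, ], sd = est[2, ])
  cv <- ifelse(out$expected > 0, out$sd / out$expected, Inf)
  stab <- out$reads[which(cv <= 0.05)[1]]
  attr(out, "stabilization_depth") <- if (length(stab)) stab else NA
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

#' Read-share and occurrence-rate summaries
#'
#' `read_share` rescales per-item read counts to percentages of the total;
#' `occurrence_rate` gives the percentage of all samples containing each
#' item (frequency of occurrence across the whole study).
#'
#' @param reads named numeric vector of per-item read counts.
#' @return named numeric vector of percentages.
#' @examples
#' read_share(c(a = 31700, other = 244189 - 31700))[["a"]]  # 12.98
#' @export
read_share <- function(reads) {
  stopifnot(all(reads >= 0), sum(reads) > 0)
  100 * reads / sum(reads)
}

#' @rdname read_share
#' @param occ an `occurrence_matrix` or binary matrix.
#' @export
occurrence_rate <- function(occ) {
  m <- if (inherits(occ, "occurrence_matrix")) occ$matrix else as.matrix(occ)
  100 * colMeans(m > 0)
}
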