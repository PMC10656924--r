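#' Convert counts to relative abundances
#'
#' @param t a [community_table()] or a non-negative numeric matrix
#'   (samples x taxa).
#' @return numeric matrix of row-normalized relative abundances; every row
#'   sums to 1.
#' @export
relative_abundance <- function(t) {
  m <- if (inherits(t, "community_table")) t$counts else as.matrix(t)
  tot <- rowSums(m)
  zero <- rownames(m)[tot == 0]
  if (length(zero) > 0)
    stop(sprintf("all-zero sample(s): %s", paste(zero, collapse = ", ")),
         call. = FALSE)
  sweep(m, 1, tot, "/")
}

#' Bias-corrected Chao1 richness estimate
#'
#' `S_obs + f1 * (f1 - 1) / (2 * (f2 + 1))` where `f1` and `f2` are the
#' numbers of singleton and doubleton taxa.
#'
#' @param counts_row non-negative integer vector of counts for one sample.
#' @return estimated richness (never below the observed richness).
#' @export
chao1 <- function(counts_row) {
  x <- as.numeric(counts_row)
  if (anyNA(x) || any(x < 0) || any(x != round(x)))
    stop("chao1 requires non-negative integer counts", call. = FALSE)
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Pairwise sample dissimilarity matrix
#'
#' Quantitative metrics (`bray_curtis`, `jaccard`, `jensen_shannon`) expect
#' rows of relative abundances summing to 1; `binary_jaccard` accepts any
#' non-negative rows and uses presence/absence. `jaccard` is the
#' quantitative (Ruzicka) form, related to Bray-Curtis `d` by
#' `2 d / (1 + d)`. `jensen_shannon` is the square root of the
#' Jensen-Shannon divergence with base-2 logarithms, so entries lie in
#' `[0, 1]`.
#'
#' @param rel samples x taxa fractional matrix (see
#'   [relative_abundance()]).
#' @param metric one of `"bray_curtis"`, `"jaccard"`, `"binary_jaccard"`,
#'   `"jensen_shannon"`.
#' @return object of class `dist_matrix`: list with the symmetric matrix
#'   `d` (zero diagonal), `metric` and `sample_ids`.
#' @export
distance_matrix <- function(rel, metric = c("bray_curtis", "jaccard",
                                            "binary_jaccard",
                                            "jensen_shannon")) {
  metric <- match.arg(metric)
  rel <- as.matrix(rel)
  if (anyNA(rel) || any(!is.finite(rel)))
    stop("input contains NaN or non-finite values", call. = FALSE)
  .assert(all(rel >= 0), "abundances must be non-negative")
  if (metric != "binary_jaccard")
    .assert(all(abs(rowSums(rel) - 1) < 1e-8),
            "rows must sum to 1 for quantitative metrics")
  d <- switch(metric,
    bray_curtis = as.matrix(vegan::vegdist(rel, method = "bray")),
    jaccard = as.matrix(vegan::vegdist(rel, method = "jaccard")),
    binary_jaccard = as.matrix(vegan::vegdist(rel, method = "jaccard",
                                              binary = TRUE)),
    jensen_shannon = .jsd_matrix(rel))
  diag(d) <- 0
  d[is.na(d)] <- 0  # vegdist yields NaN for identical all-zero binary rows
  structure(list(d = d, metric = metric, sample_ids = rownames(rel)),
            class = "dist_matrix")
}

.jsd_matrix <- function(rel) {
  n <- nrow(rel)
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  h <- rowSums(plogp(rel))  # negative entropy per sample
  d <- matrix(0, n, n, dimnames = list(rownames(rel), rownames(rel)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m <- (rel[i, ] + rel[j, ]) / 2
    jsd <- 0.5 * (h[i] + h[j]) - sum(plogp(m))
    d[i, j] <- d[j, i] <- sqrt(max(jsd, 0))
  }
  d
}

.as_dist_matrix <- function(d) {
  if (inherits(d, "dist_matrix")) return(d)
  m <- as.matrix(d)
  structure(list(d = m, metric = "user",
                 sample_ids = rownames(m) %||%
                   as.character(seq_len(nrow(m)))),
            class = "dist_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix (%s): %d samples\n", x$metric, nrow(x$d)))
  invisible(x)
}

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Double-centers the squared dissimilarities, eigendecomposes, and scales
#' eigenvectors by the square roots of the positive eigenvalues. When the
#' dissimilarity is Euclidean-embeddable, pairwise distances among the full
#' set of coordinates reproduce the input exactly.
#'
#' @param d a [distance_matrix()] result (or symmetric matrix).
#' @param n_axes number of axes to retain; truncated with a warning if it
#'   exceeds the number of positive eigenvalues.
#' @return object of class `ordination`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (all positive eigenvalues,
#'   non-increasing) and `proportion_explained` (per retained axis,
#'   relative to the sum of positive eigenvalues).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- .as_dist_matrix(d)
  n <- nrow(d$d)
  a <- -0.5 * d$d^2
  j <- diag(n) - matrix(1 / n, n, n)
  g <- j %*% a %*% j
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9 + 1e-12
  pos <- which(e$values > tol)
  if (length(pos) == 0) {
    coords <- matrix(0, n, n_axes,
                     dimnames = list(d$sample_ids,
                                     paste0("PCo", seq_len(n_axes))))
    return(structure(list(coordinates = coords, eigenvalues = numeric(0),
                          proportion_explained = rep(0, n_axes)),
                     class = "ordination"))
  }
  if (n_axes > length(pos)) {
    warning(sprintf("only %d positive eigenvalues; truncating axes",
                    length(pos)))
    n_axes <- length(pos)
  }
  ev <- e$values[pos]
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev), length(pos))
  dimnames(coords) <- list(d$sample_ids, paste0("PCo", seq_along(pos)))
  structure(list(coordinates = coords[, seq_len(n_axes), drop = FALSE],
                 eigenvalues = ev,
                 proportion_explained = (ev / sum(ev))[seq_len(n_axes)],
                 coordinates_full = coords),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("ordination: %d samples, %d axes (%.1f%% on axis 1)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * (x$proportion_explained[1] %||% 0)))
  invisible(x)
}

.perm_indices <- function(n, permutations) {
  if (is.matrix(permutations)) {
    .assert(ncol(permutations) == n, "permutation matrix must have n columns")
    return(permutations)
  }
  t(replicate(permutations, sample.int(n)))
}

.check_groups <- function(groups, n) {
  g <- factor(groups)
  .assert(length(g) == n, "groups must have one label per sample")
  .assert(nlevels(g) >= 2, "need at least two groups")
  small <- names(which(table(g) < 2))
  .assert(length(small) == 0, "group(s) with fewer than 2 samples: %s",
          paste(small, collapse = ", "))
  g
}

.permanova_f <- function(d2, idx_by_group, n, k, ss_total) {
  ss_within <- 0
  for (idx in idx_by_group)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  ss_between <- ss_total - ss_within
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

#' One-way PERMANOVA (permutational multivariate ANOVA, adonis-style)
#'
#' Partitions the total sum of squared dissimilarities into between- and
#' within-group components and forms a pseudo-F statistic; significance is
#' assessed by permuting sample labels.
#'
#' @param d a [distance_matrix()] result (or symmetric matrix).
#' @param groups group label per sample (>= 2 groups, each with >= 2
#'   samples).
#' @param n_permutations number of label permutations, or a matrix whose
#'   rows are explicit permutations of `1:n` (e.g. the full enumeration).
#' @param seed integer seed for the permutation stream.
#' @return object of class `perm_test`: list with `statistic` (pseudo-F),
#'   `effect` (R^2), `p_value`, `n_permutations`, `seed`, `method`.
#' @references Anderson, M.J. (2001) A new method for non-parametric
#'   multivariate analysis of variance. Austral Ecology 26, 32-46.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1) {
  d <- .as_dist_matrix(d)
  n <- nrow(d$d)
  g <- .check_groups(groups, n)
  k <- nlevels(g)
  d2 <- d$d^2
  ss_total <- sum(d2) / (2 * n)
  idx0 <- split(seq_len(n), g)
  f_obs <- .permanova_f(d2, idx0, n, k, ss_total)
  ss_within <- 0
  for (idx in idx0) ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  r2 <- (ss_total - ss_within) / ss_total
  res <- with_seed(seed, {
    perms <- .perm_indices(n, n_permutations)
    gi <- as.integer(g)
    f_perm <- apply(perms, 1, function(ord) {
      .permanova_f(d2, split(seq_len(n), gi[ord]), n, k, ss_total)
    })
    f_perm
  })
  p <- (1 + sum(res >= f_obs - 1e-12)) / (1 + length(res))
  structure(list(statistic = f_obs, effect = r2, p_value = p,
                 n_permutations = length(res), seed = seed,
                 method = "permanova"),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g (%d permutations)\n",
              x$method, x$statistic,
              if (!is.null(x$effect) && !is.na(x$effect))
                sprintf(", R2 = %.4g", x$effect) else "",
              x$p_value, x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA with Benjamini-Hochberg correction
#'
#' Runs [permanova()] on every pair of groups and adjusts the p-values
#' across pairs by the Benjamini-Hochberg procedure.
#'
#' @inheritParams permanova
#' @return data.frame with one row per group pair: `group_a`, `group_b`,
#'   `pseudo_f`, `r2`, `p_value`, `q_value`.
#' @export
pairwise_permanova <- function(d, groups, n_permutations = 999, seed = 1) {
  d <- .as_dist_matrix(d)
  g <- .check_groups(groups, nrow(d$d))
  lev <- levels(g)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    sel <- g %in% pr
    sub <- structure(list(d = d$d[sel, sel, drop = FALSE], metric = d$metric,
                          sample_ids = d$sample_ids[sel]),
                     class = "dist_matrix")
    r <- permanova(sub, droplevels(g[sel]), n_permutations, seed + i)
    data.frame(group_a = pr[1], group_b = pr[2], pseudo_f = r$statistic,
               r2 = r$effect, p_value = r$p_value)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out
}

.anosim_r <- function(rk, within_mask, m) {
  (mean(rk[!within_mask]) - mean(rk[within_mask])) / (m / 2)
}

#' ANOSIM (analysis of similarities)
#'
#' Rank-based comparison of between- versus within-group dissimilarities:
#' `R = (mean rank between - mean rank within) / (M / 2)` with
#' `M = n (n - 1) / 2` pairs and midranks for ties, so `R` lies in
#' `[-1, 1]`. Significance by label permutation as in [permanova()].
#'
#' @inheritParams permanova
#' @return a `perm_test` object with `statistic` = R (and `effect` = NA).
#' @references Clarke, K.R. (1993) Non-parametric multivariate analyses of
#'   changes in community structure. Australian Journal of Ecology 18,
#'   117-143.
#' @export
anosim <- function(d, groups, n_permutations = 999, seed = 1) {
  d <- .as_dist_matrix(d)
  n <- nrow(d$d)
  g <- .check_groups(groups, n)
  lower <- lower.tri(d$d)
  rk_vec <- rank(d$d[lower])  # midranks
  rk <- matrix(0, n, n)
  rk[lower] <- rk_vec
  rk <- rk + t(rk)
  m <- n * (n - 1) / 2
  same <- outer(g, g, "==")
  lw <- lower
  r_obs <- .anosim_r(rk[lw], same[lw], m)
  r_perm <- with_seed(seed, {
    perms <- .perm_indices(n, n_permutations)
    apply(perms, 1, function(ord) {
      gp <- g[ord]
      .anosim_r(rk[lw], outer(gp, gp, "==")[lw], m)
    })
  })
  p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + length(r_perm))
  structure(list(statistic = r_obs, effect = NA_real_, p_value = p,
                 n_permutations = length(r_perm), seed = seed,
                 method = "anosim"),
            class = "perm_test")
}

#' Kruskal-Wallis rank sum test
#'
#' Wrapper around [stats::kruskal.test()] (tie-corrected H statistic,
#' chi-squared reference distribution with k - 1 df) returning the
#' package's common test-result structure.
#'
#' @param values numeric observations.
#' @param groups group label per observation.
#' @return a `perm_test`-classed list with `statistic` (H), `p_value` and
#'   `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- factor(groups)
  .assert(nlevels(g) >= 2, "need at least two groups")
  if (length(unique(values)) == 1)  # degenerate: no variation at all
    return(structure(list(statistic = 0, effect = NA_real_, p_value = 1,
                          df = nlevels(g) - 1, n_permutations = NA_integer_,
                          seed = NA_integer_, method = "kruskal_wallis"),
                     class = "perm_test"))
  kt <- kruskal.test(values, g)
  structure(list(statistic = unname(kt$statistic), effect = NA_real_,
                 p_value = kt$p.value, df = unname(kt$parameter),
                 n_permutations = NA_integer_, seed = NA_integer_,
                 method = "kruskal_wallis"),
            class = "perm_test")
}
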