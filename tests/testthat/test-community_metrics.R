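test_that("relative abundance normalizes rows and flags empty samples", {
  set.seed(1)
  m <- matrix(rpois(50, 5), 10, 5,
              dimnames = list(paste0("s", 1:10), paste0("t", 1:5)))
  m[m == 0] <- 1L
  rel <- relative_abundance(m)
  expect_equal(unname(rowSums(rel)), rep(1, 10), tolerance = 1e-12)
  expect_equal(unname(relative_abundance(matrix(c(1L, 1L), 1, 2,
    dimnames = list("s", c("a", "b"))))[1, ]), c(0.5, 0.5))
  m[3, ] <- 0L
  expect_error(relative_abundance(m), "s3")
})

test_that("chao1 matches the bias-corrected closed form", {
  expect_equal(chao1(c(5, 5, 5)), 3)
  expect_equal(chao1(c(1, 1, 2)), 3 + 2 * 1 / (2 * 2))  # 3.5
  expect_equal(chao1(c(1, 0, 0)), 1)
  expect_error(chao1(c(1.5, 2)), "integer")
  set.seed(2)
  for (i in 1:20) {
    x <- rpois(30, 2)
    x[1] <- 5  # never all-zero
    f1 <- sum(x == 1); f2 <- sum(x == 2)
    expect_equal(chao1(x), sum(x > 0) + f1 * (f1 - 1) / (2 * (f2 + 1)))
    expect_gte(chao1(x), sum(x > 0))
  }
})

test_that("distance metrics satisfy their definitions and invariants", {
  x <- c(1, 0); y <- c(0.5, 0.5)
  rel <- rbind(a = x, b = y)
  colnames(rel) <- c("t1", "t2")
  d <- distance_matrix(rel, "bray_curtis")
  expect_equal(d$d["a", "b"], 0.5)  # 1 - 2*0.5/2
  # Jaccard derived from Bray-Curtis as 2d/(1+d)
  dj <- distance_matrix(rel, "jaccard")
  expect_equal(dj$d["a", "b"], 2 * 0.5 / (1 + 0.5))
  # identical rows are 0, disjoint supports are 1, under all metrics
  rel2 <- rbind(a = c(0.5, 0.5, 0), b = c(0.5, 0.5, 0), c = c(0, 0, 1))
  colnames(rel2) <- paste0("t", 1:3)
  for (m in c("bray_curtis", "jaccard", "binary_jaccard", "jensen_shannon")) {
    dm <- distance_matrix(rel2, m)$d
    expect_equal(dm["a", "b"], 0)
    expect_equal(unname(diag(dm)), rep(0, 3))
    expect_true(isSymmetric(dm))
    expect_true(all(dm >= 0 & dm <= 1 + 1e-12))
    if (m != "jensen_shannon") expect_equal(dm["a", "c"], 1)
  }
  # Jensen-Shannon: sqrt of base-2 JSD; disjoint supports give JSD = 1
  expect_equal(distance_matrix(rel2, "jensen_shannon")$d["a", "c"], 1)
  expect_error(distance_matrix(rbind(c(NaN, 1), c(0.5, 0.5)), "bray_curtis"),
               "NaN")
  expect_error(distance_matrix(rbind(c(2, 1), c(0.5, 0.5)), "bray_curtis"),
               "sum to 1")
})

test_that("pcoa embeds Euclidean data exactly and handles edge cases", {
  # 3 collinear points with distances 1, 1, 2 -> 1-D coordinates -1, 0, 1
  dm <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  ord <- pcoa(dm, 1)
  v <- sort(ord$coordinates[, 1])
  expect_equal(unname(v), c(-1, 0, 1), tolerance = 1e-10)
  # random Euclidean cloud: full coordinates reproduce all distances
  set.seed(4)
  pts <- matrix(rnorm(8 * 3), 8)
  d <- as.matrix(dist(pts))
  ord <- pcoa(d, 3)
  expect_lt(max(abs(as.matrix(dist(ord$coordinates_full)) - d)), 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))
  expect_lte(sum(ord$proportion_explained), 1 + 1e-12)
  # degenerate all-zero distances
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(pcoa(z, 2)$coordinates == 0))
  expect_warning(pcoa(dm, 3), "truncating")
})

test_that("permanova matches the formula-level oracle and vegan's adonis", {
  set.seed(7)
  rel <- matrix(rexp(7 * 5), 7); rel <- rel / rowSums(rel)
  rownames(rel) <- paste0("s", 1:7); colnames(rel) <- paste0("t", 1:5)
  g <- c("a", "a", "a", "b", "b", "b", "b")
  d <- distance_matrix(rel, "bray_curtis")
  r <- permanova(d, g, 99, seed = 1)
  expect_equal(r$statistic, oracle_permanova_f(d$d, g), tolerance = 1e-12)
  # vegan cross-check of pseudo-F and R2
  va <- vegan::adonis2(as.dist(d$d) ~ g, data = data.frame(g = g),
                       permutations = 99)
  expect_equal(r$statistic, va$F[1], tolerance = 1e-10)
  expect_equal(r$effect, va$R2[1], tolerance = 1e-10)
  # identical duplicated point clouds: F ~ 0, p ~ 1
  rel2 <- rbind(rel[1:3, ], rel[1:3, ])
  rownames(rel2) <- paste0("s", 1:6)
  d2 <- distance_matrix(rel2, "bray_curtis")
  r2 <- permanova(d2, rep(c("a", "b"), each = 3), 199, seed = 1)
  expect_lt(r2$statistic, 1e-8)
  expect_gt(r2$p_value, 0.9)
  expect_error(permanova(d, c("a", rep("b", 6)), 99), "fewer than 2")
})

test_that("permutation p-values equal exhaustive enumeration on small n", {
  set.seed(12)
  rel <- matrix(rexp(6 * 4), 6); rel <- rel / rowSums(rel)
  rownames(rel) <- paste0("s", 1:6); colnames(rel) <- paste0("t", 1:4)
  g <- rep(c("a", "b"), each = 3)
  d <- distance_matrix(rel, "bray_curtis")
  perms <- all_permutations(6)
  # feed every non-identity permutation explicitly; with the +1 convention
  # this equals the proportion over all n! labelings
  nonid <- perms[rowSums(perms == matrix(1:6, nrow(perms), 6, TRUE)) < 6, ]
  r <- permanova(d, g, n_permutations = nonid, seed = 1)
  expect_equal(r$p_value, oracle_exhaustive_p(d$d, g, oracle_permanova_f))
  a <- anosim(d, g, n_permutations = nonid, seed = 1)
  expect_equal(a$p_value, oracle_exhaustive_p(d$d, g, oracle_anosim_r))
})

test_that("anosim matches hand ranks, vegan, and boundary behaviour", {
  set.seed(9)
  rel <- matrix(rexp(8 * 5), 8); rel <- rel / rowSums(rel)
  rownames(rel) <- paste0("s", 1:8); colnames(rel) <- paste0("t", 1:5)
  g <- rep(c("a", "b"), each = 4)
  d <- distance_matrix(rel, "bray_curtis")
  r <- anosim(d, g, 99, seed = 1)
  expect_equal(r$statistic, oracle_anosim_r(d$d, g), tolerance = 1e-12)
  va <- vegan::anosim(as.dist(d$d), g, permutations = 19)
  expect_equal(r$statistic, unname(va$statistic), tolerance = 1e-10)
  expect_gte(r$statistic, -1); expect_lte(r$statistic, 1)
  # perfectly separated groups: all between > all within -> R = 1
  sep <- matrix(c(0, 1, 9, 9, 1, 0, 9, 9, 9, 9, 0, 1, 9, 9, 1, 0), 4,
                dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  expect_equal(anosim(sep, c("a", "a", "b", "b"), 23, seed = 1)$statistic, 1)
})

test_that("anosim R is centred at zero under exchangeable labels", {
  set.seed(21)
  rs <- replicate(300, {
    rel <- matrix(rexp(8 * 4), 8); rel <- rel / rowSums(rel)
    rownames(rel) <- paste0("s", 1:8); colnames(rel) <- paste0("t", 1:4)
    d <- distance_matrix(rel, "bray_curtis")
    g <- sample(rep(c("a", "b"), each = 4))
    oracle_anosim_r(d$d, g)
  })
  expect_lt(abs(mean(rs)), 0.04)
})

test_that("pairwise permanova applies BH exactly and covers all pairs", {
  set.seed(15)
  rel <- matrix(rexp(12 * 5), 12); rel <- rel / rowSums(rel)
  rownames(rel) <- paste0("s", 1:12); colnames(rel) <- paste0("t", 1:5)
  g <- rep(c("a", "b", "c"), each = 4)
  d <- distance_matrix(rel, "bray_curtis")
  pw <- pairwise_permanova(d, g, 99, seed = 2)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$q_value >= pw$p_value))
  expect_equal(pw$q_value, oracle_bh(pw$p_value))
})

test_that("kruskal-wallis agrees with the closed form and handles ties", {
  r <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # tie-free closed form: 12/(n(n+1)) * sum n_i rbar_i^2 - 3(n+1)
  expect_equal(r$statistic, 3.857142857, tolerance = 1e-8)
  expect_equal(kruskal_wallis(rep(2, 6), rep(c("a", "b"), 3))$statistic, 0)
  expect_equal(kruskal_wallis(rep(2, 6), rep(c("a", "b"), 3))$p_value, 1)
  set.seed(8)
  for (i in 1:100) {
    v <- round(rnorm(15), 1)  # rounding induces ties
    g <- sample(c("a", "b", "c"), 15, TRUE)
    if (length(unique(g)) < 2 || length(unique(v)) < 2) next
    expect_equal(kruskal_wallis(v, g)$statistic, oracle_kw_h(v, g),
                 tolerance = 1e-10)
  }
})

test_that("permutation tests are invariant to sample reordering", {
  set.seed(30)
  rel <- matrix(rexp(8 * 4), 8); rel <- rel / rowSums(rel)
  rownames(rel) <- paste0("s", 1:8); colnames(rel) <- paste0("t", 1:4)
  g <- rep(c("a", "b"), each = 4)
  d <- distance_matrix(rel, "bray_curtis")
  o <- sample(8)
  d2 <- distance_matrix(rel[o, ], "bray_curtis")
  expect_equal(permanova(d, g, 99, 5)$statistic,
               permanova(d2, g[o], 99, 5)$statistic, tolerance = 1e-12)
  expect_equal(anosim(d, g, 99, 5)$statistic,
               anosim(d2, g[o], 99, 5)$statistic, tolerance = 1e-12)
})
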