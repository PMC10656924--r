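# Independent brute-force oracles used to freeze expected values.
# These deliberately share no code with the package internals.

# ---- global alignment ------------------------------------------------------
# Gotoh dynamic program: match +1, mismatch -1, a gap of length L costs
# 2 + L (open 2, extend 1 per gapped position). Returns the optimal score.
oracle_nw_score <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  open <- 2; ext <- 1
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in aligned pair
  X <- matrix(NEG, n + 1, m + 1)  # ends with gap in b (a consumed)
  Y <- matrix(NEG, n + 1, m + 1)  # ends with gap in a (b consumed)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  sub <- function(x, y) if (x == y && x != "N" && y != "N") 1 else -1
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- sub(a[i], b[j])
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                           Y[i, j + 1] - open - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext,
                           X[i + 1, j] - open - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# exhaustive enumeration of every global alignment of two short sequences;
# returns the identities (matches / alignment length) of all optimal-score
# alignments under the same affine scheme
oracle_optimal_identities <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  open <- 2; ext <- 1
  res <- list()
  # state: last move (0 start, 1 diag, 2 up=gap in b, 3 left=gap in a)
  recur <- function(i, j, score, matches, len, last) {
    if (i > length(av) && j > length(bv)) {
      res[[length(res) + 1]] <<- c(score, matches, len)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j] && av[i] != "N") 1 else -1
      recur(i + 1, j + 1, score + s, matches + (s == 1), len + 1, 1)
    }
    if (i <= length(av))
      recur(i + 1, j, score - ext - if (last == 2) 0 else open,
            matches, len + 1, 2)
    if (j <= length(bv))
      recur(i, j + 1, score - ext - if (last == 3) 0 else open,
            matches, len + 1, 3)
  }
  recur(1, 1, 0, 0, 0, 0)
  tab <- do.call(rbind, res)
  best <- max(tab[, 1])
  unique(tab[tab[, 1] == best, 2] / tab[tab[, 1] == best, 3])
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, TRUE), collapse = "")
}

# ---- permutations ----------------------------------------------------------
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# slow, formula-level PERMANOVA pseudo-F written directly from the
# sum-of-squares definition (explicit pair loops)
oracle_permanova_f <- function(dm, groups) {
  n <- nrow(dm)
  g <- as.character(groups)
  ss <- function(idx) {
    tot <- 0
    for (i in idx) for (j in idx) if (i < j) tot <- tot + dm[i, j]^2
    tot / length(idx)
  }
  ss_total <- ss(seq_len(n))
  ss_within <- 0
  for (lev in unique(g)) ss_within <- ss_within + ss(which(g == lev))
  k <- length(unique(g))
  ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
}

# exhaustive-permutation p-value: proportion of ALL n! labelings whose
# statistic is >= the observed one (identity included)
oracle_exhaustive_p <- function(dm, groups, stat_fun) {
  n <- nrow(dm)
  obs <- stat_fun(dm, groups)
  perms <- all_permutations(n)
  stats <- apply(perms, 1, function(o) stat_fun(dm, groups[o]))
  mean(stats >= obs - 1e-12)
}

# rank-based ANOSIM R from first principles (midranks)
oracle_anosim_r <- function(dm, groups) {
  n <- nrow(dm)
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  dvals <- dm[pairs]
  rk <- rank(dvals)
  within <- groups[pairs[, 1]] == groups[pairs[, 2]]
  m <- n * (n - 1) / 2
  (mean(rk[!within]) - mean(rk[within])) / (m / 2)
}

# ---- multiple testing and rank tests --------------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# tie-corrected Kruskal-Wallis H from the closed form
oracle_kw_h <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# ---- small fixtures --------------------------------------------------------
# minimal valid recolonization design: n_rep replicates on one substrate
tiny_meta <- function(n_rep = 2, substrate = "polyp",
                      inocula = c("bL", "bJ", "bA"),
                      timepoints = c("2", "7", "14", "28")) {
  rows <- expand.grid(replicate = seq_len(n_rep), timepoint = timepoints,
                      inoculum = inocula, stringsAsFactors = FALSE)
  rows$substrate <- substrate
  rows$sample_id <- sprintf("%s_%s_d%s_r%d", substrate, rows$inoculum,
                            rows$timepoint, rows$replicate)
  rows[, c("sample_id", "substrate", "inoculum", "timepoint", "replicate")]
}

tiny_community <- function(counts, n_rep = 2, substrate = "polyp") {
  meta <- tiny_meta(n_rep, substrate)
  stopifnot(nrow(counts) == nrow(meta))
  rownames(counts) <- meta$sample_id
  community_table(counts, meta)
}

# the default synthetic experiment, generated once per test run
default_experiment <- local({
  cache <- NULL
  function(seed = 7) {
    if (is.null(cache))
      cache <<- simulate_recolonization(truth_spec(seed = seed))
    cache
  }
})

# pathway abundance with taxa acting as their own perfectly-matched
# clusters (bypasses sequence clustering where it is not under test)
taxa_level_pathway_abundance <- function(sim, substrate = "polyp") {
  rel <- relative_abundance(sim$community)
  meta <- sim$community$meta
  keep <- !is.na(meta$substrate) & meta$substrate == substrate &
    meta$timepoint != "inoculum"
  t(rel[keep, , drop = FALSE] %*% sim$pathways$presence)
}
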