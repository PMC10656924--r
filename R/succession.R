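#' Filter core ASVs constantly detected at one or more timepoints
#'
#' An ASV is retained if there is at least one recolonization timepoint
#' (2, 7, 14 or 28 dpr) at which its relative abundance reaches
#' `min_abund` in *every* sample of that timepoint (all inocula and
#' replicates of the given substrate). Inoculum samples never enter the
#' filter. The default floor of `5e-5` corresponds to a 0.005% detection
#' limit.
#'
#' @param rel samples x taxa relative abundance matrix.
#' @param meta metadata data.frame matching the rows of `rel` (see
#'   [community_table()]).
#' @param min_abund detection floor as a fraction.
#' @param substrate restrict to one substrate (`"polyp"` or `"tube"`), or
#'   `NULL` to use all recolonization samples in `rel`.
#' @return character vector of retained ASV ids (column order preserved).
#' @export
filter_core_asvs <- function(rel, meta, min_abund = 5e-5, substrate = NULL) {
  rel <- as.matrix(rel)
  meta <- meta[match(rownames(rel), meta$sample_id), , drop = FALSE]
  keep_s <- meta$timepoint %in% .RECOL_TIMEPOINTS
  if (!is.null(substrate)) {
    .assert(substrate %in% .SUBSTRATES, "unknown substrate: %s", substrate)
    keep_s <- keep_s & !is.na(meta$substrate) & meta$substrate == substrate
  }
  rel <- rel[keep_s, , drop = FALSE]
  tp <- meta$timepoint[keep_s]
  present <- intersect(.RECOL_TIMEPOINTS, unique(tp))
  missing_tp <- setdiff(.RECOL_TIMEPOINTS, present)
  .assert(length(missing_tp) == 0, "timepoint(s) with zero samples: %s",
          paste(missing_tp, collapse = ", "))
  ok <- rep(FALSE, ncol(rel))
  for (t in .RECOL_TIMEPOINTS) {
    sub <- rel[tp == t, , drop = FALSE]
    ok <- ok | (apply(sub, 2, min) >= min_abund)
  }
  colnames(rel)[ok]
}

#' Scale abundances to [0, 1] within display column blocks
#'
#' Reproduces sub-heatmap normalization: samples are grouped into an
#' inocula block plus one block per recolonization treatment (the inoculum
#' applied), each block spanning all timepoints and replicates. Within
#' each block every ASV's values are divided by that ASV's block maximum,
#' so a taxon's temporal trajectory is preserved within a treatment while
#' magnitudes are made comparable across taxa. All-zero block rows stay
#' zero.
#'
#' @param rel samples x taxa relative abundance matrix restricted to the
#'   ASVs of interest (e.g. the [filter_core_asvs()] set).
#' @param meta metadata matching the rows of `rel`.
#' @return object of class `succession_profile`: list with `scaled`
#'   (ASVs x samples matrix, entries in `[0, 1]`), `block` (factor per
#'   column: `inoculum` or the treatment's inoculum label) and `meta`.
#' @export
scale_blocks <- function(rel, meta) {
  rel <- as.matrix(rel)
  .assert(ncol(rel) >= 1, "filtered ASV set is empty")
  meta <- meta[match(rownames(rel), meta$sample_id), , drop = FALSE]
  block <- factor(ifelse(meta$timepoint == "inoculum", "inoculum",
                         meta$inoculum),
                  levels = c("inoculum", .INOCULA))
  tp_rank <- match(meta$timepoint, .TIMEPOINTS)
  ord <- order(block, tp_rank, meta$replicate)
  x <- t(rel[ord, , drop = FALSE])  # ASVs x samples
  block <- block[ord]
  for (b in levels(block)) {
    sel <- block == b
    if (!any(sel)) next
    mx <- apply(x[, sel, drop = FALSE], 1, max)
    mx[mx == 0] <- 1
    x[, sel] <- x[, sel, drop = FALSE] / mx
  }
  structure(list(scaled = x, block = block,
                 meta = meta[ord, , drop = FALSE]),
            class = "succession_profile")
}

# optimal leaf ordering (Bar-Joseph): for each merge node, choose child
# orientations minimizing the summed distance across adjacent block borders
.olo_order <- function(hc, dmat) {
  n <- length(hc$order)
  # leaves(v): integer vector in dendrogram order; M[[v]]: cost matrix
  # indexed (leftmost leaf, rightmost leaf)
  nodes <- vector("list", nrow(hc$merge))
  node_leaves <- vector("list", nrow(hc$merge))
  get_child <- function(id) {
    if (id < 0) list(leaves = -id, m = matrix(0, 1, 1,
                                              dimnames = list(-id, -id)))
    else list(leaves = node_leaves[[id]], m = nodes[[id]])
  }
  for (v in seq_len(nrow(hc$merge))) {
    l <- get_child(hc$merge[v, 1])
    r <- get_child(hc$merge[v, 2])
    ll <- l$leaves; rl <- r$leaves
    leaves <- c(ll, rl)
    m <- matrix(Inf, length(leaves), length(leaves),
                dimnames = list(leaves, leaves))
    lc <- as.character(ll); rc <- as.character(rl)
    # border cost: min over (right edge of left block, left edge of right
    # block); computed for both (L,R) and (R,L) arrangements
    for (a in list(c("lr"), c("rl"))) {
      if (a == "lr") { A <- l; B <- r } else { A <- r; B <- l }
      ac <- as.character(A$leaves); bc <- as.character(B$leaves)
      for (i in ac) for (j in bc) {
        # i = outer-left leaf (in A), j = outer-right leaf (in B)
        best <- min(outer(A$m[i, ac], B$m[bc, j], "+") +
                      dmat[ac, bc, drop = FALSE])
        if (best < m[i, j]) m[i, j] <- best
      }
    }
    nodes[[v]] <- m
    node_leaves[[v]] <- leaves
  }
  # backtrack: recursively pick orientations consistent with the optimal
  # (i, j) endpoints
  order_node <- function(id, i, j) {
    if (id < 0) return(-id)
    l <- get_child(hc$merge[id, 1])
    r <- get_child(hc$merge[id, 2])
    for (a in c("lr", "rl")) {
      if (a == "lr") { A <- l; B <- r; aid <- hc$merge[id, 1]; bid <- hc$merge[id, 2] }
      else { A <- r; B <- l; aid <- hc$merge[id, 2]; bid <- hc$merge[id, 1] }
      ac <- as.character(A$leaves); bc <- as.character(B$leaves)
      ic <- as.character(i); jc <- as.character(j)
      if (!(ic %in% ac) || !(jc %in% bc)) next
      cost <- outer(A$m[ic, ac], B$m[bc, jc], "+") + dmat[ac, bc, drop = FALSE]
      tot <- min(cost)
      if (abs(tot - nodes[[id]][ic, jc]) < 1e-9) {
        w <- which(cost == tot, arr.ind = TRUE)[1, ]
        k <- A$leaves[w[1]]; mm <- B$leaves[w[2]]
        return(c(order_node(aid, i, k), order_node(bid, mm, j)))
      }
    }
    stop("internal error in optimal leaf ordering backtrack")
  }
  root <- nrow(hc$merge)
  m <- nodes[[root]]
  w <- which(m == min(m), arr.ind = TRUE)[1, ]
  i <- node_leaves[[root]][w[1]]; j <- node_leaves[[root]][w[2]]
  order_node(root, i, j)
}

#' Order profile rows by hierarchical clustering with optimal leaf ordering
#'
#' Average-linkage hierarchical clustering on the Euclidean distances
#' between scaled rows; the dendrogram's leaves are rotated to minimize the
#' summed distance between adjacent rows (optimal leaf ordering), giving a
#' deterministic display permutation.
#'
#' @param scaled ASVs x samples matrix (e.g. `scale_blocks()$scaled`), or a
#'   `succession_profile`.
#' @return integer permutation of the row indices.
#' @export
order_rows <- function(scaled) {
  if (inherits(scaled, "succession_profile")) scaled <- scaled$scaled
  scaled <- as.matrix(scaled)
  n <- nrow(scaled)
  .assert(n >= 2, "need at least two rows to order")
  dmat <- as.matrix(dist(scaled))
  dimnames(dmat) <- list(seq_len(n), seq_len(n))
  hc <- hclust(as.dist(dmat), method = "average")
  .olo_order(hc, dmat)
}

#' Classify filtered ASVs into early and late colonizers
#'
#' For each ASV the mean scaled abundance per recolonization timepoint is
#' computed across all recolonization samples; the ASV is `early` when the
#' maximum falls at 2 or 7 dpr and `late` when it falls at 14 or 28 dpr.
#' Ties break toward the earlier timepoint. The published assignments
#' involved visual judgment; this rule is the declared deterministic
#' equivalent, and a user-supplied class table can override it downstream.
#'
#' @param profile a `succession_profile` from [scale_blocks()].
#' @return named character vector (`"early"`/`"late"`) over the profile's
#'   ASVs; ASVs absent from every recolonization sample are dropped with a
#'   warning.
#' @export
classify_colonizers <- function(profile) {
  stopifnot(inherits(profile, "succession_profile"))
  tp_all <- profile$meta$timepoint
  recol <- tp_all %in% .RECOL_TIMEPOINTS
  .assert(all(.RECOL_TIMEPOINTS %in% tp_all),
          "all four recolonization timepoints must be present")
  x <- profile$scaled[, recol, drop = FALSE]
  tp <- tp_all[recol]
  means <- sapply(.RECOL_TIMEPOINTS, function(t)
    rowMeans(x[, tp == t, drop = FALSE]))
  if (!is.matrix(means))  # single-ASV profile
    means <- matrix(means, 1, dimnames = list(rownames(x), .RECOL_TIMEPOINTS))
  absent <- rowSums(means) == 0
  if (any(absent)) {
    warning(sprintf("%d ASV(s) absent from all recolonization samples excluded",
                    sum(absent)))
    means <- means[!absent, , drop = FALSE]
  }
  peak <- .RECOL_TIMEPOINTS[apply(means, 1, which.max)]  # first max = earlier
  setNames(ifelse(peak %in% c("2", "7"), "early", "late"), rownames(means))
}

#' Run the full succession analysis for one substrate
#'
#' Convenience wrapper: relative abundance, core filter, block scaling,
#' row ordering and colonizer classification.
#'
#' @param t a [community_table()].
#' @param substrate substrate to analyse (inoculum samples are always
#'   included in the scaling blocks).
#' @param min_abund detection floor for [filter_core_asvs()].
#' @return a `succession_profile` with additional elements `asv_ids`,
#'   `order` and `class_of`.
#' @export
succession_analysis <- function(t, substrate = "polyp", min_abund = 5e-5) {
  stopifnot(inherits(t, "community_table"))
  rel <- relative_abundance(t)
  core <- filter_core_asvs(rel, t$meta, min_abund, substrate)
  .assert(length(core) > 0, "no ASV passes the core filter")
  keep <- t$meta$timepoint == "inoculum" |
    (!is.na(t$meta$substrate) & t$meta$substrate == substrate)
  prof <- scale_blocks(rel[keep, core, drop = FALSE],
                       t$meta[keep, , drop = FALSE])
  prof$asv_ids <- core
  prof$order <- if (length(core) >= 2) order_rows(prof) else 1L
  prof$class_of <- classify_colonizers(prof)
  prof
}
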