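#' Aggregate ASV relative abundances to cluster level
#'
#' Cluster abundance is the sum of its member ASVs' relative abundances;
#' row sums are preserved.
#'
#' @param rel samples x ASVs fractional matrix.
#' @param cmap a [greedy_cluster()] result covering every ASV in `rel`.
#' @return samples x clusters fractional matrix.
#' @export
aggregate_to_clusters <- function(rel, cmap) {
  stopifnot(inherits(cmap, "cluster_map"))
  rel <- as.matrix(rel)
  unmapped <- setdiff(colnames(rel), names(cmap$cluster_of_asv))
  if (length(unmapped) > 0)
    stop(sprintf("ASV(s) not in cluster map: %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  cl <- factor(cmap$cluster_of_asv[colnames(rel)],
               levels = names(cmap$representative))
  agg <- t(rowsum(t(rel), cl))  # sums member columns per cluster
  out <- matrix(0, nrow(rel), length(cmap$representative),
                dimnames = list(rownames(rel), names(cmap$representative)))
  out[, colnames(agg)] <- agg  # clusters absent from rel stay zero
  out
}

#' Project genome pathway repertoires onto community profiles
#'
#' The core abundance-weighted functional projection: for every pathway,
#' the relative cumulative pathway abundance in a sample is the sum of
#' relative abundances of all clusters predicted (via their assigned
#' genomes) to possess that pathway. A cluster possesses a pathway when at
#' least one assigned genome does (`consensus = "union"`), or when more
#' than half do (`consensus = "majority"`). Clusters without any assigned
#' genome contribute to no pathway; the fraction of the community they
#' represent is reported as `1 - coverage`, never silently renormalized.
#'
#' @param cluster_rel samples x clusters fractional matrix from
#'   [aggregate_to_clusters()].
#' @param pp a [pathway_presence()] whose rows are genome ids.
#' @param cmap a [assign_genomes()]-completed cluster map.
#' @param consensus `"union"` (default) or `"majority"` rule for
#'   multi-genome clusters.
#' @return object of class `pathway_abundance`: list with `A`
#'   (pathways x samples matrix), `coverage` (named per-sample fraction)
#'   and `cluster_presence` (clusters x pathways binary matrix actually
#'   used).
#' @export
project_pathways <- function(cluster_rel, pp, cmap,
                             consensus = c("union", "majority")) {
  stopifnot(inherits(pp, "pathway_presence"), inherits(cmap, "cluster_map"))
  consensus <- match.arg(consensus)
  cluster_rel <- as.matrix(cluster_rel)
  .assert(ncol(pp$presence) >= 1, "pathway matrix has no pathways")
  .assert(nrow(pp$presence) >= 1, "pathway matrix has no taxa")
  genomes <- unlist(cmap$genomes_of)
  missing <- setdiff(genomes, rownames(pp$presence))
  .assert(length(missing) == 0, "genome(s) without pathway data: %s",
          paste(missing, collapse = ", "))
  clusters <- colnames(cluster_rel)
  pws <- colnames(pp$presence)
  cp <- matrix(0L, length(clusters), length(pws),
               dimnames = list(clusters, pws))
  for (cid in clusters) {
    g <- cmap$genomes_of[[cid]]
    if (length(g) == 0) next
    sub <- pp$presence[g, , drop = FALSE]
    cp[cid, ] <- if (consensus == "union") as.integer(colSums(sub) > 0)
                 else as.integer(colSums(sub) > length(g) / 2)
  }
  matched <- clusters[vapply(cmap$genomes_of[clusters], length, 1L) > 0]
  coverage <- rowSums(cluster_rel[, matched, drop = FALSE])
  a <- t(cluster_rel %*% cp)  # pathways x samples
  structure(list(A = a, coverage = coverage, cluster_presence = cp,
                 consensus = consensus),
            class = "pathway_abundance")
}

#' @export
print.pathway_abundance <- function(x, ...) {
  cat(sprintf("pathway_abundance: %d pathways x %d samples; mean coverage %.3f\n",
              nrow(x$A), ncol(x$A), mean(x$coverage)))
  invisible(x)
}

#' Per-timepoint summary of pathway abundances
#'
#' @param pa a [project_pathways()] result.
#' @param meta metadata covering the samples of `pa`.
#' @param pathways pathway ids to summarize.
#' @return tidy data.frame with columns `pathway`, `timepoint`, `mean`,
#'   `sd`, `n`, aggregated across inocula and replicates.
#' @export
pathway_timecourse <- function(pa, meta, pathways) {
  stopifnot(inherits(pa, "pathway_abundance"))
  .assert(length(pathways) > 0, "empty pathway set")
  missing <- setdiff(pathways, rownames(pa$A))
  .assert(length(missing) == 0, "unknown pathway(s): %s",
          paste(missing, collapse = ", "))
  meta <- meta[match(colnames(pa$A), meta$sample_id), , drop = FALSE]
  keep <- meta$timepoint %in% .RECOL_TIMEPOINTS
  out <- list()
  for (p in pathways) for (t in intersect(.RECOL_TIMEPOINTS,
                                          unique(meta$timepoint[keep]))) {
    v <- pa$A[p, keep & meta$timepoint == t]
    out[[paste(p, t)]] <- data.frame(pathway = p, timepoint = t,
                                     mean = mean(v), sd = sd(v),
                                     n = length(v))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
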