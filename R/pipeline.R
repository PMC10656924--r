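#' Build and validate a pipeline run configuration
#'
#' A configuration is a flat named list (or a `key = value` text file) of
#' paths, thresholds and seeds. Unknown keys are rejected; every threshold
#' is checked against its documented range.
#'
#' @param ... configuration entries overriding the defaults, or a single
#'   path to a `key = value` file.
#' @return validated named list of class `run_config`.
#' @section Keys:
#' \describe{
#'   \item{out_dir}{output directory (required).}
#'   \item{counts, meta, pathways, subsystems, asv_fasta, genome_fasta}{
#'     input paths; when `simulate = TRUE` they are generated instead.}
#'   \item{simulate}{logical; generate the synthetic experiment first.}
#'   \item{seed}{master seed (default 1).}
#'   \item{identity_threshold}{clustering/assignment identity, (0.5, 1],
#'     default 0.97.}
#'   \item{core_min_abund}{core-ASV detection floor, default 5e-5.}
#'   \item{subsystem_threshold}{subsystem score cutoff, default 0.5.}
#'   \item{n_permutations}{permutations for PERMANOVA/ANOSIM, default 999.}
#'   \item{n_repeats, n_trees}{feature selection repeats/forest size.}
#'   \item{substrate}{substrate for the succession stage, default "polyp".}
#' }
#' @export
run_config <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.character(args[[1]]) && is.null(names(args))) {
    lines <- readLines(args[[1]])
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    kv <- strsplit(lines, "\\s*=\\s*")
    args <- setNames(lapply(kv, function(x) {
      v <- trimws(x[2])
      if (v %in% c("TRUE", "FALSE")) as.logical(v)
      else if (grepl("^-?[0-9.eE+-]+$", v) && !is.na(suppressWarnings(as.numeric(v))))
        as.numeric(v)
      else v
    }), trimws(vapply(kv, `[`, "", 1)))
  }
  defaults <- list(out_dir = NULL, counts = NULL, meta = NULL,
                   pathways = NULL, subsystems = NULL, asv_fasta = NULL,
                   genome_fasta = NULL, simulate = FALSE, seed = 1,
                   identity_threshold = 0.97, core_min_abund = 5e-5,
                   subsystem_threshold = 0.5, n_permutations = 999,
                   n_repeats = 10, n_trees = 500, substrate = "polyp")
  unknown <- setdiff(names(args), names(defaults))
  .assert(length(unknown) == 0, "unknown config key(s): %s",
          paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, args)
  .assert(!is.null(cfg$out_dir), "out_dir is required")
  .assert(cfg$identity_threshold > 0.5 && cfg$identity_threshold <= 1,
          "identity_threshold must be in (0.5, 1]")
  .assert(cfg$core_min_abund >= 0 && cfg$core_min_abund < 1,
          "core_min_abund must be in [0, 1)")
  .assert(cfg$subsystem_threshold >= 0, "subsystem_threshold must be >= 0")
  .assert(cfg$n_permutations >= 1, "n_permutations must be >= 1")
  .assert(cfg$substrate %in% .SUBSTRATES, "substrate must be polyp or tube")
  if (!isTRUE(cfg$simulate)) {
    needed <- c("counts", "meta", "pathways", "asv_fasta", "genome_fasta")
    miss <- needed[vapply(cfg[needed], is.null, TRUE)]
    .assert(length(miss) == 0,
            "input path(s) required unless simulate = TRUE: %s",
            paste(miss, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

.stage <- function(name, code) {
  t0 <- Sys.time()
  res <- tryCatch(code, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full recolonization analysis pipeline
#'
#' Executes the stages in dependency order — simulate (optional), validate,
#' beta diversity, succession, clustering/genome assignment, pathway
#' projection, feature selection — writing per-stage outputs under
#' `out_dir` and a machine-readable JSON manifest with versions, seeds,
#' input digests and headline numbers. A rerun with identical configuration
#' and inputs reproduces the manifest's numbers exactly.
#'
#' @param cfg a [run_config()].
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "recolonizr",
                   version = as.character(utils::packageVersion("recolonizr")),
                   seed = cfg$seed, parameters = unclass(cfg),
                   stages = list())

  if (isTRUE(cfg$simulate)) {
    sim_dir <- file.path(cfg$out_dir, "simulated")
    .stage("simulate", {
      spec <- truth_spec(seed = cfg$seed)
      write_synthetic_experiment(spec, sim_dir)
    })
    cfg$counts <- file.path(sim_dir, "counts.tsv")
    cfg$meta <- file.path(sim_dir, "meta.tsv")
    cfg$pathways <- file.path(sim_dir, "pathways.tsv")
    cfg$subsystems <- file.path(sim_dir, "subsystems.tsv")
    cfg$asv_fasta <- file.path(sim_dir, "asv.fasta")
    cfg$genome_fasta <- file.path(sim_dir, "genomes_16s.fasta")
    manifest$stages$simulate <- sim_dir
  }

  inputs <- c(cfg$counts, cfg$meta, cfg$pathways, cfg$subsystems,
              cfg$asv_fasta, cfg$genome_fasta)
  manifest$input_digests <- as.list(tools::md5sum(inputs[file.exists(inputs)]))

  ct <- .stage("validate", read_community_table(cfg$counts, cfg$meta))
  pp <- .stage("read pathways",
               read_pathway_presence(cfg$pathways, cfg$subsystems))

  beta <- .stage("betadiv", {
    out <- list()
    for (s in .SUBSTRATES) {
      sel <- !is.na(ct$meta$substrate) & ct$meta$substrate == s &
        ct$meta$timepoint %in% .RECOL_TIMEPOINTS
      rel <- relative_abundance(subset_samples(ct, sel))
      d <- distance_matrix(rel, "bray_curtis")
      meta_s <- ct$meta[rownames(rel), ]
      for (fac in c("inoculum", "timepoint")) {
        r <- permanova(d, meta_s[[fac]], cfg$n_permutations, cfg$seed)
        a <- anosim(d, meta_s[[fac]], cfg$n_permutations, cfg$seed)
        out[[paste(s, fac, sep = "_")]] <-
          list(adonis_r2 = r$effect, adonis_p = r$p_value,
               pseudo_f = r$statistic, anosim_r = a$statistic,
               anosim_p = a$p_value)
      }
      utils::write.table(
        data.frame(sample_id = rownames(d$d), d$d, check.names = FALSE),
        file.path(cfg$out_dir, sprintf("distance_%s.tsv", s)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      ord <- pcoa(d, 2)
      utils::write.table(
        data.frame(sample_id = rownames(ord$coordinates), ord$coordinates),
        file.path(cfg$out_dir, sprintf("pcoa_%s.tsv", s)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
  })
  manifest$stages$betadiv <- beta

  prof <- .stage("succession", {
    p <- succession_analysis(ct, cfg$substrate, cfg$core_min_abund)
    writeLines(p$asv_ids, file.path(cfg$out_dir, "filtered_asvs.txt"))
    utils::write.table(
      data.frame(asv = rownames(p$scaled), p$scaled, check.names = FALSE),
      file.path(cfg$out_dir, "scaled_matrix.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    writeLines(rownames(p$scaled)[p$order],
               file.path(cfg$out_dir, "row_order.txt"))
    utils::write.table(
      data.frame(asv = names(p$class_of), class = unname(p$class_of)),
      file.path(cfg$out_dir, "classes.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    p
  })
  manifest$stages$succession <- list(n_core_asvs = length(prof$asv_ids),
                                     n_early = sum(prof$class_of == "early"),
                                     n_late = sum(prof$class_of == "late"))

  cmap <- .stage("cluster", {
    seqs <- read_fasta(cfg$asv_fasta)
    cm <- greedy_cluster(seqs, cfg$identity_threshold)
    utils::write.table(
      data.frame(asv = names(cm$cluster_of_asv),
                 cluster = unname(cm$cluster_of_asv)),
      file.path(cfg$out_dir, "clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    cm
  })
  cmap <- .stage("assign", {
    g <- read_fasta(cfg$genome_fasta)
    cm <- assign_genomes(g, cmap)
    gm <- data.frame(
      genome = unlist(cm$genomes_of),
      cluster = rep(names(cm$genomes_of),
                    vapply(cm$genomes_of, length, 1L)))
    utils::write.table(gm, file.path(cfg$out_dir, "genome_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cm
  })
  manifest$stages$cluster <- list(n_clusters = length(cmap$representative),
                                  n_unassigned_genomes =
                                    length(cmap$unassigned_genomes))

  pa <- .stage("project", {
    sel <- !is.na(ct$meta$substrate) & ct$meta$substrate == cfg$substrate &
      ct$meta$timepoint %in% .RECOL_TIMEPOINTS
    rel <- relative_abundance(subset_samples(ct, sel))
    crel <- aggregate_to_clusters(rel, cmap)
    p <- project_pathways(crel, pp, cmap)
    utils::write.table(
      data.frame(pathway = rownames(p$A), p$A, check.names = FALSE),
      file.path(cfg$out_dir, "pathway_abundance.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = names(p$coverage),
                 coverage = unname(p$coverage)),
      file.path(cfg$out_dir, "coverage.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    p
  })

  sel_res <- .stage("select", {
    labels <- label_stages(ct$meta)
    sel <- repeated_selection(pa, labels, n_repeats = cfg$n_repeats,
                              n_trees = cfg$n_trees, seed = cfg$seed)
    acc <- if (length(sel$consistent_set) > 0)
      cv_accuracy(pa$A[sel$consistent_set, , drop = FALSE], labels,
                  seed = cfg$seed) else NA_real_
    lfc <- early_late_lfc(pa, labels)
    ss <- subsystem_scores(sel, pp$subsystem_of, cfg$subsystem_threshold)
    utils::write.table(
      data.frame(pathway = names(sel$importance),
                 importance = unname(sel$importance),
                 decision = unname(sel$decision),
                 consistent = names(sel$importance) %in% sel$consistent_set,
                 lfc_late_over_early = unname(lfc[names(sel$importance)])),
      file.path(cfg$out_dir, "selection.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(ss, file.path(cfg$out_dir, "subsystem_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(sel = sel, cv_accuracy = acc, subsystems = ss)
  })
  manifest$stages$select <-
    list(n_consistent = length(sel_res$sel$consistent_set),
         cv_accuracy = sel_res$cv_accuracy,
         n_subsystems_retained = nrow(sel_res$subsystems))

  manifest$headline <- list(
    polyp_adonis_r2_dpr = beta$polyp_timepoint$adonis_r2,
    polyp_adonis_r2_inoculum = beta$polyp_inoculum$adonis_r2,
    tube_adonis_r2_dpr = beta$tube_timepoint$adonis_r2,
    tube_adonis_r2_inoculum = beta$tube_inoculum$adonis_r2,
    n_core_asvs = length(prof$asv_ids),
    n_consistent_pathways = length(sel_res$sel$consistent_set),
    cv_accuracy = sel_res$cv_accuracy)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
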