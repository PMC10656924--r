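#' Define the ground truth of a synthetic recolonization experiment
#'
#' Builds a `truth_spec`: taxon pools for the three inocula (`bL`, `bJ`,
#' `bA`), early/late/inoculum-specific colonizer classes with per-timepoint
#' expected relative abundances, and planted pathway-stage associations.
#' The default design mirrors a host recolonization study: on the host
#' (`polyp`) substrate every inoculum converges onto the same succession
#' trajectory (host-driven reset), whereas on the inert `tube` substrate the
#' composition stays anchored to the inoculum pool with only a mild drift
#' toward the succession profile.
#'
#' Early-class taxa peak at 2 or 7 days post recolonization (dpr) and decay
#' afterwards; late-class taxa mirror them. Class abundance budgets on the
#' polyp are fixed so that the early class holds three times the late
#' class's share at 2 dpr and vice versa at 28 dpr. Pathway presence is
#' Bernoulli with probability `base_p`, pulled toward 1 by `effect_size` for
#' taxa of the matching class:
#' `p = base_p + effect_size * (1 - base_p)`.
#'
#' With balanced classes (`n_early == n_late`) the late taxa are exact
#' mirrors of the early taxa (same weight, time-reflected peak) and every
#' stage-neutral pathway is carried by a late taxon exactly when its early
#' partner carries it. Neutral pathways therefore have equal expected
#' abundance in both stages — they are noise, not weak signal — which is
#' what makes false-confirmation rates of the downstream feature selection
#' interpretable.
#'
#' @param n_early,n_late number of early/late colonizer taxa shared by all
#'   inocula.
#' @param n_specific_per_inoculum taxa unique to each inoculum pool.
#' @param n_pathways total pathways in the planted presence matrix.
#' @param frac_associated fraction of pathways planted as stage-associated
#'   (split evenly between early- and late-associated).
#' @param effect_size in (0, 1]: strength of the pathway-class enrichment.
#' @param base_p baseline pathway presence probability.
#' @param overdispersion Dirichlet concentration for replicate noise
#'   (larger = less overdispersed); passed on to
#'   [simulate_recolonization()].
#' @param seed integer seed controlling all randomized choices in the spec
#'   and in downstream generation.
#' @return an object of class `truth_spec`.
#' @export
truth_spec <- function(n_early = 24, n_late = 24, n_specific_per_inoculum = 4,
                       n_pathways = 100, frac_associated = 0.1,
                       effect_size = 0.6, base_p = 0.3,
                       overdispersion = 200, seed = 1) {
  .assert(n_early >= 0 && n_late >= 0 && n_specific_per_inoculum >= 0,
          "taxon counts must be non-negative")
  .assert(n_early + n_late + 3 * n_specific_per_inoculum >= 1,
          "need at least one taxon")
  .assert(effect_size > 0 && effect_size <= 1, "effect_size must be in (0, 1]")
  .assert(base_p > 0 && base_p < 1, "base_p must be in (0, 1)")
  .assert(overdispersion > 0, "overdispersion must be positive")

  early_ids <- if (n_early > 0) sprintf("E%02d", seq_len(n_early)) else character(0)
  late_ids <- if (n_late > 0) sprintf("L%02d", seq_len(n_late)) else character(0)
  spec_ids <- unlist(lapply(.INOCULA, function(i)
    if (n_specific_per_inoculum > 0)
      sprintf("S_%s_%02d", i, seq_len(n_specific_per_inoculum)) else character(0)))
  taxa <- c(early_ids, late_ids, spec_ids)
  class_of <- setNames(c(rep("early", n_early), rep("late", n_late),
                         rep("inoculum_specific", length(spec_ids))), taxa)
  specific_owner <- setNames(rep(.INOCULA, each = n_specific_per_inoculum),
                             spec_ids)

  tp <- .RECOL_TIMEPOINTS
  with_seed(seed, {
    # per-taxon lognormal-ish weights and a peak timepoint per colonizer
    w <- setNames(rgamma(length(taxa), shape = 1.5, rate = 1) + 0.05, taxa)
    peak <- setNames(rep(NA_character_, length(taxa)), taxa)
    if (n_early > 0) peak[early_ids] <- sample(c("2", "7"), n_early, TRUE)
    if (n_late > 0) peak[late_ids] <- sample(c("14", "28"), n_late, TRUE)
    # when the classes are balanced, late taxa mirror early taxa (same
    # weight, time-reflected peak) and each late taxon has an early
    # partner; stage-neutral pathways are later carried pairwise, so their
    # expected abundance is identical in the early and late stage
    mirror_of <- NULL
    if (n_early == n_late && n_early > 0) {
      mirror_of <- setNames(early_ids, late_ids)
      w[late_ids] <- w[early_ids]
      peak[late_ids] <- c("2" = "28", "7" = "14")[peak[early_ids]]
    }

    # geometric decay of a taxon's share with time-rank distance to its peak
    decay <- 0.35
    shape <- matrix(0, length(taxa), length(tp), dimnames = list(taxa, tp))
    for (k in c(early_ids, late_ids))
      shape[k, ] <- w[k] * decay^abs(seq_along(tp) - match(peak[k], tp))

    # class abundance budgets per timepoint (polyp substrate)
    budget <- rbind(early = c(0.72, 0.60, 0.36, 0.24),
                    late = c(0.24, 0.36, 0.60, 0.72),
                    inoculum_specific = rep(0.04, 4))
    colnames(budget) <- tp
    present <- c(n_early, n_late, length(spec_ids) > 0) > 0
    budget[!present, ] <- 0
    budget <- sweep(budget, 2, colSums(budget), "/")

    # inoculum pool proportions: shared taxa reweighted per inoculum, plus
    # a 30% share for the inoculum's own specific taxa
    pools <- list()
    pool_props <- list()
    shared <- c(early_ids, late_ids)
    for (i in .INOCULA) {
      own <- spec_ids[specific_owner[spec_ids] == i]
      pools[[i]] <- c(shared, own)
      p <- setNames(numeric(length(taxa)), taxa)
      if (length(shared) > 0) {
        u <- rgamma(length(shared), shape = 1, rate = 1) + 0.02
        sh <- if (length(own) > 0) 0.7 else 1
        p[shared] <- sh * w[shared] * u / sum(w[shared] * u)
      }
      if (length(own) > 0) {
        v <- rgamma(length(own), shape = 2, rate = 1) + 0.05
        sh <- if (length(shared) > 0) 0.3 else 1
        p[own] <- sh * v / sum(v)
      }
      pool_props[[i]] <- p
    }

    # trajectories: expected relative abundance per (substrate, inoculum,
    # timepoint, taxon); columns sum to 1
    tube_mix <- setNames(c(0.45, 0.6, 0.75, 0.85), tp)  # drift toward succession
    trajectory <- list()
    for (s in .SUBSTRATES) {
      trajectory[[s]] <- list()
      for (i in .INOCULA) {
        own <- spec_ids[specific_owner[spec_ids] == i]
        m <- matrix(0, length(taxa), length(tp), dimnames = list(taxa, tp))
        for (t in tp) {
          p <- setNames(numeric(length(taxa)), taxa)
          for (cl in c("early", "late")) {
            mem <- taxa[class_of == cl]
            if (length(mem) > 0 && sum(shape[mem, t]) > 0)
              p[mem] <- budget[cl, t] * shape[mem, t] / sum(shape[mem, t])
          }
          if (length(own) > 0)
            p[own] <- budget["inoculum_specific", t] *
              pool_props[[i]][own] / sum(pool_props[[i]][own])
          p <- p / sum(p)
          m[, t] <- if (s == "polyp") p else
            (1 - tube_mix[t]) * pool_props[[i]] + tube_mix[t] * p
        }
        trajectory[[s]][[i]] <- m
      }
    }

    # planted pathway truth
    n_assoc <- round(n_pathways * frac_associated)
    n_ea <- floor(n_assoc / 2)
    n_la <- n_assoc - n_ea
    pw <- sprintf("PWY%03d", seq_len(n_pathways))
    pathway_truth <- setNames(rep("neutral", n_pathways), pw)
    if (n_ea > 0) pathway_truth[seq_len(n_ea)] <- "early_associated"
    if (n_la > 0) pathway_truth[n_ea + seq_len(n_la)] <- "late_associated"
    subsystems <- c("polysaccharide degradation", "nitrogen cycle",
                    "sulfur cycle", "amino acid biosynthesis",
                    "cofactor biosynthesis", "lipid biosynthesis",
                    "nucleotide metabolism", "fermentation",
                    "energy metabolism", "transport")
    subsystem_of <- setNames(rep("", n_pathways), pw)
    subsystem_of[pathway_truth == "early_associated"] <- "polysaccharide degradation"
    late_idx <- which(pathway_truth == "late_associated")
    subsystem_of[late_idx] <- rep(c("nitrogen cycle", "sulfur cycle"),
                                  length.out = length(late_idx))
    neutral_idx <- which(pathway_truth == "neutral")
    subsystem_of[neutral_idx] <- sample(subsystems[-(1:3)],
                                        length(neutral_idx), TRUE)
  })

  structure(list(
    n_taxa = length(taxa), taxa = taxa, class_of = class_of,
    mirror_of = mirror_of,
    specific_owner = specific_owner, inoculum_pools = pools,
    pool_props = pool_props, trajectory = trajectory,
    pathway_truth = pathway_truth, subsystem_of = subsystem_of,
    effect_size = effect_size, base_p = base_p,
    overdispersion = overdispersion, seed = as.integer(seed)
  ), class = "truth_spec")
}

#' @export
print.truth_spec <- function(x, ...) {
  cat(sprintf("truth_spec: %d taxa (%d early, %d late, %d inoculum-specific), %d pathways (%d associated), seed %d\n",
              x$n_taxa, sum(x$class_of == "early"), sum(x$class_of == "late"),
              sum(x$class_of == "inoculum_specific"),
              length(x$pathway_truth), sum(x$pathway_truth != "neutral"),
              x$seed))
  invisible(x)
}

.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) { # degenerate: all mass on the single positive alpha
    g[which.max(alpha)] <- 1
  }
  g / sum(g)
}

#' Simulate a recolonization experiment with known ground truth
#'
#' Draws per-sample counts as a Dirichlet-multinomial around the expected
#' trajectories in a [truth_spec()]: 3 inocula x 4 timepoints x
#' `n_replicates` replicates x 2 substrates, plus one sample per inoculum
#' homogenate. Polyp samples follow the shared succession trajectories
#' (host-driven); tube samples stay close to their inoculum pool. A planted
#' taxa-by-pathway presence matrix is drawn Bernoulli with the spec's
#' `base_p`, enriched by `effect_size` for class-matching pathways.
#'
#' Identical `(spec, n_replicates, depth)` yield bit-identical output.
#'
#' @param spec a [truth_spec()].
#' @param n_replicates replicates per (substrate, inoculum, timepoint) cell.
#' @param depth sequencing depth (total counts) per sample.
#' @return list with `community` (a [community_table()]), `pathways`
#'   (a [pathway_presence()] over taxa) and `truth` (the spec).
#' @export
simulate_recolonization <- function(spec, n_replicates = 5, depth = 20000) {
  stopifnot(inherits(spec, "truth_spec"))
  .assert(depth >= 100, "depth must be >= 100")
  .assert(n_replicates >= 2, "n_replicates must be >= 2")
  for (s in .SUBSTRATES) for (i in .INOCULA) {
    cs <- colSums(spec$trajectory[[s]][[i]])
    .assert(all(abs(cs - 1) < 1e-8),
            "trajectory columns must sum to 1 (substrate %s, inoculum %s)", s, i)
  }

  taxa <- spec$taxa
  conc <- spec$overdispersion
  rows <- list()
  meta <- list()
  with_seed(spec$seed + 1L, {
    for (i in .INOCULA) {
      sid <- paste0("inoc_", i)
      p <- .rdirichlet1(conc * spec$pool_props[[i]])
      rows[[sid]] <- as.integer(rmultinom(1, depth, p))
      meta[[sid]] <- data.frame(sample_id = sid, substrate = NA_character_,
                                inoculum = i, timepoint = "inoculum",
                                replicate = NA_integer_)
    }
    for (s in .SUBSTRATES) for (i in .INOCULA)
      for (t in .RECOL_TIMEPOINTS) for (r in seq_len(n_replicates)) {
        sid <- sprintf("%s_%s_d%s_r%d", s, i, t, r)
        mu <- spec$trajectory[[s]][[i]][, t]
        p <- .rdirichlet1(conc * mu)
        rows[[sid]] <- as.integer(rmultinom(1, depth, p))
        meta[[sid]] <- data.frame(sample_id = sid, substrate = s,
                                  inoculum = i, timepoint = t, replicate = r)
      }

    counts <- do.call(rbind, rows)
    colnames(counts) <- taxa
    meta_df <- do.call(rbind, meta)

    # planted pathway presence per taxon
    pw <- names(spec$pathway_truth)
    p_hi <- spec$base_p + spec$effect_size * (1 - spec$base_p)
    prob <- matrix(spec$base_p, length(taxa), length(pw),
                   dimnames = list(taxa, pw))
    for (k in taxa) {
      cl <- spec$class_of[k]
      if (cl == "early")
        prob[k, spec$pathway_truth == "early_associated"] <- p_hi
      if (cl == "late")
        prob[k, spec$pathway_truth == "late_associated"] <- p_hi
    }
    presence <- matrix(rbinom(length(prob), 1, prob), nrow(prob),
                       dimnames = dimnames(prob))
    if (!is.null(spec$mirror_of)) {
      # stage-balanced carriage: a neutral pathway is carried by a late
      # taxon iff its early partner carries it
      neutral <- names(spec$pathway_truth)[spec$pathway_truth == "neutral"]
      presence[names(spec$mirror_of), neutral] <-
        presence[unname(spec$mirror_of), neutral]
    }
  })
  list(community = community_table(counts, meta_df),
       pathways = pathway_presence(presence, spec$subsystem_of),
       truth = spec)
}

.mutate_seq <- function(chars, rate, alphabet = c("A", "C", "G", "T")) {
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    # substitute to a uniformly chosen *different* base
    repl <- vapply(chars[hit], function(b)
      sample(setdiff(alphabet, b), 1), character(1))
    chars[hit] <- repl
  }
  chars
}

#' Generate 16S-like sequence families with known cluster structure
#'
#' Each cluster descends from an ancestor sequence; ancestors are mutated
#' copies of a common root at per-site rate `1 - between_identity`, and
#' members are mutated copies of their ancestor at rate `1 - within_identity`.
#'
#' @param n_clusters number of sequence clusters.
#' @param members_per_cluster sequences per cluster.
#' @param within_identity expected member-to-ancestor identity, in (0, 1].
#' @param between_identity expected ancestor-to-root identity; must be
#'   `< within_identity`.
#' @param length sequence length (nt).
#' @param seed integer seed.
#' @return list with `records` (named character vector of member sequences),
#'   `cluster` (named character vector: true cluster of each member) and
#'   `ancestors` (named character vector of cluster ancestor sequences,
#'   usable as synthetic genome 16S genes).
#' @export
generate_sequences <- function(n_clusters, members_per_cluster,
                               within_identity = 0.99,
                               between_identity = 0.90,
                               length = 250, seed = 1) {
  .assert(n_clusters >= 1 && members_per_cluster >= 1,
          "need at least one cluster and one member")
  .assert(between_identity > 0 && within_identity <= 1,
          "identities must be in (0, 1]")
  .assert(within_identity > between_identity,
          "within_identity must exceed between_identity")
  with_seed(seed, {
    root <- sample(c("A", "C", "G", "T"), length, TRUE)
    ancestors <- list()
    records <- list()
    cluster <- character(0)
    for (c in seq_len(n_clusters)) {
      cid <- sprintf("C%02d", c)
      anc <- .mutate_seq(root, 1 - between_identity)
      ancestors[[cid]] <- paste(anc, collapse = "")
      for (m in seq_len(members_per_cluster)) {
        mid <- sprintf("%s_M%02d", cid, m)
        records[[mid]] <- paste(.mutate_seq(anc, 1 - within_identity),
                                collapse = "")
        cluster[mid] <- cid
      }
    }
  })
  list(records = unlist(records), cluster = cluster,
       ancestors = unlist(ancestors))
}

#' Write a full synthetic experiment to disk
#'
#' Convenience wrapper producing the file set consumed by the pipeline:
#' `counts.tsv`, `meta.tsv`, `pathways.tsv`, `subsystems.tsv`, `asv.fasta`,
#' `genomes_16s.fasta` and `truth.json`. ASV sequences are generated with
#' one cluster per taxon; genome 16S genes are the cluster ancestors, so
#' each taxon's genome matches its own cluster.
#'
#' @param spec a [truth_spec()].
#' @param out_dir output directory (created if needed).
#' @param n_replicates,depth passed to [simulate_recolonization()].
#' @param asvs_per_taxon ASV sequence variants generated per taxon.
#' @param within_identity,between_identity,seq_length sequence family
#'   parameters, see [generate_sequences()].
#' @return invisibly, a named list of the written file paths plus the
#'   in-memory objects.
#' @export
write_synthetic_experiment <- function(spec, out_dir, n_replicates = 5,
                                       depth = 20000, asvs_per_taxon = 1,
                                       within_identity = 0.99,
                                       between_identity = 0.90,
                                       seq_length = 250) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_recolonization(spec, n_replicates, depth)
  seqs <- generate_sequences(spec$n_taxa, asvs_per_taxon, within_identity,
                             between_identity, seq_length,
                             seed = spec$seed + 2L)
  # name sequence clusters after taxa so truth links counts to sequences
  map <- setNames(spec$taxa, sprintf("C%02d", seq_len(spec$n_taxa)))
  asv_ids <- names(seqs$records)
  # one ASV per taxon keeps the count table unchanged; extra variants would
  # need count splitting, so the community table uses the first member
  first <- !duplicated(seqs$cluster)
  asv_seqs <- setNames(seqs$records[first], map[seqs$cluster[first]])
  genome_seqs <- setNames(seqs$ancestors, paste0("genome_", map[names(seqs$ancestors)]))

  paths <- list(counts = file.path(out_dir, "counts.tsv"),
                meta = file.path(out_dir, "meta.tsv"),
                pathways = file.path(out_dir, "pathways.tsv"),
                subsystems = file.path(out_dir, "subsystems.tsv"),
                asv_fasta = file.path(out_dir, "asv.fasta"),
                genome_fasta = file.path(out_dir, "genomes_16s.fasta"),
                truth = file.path(out_dir, "truth.json"))
  write_community_table(sim$community, paths$counts, paths$meta)
  # pathway matrix rows renamed to genome ids for the assignment stage
  pres <- sim$pathways$presence
  rownames(pres) <- paste0("genome_", rownames(pres))
  write_pathway_presence(pathway_presence(pres, sim$pathways$subsystem_of),
                         paths$pathways, paths$subsystems)
  write_fasta(asv_seqs, paths$asv_fasta)
  write_fasta(genome_seqs, paths$genome_fasta)
  truth <- list(seed = spec$seed, class_of = as.list(spec$class_of),
                pathway_truth = as.list(spec$pathway_truth))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, list(community = sim$community,
                          pathways = sim$pathways, truth_spec = spec)))
}
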