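test_that("trajectories are proper compositions and generation is deterministic", {
  spec <- truth_spec(seed = 3)
  for (s in c("polyp", "tube")) for (i in c("bL", "bJ", "bA"))
    expect_equal(colSums(spec$trajectory[[s]][[i]]),
                 setNames(rep(1, 4), c("2", "7", "14", "28")))
  sim1 <- simulate_recolonization(spec, n_replicates = 2, depth = 500)
  sim2 <- simulate_recolonization(spec, n_replicates = 2, depth = 500)
  expect_identical(sim1$community$counts, sim2$community$counts)
  expect_identical(sim1$pathways$presence, sim2$pathways$presence)
  # design shape: 3 inocula + 2 substrates x 3 inocula x 4 timepoints x 2 reps
  expect_equal(nrow(sim1$community$counts), 3 + 2 * 3 * 4 * 2)
  expect_true(all(rowSums(sim1$community$counts) == 500))
})

test_that("per-sample relative abundances converge to trajectory means", {
  # law of large numbers: tiny overdispersion, large depth
  spec <- truth_spec(seed = 5, overdispersion = 1e7)
  sim <- simulate_recolonization(spec, n_replicates = 2, depth = 1e6)
  rel <- relative_abundance(sim$community)
  meta <- sim$community$meta
  for (sid in c("polyp_bL_d2_r1", "tube_bA_d28_r2", "polyp_bJ_d14_r1")) {
    mu <- spec$trajectory[[meta[sid, "substrate"]]][[meta[sid, "inoculum"]]][, meta[sid, "timepoint"]]
    expect_lt(max(abs(rel[sid, ] - mu)), 0.01)
  }
})

test_that("single-taxon spec puts the whole depth on that taxon", {
  spec <- truth_spec(n_early = 1, n_late = 0, n_specific_per_inoculum = 0,
                     seed = 1)
  sim <- simulate_recolonization(spec, n_replicates = 2, depth = 300)
  expect_true(all(sim$community$counts == 300))
})

test_that("polyp trajectories are host-driven and shared across inocula", {
  spec <- truth_spec(seed = 2)
  shared <- names(spec$class_of)[spec$class_of != "inoculum_specific"]
  for (i in c("bJ", "bA"))
    expect_equal(spec$trajectory$polyp[[i]][shared, ],
                 spec$trajectory$polyp$bL[shared, ])
  # early class holds 3x the late share at 2 dpr and vice versa at 28 dpr
  early <- names(spec$class_of)[spec$class_of == "early"]
  late <- names(spec$class_of)[spec$class_of == "late"]
  tr <- spec$trajectory$polyp$bL
  expect_equal(sum(tr[early, "2"]) / sum(tr[late, "2"]), 3, tolerance = 1e-9)
  expect_equal(sum(tr[late, "28"]) / sum(tr[early, "28"]), 3, tolerance = 1e-9)
  # tube trajectories retain inoculum-specific taxa through time
  for (i in c("bL", "bJ", "bA")) {
    own <- names(spec$specific_owner)[spec$specific_owner == i]
    expect_true(all(colSums(spec$trajectory$tube[[i]][own, , drop = FALSE]) >
                      0.05))
  }
})

test_that("invalid specs and arguments are rejected", {
  expect_error(truth_spec(effect_size = 0), "effect_size")
  expect_error(truth_spec(effect_size = 1.2), "effect_size")
  spec <- truth_spec(seed = 1)
  expect_error(simulate_recolonization(spec, n_replicates = 1), "n_replicates")
  expect_error(simulate_recolonization(spec, depth = 10), "depth")
  broken <- spec
  broken$trajectory$polyp$bL[1, 1] <- broken$trajectory$polyp$bL[1, 1] + 0.5
  expect_error(simulate_recolonization(broken), "sum to 1")
})

test_that("sequence families respect the planted identity structure", {
  gs <- generate_sequences(6, 4, within_identity = 0.99,
                           between_identity = 0.90, length = 1000, seed = 2)
  gs_again <- generate_sequences(6, 4, within_identity = 0.99,
                                 between_identity = 0.90, length = 1000,
                                 seed = 2)
  expect_identical(gs$records, gs_again$records)
  # mean pairwise identity within vs between clusters
  within <- c(); between <- c()
  ids <- names(gs$records)
  for (i in seq_along(ids)[-1]) for (j in seq_len(i - 1)) {
    idt <- global_identity(gs$records[[ids[i]]], gs$records[[ids[j]]])
    if (gs$cluster[ids[i]] == gs$cluster[ids[j]]) within <- c(within, idt)
    else between <- c(between, idt)
  }
  expect_gte(mean(within), 0.975)
  expect_lte(mean(within), 1.0)
  expect_lt(mean(between), 0.95)
  # degenerate settings
  same <- generate_sequences(2, 3, within_identity = 1, between_identity = 0.9,
                             length = 100, seed = 1)
  expect_length(unique(same$records[1:3]), 1)
  expect_error(generate_sequences(2, 2, within_identity = 0.9,
                                  between_identity = 0.95),
               "exceed")
})

test_that("written synthetic experiments are readable by the IO layer", {
  tmp <- withr::local_tempdir()
  spec <- truth_spec(n_early = 4, n_late = 4, n_specific_per_inoculum = 1,
                     n_pathways = 10, seed = 9)
  out <- write_synthetic_experiment(spec, tmp, n_replicates = 2, depth = 500,
                                    seq_length = 120)
  ct <- read_community_table(out$counts, out$meta)
  expect_identical(ct$counts, out$community$counts)
  pp <- read_pathway_presence(out$pathways, out$subsystems)
  expect_equal(sort(rownames(pp$presence)),
               sort(paste0("genome_", spec$taxa)))
  asv <- read_fasta(out$asv_fasta)
  expect_setequal(names(asv), spec$taxa)
})
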