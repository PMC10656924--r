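test_that("community table round-trips through TSV and keeps order", {
  set.seed(11)
  for (rep in 1:3) {
    n_taxa <- sample(3:8, 1)
    counts <- matrix(rpois(24 * n_taxa, 20) + 1L, 24, n_taxa,
                     dimnames = list(NULL, paste0("asv", seq_len(n_taxa))))
    ct <- tiny_community(counts)
    tmp <- withr::local_tempdir()
    write_community_table(ct, file.path(tmp, "c.tsv"), file.path(tmp, "m.tsv"))
    back <- read_community_table(file.path(tmp, "c.tsv"),
                                 file.path(tmp, "m.tsv"))
    expect_identical(back$counts, ct$counts)
    expect_identical(back$meta$sample_id, ct$meta$sample_id)
    expect_identical(back$meta$timepoint, ct$meta$timepoint)
  }
})

test_that("community table validation rejects schema violations", {
  counts <- matrix(c(5L, 3L, 0L, 2L), 2, 2,
                   dimnames = list(c("s1", "s2"), c("a1", "a2")))
  meta <- data.frame(sample_id = c("s1", "s2"), substrate = "polyp",
                     inoculum = "bL", timepoint = c("2", "7"), replicate = 1L)
  expect_s3_class(community_table(counts, meta), "community_table")
  # missing metadata names the offending sample
  expect_error(community_table(counts, meta[1, , drop = FALSE]), "s2")
  # negative and fractional counts are named by position
  bad <- counts; bad[2, 1] <- -1L
  expect_error(community_table(bad, meta), "negative or non-integer")
  badf <- matrix(c(0.5, 3, 1, 2), 2, 2, dimnames = dimnames(counts))
  expect_error(community_table(badf, meta), "s1")
  # all-zero sample, unknown levels, duplicate taxa
  zero <- counts; zero[1, ] <- 0L
  expect_error(community_table(zero, meta), "all-zero")
  m2 <- meta; m2$timepoint[1] <- "3"
  expect_error(community_table(counts, m2), "timepoint")
  m3 <- meta; m3$substrate[1] <- "rock"
  expect_error(community_table(counts, m3), "substrate")
  dup <- counts; colnames(dup) <- c("a1", "a1")
  expect_error(community_table(dup, meta), "unique")
  # NA substrate tolerated only for inoculum homogenates
  m4 <- meta; m4$substrate[1] <- NA
  expect_error(community_table(counts, m4), "substrate")
  m5 <- meta; m5$substrate[1] <- NA; m5$timepoint[1] <- "inoculum"
  expect_s3_class(community_table(counts, m5), "community_table")
})

test_that("fasta reader validates and round-trips", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "x.fasta")
  writeLines(c(">a desc", "acgt", ">b", "ACGU"), f)
  recs <- read_fasta(f)
  expect_identical(recs, c(a = "ACGT", b = "ACGT"))  # upper-cased, U -> T
  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">a", "ACXT"), f)
  expect_error(read_fasta(f), "non-ACGTN")
  # random records round-trip modulo line wrapping
  set.seed(5)
  recs <- setNames(vapply(1:100, function(i) random_dna(sample(50:300, 1)), ""),
                   paste0("seq", 1:100))
  write_fasta(recs, f, width = 60)
  expect_identical(read_fasta(f), recs)
})

test_that("pathway presence reader enforces binary cells and maps subsystems", {
  tmp <- withr::local_tempdir()
  pf <- file.path(tmp, "p.tsv"); sf <- file.path(tmp, "s.tsv")
  writeLines(c("taxon\tp1\tp2\tp3", "t1\t1\t0\t1", "t2\t0\t0\t1"), pf)
  writeLines(c("pathway\tsubsystem", "p1\tchitin degradation",
               "p2\tsulfur oxidation"), sf)
  expect_message(pp <- read_pathway_presence(pf, sf), "unassigned")
  expect_equal(dim(pp$presence), c(2, 3))
  expect_identical(unname(pp$subsystem_of["p3"]), "unassigned")
  writeLines(c("taxon\tp1", "t1\t2"), pf)
  expect_error(read_pathway_presence(pf), "non-binary")
  # round-trip
  set.seed(3)
  m <- matrix(rbinom(40, 1, 0.4), 8, 5,
              dimnames = list(paste0("t", 1:8), paste0("p", 1:5)))
  pp <- pathway_presence(m, setNames(rep(c("s1", "s2"), length.out = 5),
                                     paste0("p", 1:5)))
  write_pathway_presence(pp, pf, sf)
  back <- read_pathway_presence(pf, sf)
  expect_identical(back$presence, pp$presence)
  expect_identical(back$subsystem_of, pp$subsystem_of)
})

test_that("validate_inputs reports failures without raising", {
  tmp <- withr::local_tempdir()
  ct <- tiny_community(matrix(5L, 24, 2,
                              dimnames = list(NULL, c("a1", "a2"))))
  write_community_table(ct, file.path(tmp, "c.tsv"), file.path(tmp, "m.tsv"))
  suppressMessages(
    res <- validate_inputs(file.path(tmp, "c.tsv"), file.path(tmp, "m.tsv")))
  expect_true(res$ok)
  # corrupt the counts
  writeLines(c("sample_id\ta1", "nope\t-3"), file.path(tmp, "c.tsv"))
  suppressMessages(
    res <- validate_inputs(file.path(tmp, "c.tsv"), file.path(tmp, "m.tsv")))
  expect_false(res$ok)
  expect_match(res$errors, "community table", all = FALSE)
})
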