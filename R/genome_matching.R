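.NW_MATCH <- 1L
.NW_MISMATCH <- -1L
.NW_GAP_OPEN <- 2L    # penalty charged once per gap
.NW_GAP_EXTEND <- 1L  # penalty per gapped position

.nw_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      b <- c("A", "C", "G", "T", "N")
      mm <- matrix(.NW_MISMATCH, 5, 5, dimnames = list(b, b))
      diag(mm) <- .NW_MATCH
      mm["N", ] <- .NW_MISMATCH  # ambiguous sites never count as matches
      mm[, "N"] <- .NW_MISMATCH
      m <<- mm
    }
    m
  }
})

#' Global alignment identity of two DNA sequences
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap open -2,
#' gap extend -1 per gapped position), with identity defined as the number
#' of identical aligned bases divided by the full alignment length
#' (gap columns count in the denominator). `N` counts as a mismatch.
#'
#' @param seq_a,seq_b DNA strings over `A`, `C`, `G`, `T`, `N`.
#' @return identity fraction in `[0, 1]`; symmetric in its arguments.
#' @export
global_identity <- function(seq_a, seq_b) {
  .identity_many(seq_a, seq_b)[1]
}

# identity of one query against many targets in a single alignment call
.identity_many <- function(query, targets) {
  q <- .normalize_dna(query, "query")
  tg <- vapply(targets, .normalize_dna, character(1), id = "target")
  .assert(nchar(q) > 0 && all(nchar(tg) > 0), "sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(tg), Biostrings::DNAString(q), type = "global",
    substitutionMatrix = .nw_submat(),
    gapOpening = .NW_GAP_OPEN, gapExtension = .NW_GAP_EXTEND)
  if (!grepl("N", q, fixed = TRUE) && !any(grepl("N", tg, fixed = TRUE))) {
    # fast path: nmatch/nchar exclude terminal gap columns, so add the
    # unaligned overhangs of both sequences back into the denominator
    p <- Biostrings::pattern(aln)
    s <- Biostrings::subject(aln)
    alen <- Biostrings::nchar(aln) +
      (BiocGenerics::start(p) - 1) + (nchar(tg) - BiocGenerics::end(p)) +
      (BiocGenerics::start(s) - 1) + (nchar(q) - BiocGenerics::end(s))
    return(unname(Biostrings::nmatch(aln) / alen))
  }
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  vapply(seq_along(pa), function(i) {
    a <- strsplit(pa[i], "")[[1]]
    b <- strsplit(pb[i], "")[[1]]
    sum(a == b & a != "N") / length(a)
  }, numeric(1))
}

#' Greedy incremental sequence clustering at an identity threshold
#'
#' cd-hit-style greedy clustering: sequences are sorted by length
#' (descending; ties broken by id, lexicographically), then each sequence
#' joins the first existing cluster whose representative has
#' [global_identity()] at or above `threshold`, or founds a new cluster.
#' The declared sort makes the result independent of input order.
#'
#' @param seqs named character vector of DNA sequences (e.g. from
#'   [read_fasta()]).
#' @param threshold identity threshold in (0.5, 1]; default 0.97, the
#'   conventional OTU level bridging ASVs and genomes.
#' @return object of class `cluster_map`: list with `cluster_of_asv`
#'   (named character), `representative` (cluster -> member id),
#'   `members` (list cluster -> ids), `genomes_of` (empty until
#'   [assign_genomes()]), `threshold` and `seqs` (the representative
#'   sequences).
#' @export
greedy_cluster <- function(seqs, threshold = 0.97) {
  .assert(length(seqs) >= 1, "need at least one sequence")
  .assert(!is.null(names(seqs)) && anyDuplicated(names(seqs)) == 0,
          "sequences must have unique names")
  .assert(threshold > 0.5 && threshold <= 1,
          "threshold must be in (0.5, 1]")
  ord <- order(-nchar(seqs), names(seqs))
  ids <- names(seqs)[ord]
  reps <- character(0)         # representative member id per cluster
  assignment <- character(0)
  for (id in ids) {
    placed <- FALSE
    if (length(reps) > 0) {
      ident <- .identity_many(seqs[[id]], seqs[reps])
      hit <- which(ident >= threshold)
      if (length(hit) > 0) {  # first founded cluster wins
        assignment[id] <- names(reps)[hit[1]]
        placed <- TRUE
      }
    }
    if (!placed) {
      cid <- sprintf("cluster_%03d", length(reps) + 1)
      reps[cid] <- id
      assignment[id] <- cid
    }
  }
  members <- split(names(assignment), assignment)
  structure(list(cluster_of_asv = assignment[names(seqs)],
                 representative = reps,
                 members = members[names(reps)],
                 genomes_of = setNames(vector("list", length(reps)),
                                       names(reps)),
                 unassigned_genomes = character(0),
                 threshold = threshold,
                 rep_seqs = setNames(unname(seqs[reps]), names(reps))),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("cluster_map: %d sequences in %d clusters at %.0f%% identity; %d genome(s) assigned\n",
              length(x$cluster_of_asv), length(x$representative),
              100 * x$threshold, length(unlist(x$genomes_of))))
  invisible(x)
}

#' Assign genome 16S sequences to ASV clusters
#'
#' Each genome's 16S gene is compared against every cluster representative;
#' the genome is attached to *all* clusters reached at or above the
#' threshold (a genome may legitimately match several 97% clusters).
#' Genomes matching no cluster are recorded in `unassigned_genomes`.
#'
#' @param genome_seqs named character vector of genome 16S sequences.
#' @param cmap a [greedy_cluster()] result.
#' @param threshold identity threshold; defaults to the clustering
#'   threshold.
#' @return the `cluster_map` with `genomes_of` and `unassigned_genomes`
#'   filled in.
#' @export
assign_genomes <- function(genome_seqs, cmap, threshold = cmap$threshold) {
  stopifnot(inherits(cmap, "cluster_map"))
  .assert(!is.null(names(genome_seqs)), "genome sequences must be named")
  unassigned <- character(0)
  for (gid in names(genome_seqs)) {
    ident <- .identity_many(genome_seqs[[gid]], cmap$rep_seqs)
    hits <- names(cmap$representative)[ident >= threshold]
    for (cid in hits)
      cmap$genomes_of[[cid]] <- c(cmap$genomes_of[[cid]], gid)
    if (length(hits) == 0) unassigned <- c(unassigned, gid)
  }
  cmap$unassigned_genomes <- unassigned
  cmap
}
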