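#' Construct and validate a community table
#'
#' A community table couples a samples-by-taxa matrix of sequence counts with
#' per-sample experimental metadata. Metadata rows describe the
#' recolonization design: substrate (`polyp` or `tube`), inoculum source
#' community (`bL`, `bJ`, `bA` for larvae-, juvenile- and adult-derived
#' consortia), timepoint (`inoculum` or days post recolonization, dpr:
#' `2`, `7`, `14`, `28`) and replicate number. Inoculum samples are the
#' source homogenates and may carry `NA` substrate.
#'
#' @param counts integer matrix, samples in rows, taxa (ASVs) in columns;
#'   dimnames required.
#' @param meta data.frame with columns `sample_id`, `substrate`, `inoculum`,
#'   `timepoint`, `replicate`; one row per sample in `counts`.
#' @param taxonomy optional character vector of lineage strings, one per
#'   taxon.
#' @return an object of class `community_table`: a list with elements
#'   `counts`, `meta` and `taxonomy`.
#' @examples
#' cts <- matrix(c(5L, 3L, 0L, 2L), 2, 2,
#'               dimnames = list(c("s1", "s2"), c("asv1", "asv2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), substrate = "polyp",
#'                    inoculum = "bL", timepoint = c("2", "7"), replicate = 1L)
#' community_table(cts, meta)
#' @export
community_table <- function(counts, meta, taxonomy = NULL) {
  .assert(is.matrix(counts), "counts must be a matrix")
  .assert(!is.null(rownames(counts)) && !is.null(colnames(counts)),
          "counts must have sample rownames and taxon colnames")
  if (anyNA(counts) || any(!is.finite(counts)))
    stop("counts contains missing or non-finite values", call. = FALSE)
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative or non-integer count at sample '%s', taxon '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]),
         call. = FALSE)
  storage.mode(counts) <- "integer"
  .assert(anyDuplicated(colnames(counts)) == 0, "taxa ids must be unique")
  .assert(anyDuplicated(rownames(counts)) == 0, "sample ids must be unique")

  required <- c("sample_id", "substrate", "inoculum", "timepoint", "replicate")
  missing_cols <- setdiff(required, names(meta))
  .assert(length(missing_cols) == 0, "metadata lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  .assert(anyDuplicated(meta$sample_id) == 0, "duplicate sample_id in metadata")
  absent <- setdiff(rownames(counts), meta$sample_id)
  if (length(absent) > 0)
    stop(sprintf("no metadata for sample(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- meta$sample_id

  meta$substrate <- as.character(meta$substrate)
  meta$inoculum <- as.character(meta$inoculum)
  meta$timepoint <- as.character(meta$timepoint)
  bad_tp <- setdiff(meta$timepoint, .TIMEPOINTS)
  .assert(length(bad_tp) == 0, "unknown timepoint(s): %s",
          paste(bad_tp, collapse = ", "))
  is_inoc <- meta$timepoint == "inoculum"
  bad_sub <- !is.na(meta$substrate) & !(meta$substrate %in% .SUBSTRATES)
  .assert(!any(bad_sub), "unknown substrate(s): %s",
          paste(unique(meta$substrate[bad_sub]), collapse = ", "))
  .assert(all(!is.na(meta$substrate) | is_inoc),
          "substrate may be NA only for inoculum samples")
  bad_in <- !(meta$inoculum %in% .INOCULA)
  .assert(!any(bad_in), "unknown inoculum label(s): %s",
          paste(unique(meta$inoculum[bad_in]), collapse = ", "))
  meta$replicate <- as.integer(meta$replicate)
  .assert(all(is_inoc | (!is.na(meta$replicate) & meta$replicate >= 1)),
          "replicate must be a positive integer for recolonization samples")

  zero <- rownames(counts)[rowSums(counts) == 0]
  if (length(zero) > 0)
    stop(sprintf("all-zero count row(s) for sample(s): %s",
                 paste(zero, collapse = ", ")), call. = FALSE)

  if (!is.null(taxonomy)) {
    .assert(length(taxonomy) == ncol(counts),
            "taxonomy must have one entry per taxon")
    taxonomy <- setNames(as.character(taxonomy), colnames(counts))
  }
  structure(list(counts = counts, meta = meta, taxonomy = taxonomy),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d samples x %d taxa\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(substrate = ifelse(is.na(x$meta$substrate), "<inoculum>",
                                  x$meta$substrate),
               timepoint = x$meta$timepoint)
  print(tab)
  invisible(x)
}

#' Subset a community table by sample
#'
#' @param t a [community_table()].
#' @param keep logical or character vector selecting samples.
#' @param drop_empty_taxa drop taxa with zero total count after subsetting.
#' @return a `community_table` restricted to the selected samples.
#' @export
subset_samples <- function(t, keep, drop_empty_taxa = FALSE) {
  stopifnot(inherits(t, "community_table"))
  cts <- t$counts[keep, , drop = FALSE]
  if (drop_empty_taxa) cts <- cts[, colSums(cts) > 0, drop = FALSE]
  taxonomy <- if (is.null(t$taxonomy)) NULL else t$taxonomy[colnames(cts)]
  community_table(cts, t$meta[rownames(cts), , drop = FALSE], taxonomy)
}

#' Read a community table from TSV files
#'
#' Both files are plain tab-separated text with a header row; the first
#' column holds the row identifier (sample id). Counts must be non-negative
#' integers — relative abundances are rejected here so that normalization
#' stays an explicit downstream step ([relative_abundance()]).
#'
#' @param counts_path TSV of counts, samples in rows, taxa in columns.
#' @param meta_path TSV of sample metadata (columns `sample_id`, `substrate`,
#'   `inoculum`, `timepoint`, `replicate`).
#' @return a validated [community_table()]; file row/column order preserved.
#' @export
read_community_table <- function(counts_path, meta_path) {
  .assert(file.exists(counts_path), "counts file not found: %s", counts_path)
  .assert(file.exists(meta_path), "metadata file not found: %s", meta_path)
  raw <- read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  .assert(ncol(raw) >= 2, "counts table needs an id column and >=1 taxon")
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric count cell(s) in counts table", call. = FALSE)
  rownames(m) <- ids
  meta <- read.delim(meta_path, stringsAsFactors = FALSE,
                     na.strings = c("NA", ""))
  community_table(m, meta)
}

#' Write a community table to TSV files
#'
#' @param t a [community_table()].
#' @inheritParams read_community_table
#' @return invisibly, `t`.
#' @export
write_community_table <- function(t, counts_path, meta_path) {
  stopifnot(inherits(t, "community_table"))
  df <- data.frame(sample_id = rownames(t$counts), t$counts,
                   check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(t$meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(t)
}

.normalize_dna <- function(x, id) {
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- gsub("[ACGTN]", "", x)
  if (nzchar(bad))
    stop(sprintf("sequence '%s' contains non-ACGTN symbol(s): %s", id,
                 paste(unique(strsplit(bad, "")[[1]]), collapse = "")),
         call. = FALSE)
  x
}

#' Read a DNA FASTA file
#'
#' Sequences are uppercased, `U` is mapped to `T`, and the alphabet is
#' restricted to `A`, `C`, `G`, `T`, `N`. Ids are the first whitespace token
#' of each header and must be unique.
#'
#' @param path FASTA file.
#' @return named character vector of sequences (names are record ids), in
#'   file order.
#' @export
read_fasta <- function(path) {
  .assert(file.exists(path), "FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop(sprintf("duplicate FASTA id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  seqs <- as.character(set)
  empty <- ids[nchar(seqs) == 0]
  if (length(empty) > 0)
    stop(sprintf("empty sequence for id(s): %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  setNames(mapply(.normalize_dna, seqs, ids, USE.NAMES = FALSE), ids)
}

#' Write DNA sequences to FASTA
#'
#' @param records named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70) {
  .assert(!is.null(names(records)) && all(nzchar(names(records))),
          "records must be a named character vector")
  set <- Biostrings::DNAStringSet(records)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a pathway presence object
#'
#' A binary taxa-by-pathways matrix (as predicted from genomes by an
#' external metabolic reconstruction tool such as gapseq) together with a
#' pathway-to-subsystem mapping. Pathways without a mapping are labelled
#' `"unassigned"`.
#'
#' @param presence binary matrix, taxa (genomes or clusters) in rows,
#'   pathways in columns.
#' @param subsystem_of named character vector mapping pathway id to
#'   subsystem label; may omit pathways.
#' @return object of class `pathway_presence` with elements `presence` and
#'   `subsystem_of` (complete over all pathways).
#' @export
pathway_presence <- function(presence, subsystem_of = character(0)) {
  .assert(is.matrix(presence), "presence must be a matrix")
  .assert(!is.null(rownames(presence)) && !is.null(colnames(presence)),
          "presence needs taxon rownames and pathway colnames")
  if (anyNA(presence) || !all(presence %in% c(0, 1)))
    stop("presence cells must all be 0 or 1", call. = FALSE)
  storage.mode(presence) <- "integer"
  .assert(anyDuplicated(colnames(presence)) == 0, "pathway ids must be unique")
  full <- setNames(rep("unassigned", ncol(presence)), colnames(presence))
  known <- intersect(names(subsystem_of), colnames(presence))
  full[known] <- unname(subsystem_of[known])
  n_un <- sum(full == "unassigned")
  if (n_un > 0 && length(subsystem_of) > 0)
    message(sprintf("%d pathway(s) without subsystem mapping set to 'unassigned'",
                    n_un))
  structure(list(presence = presence, subsystem_of = full),
            class = "pathway_presence")
}

#' Read a pathway presence matrix and subsystem map from TSV
#'
#' @param path TSV with taxa in rows (first column id) and pathways in
#'   columns; cells must be 0/1.
#' @param subsystem_path optional two-column TSV (`pathway`, `subsystem`).
#' @return a [pathway_presence()] object.
#' @export
read_pathway_presence <- function(path, subsystem_path = NULL) {
  .assert(file.exists(path), "pathway table not found: %s", path)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- as.character(raw[[1]])
  if (!is.numeric(m) || anyNA(m) || !all(m %in% c(0, 1))) {
    bad <- which(is.na(m) | !(m %in% c(0, 1)), arr.ind = TRUE)
    stop(sprintf("non-binary cell at taxon '%s', pathway '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]),
         call. = FALSE)
  }
  subsys <- character(0)
  if (!is.null(subsystem_path)) {
    .assert(file.exists(subsystem_path), "subsystem table not found: %s",
            subsystem_path)
    sm <- read.delim(subsystem_path, stringsAsFactors = FALSE)
    .assert(ncol(sm) >= 2, "subsystem table needs two columns")
    subsys <- setNames(as.character(sm[[2]]), as.character(sm[[1]]))
  }
  pathway_presence(m, subsys)
}

#' Write a pathway presence object to TSV
#'
#' @param pp a [pathway_presence()].
#' @param path output TSV for the binary matrix.
#' @param subsystem_path optional output TSV for the subsystem map.
#' @return invisibly, `pp`.
#' @export
write_pathway_presence <- function(pp, path, subsystem_path = NULL) {
  stopifnot(inherits(pp, "pathway_presence"))
  df <- data.frame(taxon = rownames(pp$presence), pp$presence,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(subsystem_path)) {
    sm <- data.frame(pathway = names(pp$subsystem_of),
                     subsystem = unname(pp$subsystem_of))
    write.table(sm, subsystem_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(pp)
}

#' Validate pipeline input files and print a schema report
#'
#' Reads the counts/metadata pair (and optionally a pathway presence matrix
#' and FASTA files) and reports every schema violation found.
#'
#' @param counts_path,meta_path community table TSVs.
#' @param pathway_path,subsystem_path optional pathway presence inputs.
#' @param fasta_paths optional character vector of FASTA files to validate.
#' @return invisibly, a list with `ok` (logical) and `errors` (character);
#'   messages are printed as a report.
#' @export
validate_inputs <- function(counts_path, meta_path, pathway_path = NULL,
                            subsystem_path = NULL, fasta_paths = NULL) {
  errors <- character(0)
  try_step <- function(label, expr) {
    res <- tryCatch({ expr; NULL }, error = function(e) conditionMessage(e))
    if (is.null(res)) message(sprintf("OK   %s", label))
    else {
      message(sprintf("FAIL %s: %s", label, res))
      errors <<- c(errors, sprintf("%s: %s", label, res))
    }
  }
  try_step("community table", read_community_table(counts_path, meta_path))
  if (!is.null(pathway_path))
    try_step("pathway presence",
             read_pathway_presence(pathway_path, subsystem_path))
  for (fp in fasta_paths) try_step(paste("fasta", fp), read_fasta(fp))
  invisible(list(ok = length(errors) == 0, errors = errors))
}
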