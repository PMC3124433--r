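#' Read protein sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file into a protein
#' table. Sequences are upper-cased and the header token before the first
#' whitespace becomes the protein identifier. Records with empty sequences
#' are dropped with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `id` (character), `sequence`
#'   (character, upper case), `length` (integer) and `signal_end` (integer,
#'   `NA` unless annotated later), one row per retained record.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 example", "ACDFLLLLLGWSLLV"), fa)
#' read_protein_fasta(fa)
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  # Biostrings tolerates some malformations silently; pre-scan so that a
  # sequence line before any header is reported with its line number.
  head_lines <- readLines(path, n = 1000L, warn = FALSE)
  first_content <- which(nzchar(trimws(head_lines)))[1]
  if (!is.na(first_content) &&
      !startsWith(trimws(head_lines[first_content]), ">")) {
    stop("malformed FASTA: line ", first_content,
         " contains sequence data before any '>' header", call. = FALSE)
  }
  aas <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aas))
  seqs <- toupper(as.character(aas))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    warning("dropping ", sum(empty), " record(s) with empty sequence: ",
            paste(ids[empty], collapse = ", "), call. = FALSE)
    ids <- ids[!empty]
    seqs <- seqs[!empty]
  }
  protein_table(ids, seqs)
}

#' Assemble a protein table
#'
#' Builds the `data.frame` representation of a protein set used throughout
#' the package: one row per protein with its identifier, residue string,
#' length, and an optional 1-based position of the last signal-peptide
#' residue (`signal_end`; the mature sequence is `signal_end + 1 .. length`).
#'
#' @param id Character vector of identifiers.
#' @param sequence Character vector of residue strings (upper case).
#' @param signal_end Optional integer vector; `NA` where no signal peptide is
#'   annotated. Must satisfy `1 <= signal_end < length`.
#' @return A `data.frame` with columns `id`, `sequence`, `length`,
#'   `signal_end`.
#' @export
protein_table <- function(id, sequence, signal_end = NA_integer_) {
  stopifnot(length(id) == length(sequence))
  len <- nchar(sequence)
  if (any(len < 1L)) stop("all sequences must have length >= 1", call. = FALSE)
  signal_end <- as.integer(rep_len(signal_end, length(id)))
  bad <- !is.na(signal_end) & (signal_end < 1L | signal_end >= len)
  if (any(bad)) {
    stop("signal_end must satisfy 1 <= signal_end < length for: ",
         paste(id[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(id = as.character(id), sequence = as.character(sequence),
             length = as.integer(len), signal_end = signal_end,
             stringsAsFactors = FALSE)
}

#' Write a protein table to FASTA
#'
#' @param proteins Protein table from [protein_table()].
#' @param path Output file path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path, width = 60L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$id[i]), con)
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Maximal homopolymer runs of one residue
#'
#' Decomposes a sequence into maximal runs (blocks of identical letters
#' bounded by a different letter or a sequence end) and returns the lengths
#' of the runs of `residue`, in sequence order. A maximal run of length five
#' followed elsewhere by one of length two yields `c(5, 2)`; runs are never
#' subdivided into shorter tracts.
#'
#' @param sequence A residue string.
#' @param residue A single standard amino-acid letter.
#' @return Integer vector of run lengths (possibly empty).
#' @examples
#' find_maximal_runs("ACDFLLLLLGWSLLV", "L")  # 5 2
#' @export
find_maximal_runs <- function(sequence, residue) {
  check_residue(residue)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  r <- rle(strsplit(sequence, "", fixed = TRUE)[[1]])
  as.integer(r$lengths[r$values == residue])
}

# Maximal runs of every letter at once: data.frame(residue, length),
# in sequence order. Internal workhorse for count tables.
find_all_runs <- function(sequence) {
  r <- rle(strsplit(sequence, "", fixed = TRUE)[[1]])
  data.frame(residue = r$values, length = as.integer(r$lengths),
             stringsAsFactors = FALSE)
}

#' Cumulative non-overlapping tract counts
#'
#' Converts maximal-run lengths into the cumulative count function c(n) =
#' number of maximal runs of length at least n. The cumulative construction
#' is what is modelled and reported throughout: "repeat counts" always means
#' these cumulative counts.
#'
#' @param runs Integer vector of maximal-run lengths (e.g. from
#'   [find_maximal_runs()]).
#' @param n_max Largest repeat length to report (`n_max >= 2`).
#' @return Named integer vector `c(n)` for `n = 2 .. n_max`.
#' @examples
#' cumulative_counts(c(5, 2), 6)  # 2 1 1 1 0
#' @export
cumulative_counts <- function(runs, n_max) {
  stopifnot(n_max >= 2)
  n <- 2:n_max
  out <- vapply(n, function(k) sum(runs >= k), integer(1))
  names(out) <- n
  out
}

#' Protein length and composition covariates
#'
#' Computes, for each protein, its length `l` and the relative frequency
#' `f_AA` of each of the 20 standard residues. Ambiguity letters count
#' towards `l` but towards no standard-residue frequency, so the frequencies
#' sum to at most 1 (exactly 1 when no ambiguity letters are present).
#'
#' @param proteins Protein table ([protein_table()]), or a single residue
#'   string.
#' @return A `data.frame` with columns `id`, `l`, and `f_A` .. `f_Y` (one
#'   frequency column per standard residue).
#' @examples
#' composition_and_length(protein_table("p1", "ACDFLLLLLGWSLLV"))$f_L  # 7/15
#' @export
composition_and_length <- function(proteins) {
  if (is.character(proteins)) {
    proteins <- protein_table(sprintf("seq%d", seq_along(proteins)), proteins)
  }
  mat <- residue_count_matrix(proteins$sequence)
  f <- mat / proteins$length
  colnames(f) <- paste0("f_", AA_STANDARD)
  cbind(data.frame(id = proteins$id, l = proteins$length,
                   stringsAsFactors = FALSE),
        as.data.frame(f))
}

# counts of each standard residue per sequence (n_proteins x 20)
residue_count_matrix <- function(sequences) {
  counts <- Biostrings::letterFrequency(Biostrings::AAStringSet(sequences),
                                        letters = AA_STANDARD)
  colnames(counts) <- AA_STANDARD
  counts
}

#' Cumulative repeat-count table for a protein set
#'
#' Records, for every protein, residue and repeat length, the cumulative
#' number of maximal runs of length at least `n`. Residues are modelled
#' independently throughout the package, and this long-format table is the
#' common input of the model-fitting functions.
#'
#' @param proteins Protein table ([protein_table()]).
#' @param residues Residues to tabulate (default: all 20 standard).
#' @param n_range Integer range of repeat lengths (subset of 2..50).
#' @return A `data.frame` with columns `protein_id`, `residue`, `n`, `count`,
#'   carrying the underlying 3-d count array in attribute `count_array`
#'   (dimensions protein x residue x n).
#' @examples
#' p <- protein_table("p1", "ACDFLLLLLGWSLLV")
#' tab <- build_count_table(p, "L", 2:6)
#' subset(tab, n == 5)$count  # 1
#' @export
build_count_table <- function(proteins, residues = AA_STANDARD,
                              n_range = 2:10) {
  stopifnot(all(n_range >= 2), all(n_range <= 50))
  residues <- as.character(residues)
  lapply(residues, check_residue)
  n_range <- sort(as.integer(n_range))
  arr <- count_array(proteins, residues, n_range)
  long <- expand.grid(protein_id = proteins$id, residue = residues,
                      n = n_range, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  long$count <- as.vector(arr)
  attr(long, "count_array") <- arr
  long
}

# 3-d array of cumulative counts: proteins x residues x n
count_array <- function(proteins, residues, n_range) {
  np <- nrow(proteins)
  arr <- array(0L, dim = c(np, length(residues), length(n_range)),
               dimnames = list(proteins$id, residues, n_range))
  nmax <- max(n_range)
  for (i in seq_len(np)) {
    runs <- find_all_runs(proteins$sequence[i])
    runs <- runs[runs$residue %in% residues & runs$length >= min(n_range), ,
                 drop = FALSE]
    if (nrow(runs) == 0L) next
    for (j in seq_along(residues)) {
      rl <- runs$length[runs$residue == residues[j]]
      if (length(rl)) {
        arr[i, j, ] <- vapply(n_range, function(k) sum(rl >= k), integer(1))
      }
    }
  }
  arr
}

#' Write a repeat-count table as TSV
#'
#' @param table Output of [build_count_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  utils::write.table(table[, c("protein_id", "residue", "n", "count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
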