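# Reference genome container: chromosomes concatenated into one string with
# a '$' sentinel after each chromosome. The sentinel sorts below every
# nucleotide so no suffix comparison or seed match can cross a chromosome
# boundary. All user-facing coordinates are 1-based.

SENTINEL <- "$"

new_ref_genome <- function(seqs) {
  if (length(seqs) == 0L) stop("reference contains no sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every reference sequence needs a name")
  lens <- nchar(seqs)
  if (any(lens == 0L)) stop("zero-length reference sequence: ",
                            names(seqs)[which(lens == 0L)[1L]])
  structure(list(
    sequence      = paste0(paste0(seqs, SENTINEL), collapse = ""),
    chrom_names   = names(seqs),
    chrom_offsets = unname(c(0L, cumsum(head(lens + 1L, -1L))) + 1L),
    chrom_lengths = unname(lens)
  ), class = "ref_genome")
}

normalize_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

#' Load a reference genome from a FASTA file
#'
#' Reads a (possibly gzip-compressed) multi-record FASTA file and builds the
#' concatenated reference used by the indexing and mapping functions.
#' Sequences are uppercased and characters outside `A,C,G,T,N` are converted
#' to `N`; a sentinel character separates chromosomes in the concatenation so
#' matches can never span a chromosome boundary.
#'
#' @param fasta_path Path to a FASTA file (plain or gzipped).
#' @return An object of class `ref_genome` with elements `sequence` (the
#'   concatenated string, including sentinels), `chrom_names`,
#'   `chrom_offsets` (1-based start of each chromosome in the concatenation)
#'   and `chrom_lengths`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT", ">chr2", "TTTT"), fa)
#' ref <- load_reference(fa)
#' ref$chrom_offsets  # 1 and 10 (sentinel between chromosomes)
#' @export
load_reference <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  set <- tryCatch(
    Biostrings::readBStringSet(fasta_path),
    error = function(e) stop("malformed FASTA file '", fasta_path, "': ",
                             conditionMessage(e))
  )
  if (length(set) == 0L) stop("FASTA file contains no sequences: ", fasta_path)
  seqs <- normalize_dna(as.character(set))
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(names(seqs))))
    stop("malformed FASTA header (empty sequence name) in ", fasta_path)
  new_ref_genome(seqs)
}

#' Construct a reference genome from in-memory sequences
#'
#' Convenience constructor used by the simulator and in tests: takes a named
#' character vector of chromosome sequences and applies the same
#' normalization as [load_reference()].
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @return A `ref_genome` object.
#' @export
ref_genome <- function(seqs) {
  seqs <- normalize_dna(seqs)
  new_ref_genome(seqs)
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("Reference genome:", length(x$chrom_names), "sequence(s),",
      sum(x$chrom_lengths), "bp total\n")
  n <- min(length(x$chrom_names), 6L)
  for (i in seq_len(n))
    cat(sprintf("  %s  %d bp (offset %d)\n", x$chrom_names[i],
                x$chrom_lengths[i], x$chrom_offsets[i]))
  if (length(x$chrom_names) > n) cat("  ...\n")
  invisible(x)
}

# chromosome index for a 1-based offset into the concatenation
chrom_index_of <- function(genome, offset) {
  findInterval(offset, genome$chrom_offsets)
}

# 1-based [start, end] bounds of the chromosome containing `offset`
chrom_bounds_of <- function(genome, offset) {
  i <- chrom_index_of(genome, offset)
  c(start = genome$chrom_offsets[i],
    end   = genome$chrom_offsets[i] + genome$chrom_lengths[i] - 1L)
}
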