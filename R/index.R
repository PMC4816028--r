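# Suffix-array index with a k-mer prefix lookup table.
#
# The suffix array holds the 1-based start offsets of every suffix of the
# concatenated genome that does not begin at a sentinel, ordered by the
# lexicographic rank of the suffix (sentinel smallest, byte order
# $ < A < C < G < N < T). The prefix table maps every length-k nucleotide
# string occurring at a suffix start to the half-open interval of suffix
# array ranks whose suffixes begin with it; only occurring prefixes are
# stored (a sorted key vector plus dense interval arrays - compressed row
# storage), so memory scales with the genome, not with 4^k.

#' Build the suffix array of a reference genome
#'
#' Sorts all suffixes of the concatenated genome (suffixes starting at
#' sentinel positions are not indexed) and returns their 1-based start
#' offsets in lexicographic order of the suffixes.
#'
#' @param genome A `ref_genome` object.
#' @return Integer vector: a permutation of the indexed offsets, ordered by
#'   suffix rank.
#' @examples
#' ref <- ref_genome(c(chr1 = "AAAA"))
#' build_suffix_array(ref)  # 4 3 2 1: shorter suffixes sort first
#' @export
build_suffix_array <- function(genome) {
  stopifnot(inherits(genome, "ref_genome"))
  cpp_build_sa(genome$sequence) + 1L
}

#' Build the k-mer prefix lookup table
#'
#' For every distinct length-`k` string over `A,C,G,T` that occurs at the
#' start of an indexed suffix, records the half-open interval `[lo, hi)` of
#' suffix-array ranks (1-based `lo`, exclusive `hi`) whose suffixes begin
#' with that string. Suffixes shorter than `k`, or containing `N` within
#' their first `k` bases, receive no entry and are skipped by seed search.
#'
#' @param sa Integer suffix array from [build_suffix_array()].
#' @param genome The `ref_genome` the suffix array was built from.
#' @param k Prefix length in bases (1--26).
#' @return A list of class `prefix_table` with elements `k`, `keys` (sorted
#'   numeric 2-bit encodings of the stored prefixes), `lo` and `hi`
#'   (1-based half-open rank intervals, parallel to `keys`).
#' @export
build_prefix_table <- function(sa, genome, k) {
  stopifnot(inherits(genome, "ref_genome"))
  if (k < 1) stop("prefix length k must be >= 1")
  pt <- cpp_build_ptable(genome$sequence, sa - 1L, as.integer(k))
  structure(list(k = as.integer(k), keys = pt$keys, lo = pt$lo + 1L,
                 hi = pt$hi + 1L),
            class = "prefix_table")
}

#' Build a searchable reference index
#'
#' Convenience wrapper that loads (or accepts) a reference genome, builds
#' its suffix array and prefix table, and bundles them for [sa_search()]
#' and [map_reads()].
#'
#' @param reference A `ref_genome` object or a path to a FASTA file.
#' @param k Prefix-table length in bases; the default 18 is also the default
#'   seed length, so each seed lookup starts with a single table probe.
#' @return A list of class `ref_index` with elements `genome`, `sa`,
#'   `ptable` and `build_params`.
#' @examples
#' idx <- build_index(ref_genome(c(chr1 = "ACGTACGT")), k = 4)
#' sa_search("ACG", idx)  # 1 5
#' @export
build_index <- function(reference, k = 18L) {
  genome <- if (inherits(reference, "ref_genome")) reference
            else load_reference(reference)
  sa <- build_suffix_array(genome)
  ptable <- build_prefix_table(sa, genome, k)
  structure(list(genome = genome, sa = sa, ptable = ptable,
                 build_params = list(k = as.integer(k))),
            class = "ref_index")
}

#' @export
print.ref_index <- function(x, ...) {
  cat("Suffix-array index:", length(x$sa), "suffixes,",
      length(x$ptable$keys), "stored prefixes (k =", x$ptable$k, ")\n")
  print(x$genome)
  invisible(x)
}

#' Exact search of a pattern in the indexed genome
#'
#' Finds every occurrence of `pattern` in the concatenated genome. When the
#' pattern is at least `k` bases long the search first narrows to the
#' prefix-table interval of its first `k` bases and then binary-searches
#' within that interval; shorter patterns fall back to a plain binary search
#' over the whole suffix array. Patterns containing `N` (or any non-ACGT
#' character) return no hits: only nucleotide prefixes are indexed.
#'
#' @param pattern Nucleotide string over `A,C,G,T`.
#' @param index A `ref_index`.
#' @param max_hits If positive, patterns with more than `max_hits`
#'   occurrences return zero hits (repeat masking); `0` disables the cap.
#' @return Integer vector of 1-based offsets into the concatenated genome,
#'   ascending. Occurrences never span a chromosome boundary.
#' @export
sa_search <- function(pattern, index, max_hits = 0L) {
  stopifnot(inherits(index, "ref_index"))
  if (length(pattern) != 1L || is.na(pattern) || nchar(pattern) < 1L)
    stop("pattern must be a single nonempty string")
  hits <- cpp_sa_search(index$genome$sequence, index$sa - 1L,
                        index$ptable$keys, index$ptable$lo - 1L,
                        index$ptable$hi - 1L, index$ptable$k,
                        toupper(pattern), as.integer(max_hits))
  hits + 1L
}

IDX_MAGIC <- "sarmapidx"
IDX_VERSION <- 1L

#' Save a reference index to a file
#'
#' Writes the genome, suffix array and prefix table as a versioned binary
#' file. The format is an internal contract of this package and is
#' byte-stable across runs for identical inputs.
#'
#' @param index A `ref_index`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "ref_index"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(IDX_MAGIC, con, eos = NULL)
  writeBin(IDX_VERSION, con)
  g <- index$genome
  writeBin(length(g$chrom_names), con)
  for (nm in g$chrom_names) {
    writeBin(nchar(nm), con)
    writeChar(nm, con, eos = NULL)
  }
  writeBin(g$chrom_offsets, con)
  writeBin(g$chrom_lengths, con)
  writeBin(nchar(g$sequence), con)
  writeChar(g$sequence, con, eos = NULL)
  writeBin(length(index$sa), con)
  writeBin(index$sa, con)
  writeBin(index$ptable$k, con)
  writeBin(length(index$ptable$keys), con)
  writeBin(index$ptable$keys, con)
  writeBin(index$ptable$lo, con)
  writeBin(index$ptable$hi, con)
  invisible(path)
}

#' Load a reference index written by [save_index()]
#'
#' @param path Path to the index file.
#' @return A `ref_index`.
#' @export
load_index <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchar(IDX_MAGIC), useBytes = TRUE)
  if (!identical(magic, IDX_MAGIC)) stop("not a sarmap index file: ", path)
  version <- readBin(con, "integer")
  if (!identical(version, IDX_VERSION))
    stop("unsupported index version: ", version)
  nchrom <- readBin(con, "integer")
  nms <- character(nchrom)
  for (i in seq_len(nchrom)) {
    nl <- readBin(con, "integer")
    nms[i] <- readChar(con, nl, useBytes = TRUE)
  }
  offs <- readBin(con, "integer", nchrom)
  lens <- readBin(con, "integer", nchrom)
  seqlen <- readBin(con, "integer")
  seq <- readChar(con, seqlen, useBytes = TRUE)
  salen <- readBin(con, "integer")
  sa <- readBin(con, "integer", salen)
  k <- readBin(con, "integer")
  nkeys <- readBin(con, "integer")
  keys <- readBin(con, "numeric", nkeys)
  lo <- readBin(con, "integer", nkeys)
  hi <- readBin(con, "integer", nkeys)
  genome <- structure(list(sequence = seq, chrom_names = nms,
                           chrom_offsets = offs, chrom_lengths = lens),
                      class = "ref_genome")
  structure(list(genome = genome, sa = sa,
                 ptable = structure(list(k = k, keys = keys, lo = lo,
                                         hi = hi), class = "prefix_table"),
                 build_params = list(k = k)),
            class = "ref_index")
}
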