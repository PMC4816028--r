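# Seed generation and exact seed mapping (pipeline step 1).

#' Reverse-complement a DNA string
#'
#' @param x Character vector of nucleotide strings; characters outside
#'   `A,C,G,T` reverse-complement to `N`.
#' @return Character vector of the same length.
#' @export
reverse_complement <- function(x) {
  vapply(x, cpp_revcomp, character(1), USE.NAMES = FALSE)
}

#' Generate uniformly distributed seeds along a read
#'
#' Seeds of length `seed_length` start at positions
#' `round(i * (L - s) / (n - 1)) + 1` for `i = 0, ..., n - 1` (1-based;
#' `L` read length, `s` seed length, `n` number of seeds; rounding is
#' round-half-to-even), with duplicate starts removed. The first seed always
#' starts at base 1 and, for `n >= 2`, the last seed ends at the last base.
#' A read shorter than `seed_length` yields a single seed covering the whole
#' read.
#'
#' @param read_length Read length in bases.
#' @param seed_length Seed length in bases (default 18, the prefix-table
#'   length, so each seed lookup is one table probe).
#' @param num_seeds Number of seeds; `NULL` selects
#'   `max(5, floor(read_length / seed_length))`.
#' @return A data frame with columns `start` (1-based) and `length`.
#' @examples
#' generate_seeds(100, 18, 5)$start  # 1 21 42 63 83
#' @export
generate_seeds <- function(read_length, seed_length = 18L, num_seeds = NULL) {
  if (read_length < 1L) stop("read_length must be >= 1")
  if (seed_length < 1L) stop("seed_length must be >= 1")
  if (is.null(num_seeds))
    num_seeds <- max(5L, read_length %/% seed_length)
  if (num_seeds < 1L) stop("num_seeds must be >= 1")
  m <- cpp_generate_seeds(as.integer(read_length), as.integer(seed_length),
                          as.integer(num_seeds))
  data.frame(start = m[, 1] + 1L, length = m[, 2])
}

#' Locate exact seed occurrences of a read in the index
#'
#' Generates seeds for the read, searches each seed substring exactly on
#' the forward strand, and searches the corresponding seeds of the
#' reverse-complemented read for reverse-strand hits. Seeds containing `N`
#' and seeds with more than `max_hits_per_seed` occurrences (repeats)
#' contribute no hits. For reverse-strand hits, `read_offset` refers to the
#' reverse-complemented (strand-oriented) read.
#'
#' @param read_seq Read sequence (a single string).
#' @param index A `ref_index`.
#' @param seed_length,num_seeds Seed layout, as in [generate_seeds()].
#' @param max_hits_per_seed Repeat cap per seed (default 100).
#' @return A data frame with one row per hit: `read_offset` (1-based start
#'   within the strand-oriented read), `length`, `genome_offset` (1-based
#'   offset in the concatenated genome), `strand` (`"+"` or `"-"`) and
#'   `chrom`.
#' @export
map_seeds <- function(read_seq, index, seed_length = 18L, num_seeds = NULL,
                      max_hits_per_seed = 100L) {
  stopifnot(inherits(index, "ref_index"))
  read_seq <- toupper(read_seq)
  L <- nchar(read_seq)
  seeds <- generate_seeds(L, seed_length, num_seeds)
  oriented <- c("+" = read_seq, "-" = cpp_revcomp(read_seq))
  out <- list()
  for (strand in c("+", "-")) {
    oseq <- oriented[[strand]]
    for (i in seq_len(nrow(seeds))) {
      pat <- substr(oseq, seeds$start[i], seeds$start[i] + seeds$length[i] - 1L)
      if (grepl("[^ACGT]", pat)) next
      hits <- sa_search(pat, index, max_hits = max_hits_per_seed)
      if (length(hits) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        read_offset = seeds$start[i], length = seeds$length[i],
        genome_offset = hits, strand = strand,
        chrom = index$genome$chrom_names[chrom_index_of(index$genome, hits)]
      )
    }
  }
  if (length(out) == 0L)
    return(data.frame(read_offset = integer(), length = integer(),
                      genome_offset = integer(), strand = character(),
                      chrom = character()))
  do.call(rbind, out)
}
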