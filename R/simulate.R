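# Synthetic genomes and dwgsim-style single-end reads with ground truth
# encoded in the read names, plus the helpers shared with the evaluator.

BASES <- c("A", "C", "G", "T")

#' Generate a uniform-composition synthetic genome
#'
#' Draws `length` i.i.d. uniform bases over `A,C,G,T` and splits them into
#' `n_chroms` chromosomes of (near-)equal size. Deterministic for a given
#' `seed`. A uniform synthetic genome is far less repetitive than a real
#' mammalian genome, so mapping accuracy measured on it upper-bounds, and
#' does not reproduce, accuracy on real references.
#'
#' @param length Total genome length in bases (>= 1000).
#' @param n_chroms Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param out Optional FASTA path; when given, the genome is also written
#'   (70-column wrapped).
#' @return A `ref_genome` object, invisibly when `out` is given.
#' @export
simulate_genome <- function(length, n_chroms = 1L, seed = NULL, out = NULL) {
  if (length < 1000L) stop("genome length must be >= 1000")
  if (n_chroms < 1L || n_chroms > length)
    stop("n_chroms must be between 1 and the genome length")
  if (!is.null(seed)) set.seed(seed)
  per <- diff(floor(seq(0, length, length.out = n_chroms + 1L)))
  seqs <- vapply(per, function(n)
    paste0(sample(BASES, n, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- paste0("chr", seq_len(n_chroms))
  g <- ref_genome(seqs)
  if (!is.null(out)) {
    write_fasta(seqs, out)
    return(invisible(g))
  }
  g
}

write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    n <- nchar(seqs[i])
    starts <- seq(1L, n, by = width)
    writeLines(substring(seqs[i], starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read-simulation parameters
#'
#' Defaults mirror the dwgsim "Illumina" protocol used for benchmark
#' datasets: per-base mutation rate `-r`, fraction of mutations that are
#' indels `-R`, indel extension probability `-X` (geometric run lengths),
#' per-base sequencer error rate `-e`, and the maximum number of `N` bases
#' per read `-n`.
#'
#' @param mut_rate Per-base mutation probability (default 0.001; the
#'   higher-noise benchmark setting is 0.01).
#' @param indel_frac Fraction of mutations that are indels (default 0.1).
#' @param indel_ext Probability an indel run extends by one more base
#'   (default 0.30); indel lengths are geometric with mean
#'   `1 / (1 - indel_ext)`.
#' @param err_rate Per-base sequencer error probability (default 0.020);
#'   errors are substitutions recorded in the quality string.
#' @param max_n Maximum `N` bases per read (default 2); reads exceeding it
#'   are redrawn.
#' @param read_len Read length in bases.
#' @param n_reads Number of reads.
#' @param seed RNG seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(mut_rate = 0.001, indel_frac = 0.1, indel_ext = 0.30,
                       err_rate = 0.020, max_n = 2L, read_len = 100L,
                       n_reads = 10000L, seed = NULL) {
  probs <- c(mut_rate, indel_frac, indel_ext, err_rate)
  if (any(probs < 0) || any(probs > 1))
    stop("all rates must be probabilities in [0, 1]")
  if (indel_ext >= 1) stop("indel_ext must be < 1")
  if (read_len < 1L || n_reads < 0L) stop("invalid read_len or n_reads")
  structure(list(mut_rate = mut_rate, indel_frac = indel_frac,
                 indel_ext = indel_ext, err_rate = err_rate,
                 max_n = as.integer(max_n), read_len = as.integer(read_len),
                 n_reads = as.integer(n_reads), seed = seed),
            class = "sim_params")
}

# random base different from `b` ('N' can substitute to any base)
other_base <- function(b) {
  choices <- setdiff(BASES, b)
  choices[sample.int(length(choices), 1L)]
}

# indel run lengths: geometric with continuation probability indel_ext,
# mean 1 / (1 - indel_ext)
sim_indel_len <- function(n, indel_ext) {
  1L + stats::rgeom(n, 1 - indel_ext)
}

QUAL_OK <- "I"   # Q40
QUAL_ERR <- "+"  # Q10 at simulated sequencer-error positions

# Apply the mutation walk to a fragment (character vector of ref bases)
# and return read_len bases plus the number of reference bases consumed,
# or NULL when the fragment is exhausted (pathologically long deletions).
mutate_fragment <- function(frag, read_len, p) {
  is_mut <- runif(read_len) < p$mut_rate
  if (!any(is_mut)) {
    if (read_len > length(frag)) return(NULL)
    return(list(bases = frag[seq_len(read_len)], consumed = read_len))
  }
  out <- character(read_len)
  ri <- 1L  # next fragment base
  oi <- 1L  # next output base
  while (oi <= read_len) {
    if (ri > length(frag)) return(NULL)
    if (!is_mut[oi]) {
      out[oi] <- frag[ri]
      ri <- ri + 1L
      oi <- oi + 1L
      next
    }
    if (runif(1) < p$indel_frac) {
      l <- sim_indel_len(1L, p$indel_ext)
      if (runif(1) < 0.5) {
        # insertion of l random bases at this output position
        ins <- sample(BASES, l, replace = TRUE)
        take <- min(l, read_len - oi + 1L)
        out[oi:(oi + take - 1L)] <- ins[seq_len(take)]
        oi <- oi + take
      } else {
        # deletion: skip l reference bases, then emit the next one
        ri <- ri + l
        if (ri > length(frag)) return(NULL)
        out[oi] <- frag[ri]
        ri <- ri + 1L
        oi <- oi + 1L
      }
    } else {
      out[oi] <- other_base(frag[ri])
      ri <- ri + 1L
      oi <- oi + 1L
    }
  }
  list(bases = out, consumed = ri - 1L)
}

encode_truth_name <- function(chrom, start, strand, serial) {
  sprintf("rd_%s_%d_%s_%06d", chrom, start, strand, serial)
}

#' Parse ground-truth origins from simulated read names
#'
#' Read names follow the grammar
#' `rd_<chrom>_<true_start>_<strand>_<serial>` (underscores inside
#' chromosome names are allowed; fields are parsed from the right).
#'
#' @param read_ids Character vector of read names.
#' @return Data frame with `read_id`, `chrom`, `strand`, `true_start`.
#' @export
parse_truth_names <- function(read_ids) {
  m <- regmatches(read_ids,
                  regexec("^rd_(.+)_([0-9]+)_([+-])_([0-9]+)$", read_ids))
  bad <- which(vapply(m, length, integer(1)) != 5L)
  if (length(bad))
    stop("read name does not encode a ground truth: ", read_ids[bad[1L]])
  data.frame(read_id = read_ids,
             chrom = vapply(m, `[[`, character(1), 2),
             strand = vapply(m, `[[`, character(1), 4),
             true_start = as.integer(vapply(m, `[[`, character(1), 3)))
}

#' Simulate dwgsim-style single-end reads with ground truth
#'
#' Each read is drawn from a uniform position and strand. Walking the
#' reference from that position, each output base mutates with probability
#' `mut_rate`: with probability `indel_frac` the mutation is an indel
#' (insertion or deletion equiprobable, geometric length with continuation
#' `indel_ext`), otherwise a substitution to a different base. Sequencer
#' errors are then applied at `err_rate` per base (substitutions, marked by
#' a low quality value in the quality string). Reads with more than `max_n`
#' `N` bases are redrawn. The true origin (chromosome, leftmost reference
#' base consumed, strand) is encoded in the read name; reverse-strand reads
#' are reverse-complemented after the walk.
#'
#' @param genome A `ref_genome` (or path to a FASTA file).
#' @param params A [sim_params()] object.
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>.fastq` and `<prefix>.truth.tsv`.
#' @return A list with `reads` (data frame `id`, `seq`, `qual`) and `truth`
#'   (data frame `read_id`, `chrom`, `strand`, `true_start`).
#' @export
simulate_reads <- function(genome, params = sim_params(),
                           out_prefix = NULL) {
  if (!inherits(genome, "ref_genome")) genome <- load_reference(genome)
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  # fragment buffer absorbs deletions; positions are drawn so the buffer
  # never runs past the chromosome end (documented edge-of-chromosome bias)
  buffer <- 100L
  eligible <- genome$chrom_lengths - p$read_len - buffer + 1L
  if (all(eligible < 1L))
    stop("read_len too large for every chromosome")
  ok_chrom <- which(eligible >= 1L)
  w <- eligible[ok_chrom] / sum(eligible[ok_chrom])
  chrom_seqs <- substring(genome$sequence, genome$chrom_offsets,
                          genome$chrom_offsets + genome$chrom_lengths - 1L)
  n <- p$n_reads
  ids <- seqs <- quals <- chroms <- strands <- character(n)
  starts <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      ci <- ok_chrom[sample.int(length(ok_chrom), 1L, prob = w)]
      s <- sample.int(eligible[ci], 1L)
      strand <- if (runif(1) < 0.5) "+" else "-"
      frag <- strsplit(substr(chrom_seqs[ci], s, s + p$read_len + buffer
                              - 1L), "")[[1]]
      mt <- mutate_fragment(frag, p$read_len, p)
      if (is.null(mt)) next
      bases <- mt$bases
      if (strand == "-") {
        bases <- rev(bases)
        bases <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[bases]
      }
      err <- runif(p$read_len) < p$err_rate
      if (any(err))
        bases[err] <- vapply(bases[err], other_base, character(1),
                             USE.NAMES = FALSE)
      if (sum(bases == "N") > p$max_n) next
      qual <- rep(QUAL_OK, p$read_len)
      qual[err] <- QUAL_ERR
      ids[i] <- encode_truth_name(genome$chrom_names[ci], s, strand, i)
      seqs[i] <- paste0(bases, collapse = "")
      quals[i] <- paste0(qual, collapse = "")
      chroms[i] <- genome$chrom_names[ci]
      strands[i] <- strand
      starts[i] <- s
      break
    }
  }
  reads <- data.frame(id = ids, seq = seqs, qual = quals)
  truth <- data.frame(read_id = ids, chrom = chroms, strand = strands,
                      true_start = starts)
  if (!is.null(out_prefix)) {
    fq <- paste0(out_prefix, ".fastq")
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
               fq)
    utils::write.table(truth, paste0(out_prefix, ".truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(reads = reads, truth = truth)
}
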