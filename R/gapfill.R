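# Smith-Waterman gap completion, CAL scoring and mapping finalization
# (pipeline step 3).

#' Alignment scoring scheme
#'
#' Match reward and mismatch/gap penalties used by [smith_waterman()] and
#' [fill_gaps()]. Penalties are magnitudes applied negatively; a gap run of
#' length `l` costs `gap_open + l * gap_extend`.
#'
#' @param match Score per identical base pair (> 0). Default 5.
#' @param mismatch Penalty per mismatching pair (>= 0). Default 4.
#' @param gap_open Penalty for opening an insertion/deletion run. Default 10.
#' @param gap_extend Penalty per gapped base. Default 0.5.
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 5, mismatch = 4, gap_open = 10,
                           gap_extend = 0.5) {
  if (match <= 0) stop("match score must be positive")
  if (mismatch < 0 || gap_open < 0 || gap_extend < 0)
    stop("penalties must be >= 0 (they are applied negatively)")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Affine-gap Smith-Waterman local alignment
#'
#' Local alignment of `query` against `target` maximizing the affine-gap
#' score. `N` never matches (it scores as a mismatch). Traceback ties are
#' broken deterministically: diagonal first, then deletion, then insertion,
#' starting from the rightmost maximal cell.
#'
#' @param query,target Nonempty nucleotide strings.
#' @param scheme A [scoring_scheme()].
#' @return A list with `score`, `cigar` (over `M`, `I`, `D`, for the aligned
#'   region only), and the 1-based inclusive aligned spans `query_start`,
#'   `query_end`, `target_start`, `target_end` (zero-width when the best
#'   local score is 0, i.e. no positive-scoring alignment exists).
#' @export
smith_waterman <- function(query, target, scheme = scoring_scheme()) {
  if (length(query) != 1L || is.na(query) || nchar(query) < 1L ||
      length(target) != 1L || is.na(target) || nchar(target) < 1L)
    stop("query and target must be nonempty strings")
  r <- cpp_align(toupper(query), toupper(target), 0L, scheme$match,
                 scheme$mismatch, scheme$gap_open, scheme$gap_extend)
  list(score = r$score, cigar = r$cigar,
       query_start = r$query_begin + 1L, query_end = r$query_end,
       target_start = r$target_begin + 1L, target_end = r$target_end)
}

#' Complete a CAL into a full read alignment
#'
#' Member extended seeds become match/mismatch runs (anchors); each
#' unaligned gap between consecutive anchors is aligned with the affine-gap
#' dynamic program; read ends that the local end-extension does not align
#' become soft clips. The CAL score is
#' `match * matches - mismatch * mismatches - gap_open * gap_runs -
#' gap_extend * gapped_bases` over the final alignment.
#'
#' @param cal A CAL from [cluster_extensions()] (at least one member).
#' @param read A list with `id`, `seq` and `qual` (original, forward
#'   orientation).
#' @param genome A `ref_genome`.
#' @param scheme A [scoring_scheme()].
#' @return A list of class `alignment`: `read_id`, `chrom`, `position`
#'   (1-based leftmost mapped base on the chromosome), `strand`, `cigar`
#'   (over `M,I,D,S`), `score`, `mapq` (`NA` until [finalize_read()]),
#'   `aligned_read_fraction`, `nm`, `seq`, `qual`; or `NULL` when no
#'   positive-scoring alignment exists for this CAL.
#' @export
fill_gaps <- function(cal, read, genome, scheme = scoring_scheme()) {
  stopifnot(inherits(genome, "ref_genome"))
  if (is.null(cal$members) || nrow(cal$members) == 0L)
    stop("CAL has no member extensions")
  oriented <- if (cal$strand == "-") cpp_revcomp(toupper(read$seq))
              else toupper(read$seq)
  mem <- cbind(cal$members$read_start - 1L, cal$members$read_end,
               cal$members$genome_start - 1L, cal$members$genome_end)
  storage.mode(mem) <- "integer"
  ci <- match(cal$chrom, genome$chrom_names)
  cstart <- genome$chrom_offsets[ci]
  r <- cpp_fill_cal(genome$sequence, oriented, mem,
                    as.integer(cstart - 1L),
                    as.integer(cstart - 1L + genome$chrom_lengths[ci]),
                    scheme$match, scheme$mismatch, scheme$gap_open,
                    scheme$gap_extend)
  if (!r$ok) return(NULL)
  structure(list(read_id = read$id, chrom = cal$chrom,
                 # r$pos is 0-based in the concatenation; make it 1-based
                 # local to the chromosome
                 position = r$pos + 1L - (cstart - 1L),
                 strand = cal$strand, cigar = r$cigar, score = r$score,
                 mapq = NA_integer_,
                 aligned_read_fraction = r$aligned_fraction, nm = r$nm,
                 seq = read$seq, qual = read$qual),
            class = "alignment")
}

#' Choose the reported mapping for a read
#'
#' The highest-scoring alignment wins (ties: chromosome order, then
#' coordinate, then forward strand). Mapping quality is
#' `min(60, round((best - second_best) / best * 60))`, 60 for a unique
#' candidate and 0 when the two best scores are equal (or the best score is
#' not positive).
#'
#' @param alignments List of `alignment` objects for one read (scored CALs).
#' @param read A list with `id`, `seq`, `qual`.
#' @return The winning `alignment` with `mapq` filled in, or an unmapped
#'   record (list with `read_id`, `mapped = FALSE`, `seq`, `qual`) when
#'   `alignments` is empty.
#' @export
finalize_read <- function(alignments, read) {
  alignments <- Filter(Negate(is.null), alignments)
  if (length(alignments) == 0L)
    return(structure(list(read_id = read$id, mapped = FALSE,
                          seq = read$seq, qual = read$qual),
                     class = "alignment"))
  scores <- vapply(alignments, `[[`, numeric(1), "score")
  chrom <- vapply(alignments, `[[`, character(1), "chrom")
  pos <- vapply(alignments, `[[`, numeric(1), "position")
  st <- vapply(alignments, function(a) a$strand == "-", logical(1))
  ord <- order(-scores, match(chrom, unique(sort(chrom))), pos, st)
  best <- alignments[[ord[1L]]]
  best$mapped <- TRUE
  if (length(alignments) == 1L) {
    best$mapq <- 60L
  } else {
    s1 <- scores[ord[1L]]
    s2 <- max(scores[ord[-1L]])
    best$mapq <- if (s1 <= 0 || s2 >= s1) 0L
                 else min(60L, as.integer(round((s1 - max(s2, 0)) / s1 * 60)))
  }
  best
}

#' Default mapping parameters
#'
#' Length-scaled defaults used by [map_reads()]: seed length equals the
#' prefix-table length so every seed search begins with one table lookup;
#' the number of seeds is `max(5, floor(L / seed_length))`; the mismatch
#' budget for extension is `ceiling(0.04 * L)`; CALs may span up to
#' `2 * L` between members and must cover at least `0.25 * L` of genome.
#'
#' @param seed_length Seed length in bases (default: index prefix length).
#' @param num_seeds Seeds per read; `NULL` scales with read length.
#' @param max_hits_per_seed Repeat cap per seed.
#' @param max_mismatches Extension budget; `NULL` scales with read length.
#' @param max_gap Cluster distance/diagonal tolerance; `NULL` = `2 * L`.
#' @param min_cal_length Minimum CAL envelope; `NULL` = `0.25 * L`.
#' @param max_cals CALs kept per read for gap filling.
#' @param scheme A [scoring_scheme()].
#' @return A list of class `mapping_params`.
#' @export
mapping_params <- function(seed_length = NULL, num_seeds = NULL,
                           max_hits_per_seed = 100L, max_mismatches = NULL,
                           max_gap = NULL, min_cal_length = NULL,
                           max_cals = 5L, scheme = scoring_scheme()) {
  structure(list(seed_length = seed_length, num_seeds = num_seeds,
                 max_hits_per_seed = as.integer(max_hits_per_seed),
                 max_mismatches = max_mismatches, max_gap = max_gap,
                 min_cal_length = min_cal_length,
                 max_cals = as.integer(max_cals), scheme = scheme),
            class = "mapping_params")
}

map_batch_df <- function(reads, index, params) {
  p <- params
  seed_length <- if (is.null(p$seed_length)) index$ptable$k
                 else as.integer(p$seed_length)
  res <- cpp_map_batch(
    index$genome$sequence, index$genome$chrom_offsets - 1L,
    index$genome$chrom_lengths, index$sa - 1L, index$ptable$keys,
    index$ptable$lo - 1L, index$ptable$hi - 1L, index$ptable$k,
    reads$seq, seed_length,
    if (is.null(p$num_seeds)) 0L else as.integer(p$num_seeds),
    p$max_hits_per_seed,
    if (is.null(p$max_mismatches)) -1L else as.integer(p$max_mismatches),
    0.04,
    if (is.null(p$max_gap)) 0L else as.integer(p$max_gap), 2.0,
    if (is.null(p$min_cal_length)) -1L else as.integer(p$min_cal_length),
    0.25,
    p$max_cals, p$scheme$match, p$scheme$mismatch, p$scheme$gap_open,
    p$scheme$gap_extend)
  data.frame(
    qname = reads$id,
    mapped = res$mapped,
    chrom = ifelse(res$mapped, index$genome$chrom_names[res$chrom], NA),
    pos = res$pos,
    strand = ifelse(res$mapped, ifelse(res$strand == 1L, "-", "+"), NA),
    mapq = res$mapq,
    cigar = res$cigar,
    score = res$score,
    aligned_frac = res$aligned_frac,
    nm = res$nm,
    n_cals = res$n_cals,
    seq = reads$seq,
    qual = reads$qual
  )
}

#' Map a set of reads against a reference index
#'
#' Runs the full pipeline (seeding, extension, CAL clustering and selection,
#' gap completion, finalization) over fixed-size batches of reads. Output
#' order equals input order and results are identical for any `workers` or
#' `batch_size` value: batching and parallelism are transparent.
#'
#' @param reads Data frame with columns `id`, `seq`, `qual` (e.g. from
#'   [read_fastq()] or [simulate_reads()]).
#' @param index A `ref_index`.
#' @param params A [mapping_params()] object.
#' @param workers Number of worker processes for batch processing (forked;
#'   falls back to serial where fork is unavailable).
#' @param batch_size Reads per batch.
#' @return A data frame with one row per read, in input order: `qname`,
#'   `mapped`, `chrom`, `pos` (1-based), `strand`, `mapq`, `cigar`, `score`,
#'   `aligned_frac`, `nm`, `n_cals`, `seq`, `qual`.
#' @export
map_reads <- function(reads, index, params = mapping_params(), workers = 1L,
                      batch_size = 256L) {
  stopifnot(inherits(index, "ref_index"))
  if (workers < 1L) stop("workers must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  n <- nrow(reads)
  if (n == 0L)
    return(map_batch_df(data.frame(id = character(), seq = character(),
                                   qual = character()), index, params))
  reads$seq <- toupper(reads$seq)
  idx <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  run_one <- function(ii) map_batch_df(reads[ii, , drop = FALSE], index,
                                       params)
  batches <-
    if (workers > 1L && .Platform$OS.type == "unix") {
      parallel::mclapply(idx, run_one, mc.cores = workers,
                         mc.preschedule = TRUE)
    } else {
      lapply(idx, run_one)
    }
  out <- do.call(rbind, batches)
  rownames(out) <- NULL
  out
}
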