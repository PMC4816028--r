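# Seed extension under a mismatch budget and clustering of extensions into
# candidate alignment locations (pipeline step 2).

#' Extend a seed hit bidirectionally under a mismatch budget
#'
#' Greedy, gap-free, symmetric extension: starting from the exact seed
#' match, alternately attempt to take one base leftward then one base
#' rightward (left first, exhausted directions skipped). A compared base
#' pair that differs, or involves `N`, counts as a mismatch against a budget
#' shared by both directions; a direction stops when accepting its next base
#' would exceed `max_mismatches`, or at a read or chromosome boundary.
#' Mismatching bases accepted within budget remain inside the returned span.
#'
#' @param hit A list or one-row data frame with `read_offset`, `length` and
#'   `genome_offset` (all 1-based; `read_offset` in the strand-oriented
#'   read).
#' @param read_seq The strand-oriented read sequence.
#' @param genome A `ref_genome`.
#' @param max_mismatches Mismatch budget (>= 0).
#' @return A list of class `extended_seed`: `read_start`, `read_end`,
#'   `genome_start`, `genome_end` (1-based inclusive) and `mismatches`.
#'   Read and genome spans always have equal width (the extension is
#'   gap-free).
#' @export
extend_seed <- function(hit, read_seq, genome, max_mismatches) {
  stopifnot(inherits(genome, "ref_genome"))
  if (max_mismatches < 0) stop("max_mismatches must be >= 0")
  b <- chrom_bounds_of(genome, hit$genome_offset)
  v <- cpp_extend_seed(genome$sequence, toupper(read_seq),
                       as.integer(hit$read_offset - 1L),
                       as.integer(hit$length),
                       as.integer(hit$genome_offset - 1L),
                       as.integer(b["start"] - 1L),
                       as.integer(b["end"]),   # half-open end, 0-based
                       as.integer(max_mismatches))
  structure(list(read_start = v[1] + 1L, read_end = v[2],
                 genome_start = v[3] + 1L, genome_end = v[4],
                 strand = if (is.null(hit$strand)) "+" else hit$strand,
                 mismatches = v[5]),
            class = "extended_seed")
}

# extensions data frame used across the clustering functions: columns
# read_start, read_end, genome_start, genome_end (1-based inclusive),
# strand ("+"/"-"), mismatches
as_extension_df <- function(extensions) {
  if (is.data.frame(extensions)) return(extensions)
  do.call(rbind, lapply(extensions, function(e)
    data.frame(read_start = e$read_start, read_end = e$read_end,
               genome_start = e$genome_start, genome_end = e$genome_end,
               strand = e$strand, mismatches = e$mismatches)))
}

#' Cluster extended seeds into candidate alignment locations
#'
#' Extensions are grouped per (chromosome, strand); within a group they are
#' ordered by genomic start, and two consecutive extensions share a CAL when
#' the genomic distance between them is at most `max_gap` and their
#' diagonals (genomic start minus read start) differ by at most `max_gap`.
#' CALs whose genomic envelope is shorter than `min_cal_length` are
#' discarded. Overlapping member spans are retained; [fill_gaps()] resolves
#' them.
#'
#' @param extensions A data frame (or list of `extended_seed`) with columns
#'   `read_start`, `read_end`, `genome_start`, `genome_end`, `strand`,
#'   `mismatches`, all from one read.
#' @param genome A `ref_genome`.
#' @param max_gap Maximum genomic distance (and diagonal difference)
#'   between consecutive members, in bases.
#' @param min_cal_length Minimum CAL envelope length in bases.
#' @return A list of CALs; each is a list with `chrom`, `strand`,
#'   `genome_start`, `genome_end` (1-based inclusive envelope), `members`
#'   (data frame of member extensions), `read_coverage` (read bases covered
#'   by the union of member read spans) and `mismatches` (member total).
#' @export
cluster_extensions <- function(extensions, genome, max_gap, min_cal_length) {
  stopifnot(inherits(genome, "ref_genome"))
  ext <- as_extension_df(extensions)
  if (is.null(ext) || nrow(ext) == 0L) return(list())
  m <- cbind(ext$read_start - 1L, ext$read_end, ext$genome_start - 1L,
             ext$genome_end, ext$mismatches,
             ifelse(ext$strand == "-", 1L, 0L))
  storage.mode(m) <- "integer"
  res <- cpp_cluster_extensions(
    m, genome$chrom_offsets - 1L,
    genome$chrom_offsets - 1L + genome$chrom_lengths,
    as.integer(max_gap), as.integer(min_cal_length))
  lapply(seq_along(res$chrom), function(i) {
    structure(list(
      chrom = genome$chrom_names[res$chrom[i] + 1L],
      strand = if (res$strand[i] == 1L) "-" else "+",
      genome_start = res$genome_start[i] + 1L,
      genome_end = res$genome_end[i],
      members = ext[res$members[[i]], , drop = FALSE],
      read_coverage = res$coverage[i],
      mismatches = res$mismatches[i],
      score = NA_real_
    ), class = "cal")
  })
}

#' Select the best candidate alignment locations
#'
#' Ranks CALs by read coverage (descending), breaking ties by fewer total
#' member mismatches, then leftmost genomic coordinate, then forward strand,
#' and keeps the top `max_cals`.
#'
#' @param cals List of CALs from [cluster_extensions()].
#' @param max_cals Number of CALs to retain.
#' @return The selected CALs in rank order.
#' @export
select_cals <- function(cals, max_cals = 5L) {
  if (length(cals) == 0L) return(list())
  cov <- vapply(cals, `[[`, numeric(1), "read_coverage")
  mm <- vapply(cals, `[[`, numeric(1), "mismatches")
  gs <- vapply(cals, `[[`, numeric(1), "genome_start")
  st <- vapply(cals, function(c) if (c$strand == "-") 1L else 0L, integer(1))
  ord <- order(-cov, mm, gs, st)
  cals[ord[seq_len(min(max_cals, length(ord)))]]
}
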