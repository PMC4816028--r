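# FASTQ input (plain or gzip, several files per run) and SAM/BAM output.

read_fastq_one <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)  # file() decompresses gzip transparently
  # trailing blank lines are tolerated; blank lines elsewhere are not
  while (length(lines) > 0L && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record in '", path, "': ", length(lines),
         " lines (not a multiple of 4)")
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(id = character(), seq = character(),
                      qual = character()))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("malformed FASTQ header in '", path, "' at record ", bad[1L])
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ separator line in '", path, "' at record ",
         bad[1L])
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("sequence/quality length mismatch in '", path, "' at record ",
         bad[1L])
  bad <- which(nchar(seqs) == 0L)
  if (length(bad))
    stop("empty sequence in '", path, "' at record ", bad[1L])
  data.frame(id = sub("\\s.*$", "", substring(hdr, 2L)),
             seq = toupper(seqs), qual = quals)
}

#' Read one or more FASTQ files
#'
#' Files may be plain or gzip-compressed and are processed in the order
#' given, with records concatenated; downstream, the mappings of all input
#' files end up in a single output file. Records are validated (header and
#' separator markers, matching sequence/quality lengths) with file and
#' record context on failure.
#'
#' @param paths Character vector of FASTQ paths.
#' @return A data frame with columns `id`, `seq`, `qual`, one row per read,
#'   in file order.
#' @export
read_fastq <- function(paths) {
  out <- do.call(rbind, lapply(paths, read_fastq_one))
  rownames(out) <- NULL
  out
}

cigar_lengths <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDS]", cigar))[[1]]
  if (length(ops) == 0L) return(c(read = 0L, ref = 0L, m = 0L))
  len <- as.integer(sub("[MIDS]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  c(read = sum(len[op %in% c("M", "I", "S")]),
    ref  = sum(len[op %in% c("M", "D")]),
    m    = sum(len[op == "M"]))
}

sam_header <- function(genome, extra = NULL) {
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", genome$chrom_names, genome$chrom_lengths),
    sprintf("@PG\tID:sarmap\tPN:sarmap\tVN:%s",
            as.character(utils::packageVersion("sarmap"))),
    extra)
}

sam_records <- function(alignments, genome) {
  a <- alignments
  n <- nrow(a)
  if (n == 0L) return(character())
  # write-time conservation checks on every mapped record
  mapped <- which(a$mapped)
  if (length(mapped)) {
    for (i in mapped) {
      cl <- cigar_lengths(a$cigar[i])
      if (cl["read"] != nchar(a$seq[i]))
        stop("CIGAR/read length mismatch for ", a$qname[i], ": ",
             a$cigar[i], " vs ", nchar(a$seq[i]), " bases")
      ci <- match(a$chrom[i], genome$chrom_names)
      if (is.na(ci) || a$pos[i] < 1L ||
          a$pos[i] + cl["ref"] - 1L > genome$chrom_lengths[ci])
        stop("alignment outside chromosome bounds for ", a$qname[i])
    }
  }
  flag <- ifelse(a$mapped, ifelse(a$strand == "-", 16L, 0L), 4L)
  seq <- ifelse(a$mapped & a$strand == "-",
                reverse_complement(a$seq), a$seq)
  qual <- ifelse(a$mapped & a$strand == "-",
                 vapply(a$qual, function(q)
                   intToUtf8(rev(utf8ToInt(q))), character(1),
                   USE.NAMES = FALSE),
                 a$qual)
  tags <- ifelse(a$mapped,
                 sprintf("AS:i:%d\tNM:i:%d", as.integer(round(a$score)),
                         a$nm),
                 "")
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                 a$qname, flag,
                 ifelse(a$mapped, a$chrom, "*"),
                 ifelse(a$mapped, a$pos, 0L),
                 ifelse(a$mapped, a$mapq, 0L),
                 ifelse(a$mapped, a$cigar, "*"),
                 seq, qual,
                 ifelse(nzchar(tags), paste0("\t", tags), ""))
  rec
}

#' Write alignments as SAM (optionally BAM)
#'
#' Emits a valid SAM file with `@HD` and `@SQ` header lines derived from the
#' genome; every read appears exactly once, mapped or unmapped.
#' Reverse-strand records store the reverse-complemented sequence and
#' reversed qualities; the `AS` tag carries the CAL score (rounded to
#' integer) and `NM` the edit distance. CIGAR read/reference-length
#' conservation is re-checked for every record at write time.
#'
#' @param alignments Data frame from [map_reads()].
#' @param genome A `ref_genome`.
#' @param out Output SAM path.
#' @param emit_bam If `TRUE`, additionally convert to BAM next to `out`
#'   (requires the Rsamtools package).
#' @return The path of the file written (BAM path when `emit_bam`),
#'   invisibly.
#' @export
write_sam <- function(alignments, genome, out, emit_bam = FALSE) {
  stopifnot(inherits(genome, "ref_genome"))
  lines <- c(sam_header(genome), sam_records(alignments, genome))
  writeLines(lines, out)
  if (emit_bam) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("BAM output requires the Rsamtools package")
    bam <- Rsamtools::asBam(out,
                            destination = sub("\\.sam$", "", out),
                            overwrite = TRUE, indexDestination = FALSE)
    return(invisible(bam))
  }
  invisible(out)
}

# minimal SAM reader used by the evaluator and in round-trip tests:
# returns qname, flag, rname, pos, mapq, cigar, seq, qual plus derived
# strand / mapped / aligned fraction columns
parse_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      mapq = integer(), cigar = character(),
                      seq = character(), qual = character(),
                      mapped = logical(), strand = character(),
                      aligned_frac = numeric()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  df <- data.frame(qname = get(1), flag = as.integer(get(2)),
                   rname = get(3), pos = as.integer(get(4)),
                   mapq = as.integer(get(5)), cigar = get(6),
                   seq = get(10), qual = get(11))
  df$mapped <- bitwAnd(df$flag, 4L) == 0L
  df$strand <- ifelse(bitwAnd(df$flag, 16L) == 16L, "-", "+")
  df$aligned_frac <- vapply(seq_len(nrow(df)), function(i) {
    if (!df$mapped[i]) return(0)
    cl <- cigar_lengths(df$cigar[i])
    unname(cl["m"] / max(1L, nchar(df$seq[i])))
  }, numeric(1))
  df
}
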