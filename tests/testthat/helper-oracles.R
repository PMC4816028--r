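# Independent oracles and fixture builders. Each oracle re-derives its
# result from first principles (brute force or an independent library),
# never through the code paths it checks.

BASES4 <- c("A", "C", "G", "T")

random_dna <- function(n) paste0(sample(BASES4, n, replace = TRUE),
                                 collapse = "")

# brute-force suffix sort: all non-sentinel suffixes ordered by byte value
# (radix sort collates by raw bytes, matching the index's $ < A < C < G <
# N < T convention)
naive_suffix_order <- function(genome) {
  seq <- genome$sequence
  chars <- strsplit(seq, "")[[1]]
  pos <- which(chars != "$")
  sufs <- substring(seq, pos, nchar(seq))
  pos[order(sufs, method = "radix")]
}

# find-all by sliding window over the concatenation (1-based offsets);
# ACGT-only patterns can never straddle a sentinel
naive_find_all <- function(pattern, genome) {
  seq <- genome$sequence
  m <- nchar(pattern)
  n <- nchar(seq)
  if (m > n || m == 0L) return(integer())
  starts <- seq_len(n - m + 1L)
  starts[substring(seq, starts, starts + m - 1L) == pattern]
}

# exhaustive re-implementation of the bidirectional mismatch-budget walk:
# alternate one base left then one base right (left first), skip exhausted
# directions, stop a direction when its next accepted base would exceed the
# budget or a boundary is reached; N compares as mismatch
walk_extend_oracle <- function(oread, read_off, seed_len, genome, gpos,
                               max_mm) {
  rc <- strsplit(oread, "")[[1]]
  gc <- strsplit(genome$sequence, "")[[1]]
  ci <- findInterval(gpos, genome$chrom_offsets)
  cstart <- genome$chrom_offsets[ci]
  cend <- cstart + genome$chrom_lengths[ci] - 1L
  rs <- read_off; re <- read_off + seed_len - 1L
  gs <- gpos; ge <- gpos + seed_len - 1L
  mm <- 0L
  left_open <- TRUE; right_open <- TRUE
  is_mis <- function(a, b) a != b || !(a %in% BASES4) || !(b %in% BASES4)
  while (left_open || right_open) {
    if (left_open) {
      if (rs == 1L || gs == cstart) left_open <- FALSE
      else {
        mis <- is_mis(rc[rs - 1L], gc[gs - 1L])
        if (mis && mm + 1L > max_mm) left_open <- FALSE
        else { rs <- rs - 1L; gs <- gs - 1L; if (mis) mm <- mm + 1L }
      }
    }
    if (right_open) {
      if (re == length(rc) || ge == cend) right_open <- FALSE
      else {
        mis <- is_mis(rc[re + 1L], gc[ge + 1L])
        if (mis && mm + 1L > max_mm) right_open <- FALSE
        else { re <- re + 1L; ge <- ge + 1L; if (mis) mm <- mm + 1L }
      }
    }
  }
  list(read_start = rs, read_end = re, genome_start = gs, genome_end = ge,
       mismatches = mm)
}

# quadratic affine-gap local-alignment DP in plain R (score only);
# gap of length l costs open + l * ext
sw_oracle_r <- function(q, t, match = 5, mism = 4, open = 10, ext = 0.5) {
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  m <- length(qc); n <- length(tc)
  NEG <- -1e18
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, E[i + 1, j] - ext)
      F[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, F[i, j + 1] - ext)
      s <- if (qc[i] == tc[j] && qc[i] %in% BASES4) match else -mism
      h <- max(H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1], 0)
      H[i + 1, j + 1] <- h
      if (h > best) best <- h
    }
  }
  best
}

# Biostrings local alignment with the same scheme, used for the large
# random sweeps (an independent, compiled implementation)
sw_oracle_biostrings <- function(q, t, match = 5, mism = 4, open = 10,
                                 ext = 0.5) {
  submat <- matrix(-mism, 4, 4, dimnames = list(BASES4, BASES4))
  diag(submat) <- match
  Biostrings::pairwiseAlignment(q, t, type = "local",
                                substitutionMatrix = submat,
                                gapOpening = open, gapExtension = ext,
                                scoreOnly = TRUE)
}

parse_cigar_ops <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDSHNP=X]", cigar))[[1]]
  data.frame(len = as.integer(sub("[A-Z=]$", "", ops)),
             op = sub("^[0-9]+", "", ops))
}

# re-score an emitted alignment from its CIGAR, the strand-oriented read
# and the reference; mirrors the documented CAL score formula
rescore_alignment <- function(cigar, oriented_read, genome, chrom, pos,
                              match = 5, mism = 4, open = 10, ext = 0.5) {
  ops <- parse_cigar_ops(cigar)
  ci <- which(genome$chrom_names == chrom)
  goff <- genome$chrom_offsets[ci] + pos - 1L
  ri <- 1L
  nmatch <- 0L; nmis <- 0L; runs <- 0L; gapb <- 0L
  for (r in seq_len(nrow(ops))) {
    len <- ops$len[r]; op <- ops$op[r]
    if (op == "M") {
      a <- substring(oriented_read, ri, ri + len - 1L)
      b <- substring(genome$sequence, goff, goff + len - 1L)
      av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
      eq <- av == bv & av %in% BASES4
      nmatch <- nmatch + sum(eq)
      nmis <- nmis + sum(!eq)
      ri <- ri + len; goff <- goff + len
    } else if (op == "I") {
      runs <- runs + 1L; gapb <- gapb + len; ri <- ri + len
    } else if (op == "D") {
      runs <- runs + 1L; gapb <- gapb + len; goff <- goff + len
    } else if (op == "S") {
      ri <- ri + len
    } else stop("unexpected CIGAR op ", op)
  }
  match * nmatch - mism * nmis - open * runs - ext * gapb
}

# genome with a known unique region planted at a known position
planted_genome <- function(flank = 400L, insert, seed = 1L) {
  set.seed(seed)
  left <- random_dna(flank)
  right <- random_dna(flank)
  list(genome = ref_genome(c(chr1 = paste0(left, insert, right))),
       insert_start = flank + 1L)
}

write_toy_fastq <- function(reads, path) {
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
             path)
  path
}
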