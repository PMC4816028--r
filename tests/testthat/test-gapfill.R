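# Smith-Waterman alignment, CAL gap completion, mapping finalization,
# batch mapping contracts.

test_that("local alignment of identical sequences scores length x match", {
  r <- smith_waterman("ACGTACGT", "ACGTACGT")
  expect_equal(r$score, 40)
  expect_equal(r$cigar, "8M")
  expect_equal(c(r$query_start, r$query_end), c(1L, 8L))
})

test_that("local alignment score equals the quadratic DP oracle", {
  expect_equal(smith_waterman("ACGT", "AGGT")$score,
               sw_oracle_r("ACGT", "AGGT"))
  set.seed(31)
  for (rep in 1:60) {
    q <- random_dna(sample(3:40, 1))
    t <- random_dna(sample(3:40, 1))
    expect_equal(smith_waterman(q, t)$score, sw_oracle_r(q, t))
  }
  expect_error(smith_waterman("", "ACGT"), "nonempty")
})

test_that("N aligns as a mismatch, never a match", {
  r <- smith_waterman("ACGNACGT", "ACGNACGT")
  # 7 matches - 1 mismatch beats clipping around the N (7*5-4 = 31 > 4*5)
  expect_equal(r$score, 31)
})

# convenience: a CAL whose members are given directly
manual_cal <- function(chrom, strand, members) {
  structure(list(chrom = chrom, strand = strand,
                 genome_start = min(members$genome_start),
                 genome_end = max(members$genome_end),
                 members = members,
                 read_coverage = sum(members$read_end - members$read_start
                                     + 1L),
                 mismatches = sum(members$mismatches), score = NA_real_),
            class = "cal")
}

test_that("a CAL covering the whole read yields an all-match alignment", {
  pg <- planted_genome(200, random_dna(100), seed = 41)
  g <- pg$genome
  read_seq <- substring(g$sequence, pg$insert_start, pg$insert_start + 99L)
  read <- list(id = "r1", seq = read_seq, qual = strrep("I", 100))
  cal <- manual_cal("chr1", "+", data.frame(
    read_start = 1L, read_end = 100L, genome_start = pg$insert_start,
    genome_end = pg$insert_start + 99L, strand = "+", mismatches = 0L))
  a <- fill_gaps(cal, read, g)
  expect_equal(a$cigar, "100M")
  expect_equal(a$score, 500)            # 100 x match
  expect_equal(a$position, pg$insert_start)
  expect_equal(a$aligned_read_fraction, 1)
  expect_equal(a$nm, 0L)
})

test_that("an unseeded deletion between two anchors becomes a D run", {
  set.seed(42)
  region <- random_dna(103)
  g <- ref_genome(c(chr1 = paste0(random_dna(150), region,
                                  random_dna(150))))
  start <- 151L
  # read = first 50 bases + last 50 bases of the region (3-bp deletion)
  read_seq <- paste0(substring(region, 1, 50), substring(region, 54, 103))
  read <- list(id = "r1", seq = read_seq, qual = strrep("I", 100))
  cal <- manual_cal("chr1", "+", data.frame(
    read_start = c(1L, 51L), read_end = c(50L, 100L),
    genome_start = c(start, start + 53L),
    genome_end = c(start + 49L, start + 102L),
    strand = "+", mismatches = 0L))
  a <- fill_gaps(cal, read, g)
  expect_equal(a$cigar, "50M3D50M")
  # 100 matches, one gap run of 3 bases
  expect_equal(a$score, 100 * 5 - 10 - 0.5 * 3)
  expect_equal(a$nm, 3L)
})

test_that("an unaligned read tail is soft-clipped and read bases conserved", {
  pg <- planted_genome(200, random_dna(80), seed = 43)
  g <- pg$genome
  head_seq <- substring(g$sequence, pg$insert_start, pg$insert_start + 79L)
  set.seed(44)
  tail_seq <- random_dna(20)  # unrelated to the genome
  read <- list(id = "r1", seq = paste0(head_seq, tail_seq),
               qual = strrep("I", 100))
  cal <- manual_cal("chr1", "+", data.frame(
    read_start = 1L, read_end = 80L, genome_start = pg$insert_start,
    genome_end = pg$insert_start + 79L, strand = "+", mismatches = 0L))
  a <- fill_gaps(cal, read, g)
  ops <- parse_cigar_ops(a$cigar)
  expect_equal(ops$op[nrow(ops)], "S")
  expect_equal(sum(ops$len[ops$op %in% c("M", "I", "S")]), 100L)
  expect_lte(a$aligned_read_fraction, 0.9)
})

test_that("finalization picks the best score and assigns mapping quality", {
  mk <- function(score, chrom = "chr1", pos = 100, strand = "+") {
    structure(list(read_id = "r", chrom = chrom, position = pos,
                   strand = strand, cigar = "50M", score = score,
                   mapq = NA_integer_, aligned_read_fraction = 1,
                   nm = 0L, seq = strrep("A", 50), qual = strrep("I", 50)),
              class = "alignment")
  }
  read <- list(id = "r", seq = strrep("A", 50), qual = strrep("I", 50))
  expect_equal(finalize_read(list(mk(200)), read)$mapq, 60L)
  f <- finalize_read(list(mk(150), mk(150, pos = 900)), read)
  expect_equal(f$mapq, 0L)
  expect_equal(f$position, 100)          # leftmost wins the tie
  expect_equal(finalize_read(list(mk(100), mk(50)), read)$mapq, 30L)
  un <- finalize_read(list(), read)
  expect_false(un$mapped)
})

test_that("batch size and worker count do not change mapping output", {
  g <- simulate_genome(50000, n_chroms = 2, seed = 51)
  idx <- build_index(g, k = 14)
  sim <- simulate_reads(g, sim_params(read_len = 100, n_reads = 300,
                                      seed = 52))
  a1 <- map_reads(sim$reads, idx, workers = 1, batch_size = 256)
  a2 <- map_reads(sim$reads, idx, workers = 4, batch_size = 256)
  a3 <- map_reads(sim$reads, idx, workers = 1, batch_size = 1)
  expect_identical(a1, a2)
  expect_identical(a1, a3)
  expect_equal(a1$qname, sim$reads$id)   # input order preserved

  empty <- map_reads(sim$reads[0, ], idx)
  expect_equal(nrow(empty), 0L)
})

test_that("a read and its reverse complement map to the same locus", {
  g <- simulate_genome(30000, n_chroms = 1, seed = 53)
  idx <- build_index(g, k = 14)
  sim <- simulate_reads(g, sim_params(read_len = 120, n_reads = 40,
                                      seed = 54, mut_rate = 0,
                                      err_rate = 0))
  fwd <- map_reads(sim$reads, idx)
  rcreads <- sim$reads
  rcreads$seq <- reverse_complement(rcreads$seq)
  rev <- map_reads(rcreads, idx)
  expect_true(all(fwd$mapped) && all(rev$mapped))
  expect_equal(rev$chrom, fwd$chrom)
  expect_equal(rev$pos, fwd$pos)
  expect_true(all(rev$strand != fwd$strand))
})

test_that("emitted scores are reproduced by independent re-scoring", {
  g <- simulate_genome(40000, n_chroms = 2, seed = 55)
  idx <- build_index(g, k = 14)
  sim <- simulate_reads(g, sim_params(read_len = 150, n_reads = 120,
                                      seed = 56, mut_rate = 0.01))
  aln <- map_reads(sim$reads, idx)
  mapped <- aln[aln$mapped, ]
  expect_gt(nrow(mapped), 100)
  for (i in seq_len(nrow(mapped))) {
    oread <- if (mapped$strand[i] == "-")
      reverse_complement(mapped$seq[i]) else mapped$seq[i]
    expect_equal(rescore_alignment(mapped$cigar[i], oread, g,
                                   mapped$chrom[i], mapped$pos[i]),
                 mapped$score[i])
  }
})
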