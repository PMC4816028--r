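# Bidirectional mismatch-budget extension, CAL clustering, CAL selection.

test_that("a perfect read extends to its full length with zero mismatches", {
  pg <- planted_genome(200, random_dna(100), seed = 21)
  g <- pg$genome
  read <- substring(g$sequence, pg$insert_start, pg$insert_start + 99L)
  hit <- list(read_offset = 41L, length = 18L,
              genome_offset = pg$insert_start + 40L)
  e <- extend_seed(hit, read, g, max_mismatches = 3)
  expect_equal(e$read_start, 1L)
  expect_equal(e$read_end, 100L)
  expect_equal(e$genome_start, pg$insert_start)
  expect_equal(e$genome_end, pg$insert_start + 99L)
  expect_equal(e$mismatches, 0L)
  # gap-free: read and genome spans have equal width
  expect_equal(e$read_end - e$read_start, e$genome_end - e$genome_start)
})

test_that("budget 0 stops immediately before a substitution", {
  pg <- planted_genome(200, random_dna(100), seed = 22)
  g <- pg$genome
  read <- substring(g$sequence, pg$insert_start, pg$insert_start + 99L)
  # substitute read base 31, seed starts at 41: substitution sits 10 bp
  # left of the seed
  b <- substring(read, 31, 31)
  sub <- setdiff(c("A", "C", "G", "T"), b)[1]
  read_mut <- paste0(substring(read, 1, 30), sub, substring(read, 32))
  hit <- list(read_offset = 41L, length = 18L,
              genome_offset = pg$insert_start + 40L)
  e <- extend_seed(hit, read_mut, g, max_mismatches = 0)
  expect_equal(e$read_start, 32L)   # stops just before the substitution
  expect_equal(e$read_end, 100L)    # right side reaches the read end
  expect_equal(e$mismatches, 0L)
})

test_that("extension agrees with the exhaustive alternating-walk oracle", {
  set.seed(23)
  for (rep in 1:120) {
    g <- ref_genome(c(chr1 = random_dna(300), chr2 = random_dna(200)))
    L <- sample(30:80, 1)
    ci <- sample(1:2, 1)
    s <- sample(seq_len(g$chrom_lengths[ci] - L + 1L), 1)
    gstart <- g$chrom_offsets[ci] + s - 1L
    read <- substring(g$sequence, gstart, gstart + L - 1L)
    # sprinkle substitutions
    nmut <- sample(0:5, 1)
    rv <- strsplit(read, "")[[1]]
    if (nmut > 0) {
      at <- sample(L, min(nmut, L))
      rv[at] <- vapply(rv[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    }
    read <- paste0(rv, collapse = "")
    slen <- sample(5:15, 1)
    roff <- sample(seq_len(L - slen + 1L), 1)
    budget <- sample(0:4, 1)
    hit <- list(read_offset = roff, length = slen,
                genome_offset = gstart + roff - 1L)
    mine <- extend_seed(hit, read, g, budget)
    oracle <- walk_extend_oracle(read, roff, slen, g, gstart + roff - 1L,
                                 budget)
    expect_equal(mine$read_start, oracle$read_start)
    expect_equal(mine$read_end, oracle$read_end)
    expect_equal(mine$genome_start, oracle$genome_start)
    expect_equal(mine$genome_end, oracle$genome_end)
    expect_equal(mine$mismatches, oracle$mismatches)
  }
})

test_that("raising the mismatch budget never shrinks the extension", {
  set.seed(24)
  for (rep in 1:60) {
    g <- ref_genome(c(chr1 = random_dna(400)))
    L <- 60
    s <- sample(seq_len(400 - L), 1)
    read <- substring(g$sequence, s, s + L - 1L)
    rv <- strsplit(read, "")[[1]]
    at <- sample(L, 6)
    rv[at] <- vapply(rv[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    read <- paste0(rv, collapse = "")
    hit <- list(read_offset = 25L, length = 10L, genome_offset = s + 24L)
    prev_span <- -1L
    for (budget in 0:6) {
      e <- extend_seed(hit, read, g, budget)
      span <- e$read_end - e$read_start + 1L
      expect_gte(span, prev_span)
      prev_span <- span
    }
  }
})

make_ext <- function(rs, re, gs, ge, strand = "+", mm = 0L) {
  data.frame(read_start = rs, read_end = re, genome_start = gs,
             genome_end = ge, strand = strand, mismatches = mm)
}

test_that("diagonal-consistent extensions cluster into one CAL", {
  g <- ref_genome(c(chr1 = random_dna(20000)))
  # five extensions on one diagonal across a 100-bp read
  ext <- do.call(rbind, lapply(c(1, 21, 41, 61, 81), function(o)
    make_ext(o, o + 19, 5000 + o, 5019 + o)))
  cals <- cluster_extensions(ext, g, max_gap = 500, min_cal_length = 25)
  expect_length(cals, 1L)
  expect_equal(cals[[1]]$genome_start, 5001)
  expect_equal(cals[[1]]$genome_end, 5100)
  expect_equal(cals[[1]]$read_coverage, 100L)  # union of the five spans
  expect_equal(nrow(cals[[1]]$members), 5L)
})

test_that("distant hit groups form separate CALs", {
  g <- ref_genome(c(chr1 = random_dna(20000)))
  ext <- rbind(make_ext(1, 40, 1001, 1040), make_ext(45, 90, 1045, 1090),
               make_ext(1, 40, 11001, 11040), make_ext(45, 90, 11045, 11090))
  cals <- cluster_extensions(ext, g, max_gap = 500, min_cal_length = 25)
  expect_length(cals, 2L)
  # partition: each extension in exactly one CAL
  members <- unlist(lapply(cals, function(c) rownames(c$members)))
  expect_equal(anyDuplicated(members), 0L)
  expect_length(members, 4L)
})

test_that("CALs shorter than the threshold are discarded", {
  g <- ref_genome(c(chr1 = random_dna(2000)))
  cals <- cluster_extensions(make_ext(1, 18, 101, 118), g,
                             max_gap = 200, min_cal_length = 25)
  expect_length(cals, 0L)
})

test_that("extensions on opposite strands or chromosomes never share a CAL", {
  g <- ref_genome(c(chr1 = random_dna(500), chr2 = random_dna(500)))
  ext <- rbind(make_ext(1, 40, 101, 140, "+"),
               make_ext(1, 40, 101, 140, "-"),
               make_ext(1, 40, 602, 641, "+"))  # chr2
  cals <- cluster_extensions(ext, g, max_gap = 500, min_cal_length = 10)
  expect_length(cals, 3L)
  expect_setequal(vapply(cals, `[[`, character(1), "chrom"),
                  c("chr1", "chr1", "chr2"))
})

test_that("CAL selection ranks by coverage with documented tie-breaks", {
  g <- ref_genome(c(chr1 = random_dna(5000)))
  mk_cal <- function(cov, mm, gs, strand = "+") {
    structure(list(chrom = "chr1", strand = strand, genome_start = gs,
                   genome_end = gs + 99, members = make_ext(1, 50, gs,
                                                            gs + 49),
                   read_coverage = cov, mismatches = mm, score = NA_real_),
              class = "cal")
  }
  sel <- select_cals(list(mk_cal(95, 0, 100), mk_cal(40, 0, 500),
                          mk_cal(12, 0, 900)), max_cals = 2)
  expect_equal(vapply(sel, `[[`, numeric(1), "read_coverage"), c(95, 40))

  sel <- select_cals(list(mk_cal(80, 3, 100), mk_cal(80, 0, 500)),
                     max_cals = 2)
  expect_equal(sel[[1]]$mismatches, 0)       # fewer mismatches first
  sel <- select_cals(list(mk_cal(80, 1, 900), mk_cal(80, 1, 200)),
                     max_cals = 1)
  expect_equal(sel[[1]]$genome_start, 200)   # then leftmost
  sel <- select_cals(list(mk_cal(80, 1, 300, "-"), mk_cal(80, 1, 300, "+")),
                     max_cals = 1)
  expect_equal(sel[[1]]$strand, "+")         # then forward strand
  expect_length(select_cals(list(), 5), 0L)
})
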