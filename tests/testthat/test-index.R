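# Reference loading, suffix-array construction, prefix table, exact search.

test_that("FASTA loading normalizes sequences and records layout", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT"), fa)
  g <- load_reference(fa)
  expect_equal(g$sequence, "ACGT$")
  expect_equal(g$chrom_offsets, 1L)
  expect_equal(g$chrom_lengths, 4L)

  writeLines(c(">c1 extra header words", "ACGTAC", ">c2", "GGTT"), fa)
  g2 <- load_reference(fa)
  expect_equal(g2$chrom_names, c("c1", "c2"))
  expect_equal(g2$chrom_offsets, c(1L, 8L))   # one sentinel between records
  expect_equal(g2$sequence, "ACGTAC$GGTT$")

  writeLines(c(">chr1", "acgu"), fa)
  expect_equal(load_reference(fa)$sequence, "ACGN$")
})

test_that("degenerate FASTA inputs are rejected with named errors", {
  fa <- tempfile(fileext = ".fa")
  writeLines(character(), fa)
  expect_error(load_reference(fa))
  writeLines(c(">chr1", "ACGT", ">empty", ""), fa)
  expect_error(load_reference(fa), "zero-length")
  expect_error(load_reference(tempfile()), "not found")
})

test_that("suffix array equals the brute-force suffix sort", {
  g <- ref_genome(c(chr1 = "GATTACA"))
  expect_equal(build_suffix_array(g), naive_suffix_order(g))

  expect_equal(build_suffix_array(ref_genome(c(chr1 = "A"))), 1L)
  expect_equal(build_suffix_array(ref_genome(c(chr1 = "AAAA"))),
               c(4L, 3L, 2L, 1L))

  set.seed(7)
  for (nchrom in 1:2) {
    g <- ref_genome(setNames(vapply(1:nchrom,
                                    function(i) random_dna(200),
                                    character(1)),
                             paste0("chr", 1:nchrom)))
    expect_equal(build_suffix_array(g), naive_suffix_order(g))
  }
  # genome containing N: N-suffixes still sorted correctly by byte order
  g <- ref_genome(c(chr1 = "ACGNNACGTN"))
  expect_equal(build_suffix_array(g), naive_suffix_order(g))
})

decode_key <- function(code, k) {
  out <- character(k)
  for (i in k:1) {
    out[i] <- BASES4[(code %% 4) + 1]
    code <- code %/% 4
  }
  paste0(out, collapse = "")
}

ptable_reference_counts <- function(genome, k) {
  # enumerate all N-free k-mer start positions naively
  seq <- genome$sequence
  n <- nchar(seq)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", kmers)
  table(kmers[ok])
}

test_that("prefix table stores exactly the occurring k-mers with correct intervals", {
  g <- ref_genome(c(chr1 = "ACGTACGT"))
  sa <- build_suffix_array(g)
  pt <- build_prefix_table(sa, g, 4L)
  counts <- ptable_reference_counts(g, 4L)
  expect_equal(length(pt$keys), length(counts))
  for (i in seq_along(pt$keys)) {
    kmer <- decode_key(pt$keys[i], 4L)
    ranks <- pt$lo[i]:(pt$hi[i] - 1L)
    sufs <- substring(g$sequence, sa[ranks], sa[ranks] + 3L)
    expect_true(all(sufs == kmer))
    expect_equal(length(ranks), unname(counts[kmer]))
  }

  g2 <- ref_genome(c(chr1 = "AAAA"))
  sa2 <- build_suffix_array(g2)
  pt2 <- build_prefix_table(sa2, g2, 2L)
  expect_equal(length(pt2$keys), 1L)
  expect_equal(sort(sa2[pt2$lo[1]:(pt2$hi[1] - 1L)]), c(1L, 2L, 3L))

  # k longer than the genome: no k-mer exists
  pt3 <- build_prefix_table(sa2, g2, 10L)
  expect_equal(length(pt3$keys), 0L)
  expect_error(build_prefix_table(sa2, g2, 0L), "k")
})

test_that("prefix-table intervals partition the eligible suffix ranks in order", {
  set.seed(11)
  for (rep in 1:3) {
    g <- ref_genome(c(chr1 = random_dna(400), chr2 = random_dna(150)))
    k <- sample(2:6, 1)
    sa <- build_suffix_array(g)
    pt <- build_prefix_table(sa, g, k)
    # eligible ranks: suffix at least k long within its chromosome, N-free
    kmers <- substring(g$sequence, sa, sa + k - 1L)
    eligible <- which(!grepl("[^ACGT]", kmers) & nchar(kmers) == k)
    covered <- unlist(mapply(function(l, h) l:(h - 1L), pt$lo, pt$hi,
                             SIMPLIFY = FALSE))
    expect_equal(sort(covered), eligible)
    expect_false(is.unsorted(covered))        # ordered by prefix
    expect_false(is.unsorted(pt$keys))
    expect_equal(anyDuplicated(covered), 0L)  # disjoint intervals
  }
})

test_that("sa_search matches a naive sliding-window scan", {
  g <- ref_genome(c(chr1 = "ACGTACGT"))
  idx <- build_index(g, k = 4)
  expect_equal(sa_search("ACG", idx), c(1L, 5L))
  expect_equal(sa_search("ACGTACGT", idx), 1L)
  expect_equal(sa_search("TTTT", idx), integer())
  expect_error(sa_search("", idx), "nonempty")
  expect_equal(sa_search("ACGN", idx), integer())  # N never matches

  set.seed(23)
  for (rep in 1:200) {
    g <- ref_genome(c(chr1 = random_dna(300)))
    k <- sample(2:8, 1)
    idx <- build_index(g, k = k)
    # half the patterns are sampled from the genome so hits occur
    m <- sample(1:30, 1)
    pat <- if (runif(1) < 0.5 && m <= 300) {
      s <- sample(300 - m + 1, 1)
      substring(g$sequence, s, s + m - 1L)
    } else random_dna(m)
    if (grepl("[^ACGT]", pat)) next
    expect_identical(sa_search(pat, idx), naive_find_all(pat, g))
  }
})

test_that("search never returns matches spanning a chromosome boundary", {
  g <- ref_genome(c(chr1 = "AAAT", chr2 = "TAAA"))
  idx <- build_index(g, k = 2)
  # "TT" would only occur across the sentinel
  expect_equal(sa_search("TT", idx), integer())
  expect_equal(sa_search("AT", idx), 3L)
  expect_equal(sa_search("TA", idx), 6L)
})

test_that("repeat cap suppresses high-frequency patterns", {
  g <- ref_genome(c(chr1 = strrep("A", 50)))
  idx <- build_index(g, k = 4)
  expect_equal(sa_search("AAAA", idx, max_hits = 10), integer())
  expect_length(sa_search("AAAA", idx, max_hits = 0), 47L)
})

test_that("index persistence is byte-stable and round-trips", {
  g <- ref_genome(c(chr1 = random_dna(500), chr2 = random_dna(200)))
  idx <- build_index(g, k = 5)
  f1 <- tempfile(); f2 <- tempfile()
  save_index(idx, f1)
  save_index(idx, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  idx2 <- load_index(f1)
  expect_identical(idx2$sa, idx$sa)
  expect_identical(idx2$ptable, idx$ptable)
  expect_identical(idx2$genome$sequence, idx$genome$sequence)
  expect_identical(idx2$genome$chrom_names, idx$genome$chrom_names)
  expect_error(load_index(tempfile()), "not found")
})
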