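# Circular coordinate arithmetic, local alignment against the doubled
# region, the best-hit filter chain, orientation, tabulation, and the
# uniqueness scan.

test_that("interval_length measures light-strand intervals with wrapping", {
  expect_equal(interval_length(16188, 16119, 16299), 70)
  expect_equal(interval_length(5, 5, 16299), 1)
  # descending through the origin on a 16,299-nt circle
  expect_equal(interval_length(10, 16290, 16299), 20)
  expect_error(interval_length(0, 5, 16299), "out of range")
  expect_error(interval_length(5, 17000, 16299), "out of range")
})

test_that("an exact transcript read yields one full-length perfect hit", {
  rs <- make_reads(1, error_rate = 0, full_length_fraction = 1, seed = 8)
  hits <- align_reads(stats::setNames(rs$transcript, "t"), reference = rs$reference)
  expect_identical(nrow(hits), 1L)
  expect_equal(hits$identity, 100)
  expect_identical(hits$aligned_length, 70L)
  expect_identical(hits$strand, "-")
  expect_identical(c(hits$ref_start, hits$ref_end), c(16188L, 16119L))
  # the reverse complement maps to the + strand over the same span
  rc <- align_reads(stats::setNames(oracle_revcomp(rs$transcript), "rc"),
                    reference = rs$reference)
  expect_identical(rc$strand, "+")
  expect_identical(c(rc$ref_start, rc$ref_end), c(16119L, 16188L))
})

test_that("random reads do not reach the identity threshold", {
  set.seed(99)
  ref <- make_mt_reference(seed = 1)
  rnd <- vapply(1:20, function(i) random_dna(50), "")
  hits <- align_reads(stats::setNames(rnd, paste0("r", 1:20)), reference = ref,
                      min_identity = 90, min_score = 15)
  expect_identical(nrow(hits), 0L)
})

test_that("non-DNA reads are skipped with a warning", {
  ref <- make_mt_reference(seed = 1)
  reads <- tibble::tibble(read_id = c("good", "bad"),
                          seq = c(substr(ref, 16120, 16180), "ACGTXN--ACGT"))
  expect_warning(hits <- align_reads(reads, reference = ref), "skipping 1")
  expect_identical(unique(hits$read_id), "good")
})

test_that("origin-spanning hits match a brute-force circular scan", {
  set.seed(12)
  circ <- random_dna(60)
  # plant a read across the origin: last 10 nt + first 8 nt of the circle
  read <- paste0(substr(circ, 51, 60), substr(circ, 1, 8))
  hits <- align_reads(stats::setNames(read, "wrap"), reference = circ,
                      region = c(41, 20), min_score = 10)
  expect_gte(nrow(hits), 1)
  top <- hits[which.max(hits$score), ]
  expect_equal(top$identity, 100)
  expect_identical(top$aligned_length, 18L)
  expect_identical(c(top$ref_start, top$ref_end), c(51L, 8L)) # folded across origin
  expect_equal(top$score, circular_best_score(read, circ))
  # brute-force score agreement for error-bearing reads, both strands
  for (i in 1:6) {
    r <- read
    substr(r, 5, 5) <- sample(c("A", "C", "G", "T"), 1)
    if (i %% 2 == 0) r <- oracle_revcomp(r)
    h <- align_reads(stats::setNames(r, "x"), reference = circ,
                     region = c(41, 20), min_score = 5, min_identity = 0)
    expect_equal(max(h$score), circular_best_score(r, circ))
  }
})

test_that("best_hit equals exhaustive enumeration and ignores input order", {
  set.seed(7)
  make_hits <- function(n) {
    tibble::tibble(
      read_id = "r1", ref = "ref",
      identity = sample(c(90, 95, 98, 100), n, TRUE),
      aligned_length = sample(c(40L, 55L, 70L), n, TRUE),
      ref_start = sample.int(200, n, TRUE),
      ref_end = sample.int(200, n, TRUE),
      strand = sample(c("+", "-"), n, TRUE),
      score = runif(n, 10, 70)
    )
  }
  for (trial in 1:20) {
    hits <- make_hits(sample(1:50, 1))
    chosen <- best_hit(hits)
    oracle <- oracle_best_hit(hits)
    expect_equal(as.data.frame(chosen), oracle, ignore_attr = TRUE)
    # permutation invariance
    perm <- hits[sample(nrow(hits)), ]
    expect_equal(as.data.frame(best_hit(perm)), oracle, ignore_attr = TRUE)
  }
  # worked example: identities (95, 98, 98), lengths (60, 70, 50)
  ex <- tibble::tibble(
    read_id = "r", ref = "ref",
    identity = c(95, 98, 98), aligned_length = c(60L, 70L, 50L),
    ref_start = c(1L, 5L, 9L), ref_end = c(60L, 74L, 58L),
    strand = "+", score = c(50, 60, 40)
  )
  expect_identical(best_hit(ex)$aligned_length, 70L)
  # duplicates collapse to one survivor; single hits survive as themselves
  dup <- ex[c(2, 2), ]
  expect_identical(nrow(best_hit(dup)), 1L)
  expect_identical(nrow(best_hit(ex[1, ])), 1L)
})

test_that("orient_hits flips minus hits onto plus and is idempotent", {
  hits <- tibble::tibble(
    read_id = c("a", "b"), ref = "ref", identity = 100,
    aligned_length = 70L, ref_start = c(16119L, 16188L),
    ref_end = c(16188L, 16119L), strand = c("+", "-"), score = 70
  )
  o1 <- orient_hits(hits)
  expect_true(all(o1$strand == "+"))
  expect_identical(o1$ref_start, c(16119L, 16119L))
  expect_identical(o1$ref_end, c(16188L, 16188L))
  expect_identical(o1$original_strand, c("+", "-"))
  expect_identical(orient_hits(o1), o1)
})

test_that("length tabulation finds the dominant transcript length", {
  rs <- make_reads(300, error_rate = 0, off_target_fraction = 0,
                   full_length_fraction = 1, seed = 21)
  tab <- tabulate_lengths(best_hit(align_reads(rs)))
  expect_identical(attr(tab, "modal_length"), 70L)
  expect_identical(tab$n[tab$aligned_length == 70], 300L)
  empty <- tabulate_lengths(align_reads(tibble::tibble(read_id = character(),
                                                       seq = character()),
                                        reference = rs$reference))
  expect_identical(nrow(empty), 0L)
  expect_true(is.na(attr(empty, "modal_length")))
})

test_that("uniqueness_scan returns the shortest unique prefix", {
  set.seed(5)
  genome <- random_dna(500)
  query <- random_dna(40)
  # plant the first 12 nt of the query in the genome
  planted <- paste0(substr(genome, 1, 200), substr(query, 1, 12),
                    substr(genome, 213, 500))
  res <- uniqueness_scan(query, planted)
  expect_identical(res, oracle_unique_prefix(query, planted))
  expect_gte(res, 13L) # prefixes up to the planted 12-mer still occur
  # query present verbatim -> no unique prefix
  expect_identical(uniqueness_scan(substr(genome, 100, 140), genome), 0L)
  # reverse-complement occurrences count as occurrences
  expect_identical(uniqueness_scan(oracle_revcomp(substr(genome, 100, 140)), genome), 0L)
  # empty genome set: trivially unique, full length with a warning
  expect_warning(full <- uniqueness_scan(query, character(0)), "empty genome")
  expect_identical(full, nchar(query))
  expect_error(uniqueness_scan("", genome), "non-empty")
})
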