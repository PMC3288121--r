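# helitron_caller: pairing, flanks, hairpin, autonomy flag, planted recovery

test_that("the span rule pairs a 5'/3' hit couple into exactly one call", {
  h <- make_hits(hit_row(1000, 1017, "five_prime"),
                 hit_row(14971, 15000, "three_prime"))
  calls <- pair_termini(h)
  expect_equal(nrow(calls), 1)
  expect_equal(c(calls$start, calls$end), c(1000, 15000))
  expect_equal(calls$length, 14000)
  expect_equal(calls$family, "helA")

  # >= 20 kb: no call (orphan logged)
  h2 <- make_hits(hit_row(0, 17, "five_prime"),
                  hit_row(24971, 25000, "three_prime"))
  expect_message(c2 <- pair_termini(h2), "orphan")
  expect_equal(nrow(c2), 0)

  # exactly 20 kb is excluded (strict <)
  h3 <- make_hits(hit_row(0, 17, "five_prime"),
                  hit_row(19971, 20000, "three_prime"))
  expect_equal(nrow(suppressMessages(pair_termini(h3))), 0)
  h4 <- make_hits(hit_row(0, 17, "five_prime"),
                  hit_row(19970, 19999, "three_prime"))
  expect_equal(nrow(pair_termini(h4)), 1)
})

test_that("multiple in-range 3'-hits: farthest wins, all recorded", {
  h <- make_hits(hit_row(0, 17, "five_prime"),
                 hit_row(1971, 2000, "three_prime"),
                 hit_row(7971, 8000, "three_prime"))
  calls <- pair_termini(h)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$end, 8000)
  expect_equal(calls$multi_termini_3, 2)
  expect_equal(sort(calls$three_hits[[1]]$end), c(2000, 8000))

  # brute-force cross-check over random hit layouts
  for (rep in 1:10) {
    set.seed(skip_seed + rep)
    n5 <- sample(1:3, 1); n3 <- sample(1:4, 1)
    s5 <- sort(sample(seq(0, 40000, by = 100), n5))
    e3 <- sort(sample(seq(50, 45000, by = 100), n3))
    rows5 <- lapply(s5, function(s) hit_row(s, s + 17, "five_prime"))
    rows3 <- lapply(e3, function(e) hit_row(e - 29, e, "three_prime"))
    h <- do.call(make_hits, c(rows5, rows3))
    calls <- suppressMessages(pair_termini(h))
    # oracle: for each 5' start, farthest 3' end with start>=s+17, end-s<20000
    expected <- 0L
    for (s in s5) {
      ok <- e3[e3 - 29 >= s + 17 & e3 - s < 20000]
      if (length(ok)) {
        expected <- expected + 1L
        expect_true(any(calls$start == s & calls$end == max(ok)))
      }
    }
    expect_equal(nrow(calls), expected)
  }
})

test_that("pairing respects family, strand, sortedness and pseudo exclusion", {
  # family mismatch
  h <- make_hits(hit_row(0, 17, "five_prime", family = "helA"),
                 hit_row(971, 1000, "three_prime", family = "helB"))
  expect_equal(nrow(suppressMessages(pair_termini(h))), 0)
  # strand mismatch
  h <- make_hits(hit_row(0, 17, "five_prime", strand = "+"),
                 hit_row(971, 1000, "three_prime", strand = "-"))
  expect_equal(nrow(suppressMessages(pair_termini(h))), 0)
  # pseudo 3'-hits are never element ends
  h <- make_hits(hit_row(0, 17, "five_prime"),
                 hit_row(971, 1000, "three_prime"),
                 hit_row(4971, 5000, "three_prime", pass = "pseudo"))
  calls <- pair_termini(h)
  expect_equal(calls$end, 1000)
  # unsorted input errors
  bad <- make_hits(hit_row(0, 17, "five_prime"),
                   hit_row(971, 1000, "three_prime"))
  bad <- bad[2:1, ]
  attr(bad, "seqlengths") <- c(chr = 100000L)
  expect_error(pair_termini(bad), "sorted")
})

test_that("a 3'-hit in range of two 5'-hits yields overlapping calls", {
  h <- make_hits(hit_row(0, 17, "five_prime"),
                 hit_row(500, 517, "five_prime"),
                 hit_row(1971, 2000, "three_prime"))
  calls <- pair_termini(h)
  expect_equal(nrow(calls), 2)
  expect_setequal(calls$start, c(0, 500))
  expect_true(all(calls$end == 2000))
  # the outer call records the intervening 5'
  expect_equal(calls$multi_termini_5[calls$start == 0], 2)
})

test_that("flank annotation is strand-oriented and edge-safe", {
  g <- c(chr = "GATTTTTTTTTG")  # element [2,10) between A and T? no: A at 1, G at 10
  mk <- function(start, end, strand) {
    structure(data.frame(seq_id = "chr", start = start, end = end,
                         strand = strand, family = "helA",
                         length = end - start, stringsAsFactors = FALSE),
              class = c("helitron_calls", "data.frame"))
  }
  # A[elem]T on plus
  g1 <- c(chr = "GGATTTTTTTTG")
  a <- annotate_flanks(mk(3, 11, "+"), c(chr = "GGATTTTCCCCTGG"))
  expect_equal(a$flank_upstream_base, "A")
  expect_equal(a$flank_downstream_base, "T")
  expect_true(a$at_insertion)
  # G upstream: not an AT site
  a <- annotate_flanks(mk(3, 11, "+"), c(chr = "GGGTTTTCCCCTGG"))
  expect_false(a$at_insertion)
  # contig edge: missing flank, flag FALSE
  a <- annotate_flanks(mk(0, 5, "+"), c(chr = "TTTTTTTTT"))
  expect_true(is.na(a$flank_upstream_base))
  expect_false(a$at_insertion)
  # minus strand: host A...T reads as A/T in element orientation too
  host <- c(chr = paste0("GGA", revcomp("CCCGGG"), "TGG"))
  a <- annotate_flanks(mk(3, 9, "-"), host)
  expect_equal(a$flank_upstream_base, "A")
  expect_equal(a$flank_downstream_base, "T")
  expect_true(a$at_insertion)
})

test_that("hairpin detection finds the planted palindrome and breaks ties", {
  mk <- function(seq) {
    structure(data.frame(seq_id = "chr", start = 0L, end = nchar(seq),
                         strand = "+", family = "helA", length = nchar(seq),
                         stringsAsFactors = FALSE),
              class = c("helitron_calls", "data.frame"))
  }
  stem <- "AACCGCTA"
  pal <- paste0(stem, revcomp(stem))  # perfect 16 bp palindrome
  # planted 11 bp upstream of the 3'-end inside a G-homopolymer window
  seq <- paste0(strrep("G", 60), pal, strrep("G", 11))
  hp <- detect_hairpin(mk(seq), c(chr = seq))
  expect_equal(hp$stem_length, 8)
  expect_equal(hp$mismatches, 0)
  expect_equal(hp$distance_to_3prime, 11)
  expect_equal(hp$loop_length, 0)
  expect_equal(c(hp$hairpin_start, hp$hairpin_end), c(60, 76))

  # homopolymer window: nothing can pair
  hp <- detect_hairpin(mk(strrep("A", 80)), c(chr = strrep("A", 80)))
  expect_true(is.na(hp$stem_length))

  # two equal-score palindromes: the one nearer the 3'-end is reported
  # (different stems, so no cross-palindrome structure can outscore them)
  pal2 <- paste0("ATGGTCAC", revcomp("ATGGTCAC"))
  seq2 <- paste0(strrep("G", 40), pal, strrep("G", 5), pal2, strrep("G", 6))
  hp2 <- detect_hairpin(mk(seq2), c(chr = seq2))
  expect_equal(hp2$stem_length, 8)
  expect_equal(hp2$distance_to_3prime, 6)
})

test_that("putative-autonomous flag combines length and mask overlap", {
  mk <- function(len) structure(
    data.frame(seq_id = "chr", start = 1000L, end = 1000L + len,
               strand = "+", family = "helA", length = len,
               stringsAsFactors = FALSE),
    class = c("helitron_calls", "data.frame"))
  expect_true(flag_putative_autonomous(mk(12000)))
  expect_false(flag_putative_autonomous(mk(8000)))
  retro <- data.frame(seq_id = "chr", start = 5000, end = 6000)
  expect_false(flag_putative_autonomous(mk(12000), retro))
  elsewhere <- data.frame(seq_id = "chr", start = 50000, end = 60000)
  expect_true(flag_putative_autonomous(mk(12000), elsewhere))
})

test_that("planted elements are recovered with exact boundaries, both strands", {
  sim <- generate_genome(simulation_config(
    genome_length = 150000, n_helA = 3, n_helB = 2, p_nested = 0,
    element_length_range = c(400, 3000), seed = 11))
  calls <- call_helitrons(sim$genome, pass = "strict")
  tr <- sim$truth$elements
  expect_true(any(tr$strand == "-"))  # exercise the minus-strand path
  for (i in seq_len(nrow(tr))) {
    expect_true(any(calls$start == tr$start[i] & calls$end == tr$end[i] &
                    calls$strand == tr$strand[i] &
                    calls$family == tr$family[i]),
                label = paste("element", tr$element_id[i]))
  }
  expect_true(all(calls$length < 20000))
  expect_true(all(calls$at_insertion[calls$start %in% tr$start]))
})

test_that("calls are deterministic under tie reordering of hits", {
  h <- make_hits(hit_row(0, 17, "five_prime"),
                 hit_row(0, 16, "five_prime", pass = "loose"),
                 hit_row(1971, 2000, "three_prime"),
                 hit_row(1973, 2000, "three_prime", pass = "loose"))
  a <- pair_termini(h)
  h2 <- h[c(2, 1, 3, 4), ]
  attr(h2, "seqlengths") <- attr(h, "seqlengths")
  b <- pair_termini(h2)
  expect_equal(a[, setdiff(names(a), "three_hits")],
               b[, setdiff(names(b), "three_hits")])
})
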