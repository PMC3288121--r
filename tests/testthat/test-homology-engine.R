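# homology_engine: local search, discovery, boundary validation, copy tiers

test_that("an exact planted copy is found with identity and coverage 100", {
  set.seed(skip_seed)
  q <- random_dna(400)
  g <- plant_in_genome(20000, list(list(at = 7000, seq = q)),
                       seed = skip_seed + 1)
  h <- local_search(q, g)
  top <- h[which.max(h$score), ]
  expect_equal(c(top$s_start, top$s_end), c(7000, 7400))
  expect_equal(top$identity, 100)
  expect_equal(top$coverage, 100)
  expect_equal(top$strand, "+")
})

test_that("a reverse-complement copy is found on the minus strand", {
  set.seed(skip_seed)
  q <- random_dna(300)
  g <- plant_in_genome(10000, list(list(at = 4000, seq = revcomp(q))),
                       seed = skip_seed + 2)
  h <- local_search(q, g)
  top <- h[which.max(h$score), ]
  expect_equal(top$strand, "-")
  expect_equal(c(top$s_start, top$s_end), c(4000, 4300))
})

test_that("identity tracks the planted mutation rate", {
  set.seed(skip_seed)
  q <- random_dna(1000)
  mut <- mutate_copies(q, 1, 0.1, seed = skip_seed + 3)
  g <- plant_in_genome(20000, list(list(at = 5000, seq = mut$copies[1])),
                       seed = skip_seed + 4)
  h <- local_search(q, g, min_identity = 70)
  top <- h[which.max(h$score), ]
  expect_gt(top$coverage, 95)
  expect_lt(abs(top$identity - mut$realized_identity[1]), 2)
  expect_lt(abs(top$identity - 90), 3)
})

test_that("an absent query yields no hits; short queries error", {
  set.seed(skip_seed)
  g <- c(chr = random_dna(20000))
  q <- random_dna(500)
  expect_equal(nrow(local_search(q, g, min_identity = 80)), 0)
  expect_error(local_search("ACGTACGT", g), "seed size")
})

test_that("top hits agree with a brute-force ungapped DP oracle", {
  for (rep in 1:6) {
    set.seed(skip_seed + rep)
    s <- random_dna(200)
    core <- substr(s, 61, 140)
    q <- paste0(random_dna(20),
                mutate_copies(core, 1, 0.05)$copies[1],
                random_dna(20))
    got <- local_search(q, c(chr = s), min_len_bp = 20, min_identity = 60,
                        strand_mode = "forward")
    want <- oracle_ungapped_best(q, s)
    expect_gt(nrow(got), 0)
    top <- got[which.max(got$score), ]
    expect_equal(top$score, want$score, label = paste("rep", rep))
    expect_equal(top$matches, want$matches)
    expect_equal(top$identity, want$identity)
  }
})

test_that("seed discovery pairs terminus probes under the span rule", {
  set.seed(skip_seed)
  el <- strict_element("helA", body_len = 1200, seed = skip_seed)
  g <- plant_in_genome(60000, list(list(at = 20000, seq = el$seq)),
                       seed = skip_seed + 5)
  cand <- seed_discovery(c(seed1 = el$seq), g)
  expect_equal(nrow(cand), 1)
  expect_equal(c(cand$start, cand$end), c(20000, 20000 + nchar(el$seq)))

  # 5'-probe match only: no candidate
  g5 <- plant_in_genome(30000,
                        list(list(at = 9000, seq = substr(el$seq, 1, 60))),
                        seed = skip_seed + 6)
  expect_equal(nrow(seed_discovery(c(seed1 = el$seq), g5)), 0)

  # two copies 30 kb apart: two separate candidates, never cross-paired
  g2 <- plant_in_genome(80000, list(list(at = 10000, seq = el$seq),
                                    list(at = 41500, seq = el$seq)),
                        seed = skip_seed + 7)
  cand2 <- seed_discovery(c(seed1 = el$seq), g2)
  expect_equal(nrow(cand2), 2)
  expect_setequal(cand2$start, c(10000, 41500))
  expect_true(all(cand2$end - cand2$start == nchar(el$seq)))
})

test_that("boundary validation stops where copy flanks diverge", {
  set.seed(skip_seed)
  body <- random_dna(800)
  starts <- c(3000, 12000, 22000)
  g <- plant_in_genome(30000,
                       lapply(starts, function(s) list(at = s, seq = body)),
                       seed = skip_seed + 8)
  copies <- data.frame(seq_id = "chr", start = starts, end = starts + 800,
                       strand = "+")
  ref <- validate_boundaries(copies, g)
  expect_true(all(ref$resolved))
  expect_equal(ref$five_boundary, starts)
  expect_equal(ref$three_boundary, starts + 800)

  # shared 5 bp of flank: boundary still within the 10 bp window resolution
  g5 <- plant_in_genome(
    30000, lapply(starts, function(s) list(at = s, seq = paste0("ACGTA", body))),
    seed = skip_seed + 9)
  copies5 <- data.frame(seq_id = "chr", start = starts + 5,
                        end = starts + 805, strand = "+")
  ref5 <- validate_boundaries(copies5, g5)
  expect_true(all(abs(ref5$five_boundary - (starts + 5)) <= 10))

  # identical flanks (tandem-duplication style): unresolvable, flagged
  unit <- paste0(random_dna(300), body, random_dna(300))
  gt <- plant_in_genome(30000, list(list(at = 5000, seq = unit),
                                    list(at = 15000, seq = unit)),
                        seed = skip_seed + 10)
  ct <- data.frame(seq_id = "chr", start = c(5300, 15300),
                   end = c(6100, 16100), strand = "+")
  expect_warning(rt <- validate_boundaries(ct, gt), "unresolvable")
  expect_false(any(rt$resolved))

  # single copy: unrefined, flagged
  expect_warning(r1 <- validate_boundaries(copies[1, ], g), "unrefined")
  expect_false(any(r1$resolved))
})

test_that("copy tiers count planted copies and stay monotone", {
  set.seed(skip_seed)
  el <- random_dna(1000)
  exact <- rep(list(NULL), 5)
  div <- mutate_copies(el, 3, 0.13, seed = skip_seed + 11)
  expect_true(all(div$realized_identity > 85 & div$realized_identity < 90))
  starts <- seq(10000, 150000, length.out = 8)
  plants <- c(lapply(starts[1:5], function(s) list(at = s, seq = el)),
              lapply(seq_len(3), function(i)
                list(at = starts[5 + i], seq = div$copies[i])))
  g <- plant_in_genome(170000, plants, seed = skip_seed + 12)
  tiers <- count_copies(el, g)
  expect_equal(tiers$copy_count[tiers$name == "cov95_id95"], 5)
  expect_equal(tiers$copy_count[tiers$name == "cov90_id90"], 5)
  expect_equal(tiers$copy_count[tiers$name == "cov85_id85"], 8)
  expect_equal(tiers$copy_count[tiers$name == "len200_id80"], 8)
  expect_true(!is.unsorted(tiers$copy_count))

  # no copies at all
  set.seed(skip_seed + 13)
  empty <- count_copies(random_dna(600), c(chr = random_dna(30000)))
  expect_true(all(empty$copy_count == 0))
})

test_that("copy counts are invariant under reverse-complementing the genome", {
  set.seed(skip_seed)
  el <- random_dna(800)
  div <- mutate_copies(el, 2, 0.08, seed = skip_seed + 14)
  g <- plant_in_genome(60000, list(list(at = 10000, seq = el),
                                   list(at = 30000, seq = div$copies[1]),
                                   list(at = 50000, seq = div$copies[2])),
                       seed = skip_seed + 15)
  fw <- count_copies(el, g)
  rc <- count_copies(el, c(chr = revcomp(g[[1]])))
  expect_equal(fw$copy_count, rc$copy_count)
})
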