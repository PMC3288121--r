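# motif_engine: pattern compilation, scanning, oracle equivalence

test_that("built-in pattern set is complete and matches the printed motifs", {
  ps <- helitron_patterns("all")
  expect_length(ps, 9)
  tab <- data.frame(family = vapply(ps, `[[`, "", "family"),
                    end = vapply(ps, `[[`, "", "end_type"),
                    pass = vapply(ps, `[[`, "", "pass_level"))
  expect_equal(sum(tab$pass == "loose"), 4)
  expect_equal(sum(tab$pass == "strict"), 4)
  expect_equal(sum(tab$pass == "pseudo"), 1)
  # one 5' and one 3' per family per pass
  expect_true(all(table(tab$family[tab$pass == "strict"]) == 2))
  expect_true(all(table(tab$family[tab$pass == "loose"]) == 2))
  # pseudo is helA 3' only
  expect_equal(tab$family[tab$pass == "pseudo"], "helA")
  expect_equal(tab$end[tab$pass == "pseudo"], "three_prime")
})

get_pattern <- function(family, end, pass) {
  ps <- helitron_patterns(pass, family = family)
  ps[[which(vapply(ps, `[[`, "", "end_type") == end)]]
}

test_that("pattern acceptance matches an independent regex oracle", {
  sa5 <- get_pattern("helA", "five_prime", "strict")
  sa3 <- get_pattern("helA", "three_prime", "strict")
  lb5 <- get_pattern("helB", "five_prime", "loose")
  expect_true(pattern_matches(sa5, "ATCTGTACTACAAAAAA"))
  expect_true(pattern_matches(sa3, "CCGTAGCAACGCACGGGAAAAAAACTAGT"))
  expect_false(pattern_matches(lb5, "ATCAAAAAAATTAAA"))
  # same three calls through the oracle
  expect_identical(nrow(oracle_scan("ATCTGTACTACAAAAAA", sa5$pattern)), 1L)
  expect_identical(nrow(oracle_scan("CCGTAGCAACGCACGGGAAAAAAACTAGT",
                                    sa3$pattern)), 1L)
  expect_identical(nrow(oracle_scan("ATCAAAAAAATTAAA", lb5$pattern)), 0L)
})

test_that("match length bounds follow from the quantifiers", {
  expect_equal(max_match_length(get_pattern("helA", "three_prime", "strict")),
               29)
  expect_equal(max_match_length(get_pattern("helB", "five_prime", "loose")),
               17)
  expect_equal(max_match_length(get_pattern("helA", "three_prime", "pseudo")),
               29)
  expect_equal(min_match_length(get_pattern("helA", "three_prime", "pseudo")),
               27)
  expect_lte(max(vapply(helitron_patterns("all"), max_match_length,
                        integer(1))), 40)
})

test_that("unsupported pattern syntax is rejected", {
  expect_error(terminus_pattern("helA", "five_prime", "loose", "ATC+G"),
               "unbounded")
  expect_error(terminus_pattern("helA", "five_prime", "loose", "ATC*"),
               "unbounded")
  expect_error(terminus_pattern("helA", "five_prime", "loose", "{3}ATC"),
               "quantifier without")
  expect_error(terminus_pattern("helA", "five_prime", "loose", "AT(C)"),
               "unsupported")
  # whitespace inside quantifiers is normalized, as in the printed pseudo motif
  p <- terminus_pattern("helA", "three_prime", "pseudo",
                        "CCGT[ATCG]GCA[AT]CGCACG[AG]{2}[ATCG]{6, 8}CTAT")
  expect_equal(max_match_length(p), 29)
})

test_that("scan_termini reports exact hit coordinates and lengths", {
  sa5 <- get_pattern("helA", "five_prime", "strict")
  h <- scan_termini(c(chr = "ATCTGTACTACAAAAAA"), list(sa5), "forward")
  expect_equal(nrow(h), 1)
  expect_equal(c(h$start, h$end), c(0, 17))
  expect_equal(h$matched_text, "ATCTGTACTACAAAAAA")

  sa3 <- get_pattern("helA", "three_prime", "strict")
  set.seed(skip_seed)
  motif <- "CCGTAGCAACGCACGGGAAAAAAACTAGT"
  g <- plant_in_genome(1000, list(list(at = 500, seq = motif)),
                       seed = skip_seed)
  h <- scan_termini(g, list(sa3), "forward")
  expect_true(any(h$start == 500 & h$end == 529))

  # all-N genome: nothing matches, wildcards included
  hn <- scan_termini(c(chr = strrep("N", 500)), helitron_patterns("all"))
  expect_equal(nrow(hn), 0)
})

test_that("N defeats a wildcard position", {
  sa5 <- get_pattern("helA", "five_prime", "strict")
  s <- "ATCTGTACTACAAAAAA"
  expect_equal(nrow(scan_termini(c(chr = s), list(sa5), "forward")), 1)
  broken <- paste0(substr(s, 1, 11), "N", substr(s, 13, 17))  # a "." position
  expect_equal(nrow(scan_termini(c(chr = broken), list(sa5), "forward")), 0)
})

test_that("scan equals brute-force substring matching on random sequence", {
  ps <- helitron_patterns("all")
  for (rep in 1:8) {
    set.seed(skip_seed + rep)
    g <- c(chr = random_dna(2000, 0.47))
    # plant one sampled motif to guarantee non-trivial cases
    p <- ps[[1 + (rep %% 9)]]
    m <- sample_pattern_string(p)
    g <- c(chr = paste0(substr(g, 1, 900), m,
                        substr(g, 901 + nchar(m), 2000)))
    for (p in ps) {
      got <- scan_termini(g, list(p), "forward")
      want <- oracle_scan(g[[1]], p$pattern)
      expect_equal(got[, c("start", "end")],
                   want, ignore_attr = TRUE,
                   label = paste("pattern", p$pattern, "rep", rep))
    }
  }
})

test_that("strand symmetry: forward scan of the reverse complement mirrors minus-strand hits", {
  set.seed(skip_seed)
  p <- get_pattern("helA", "three_prime", "strict")
  m <- sample_pattern_string(p)
  g <- plant_in_genome(3000, list(list(at = 1200, seq = revcomp(m))),
                       seed = skip_seed + 5)
  L <- nchar(g[[1]])
  both <- scan_termini(g, list(p), "both")
  minus <- both[both$strand == "-", , drop = FALSE]
  rc <- c(chr = revcomp(g[[1]]))
  fwd_rc <- scan_termini(rc, list(p), "forward")
  expect_equal(sort(L - minus$end), sort(fwd_rc$start))
  expect_equal(sort(L - minus$start), sort(fwd_rc$end))
  expect_true(nrow(minus) >= 1)
})

test_that("strictness containment: strict helA 3' hits with a CCCGT context are loose hits too", {
  # the printed loose pattern begins CCCGT, the strict one CCGT; when the
  # base before a strict hit supplies the extra C, the loose pattern must
  # also fire (one position earlier, same end)
  strict3 <- get_pattern("helA", "three_prime", "strict")
  loose3 <- get_pattern("helA", "three_prime", "loose")
  for (rep in 1:20) {
    set.seed(skip_seed + rep)
    m <- sample_pattern_string(strict3)
    g <- c(chr = paste0(random_dna(50), "C", m, random_dna(50)))
    hs <- scan_termini(g, list(strict3), "forward")
    hl <- scan_termini(g, list(loose3), "forward")
    s_at <- hs[hs$start == 51, , drop = FALSE]
    expect_equal(nrow(s_at), 1)
    expect_true(any(hl$start == 50 & hl$end == s_at$end),
                label = paste("containment rep", rep))
  }
})

test_that("patterns load from a plain-text config", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# custom set",
               "helA five_prime strict ATCT[ATCG]TACTAC.{5}A",
               "helB three_prime loose CGCC.{5,7}GGCG.{8,10}CTAGT"), f)
  ps <- read_patterns(f)
  expect_length(ps, 2)
  expect_equal(ps[[1]]$family, "helA")
  expect_true(pattern_matches(ps[[1]], "ATCTGTACTACAAAAAA"))
  writeLines("helA five_prime strict", f)
  expect_error(read_patterns(f), "4 fields")
})
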