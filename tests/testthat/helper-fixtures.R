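# Programmatic fixtures shared across test files.

# a genome with given strings planted at given 0-based positions over a
# random background (positions must be ascending, non-overlapping)
plant_in_genome <- function(n, plants = list(), gc = 0.47, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    bg <- random_dna(n, gc)
    for (p in plants) {
      stopifnot(p$at + nchar(p$seq) <= n)
      bg <- paste0(substr(bg, 1, p$at), p$seq,
                   substr(bg, p$at + nchar(p$seq) + 1, n))
    }
    c(chr = bg)
  })
}

# hand-built terminus hit rows for pairing tests
hit_row <- function(start, end, end_type, family = "helA", strand = "+",
                    pass = "strict", seq_id = "chr", text = "") {
  data.frame(seq_id = seq_id, start = start, end = end, strand = strand,
             family = family, end_type = end_type, pass_level = pass,
             matched_text = text, stringsAsFactors = FALSE)
}

make_hits <- function(..., seqlengths = c(chr = 100000L)) {
  h <- do.call(rbind, list(...))
  h <- h[order(h$seq_id, h$start), , drop = FALSE]
  attr(h, "seqlengths") <- seqlengths
  class(h) <- c("terminus_hits", "data.frame")
  h
}

# a strict-pass element sequence with recorded termini (oriented)
strict_element <- function(family = "helA", body_len = 400, seed = NULL) {
  build <- function() {
    ps <- helitron_patterns("strict", family = family)
    et <- vapply(ps, `[[`, "", "end_type")
    five <- sample_pattern_string(ps[[which(et == "five_prime")]])
    three <- sample_pattern_string(ps[[which(et == "three_prime")]])
    list(seq = paste0(five, random_dna(body_len), three),
         five = five, three = three)
  }
  if (is.null(seed)) build() else { set.seed(seed); build() }
}
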