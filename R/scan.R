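# Genome scanning for terminus motif hits.

# Find all 0-based start positions in an encoded sequence where a fixed-length
# variant (list of allowed-code vectors) matches. Progressive candidate
# filtering: start from matches of position 1, then shrink.
.scan_variant <- function(enc, variant) {
  L <- length(variant)
  n <- length(enc)
  if (n < L) return(integer(0))
  cand <- which(enc[seq_len(n - L + 1L)] %in% variant[[1]])
  i <- 2L
  while (i <= L && length(cand) > 0L) {
    cand <- cand[enc[cand + (i - 1L)] %in% variant[[i]]]
    i <- i + 1L
  }
  cand - 1L  # 0-based
}

#' Scan a genome for terminus motif hits
#'
#' Reports every match of every pattern, including overlapping matches and,
#' for variable-length quantifiers, every distinct match length at each start
#' position. N (and soft-masked, if encoded as N) residues never match any
#' motif position.
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param patterns list of [terminus_pattern()] objects; defaults to the
#'   built-in loose + strict sets.
#' @param strand_mode `"both"` (default) or `"forward"`.
#' @return `data.frame` of class `terminus_hits` with 0-based half-open
#'   columns `seq_id, start, end, strand, family, end_type, pass_level,
#'   matched_text`, sorted by (seq_id, start, end). `matched_text` is the
#'   strand-oriented genome substring. The vector of scanned sequence lengths
#'   is attached as attribute `"seqlengths"`.
#' @examples
#' hits <- scan_termini(c(chr = "ATCTGTACTACAAAAAA"),
#'                      helitron_patterns("strict"))
#' @export
scan_termini <- function(genome, patterns = helitron_patterns(),
                         strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  if (length(patterns) == 0L) stop("patterns must be non-empty")
  stopifnot(all(vapply(patterns, inherits, logical(1), "terminus_pattern")))
  G <- .genome_chars(genome)

  rows <- list()
  for (sid in names(G)) {
    seq_fwd <- G[[sid]]
    L <- nchar(seq_fwd)
    enc_fwd <- encode_dna(seq_fwd)
    strands <- if (strand_mode == "both") c("+", "-") else "+"
    for (strand in strands) {
      if (strand == "+") {
        enc <- enc_fwd
        seq_or <- seq_fwd
      } else {
        enc <- .revcomp_enc(enc_fwd)
        seq_or <- decode_dna(enc)
      }
      for (p in patterns) {
        hit_start <- integer(0)
        hit_len <- integer(0)
        for (v in .enumerate_variants(p)) {
          s <- .scan_variant(enc, v)
          hit_start <- c(hit_start, s)
          hit_len <- c(hit_len, rep(length(v), length(s)))
        }
        if (length(hit_start) == 0L) next
        keep <- !duplicated(cbind(hit_start, hit_len))
        hit_start <- hit_start[keep]; hit_len <- hit_len[keep]
        txt <- .substr0(rep(seq_or, length(hit_start)), hit_start,
                        hit_start + hit_len)
        if (strand == "+") {
          st <- hit_start; en <- hit_start + hit_len
        } else {
          # oriented [s, s+len) on the reverse complement maps to forward
          # coordinates [L - s - len, L - s)
          st <- L - hit_start - hit_len; en <- L - hit_start
        }
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = sid, start = st, end = en, strand = strand,
          family = p$family, end_type = p$end_type, pass_level = p$pass_level,
          matched_text = txt, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), family = character(0),
               end_type = character(0), pass_level = character(0),
               matched_text = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$seq_id, out$start, out$end, out$strand,
                   out$family, out$end_type, out$pass_level), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seqlengths") <- vapply(G, nchar, integer(1))
  class(out) <- c("terminus_hits", "data.frame")
  out
}
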