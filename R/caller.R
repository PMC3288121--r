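# Pairing terminus hits into intact helitron calls and annotating their
# structural hallmarks.

#' Pair terminus hits into helitron calls
#'
#' For each 5'-terminus locus the call extends to the farthest same-family,
#' same-strand 3'-hit whose end lies strictly less than `max_span_bp`
#' downstream of the 5'-hit start. Intervening same-family 3'-hits are
#' recorded in `three_hits` (multiple-termini candidates); intervening
#' 5'-hits are counted in `multi_termini_5`. A 5'-hit with no in-range
#' downstream 3'-hit produces no call and is logged as an orphan. Hits with
#' `pass_level == "pseudo"` never serve as element ends and are ignored here.
#'
#' Distinct 5' termini are identified by their (strand-oriented) start
#' position, distinct 3' termini by their end position: the motif anchors are
#' at the element-proximal side, so quantifier-length variants of one
#' terminus collapse to one locus.
#'
#' @param hits `terminus_hits` data.frame, sorted by (seq_id, start).
#' @param max_span_bp pairing span limit, default 20000; the 5'-start to
#'   3'-end distance must be strictly smaller.
#' @param seqlengths named integer vector of sequence lengths; required when
#'   minus-strand hits are present (taken from `attr(hits, "seqlengths")`
#'   when available).
#' @return `data.frame` of class `helitron_calls` with 0-based half-open
#'   `start`/`end`, one row per call, plus a `three_hits` list-column.
#' @export
pair_termini <- function(hits, max_span_bp = 20000, seqlengths = NULL) {
  stopifnot(is.data.frame(hits), max_span_bp > 0)
  if (nrow(hits) > 1L) {
    by_seq <- split(hits$start, hits$seq_id)
    if (any(vapply(by_seq, is.unsorted, logical(1))))
      stop("hits must be sorted by (seq_id, start)")
  }
  if (is.null(seqlengths)) seqlengths <- attr(hits, "seqlengths")
  if (any(hits$strand == "-") &&
      (is.null(seqlengths) || !all(unique(hits$seq_id) %in% names(seqlengths))))
    stop("seqlengths are required to pair minus-strand hits")

  real <- hits[hits$pass_level != "pseudo", , drop = FALSE]
  calls <- list()
  n_orphans <- 0L
  key <- interaction(real$seq_id, real$family, real$strand, drop = TRUE)
  for (grp in split(seq_len(nrow(real)), key)) {
    g <- real[grp, , drop = FALSE]
    sid <- g$seq_id[1]; fam <- g$family[1]; strand <- g$strand[1]
    L <- if (strand == "-") unname(seqlengths[sid]) else NA_integer_
    # strand-oriented coordinates: identity for "+", mirrored for "-"
    if (strand == "+") {
      g$os <- g$start; g$oe <- g$end
    } else {
      g$os <- L - g$end; g$oe <- L - g$start
    }
    five <- g[g$end_type == "five_prime", , drop = FALSE]
    three <- g[g$end_type == "three_prime", , drop = FALSE]
    if (nrow(five) == 0L) next
    for (fs in sort(unique(five$os))) {
      fh <- five[five$os == fs, , drop = FALSE]
      fe <- max(fh$oe)
      cand <- three[three$os >= fe & three$oe - fs < max_span_bp, ,
                    drop = FALSE]
      if (nrow(cand) == 0L) { n_orphans <- n_orphans + 1L; next }
      elem_end <- max(cand$oe)
      cand <- cand[order(cand$oe, cand$os), , drop = FALSE]
      n3 <- length(unique(cand$oe))
      internal5 <- unique(five$os[five$os > fs & five$os < elem_end])
      n5 <- 1L + length(internal5)
      five_pass <- if (any(fh$pass_level == "strict")) "strict" else "loose"
      end_hits <- cand[cand$oe == elem_end, , drop = FALSE]
      three_pass <- if (any(end_hits$pass_level == "strict")) "strict" else "loose"
      if (strand == "+") {
        st <- fs; en <- elem_end
        f_st <- fs; f_en <- fe
      } else {
        st <- L - elem_end; en <- L - fs
        f_st <- L - fe; f_en <- L - fs
      }
      cand$os <- NULL; cand$oe <- NULL
      calls[[length(calls) + 1L]] <- data.frame(
        seq_id = sid, start = st, end = en, strand = strand, family = fam,
        length = en - st, five_start = f_st, five_end = f_en,
        five_pass = five_pass, three_pass = three_pass,
        multi_termini_5 = n5, multi_termini_3 = n3,
        stringsAsFactors = FALSE)
      calls[[length(calls)]]$three_hits <- list(cand)
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(seq_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), family = character(0),
               length = integer(0), five_start = integer(0),
               five_end = integer(0), five_pass = character(0),
               three_pass = character(0), multi_termini_5 = integer(0),
               multi_termini_3 = integer(0), stringsAsFactors = FALSE)
  if (n_orphans > 0L)
    message(n_orphans, " orphan 5'-terminus locus(es) without an in-range 3'-hit")
  out <- out[order(out$seq_id, out$start, out$end, out$strand, out$family), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out))
    out$call_id <- sprintf("%s_%s_%04d", out$seq_id, out$family,
                           seq_len(nrow(out)))
  else out$call_id <- character(0)
  attr(out, "seqlengths") <- seqlengths
  attr(out, "n_orphans") <- n_orphans
  class(out) <- c("helitron_calls", "data.frame")
  out
}

#' Annotate insertion-site flanking bases
#'
#' Records the host residue immediately 5' and immediately 3' of each element
#' (strand-oriented) and flags the helitron-typical A...T insertion site.
#' Elements at a contig edge get `NA` flanks and `at_insertion = FALSE`.
#'
#' @param calls `helitron_calls`.
#' @param genome the genome the calls came from.
#' @return `calls` with columns `flank_upstream_base`,
#'   `flank_downstream_base`, `at_insertion` added.
#' @export
annotate_flanks <- function(calls, genome) {
  G <- .genome_chars(genome)
  n <- nrow(calls)
  up <- rep(NA_character_, n)
  dn <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- calls$start[i]; e <- calls$end[i]; sid <- calls$seq_id[i]
    L <- nchar(G[[sid]])
    left <- if (s > 0) .substr0(G[[sid]], s - 1L, s) else NA_character_
    right <- if (e < L) .substr0(G[[sid]], e, e + 1L) else NA_character_
    if (calls$strand[i] == "+") {
      up[i] <- left; dn[i] <- right
    } else {
      up[i] <- if (is.na(right)) NA_character_ else revcomp(right)
      dn[i] <- if (is.na(left)) NA_character_ else revcomp(left)
    }
  }
  calls$flank_upstream_base <- up
  calls$flank_downstream_base <- dn
  calls$at_insertion <- !is.na(up) & !is.na(dn) & up == "A" & dn == "T"
  calls
}

#' Detect the sub-terminal hairpin of helitron calls
#'
#' Searches the window upstream of each element's 3'-end for the
#' highest-scoring reverse-complement palindrome (score = stem length -
#' mismatches; ties broken by smaller distance to the 3'-end, then by longer
#' stem). Defaults realize the canonical 16-20 bp palindrome forming a
#' 10-12 bp hairpin just upstream of the 3'-terminus. Annotation only, never
#' a filter.
#'
#' @param calls `helitron_calls`.
#' @param genome genome sequences.
#' @param stem_min,stem_max stem length bounds (bp).
#' @param loop_max maximum loop length (bp).
#' @param window_bp how far upstream of the element 3'-end to search.
#' @param max_mismatch maximum mismatches tolerated in the stem.
#' @return data.frame, one row per call: `hairpin_start`, `hairpin_end`
#'   (genome coordinates, 0-based half-open), `stem_length`, `loop_length`,
#'   `mismatches`, `distance_to_3prime`; all NA when no stem >= `stem_min`.
#' @export
detect_hairpin <- function(calls, genome, stem_min = 8, stem_max = 10,
                           loop_max = 4, window_bp = 50, max_mismatch = 1) {
  G <- .genome_chars(genome)
  n <- nrow(calls)
  res <- data.frame(hairpin_start = rep(NA_integer_, n),
                    hairpin_end = rep(NA_integer_, n),
                    stem_length = rep(NA_integer_, n),
                    loop_length = rep(NA_integer_, n),
                    mismatches = rep(NA_integer_, n),
                    distance_to_3prime = rep(NA_integer_, n))
  for (i in seq_len(n)) {
    elem <- .substr0(G[[calls$seq_id[i]]], calls$start[i], calls$end[i])
    if (calls$strand[i] == "-") elem <- revcomp(elem)
    hp <- .best_hairpin(elem, stem_min, stem_max, loop_max, window_bp,
                        max_mismatch)
    if (is.null(hp)) next
    # oriented [hp$s, hp$e) within the element -> genome coordinates
    if (calls$strand[i] == "+") {
      res$hairpin_start[i] <- calls$start[i] + hp$s
      res$hairpin_end[i] <- calls$start[i] + hp$e
    } else {
      res$hairpin_start[i] <- calls$end[i] - hp$e
      res$hairpin_end[i] <- calls$end[i] - hp$s
    }
    res$stem_length[i] <- hp$stem
    res$loop_length[i] <- hp$loop
    res$mismatches[i] <- hp$mism
    res$distance_to_3prime[i] <- hp$dist
  }
  res
}

# best hairpin in the last window_bp of an oriented element sequence;
# returns list(s, e, stem, loop, mism, dist) with element-relative 0-based
# coordinates, or NULL
.best_hairpin <- function(elem, stem_min, stem_max, loop_max, window_bp,
                          max_mismatch) {
  L <- nchar(elem)
  w0 <- max(0L, L - as.integer(window_bp))
  enc <- encode_dna(.substr0(elem, w0, L))
  n <- length(enc)
  best <- NULL
  for (stem in seq.int(stem_max, stem_min)) {
    for (loop in 0:loop_max) {
      span <- 2L * stem + loop
      if (span > n) next
      for (p in 0:(n - span)) {
        left <- enc[p + seq_len(stem)]
        right <- enc[p + span - seq_len(stem) + 1L]
        valid <- left > 0L & right > 0L
        mism <- sum(!valid | left + right != 5L)
        if (mism > max_mismatch) next
        score <- stem - mism
        dist <- n - (p + span)  # from hairpin end to element 3'-end
        cand <- list(s = w0 + p, e = w0 + p + span, stem = stem, loop = loop,
                     mism = mism, dist = dist, score = score)
        # score desc, then mismatches asc (a clean stem beats a padded one),
        # then distance to the 3'-end asc, then stem desc
        better <- is.null(best) || cand$score > best$score ||
          (cand$score == best$score &&
           (cand$mism < best$mism ||
            (cand$mism == best$mism &&
             (cand$dist < best$dist ||
              (cand$dist == best$dist && cand$stem > best$stem)))))
        if (better) best <- cand
      }
    }
  }
  best
}

#' Flag putative autonomous helitrons
#'
#' An element is flagged putative-autonomous when it is longer than
#' `min_length_bp` (default 10 kb) and its interval overlaps no masked long
#' transposon (e.g. retrotransposon) interval. Length/content proxy only; no
#' ORF or protein-domain annotation is attempted.
#'
#' @param calls `helitron_calls`.
#' @param mask optional data.frame of 0-based half-open intervals
#'   (`seq_id, start, end`), e.g. from [read_mask_bed()].
#' @param min_length_bp length threshold, default 10000.
#' @return logical vector, one per call.
#' @export
flag_putative_autonomous <- function(calls, mask = NULL,
                                     min_length_bp = 10000) {
  long_enough <- calls$length > min_length_bp
  if (is.null(mask) || nrow(mask) == 0L) return(long_enough)
  hit_mask <- vapply(seq_len(nrow(calls)), function(i) {
    m <- mask[mask$seq_id == calls$seq_id[i], , drop = FALSE]
    any(.overlaps(calls$start[i], calls$end[i], m$start, m$end))
  }, logical(1))
  long_enough & !hit_mask
}

#' One-shot helitron calling
#'
#' Scans for termini, pairs them into calls, and annotates flanks, hairpins
#' and the putative-autonomous flag.
#'
#' @param genome genome sequences.
#' @param pass `"strict"`, `"loose"` or `"both"`.
#' @param strand_mode `"both"` or `"forward"`.
#' @param max_span_bp pairing span limit, default 20000.
#' @param mask optional long-transposon interval mask.
#' @return `helitron_calls` with annotation columns; the underlying hit set
#'   is attached as attribute `"hits"`.
#' @export
call_helitrons <- function(genome, pass = c("strict", "loose", "both"),
                           strand_mode = c("both", "forward"),
                           max_span_bp = 20000, mask = NULL) {
  pass <- match.arg(pass)
  strand_mode <- match.arg(strand_mode)
  levels <- if (pass == "both") c("loose", "strict") else pass
  hits <- scan_termini(genome, helitron_patterns(levels), strand_mode)
  calls <- pair_termini(hits, max_span_bp = max_span_bp)
  calls <- annotate_flanks(calls, genome)
  hp <- detect_hairpin(calls, genome)
  calls <- cbind(calls, hp)
  calls$putative_autonomous <- flag_putative_autonomous(calls, mask)
  attr(calls, "hits") <- hits
  class(calls) <- c("helitron_calls", "data.frame")
  calls
}
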