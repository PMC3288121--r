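# BLASTN-like local similarity search: exact-seed + per-diagonal maximal
# segment extension + short-gap chaining. Used for homology-based discovery,
# boundary validation, tiered copy-number counting and segment decomposition.
#
# Matching is ungapped along each diagonal; chains across nearby diagonals
# absorb small indels. Identity is computed over aligned columns, coverage
# over query length. All coordinates 0-based half-open.

# k-mer codes of an encoded sequence; NA where the window contains N
.kmer_codes <- function(enc, k) {
  n <- length(enc)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  v <- ifelse(enc == 0L, NA_real_, as.numeric(enc - 1L))
  code <- numeric(m)
  for (i in seq_len(k)) code <- code * 4 + v[i:(m + i - 1L)]
  code
}

# sorted k-mer index of a subject sequence
.kmer_index <- function(enc, k) {
  codes <- .kmer_codes(enc, k)
  pos <- which(!is.na(codes))
  codes <- codes[pos]
  o <- order(codes)
  list(codes = codes[o], pos = pos[o] - 1L, k = k)  # 0-based positions
}

# seed matches (0-based qp, sp) of query codes against a subject index
.find_seeds <- function(q_enc, idx) {
  qcodes <- .kmer_codes(q_enc, idx$k)
  qp <- which(!is.na(qcodes))
  qcodes <- qcodes[qp]
  if (length(qcodes) == 0L || length(idx$codes) == 0L)
    return(list(qp = integer(0), sp = integer(0)))
  hi <- findInterval(qcodes, idx$codes)
  lo <- findInterval(qcodes - 0.5, idx$codes) + 1L
  nhit <- hi - lo + 1L
  keep <- nhit > 0L
  if (!any(keep)) return(list(qp = integer(0), sp = integer(0)))
  qp <- qp[keep]; lo <- lo[keep]; nhit <- nhit[keep]
  sidx <- sequence(nhit, from = lo)
  list(qp = rep(qp - 1L, nhit), sp = idx$pos[sidx])
}

# all maximal ungapped segments with score >= min_score on a score vector;
# returns data.frame(i, j, score) of 1-based inclusive segment bounds
.max_segments <- function(x, min_score) {
  out <- list()
  repeat {
    cum <- cumsum(x)
    prev <- c(0, cum[-length(cum)])
    pmin_ <- cummin(prev)
    sc <- cum - pmin_
    j <- which.max(sc)
    best <- sc[j]
    if (!is.finite(best) || best < min_score) break
    i <- max(which(prev[seq_len(j)] == pmin_[j]))
    out[[length(out) + 1L]] <- c(i = i, j = j, score = best)
    x[i:j] <- -Inf
    if (length(out) > 50L) break
  }
  if (!length(out)) return(data.frame(i = integer(0), j = integer(0),
                                      score = numeric(0)))
  as.data.frame(do.call(rbind, out))
}

# HSPs from seeds on one subject: per-diagonal maximal scoring segments
.diagonal_hsps <- function(q_enc, s_enc, seeds, match, mismatch, min_score) {
  if (length(seeds$qp) == 0L)
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      matches = integer(0), length = integer(0),
                      score = numeric(0)))
  Lq <- length(q_enc); Ls <- length(s_enc)
  diags <- seeds$sp - seeds$qp
  rows <- list()
  for (d in unique(diags)) {
    # overlap range of the diagonal in query coordinates (0-based)
    r0 <- max(0L, -d)
    r1 <- min(Lq, Ls - d) - 1L
    if (r1 < r0) next
    qi <- r0:r1
    qq <- q_enc[qi + 1L]
    ss <- s_enc[qi + d + 1L]
    m <- qq > 0L & qq == ss
    x <- ifelse(m, match, mismatch)
    segs <- .max_segments(x, min_score)
    for (r in seq_len(nrow(segs))) {
      a <- r0 + segs$i[r] - 1L  # 0-based query start
      b <- r0 + segs$j[r]       # 0-based query end (half-open)
      rows[[length(rows) + 1L]] <- data.frame(
        q_start = a, q_end = b, s_start = a + d, s_end = b + d,
        matches = sum(m[(segs$i[r]):(segs$j[r])]), length = b - a,
        score = segs$score[r])
    }
  }
  if (!length(rows)) return(data.frame(q_start = integer(0),
                                       q_end = integer(0),
                                       s_start = integer(0),
                                       s_end = integer(0),
                                       matches = integer(0),
                                       length = integer(0),
                                       score = numeric(0)))
  do.call(rbind, rows)
}

# chain collinear HSPs with small gaps (absorbs short indels); greedy in
# query order. band bounds the diagonal shift, max_gap the unaligned gap.
.chain_hsps <- function(h, band = 15, max_gap = 20, gap_penalty = -3) {
  if (nrow(h) <= 1L) return(h)
  h <- h[order(h$q_start, h$s_start), , drop = FALSE]
  used <- rep(FALSE, nrow(h))
  out <- list()
  for (i in seq_len(nrow(h))) {
    if (used[i]) next
    cur <- h[i, , drop = FALSE]
    used[i] <- TRUE
    repeat {
      qg <- h$q_start - cur$q_end
      sg <- h$s_start - cur$s_end
      ok <- !used & qg > -5 & sg > -5 & qg <= max_gap & sg <= max_gap &
        abs(qg - sg) <= band
      if (!any(ok)) break
      j <- which(ok)[1]
      used[j] <- TRUE
      gap <- max(qg[j], sg[j], 0)
      cur$q_end <- max(cur$q_end, h$q_end[j])
      cur$s_end <- max(cur$s_end, h$s_end[j])
      cur$matches <- cur$matches + h$matches[j]
      cur$length <- cur$length + h$length[j] + gap
      cur$score <- cur$score + h$score[j] + gap_penalty * gap
    }
    out[[length(out) + 1L]] <- cur
  }
  do.call(rbind, out)
}

#' Local similarity search (seed-and-extend)
#'
#' An in-package stand-in for BLASTN: exact seeds of length `seed_k` are
#' extended into maximal-scoring ungapped segments along each diagonal
#' (match +1, mismatch -2 by default), then collinear segments separated by
#' small gaps are chained. Both strands are searched; overlapping hits at a
#' subject locus are merged keeping the best score.
#'
#' @param query query sequence (character or `DNAString(Set)` of length 1).
#' @param genome subject sequences.
#' @param min_len_bp minimum aligned length to report.
#' @param min_identity minimum percent identity to report.
#' @param seed_k exact seed length (default 11).
#' @param match,mismatch,gap_penalty scoring parameters.
#' @param band maximum diagonal shift when chaining across small indels.
#' @param max_gap maximum unaligned gap chained over.
#' @param min_score minimum segment score kept before filtering.
#' @param strand_mode `"both"` or `"forward"`.
#' @return data.frame of class `local_alignments`: `s_seq, s_start, s_end,
#'   q_start, q_end, strand, length, matches, identity, coverage, score`.
#'   Query coordinates always refer to the forward query.
#' @export
local_search <- function(query, genome, min_len_bp = 25, min_identity = 70,
                         seed_k = 11, match = 1, mismatch = -2,
                         gap_penalty = -3, band = 15, max_gap = 20,
                         min_score = 14, strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  q <- .single_seq_chars(query)
  G <- .genome_chars(genome)
  Lq <- nchar(q)
  if (Lq < seed_k)
    stop("query (", Lq, " bp) is shorter than the seed size (", seed_k, ")")
  strands <- if (strand_mode == "both") c("+", "-") else "+"
  rows <- list()
  for (sid in names(G)) {
    s_enc <- encode_dna(G[[sid]])
    idx <- .kmer_index(s_enc, seed_k)
    for (strand in strands) {
      q_or <- if (strand == "+") q else revcomp(q)
      q_enc <- encode_dna(q_or)
      seeds <- .find_seeds(q_enc, idx)
      h <- .diagonal_hsps(q_enc, s_enc, seeds, match, mismatch, min_score)
      if (nrow(h) == 0L) next
      h <- .chain_hsps(h, band = band, max_gap = max_gap,
                       gap_penalty = gap_penalty)
      # map oriented query coordinates back to the forward query
      if (strand == "-") {
        qs <- Lq - h$q_end; qe <- Lq - h$q_start
        h$q_start <- qs; h$q_end <- qe
      }
      h$s_seq <- sid
      h$strand <- strand
      rows[[length(rows) + 1L]] <- h
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(q_start = integer(0), q_end = integer(0),
               s_start = integer(0), s_end = integer(0),
               matches = integer(0), length = integer(0), score = numeric(0),
               s_seq = character(0), strand = character(0))
  out$identity <- ifelse(out$length > 0, 100 * out$matches / out$length, 0)
  out$coverage <- 100 * (out$q_end - out$q_start) / Lq
  out <- out[out$length >= min_len_bp & out$identity >= min_identity, ,
             drop = FALSE]
  # merge overlapping hits per subject locus, keeping the best score
  if (nrow(out) > 1L) {
    out <- out[order(-out$score), , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))[-1]) {
      prior <- which(keep[seq_len(i - 1L)])
      same <- out$s_seq[prior] == out$s_seq[i]
      ov_len <- pmin(out$s_end[prior], out$s_end[i]) -
        pmax(out$s_start[prior], out$s_start[i])
      shorter <- pmin(out$s_end[prior] - out$s_start[prior],
                      out$s_end[i] - out$s_start[i])
      if (any(same & ov_len > 0.5 * shorter)) keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$s_seq, out$s_start, out$s_end), , drop = FALSE]
  out <- out[, c("s_seq", "s_start", "s_end", "q_start", "q_end", "strand",
                 "length", "matches", "identity", "coverage", "score")]
  rownames(out) <- NULL
  class(out) <- c("local_alignments", "data.frame")
  out
}

#' Seed-based element discovery
#'
#' Uses the first and last `probe_bp` of each known (seed) element as
#' terminus probes. Loci where a seed's 5'-probe aligns (> 25 bp, identity
#' > 70%) and a downstream 3'-probe aligns (> 25 bp, identity > 80%) on the
#' same strand within less than `max_span_bp` are returned as candidate
#' elements.
#'
#' @param seed_elements named character vector or `DNAStringSet` of validated
#'   elements.
#' @param genome genome sequences.
#' @param probe_bp probe length taken from each element end (default 50).
#' @param five_min_len,five_min_id 5'-probe thresholds (strict >).
#' @param three_min_len,three_min_id 3'-probe thresholds (strict >).
#' @param max_span_bp pairing span (strict <), default 20000.
#' @return data.frame of candidate intervals: `seq_id, start, end, strand,
#'   seed_id`.
#' @export
seed_discovery <- function(seed_elements, genome, probe_bp = 50,
                           five_min_len = 25, five_min_id = 70,
                           three_min_len = 25, three_min_id = 80,
                           max_span_bp = 20000) {
  seeds <- .genome_chars(seed_elements)
  G <- .genome_chars(genome)
  rows <- list()
  for (sd in names(seeds)) {
    el <- seeds[[sd]]
    L <- nchar(el)
    p5 <- .substr0(el, 0L, min(probe_bp, L))
    p3 <- .substr0(el, max(0L, L - probe_bp), L)
    h5 <- local_search(p5, G, min_len_bp = five_min_len + 1L,
                       min_identity = five_min_id)
    h5 <- h5[h5$identity > five_min_id & h5$length > five_min_len, ,
             drop = FALSE]
    h3 <- local_search(p3, G, min_len_bp = three_min_len + 1L,
                       min_identity = three_min_id)
    h3 <- h3[h3$identity > three_min_id & h3$length > three_min_len, ,
             drop = FALSE]
    if (nrow(h5) == 0L || nrow(h3) == 0L) next
    for (i in seq_len(nrow(h5))) {
      cand <- h3[h3$s_seq == h5$s_seq[i] & h3$strand == h5$strand[i], ,
                 drop = FALSE]
      if (h5$strand[i] == "+") {
        cand <- cand[cand$s_start >= h5$s_end[i] &
                     cand$s_end - h5$s_start[i] < max_span_bp, , drop = FALSE]
        if (nrow(cand) == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = h5$s_seq[i], start = h5$s_start[i],
          end = max(cand$s_end), strand = "+", seed_id = sd,
          stringsAsFactors = FALSE)
      } else {
        cand <- cand[cand$s_end <= h5$s_start[i] &
                     h5$s_end[i] - cand$s_start < max_span_bp, , drop = FALSE]
        if (nrow(cand) == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = h5$s_seq[i], start = min(cand$s_start),
          end = h5$s_end[i], strand = "-", seed_id = sd,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), seed_id = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$seq_id, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate element boundaries across copies
#'
#' Multicopy families are trimmed/confirmed by aligning their copies: each
#' locus is extended outward until the flanking columns diverge across copies
#' (windowed column identity below `threshold`). With identical flanks
#' (tandem duplication) the boundary is flagged unresolvable; a single copy
#' cannot be refined.
#'
#' @param copies data.frame of copy loci: `seq_id, start, end, strand`
#'   (e.g. subject intervals from [local_search()]).
#' @param genome genome sequences.
#' @param window column-identity window (bp), default 10.
#' @param threshold mean column identity below which flanks have diverged,
#'   default 0.6.
#' @param max_extend_bp how far outward to look, default 200.
#' @return `copies` with columns `five_boundary`, `three_boundary` (genome
#'   coordinates per copy) and a shared `resolved` flag.
#' @export
validate_boundaries <- function(copies, genome, window = 10, threshold = 0.6,
                                max_extend_bp = 200) {
  G <- .genome_chars(genome)
  n <- nrow(copies)
  if (n < 2L) {
    copies$five_boundary <- copies$start
    copies$three_boundary <- copies$end
    copies$resolved <- FALSE
    warning("fewer than 2 copies: boundaries left unrefined")
    return(copies)
  }
  if (is.null(copies$strand)) copies$strand <- "+"
  # matrix of flanking bases per copy at offsets 1..max_extend_bp,
  # strand-oriented, on each side
  flank_mat <- function(side) {
    m <- matrix(NA_integer_, nrow = n, ncol = max_extend_bp)
    for (i in seq_len(n)) {
      seqc <- G[[copies$seq_id[i]]]
      L <- nchar(seqc)
      plus_left <- (copies$strand[i] == "+") == (side == "five")
      if (plus_left) {
        lo <- max(0L, copies$start[i] - max_extend_bp)
        s <- .substr0(seqc, lo, copies$start[i])
        e <- rev(encode_dna(s))             # offset 1 = adjacent base
      } else {
        hi <- min(L, copies$end[i] + max_extend_bp)
        s <- .substr0(seqc, copies$end[i], hi)
        e <- encode_dna(s)
      }
      if (copies$strand[i] == "-") e <- ifelse(e == 0L, 0L, 5L - e)
      if (length(e)) m[i, seq_along(e)] <- e
    }
    m
  }
  extension <- function(m) {
    # column identity = fraction of copy pairs that agree (robust for small
    # copy numbers: ~0.25 on unrelated sequence, 1 on conserved columns)
    ident <- vapply(seq_len(ncol(m)), function(j) {
      col <- m[, j]
      col <- col[!is.na(col) & col > 0L]
      n <- length(col)
      if (n < 2L) return(0)
      cnt <- tabulate(col, 4L)
      sum(cnt * (cnt - 1) / 2) / (n * (n - 1) / 2)
    }, numeric(1))
    nw <- length(ident) - window + 1L
    if (nw < 1L) return(list(ext = 0L, resolved = TRUE))
    wmean <- vapply(seq_len(nw), function(j) mean(ident[j:(j + window - 1L)]),
                    numeric(1))
    bad <- which(wmean < threshold)
    if (length(bad) == 0L) return(list(ext = NA_integer_, resolved = FALSE))
    list(ext = bad[1] - 1L, resolved = TRUE)
  }
  e5 <- extension(flank_mat("five"))
  e3 <- extension(flank_mat("three"))
  resolved <- e5$resolved && e3$resolved
  ext5 <- if (e5$resolved) e5$ext else 0L
  ext3 <- if (e3$resolved) e3$ext else 0L
  plus <- copies$strand == "+"
  copies$five_boundary <- ifelse(plus, copies$start - ext5,
                                 copies$start - ext3)
  copies$three_boundary <- ifelse(plus, copies$end + ext3,
                                  copies$end + ext5)
  copies$resolved <- resolved
  if (!resolved)
    warning("flanks do not diverge within ", max_extend_bp,
            " bp: boundary unresolvable (identical flanks?)")
  copies
}

#' Copy-number tier definitions
#'
#' The four standard tiers, strictest first: coverage/identity >95/95,
#' >90/90, >85/85, and the relaxed aligned-length tier (>200 bp, identity
#' >80%). The relaxed tier uses aligned length, not query coverage.
#'
#' @return data.frame with `name, min_coverage, min_length, min_identity`.
#' @export
copy_tiers <- function() {
  data.frame(
    name = c("cov95_id95", "cov90_id90", "cov85_id85", "len200_id80"),
    min_coverage = c(95, 90, 85, NA),
    min_length = c(NA, NA, NA, 200),
    min_identity = c(95, 90, 85, 80),
    stringsAsFactors = FALSE)
}

#' Tiered copy-number counting
#'
#' Counts distinct non-overlapping subject loci of an element per tier
#' (greedy by score). Counts must be non-decreasing from the strictest to
#' the most relaxed tier; a violation raises a warning.
#'
#' @param element element sequence.
#' @param genome genome sequences.
#' @param tiers tier definitions, default [copy_tiers()].
#' @param ... passed to [local_search()].
#' @return `tiers` with a `copy_count` column added.
#' @export
count_copies <- function(element, genome, tiers = copy_tiers(), ...) {
  el <- .single_seq_chars(element)
  min_id <- min(tiers$min_identity) - 2
  min_len <- min(c(tiers$min_length[!is.na(tiers$min_length)], 50))
  hits <- local_search(el, genome, min_len_bp = min_len,
                       min_identity = min_id, ...)
  counts <- integer(nrow(tiers))
  for (t in seq_len(nrow(tiers))) {
    sel <- hits$identity > tiers$min_identity[t]
    if (!is.na(tiers$min_coverage[t]))
      sel <- sel & hits$coverage > tiers$min_coverage[t]
    if (!is.na(tiers$min_length[t]))
      sel <- sel & hits$length > tiers$min_length[t]
    h <- hits[sel, , drop = FALSE]
    # greedy non-overlap by score
    h <- h[order(-h$score), , drop = FALSE]
    taken <- h[0, , drop = FALSE]
    for (i in seq_len(nrow(h))) {
      same <- taken$s_seq == h$s_seq[i]
      if (!any(same & .overlaps(taken$s_start, taken$s_end,
                                h$s_start[i], h$s_end[i])))
        taken <- rbind(taken, h[i, , drop = FALSE])
    }
    counts[t] <- nrow(taken)
  }
  tiers$copy_count <- counts
  if (is.unsorted(counts))
    warning("copy counts are not monotone from strict to relaxed tiers")
  tiers
}
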