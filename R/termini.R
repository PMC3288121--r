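# Pseudo-terminus scanning, multiple-termini profiling, and nested
# transposition read-out prediction.
#
# Internal terminal structures inside a larger element are "pseudo termini".
# Real 3'-termini carry a highly conserved CTAG motif; pseudo 3'-termini have
# decayed to CTAT. Pseudo 5'-termini show no sequence difference from real
# ones, so 5'-hits inside element bodies are classified by position alone.

#' Scan for pseudo 3'-termini
#'
#' Scans the genome for the pseudo 3'-terminus consensus (the strict helA
#' 3'-motif with CTAG decayed to CTAT). With `exclude_real = TRUE` (default),
#' matches whose locus also completes a real strict CTAG(T) 3'-terminus are
#' excluded from the pseudo set and reported with `ctag_intact = TRUE`
#' instead, so the pseudo set never swallows real termini.
#'
#' @param genome genome sequences.
#' @param strand_mode `"both"` or `"forward"`.
#' @param exclude_real drop pseudo matches overlapping a real strict
#'   3'-terminus match.
#' @return `terminus_hits` data.frame with an added logical `ctag_intact`
#'   column: FALSE for pseudo (CTAT) hits, TRUE for loci reported as real.
#' @export
scan_pseudo_3prime <- function(genome, strand_mode = c("both", "forward"),
                               exclude_real = TRUE) {
  strand_mode <- match.arg(strand_mode)
  pseudo <- scan_termini(genome, helitron_patterns("pseudo"), strand_mode)
  pseudo$ctag_intact <- rep(FALSE, nrow(pseudo))
  if (!exclude_real || nrow(pseudo) == 0L) return(pseudo)
  real <- scan_termini(genome,
                       helitron_patterns("strict", family = "helA"),
                       strand_mode)
  real <- real[real$end_type == "three_prime", , drop = FALSE]
  if (nrow(real) == 0L) return(pseudo)
  drop <- vapply(seq_len(nrow(pseudo)), function(i) {
    r <- real[real$seq_id == pseudo$seq_id[i] &
              real$strand == pseudo$strand[i], , drop = FALSE]
    any(.overlaps(pseudo$start[i], pseudo$end[i], r$start, r$end))
  }, logical(1))
  if (any(drop)) {
    real$ctag_intact <- TRUE
    out <- rbind(pseudo[!drop, , drop = FALSE], real)
    out <- out[order(out$seq_id, out$start, out$end), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "seqlengths") <- attr(pseudo, "seqlengths")
    class(out) <- class(pseudo)
    return(out)
  }
  pseudo
}

#' Profile multiple-termini structure of helitron calls
#'
#' For each call, counts distinct 5'- and 3'-terminus loci strictly inside
#' the element body (position-classified pseudo termini) in addition to the
#' element's own termini, and flags which internal 3'-structures retain an
#' intact CTAG. Distinct loci are counted by strand-oriented start (5') or
#' end (3'), matching the motif anchor sides.
#'
#' @param calls `helitron_calls`.
#' @param hits the full `terminus_hits` set from the same genome; may include
#'   pseudo-pattern hits from [scan_pseudo_3prime()].
#' @return list with `per_call` (data.frame: call_id, n_termini_5,
#'   n_termini_3, n_internal_5, n_internal_3, n_internal_3_ctag_intact) and
#'   `summary` (fractions of calls with more than one terminus per end).
#' @export
profile_multi_termini <- function(calls, hits) {
  stopifnot(is.data.frame(calls), is.data.frame(hits))
  n <- nrow(calls)
  per <- data.frame(call_id = if (n) calls$call_id else character(0),
                    n_termini_5 = integer(n), n_termini_3 = integer(n),
                    n_internal_5 = integer(n), n_internal_3 = integer(n),
                    n_internal_3_ctag_intact = integer(n),
                    stringsAsFactors = FALSE)
  sl <- attr(hits, "seqlengths")
  for (i in seq_len(n)) {
    s <- calls$start[i]; e <- calls$end[i]
    h <- hits[hits$seq_id == calls$seq_id[i] &
              hits$strand == calls$strand[i] &
              hits$family == calls$family[i], , drop = FALSE]
    inside <- h[h$start > s & h$end < e, , drop = FALSE]
    # orient: the element's own 5' locus sits at its start (+) / end (-)
    f <- inside[inside$end_type == "five_prime" &
                inside$pass_level != "pseudo", , drop = FALSE]
    t3 <- inside[inside$end_type == "three_prime", , drop = FALSE]
    if (calls$strand[i] == "+") {
      n_int5 <- length(unique(f$start))
      key3 <- unique(t3$end)
    } else {
      n_int5 <- length(unique(f$end))
      key3 <- unique(t3$start)
    }
    n_int3 <- length(key3)
    intact <- t3[!duplicated(if (calls$strand[i] == "+") t3$end else t3$start), ,
                 drop = FALSE]
    n_int3_ctag <- sum(grepl("CTAGT$", intact$matched_text))
    per$n_internal_5[i] <- n_int5
    per$n_internal_3[i] <- n_int3
    per$n_internal_3_ctag_intact[i] <- n_int3_ctag
    per$n_termini_5[i] <- 1L + n_int5
    per$n_termini_3[i] <- 1L + n_int3
  }
  list(per_call = per,
       summary = list(
         frac_multi_5 = if (n) mean(per$n_termini_5 > 1L) else NA_real_,
         frac_multi_3 = if (n) mean(per$n_termini_3 > 1L) else NA_real_))
}

#' Build a nested helitron configuration
#'
#' Describes a stack of same-family elements, each inserted within the body
#' of the previous one (outermost first). Each element contributes one
#' 5'-terminus position and one 3'-terminus position on a shared coordinate
#' axis; nesting requires `five_pos` strictly increasing and `three_pos`
#' strictly decreasing from outer to inner.
#'
#' @param element_id character ids, outermost first.
#' @param five_pos 5'-terminus positions (bp, element starts).
#' @param three_pos 3'-terminus positions (bp, element ends).
#' @param family shared family label.
#' @return object of class `nested_config`.
#' @examples
#' cfg <- nested_config(c("outer", "mid", "inner"),
#'                      five_pos = c(0, 200, 400),
#'                      three_pos = c(1500, 1200, 900))
#' @export
nested_config <- function(element_id, five_pos, three_pos, family = "helA") {
  stopifnot(length(element_id) >= 1L,
            length(five_pos) == length(element_id),
            length(three_pos) == length(element_id))
  if (anyDuplicated(element_id)) stop("element ids must be unique")
  if (any(five_pos >= three_pos))
    stop("each element's 5'-terminus must precede its 3'-terminus")
  k <- length(element_id)
  if (k > 1L) {
    if (any(diff(five_pos) <= 0) || any(diff(three_pos) >= 0))
      stop("elements must be strictly nested, outermost first")
  }
  structure(
    data.frame(element_id = element_id, five_pos = five_pos,
               three_pos = three_pos, family = family,
               level = seq_len(k), stringsAsFactors = FALSE),
    class = c("nested_config", "data.frame"))
}

#' Predict the products of a nested-helitron transposition
#'
#' A rolling-circle read-out launched from one element's 5'-terminus copies
#' the sequence from that terminus through the outermost element's final
#' 3'-terminus. The product therefore carries every 3'-terminus at or
#' downstream of the launch point and every 5'-terminus in that span; the
#' remnant retains the complement. Pure interval bookkeeping - no replication
#' chemistry is modeled.
#'
#' @param config a [nested_config()].
#' @param launch element id whose 5'-terminus fires.
#' @return list with `product` and `remnant`, each
#'   `c(n_termini_5 =, n_termini_3 =)`, plus the product `span`
#'   (c(start, end)).
#' @examples
#' cfg <- nested_config(c("outer", "mid", "inner"),
#'                      five_pos = c(0, 200, 400),
#'                      three_pos = c(1500, 1200, 900))
#' predict_nested_products(cfg, "inner")$product  # three 3'-termini
#' @export
predict_nested_products <- function(config, launch) {
  stopifnot(inherits(config, "nested_config"))
  i <- match(launch, config$element_id)
  if (is.na(i))
    stop("launch terminus '", launch, "' is not in the configuration")
  span <- c(config$five_pos[i], max(config$three_pos))
  in5 <- config$five_pos >= span[1] & config$five_pos <= span[2]
  in3 <- config$three_pos >= span[1] & config$three_pos <= span[2]
  prod <- c(n_termini_5 = sum(in5), n_termini_3 = sum(in3))
  remn <- c(n_termini_5 = sum(!in5), n_termini_3 = sum(!in3))
  if (length(config$element_id) == 1L) {
    # identity case: a lone element transposes wholesale, leaving nothing
    remn <- c(n_termini_5 = 0L, n_termini_3 = 0L)
  }
  list(product = prod, remnant = remn, span = span)
}
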