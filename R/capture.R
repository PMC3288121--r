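# Segment decomposition of related elements and inference of stepwise
# capture / internal-loss / nested-insertion histories.
#
# Related helitrons share mosaics of homologous segments: the same captured
# gene fragment shows up in several elements at >85% identity, interleaved
# with element-specific sequence. Decomposing each element into an ordered
# string of shared block ids turns event inference into string edits:
# one contiguous novel run inserted = capture, one contiguous internal run
# deleted = loss, one element's full string embedded in another = nested
# insertion. A capture read forward is a loss read backward, so single-pair
# directions stay flagged ambiguous unless a third element breaks the tie.

#' Decompose related elements into shared segment blocks
#'
#' All-vs-all local alignments (via [local_search()]) are used to split each
#' element at alignment breakpoints (propagated across elements to a fixed
#' point) and to cluster the resulting atomic segments transitively into
#' shared block ids. Each element is then an ordered string of block ids;
#' unaligned runs become element-specific unique blocks. Blocks shorter than
#' `min_block_bp` are treated as indel noise and dropped from the strings.
#'
#' @param elements named character vector or `DNAStringSet`, length >= 2.
#'   Elements are assumed co-oriented.
#' @param min_identity minimum percent identity for a shared block (>85% is
#'   the conventional coloring threshold).
#' @param min_block_bp minimum block length (default 50).
#' @param tol breakpoint snapping tolerance in bp (default 10).
#' @return object of class `segment_blocks`: list with `blocks` (data.frame
#'   `element_id, start, end, block_id, identity, is_unique`), `strings`
#'   (per-element character vectors of block ids), and `elements`.
#' @export
decompose_segments <- function(elements, min_identity = 85,
                               min_block_bp = 50, tol = 10) {
  els <- .genome_chars(elements)
  if (length(els) < 2L) stop("need at least 2 elements")
  ids <- names(els)
  lens <- vapply(els, nchar, integer(1))

  # pairwise alignments (forward orientation)
  alns <- list()
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1L):length(ids)) {
      h <- local_search(els[[i]], els[j], min_len_bp = min_block_bp,
                        min_identity = min_identity, strand_mode = "forward")
      if (nrow(h) == 0L) next
      h$A <- ids[i]; h$B <- ids[j]
      alns[[length(alns) + 1L]] <- h
    }
  }
  aln <- if (length(alns)) do.call(rbind, alns) else NULL

  bps <- lapply(lens, function(L) c(0L, L))
  names(bps) <- ids
  add_bp <- function(cur, new) {
    new <- new[new > 0 & !vapply(new, function(b) any(abs(cur - b) <= tol),
                                 logical(1))]
    sort(unique(c(cur, new)))
  }
  if (!is.null(aln)) {
    # alignment endpoints are breakpoints themselves
    for (r in seq_len(nrow(aln))) {
      bps[[aln$A[r]]] <- add_bp(bps[[aln$A[r]]],
                                c(aln$q_start[r], aln$q_end[r]))
      bps[[aln$B[r]]] <- add_bp(bps[[aln$B[r]]],
                                c(aln$s_start[r], aln$s_end[r]))
    }
  }
  if (!is.null(aln)) {
    for (iter in 1:20) {
      changed <- FALSE
      for (r in seq_len(nrow(aln))) {
        A <- aln$A[r]; B <- aln$B[r]
        qs <- aln$q_start[r]; qe <- aln$q_end[r]
        ss <- aln$s_start[r]; se <- aln$s_end[r]
        sc <- (se - ss) / (qe - qs)
        bA <- bps[[A]]; bB <- bps[[B]]
        inA <- bA[bA >= qs & bA <= qe]
        mapped <- as.integer(round(ss + (inA - qs) * sc))
        nB <- add_bp(bB, mapped)
        inB <- bB[bB >= ss & bB <= se]
        mappedA <- as.integer(round(qs + (inB - ss) / sc))
        nA <- add_bp(bA, mappedA)
        if (length(nA) != length(bA)) { bps[[A]] <- nA; changed <- TRUE }
        if (length(nB) != length(bB)) { bps[[B]] <- nB; changed <- TRUE }
      }
      if (!changed) break
    }
  }

  # atomic segments per element
  seg <- do.call(rbind, lapply(ids, function(el) {
    b <- bps[[el]]
    data.frame(element_id = el, start = b[-length(b)], end = b[-1],
               stringsAsFactors = FALSE)
  }))
  seg$node <- seq_len(nrow(seg))

  # link atomic segments across elements through alignments
  edges <- list()
  seg_ident <- rep(NA_real_, nrow(seg))
  if (!is.null(aln)) {
    for (r in seq_len(nrow(aln))) {
      A <- aln$A[r]; B <- aln$B[r]
      qs <- aln$q_start[r]; qe <- aln$q_end[r]
      ss <- aln$s_start[r]; se <- aln$s_end[r]
      sc <- (se - ss) / (qe - qs)
      sa <- seg[seg$element_id == A, , drop = FALSE]
      sa <- sa[pmin(sa$end, qe) - pmax(sa$start, qs) >
               0.5 * (sa$end - sa$start), , drop = FALSE]
      if (nrow(sa) == 0L) next
      sb_all <- seg[seg$element_id == B, , drop = FALSE]
      for (u in seq_len(nrow(sa))) {
        img_s <- ss + (max(sa$start[u], qs) - qs) * sc
        img_e <- ss + (min(sa$end[u], qe) - qs) * sc
        ov <- pmin(sb_all$end, img_e) - pmax(sb_all$start, img_s)
        hit <- ov > 0.5 * pmin(sb_all$end - sb_all$start, img_e - img_s)
        for (v in which(hit)) {
          edges[[length(edges) + 1L]] <- c(sa$node[u], sb_all$node[v])
          seg_ident[sa$node[u]] <-
            max(seg_ident[sa$node[u]], aln$identity[r], na.rm = TRUE)
          seg_ident[sb_all$node[v]] <-
            max(seg_ident[sb_all$node[v]], aln$identity[r], na.rm = TRUE)
        }
      }
    }
  }

  g <- igraph::make_empty_graph(n = nrow(seg), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, as.integer(t(do.call(rbind, edges))))
  comp <- igraph::components(g)$membership
  linked <- if (length(edges))
    unique(unlist(edges)) else integer(0)

  seg$identity <- seg_ident
  seg$is_unique <- !(seg$node %in% linked)
  seg$block_id <- ifelse(seg$is_unique,
                         paste0("U_", seg$element_id, "_", seg$node),
                         paste0("B", comp))
  too_small <- (seg$end - seg$start) < min_block_bp
  seg$drop <- too_small

  # merge consecutive blocks whose adjacency is identical in every element
  strings <- lapply(ids, function(el) {
    s <- seg[seg$element_id == el & !seg$drop, , drop = FALSE]
    s$block_id[order(s$start)]
  })
  names(strings) <- ids
  repeat {
    pair_next <- list()
    ok_merge <- character(0)
    # candidate pairs: (x, y) consecutive somewhere
    occ <- function(b) names(Filter(function(s) b %in% s, strings))
    pairs <- unique(do.call(rbind, lapply(strings, function(s) {
      if (length(s) < 2L) return(NULL)
      cbind(s[-length(s)], s[-1])
    })))
    merged <- FALSE
    if (!is.null(pairs)) for (r in seq_len(nrow(pairs))) {
      x <- pairs[r, 1]; y <- pairs[r, 2]
      if (startsWith(x, "U_") || startsWith(y, "U_")) next
      ex <- occ(x); ey <- occ(y)
      if (!setequal(ex, ey)) next
      always <- all(vapply(ex, function(el) {
        s <- strings[[el]]
        ix <- which(s == x); iy <- which(s == y)
        length(ix) == 1L && length(iy) == 1L && iy == ix + 1L
      }, logical(1)))
      if (!always) next
      for (el in ex) {
        s <- strings[[el]]
        iy <- which(s == y)
        strings[[el]] <- s[-iy]
      }
      seg$block_id[seg$block_id == y] <- x
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  # merge block rows in seg that became the same id and are adjacent
  out_blocks <- do.call(rbind, lapply(ids, function(el) {
    s <- seg[seg$element_id == el & !seg$drop, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L) {
      runs <- rle(s$block_id)
      last <- cumsum(runs$lengths)
      first <- last - runs$lengths + 1L
      s <- do.call(rbind, lapply(seq_along(first), function(k) {
        r <- s[first[k]:last[k], , drop = FALSE]
        r$end[1] <- max(r$end)
        r$identity[1] <- suppressWarnings(max(r$identity, na.rm = TRUE))
        r[1, , drop = FALSE]
      }))
    }
    s
  }))
  out_blocks <- out_blocks[, c("element_id", "start", "end", "block_id",
                               "identity", "is_unique")]
  rownames(out_blocks) <- NULL
  structure(list(blocks = out_blocks, strings = strings, elements = els),
            class = "segment_blocks")
}

#' @export
print.segment_blocks <- function(x, ...) {
  cat("<segment_blocks>", length(x$elements), "elements,",
      length(unique(x$blocks$block_id[!x$blocks$is_unique])),
      "shared blocks\n")
  for (el in names(x$strings))
    cat(" ", el, ":", paste(x$strings[[el]], collapse = " "), "\n")
  invisible(x)
}

# longest common prefix / suffix length of two character vectors
.lcp <- function(a, b) {
  n <- min(length(a), length(b))
  i <- 0L
  while (i < n && a[i + 1L] == b[i + 1L]) i <- i + 1L
  i
}
.lcs <- function(a, b) .lcp(rev(a), rev(b))

# single-indel comparison of block strings: does long == short with one
# contiguous run inserted? returns the inserted run indices in long, or NULL
.single_insert_run <- function(short, long) {
  if (length(long) <= length(short)) return(NULL)
  p <- .lcp(short, long)
  s <- .lcs(short, long)
  s <- min(s, length(short) - p)
  if (p + s != length(short)) return(NULL)
  run <- (p + 1L):(length(long) - s)
  run
}

#' Infer capture / loss / nested-insertion events among related elements
#'
#' For every ordered element pair (P, C): a `capture` edge P -> C is emitted
#' when C's block string equals P's with exactly one contiguous novel run
#' inserted; a `loss` edge when C equals P with one contiguous internal run
#' deleted; a `nested_insertion` edge when C's full block string appears as a
#' contiguous run inside P. Every emitted edge replays exactly on the block
#' strings (checked internally). Because a capture forward is a loss
#' backward, paired edges are flagged `ambiguous`; a third element sharing
#' the parent configuration orients the pair (parsimony tie-break).
#'
#' @param seg a [decompose_segments()] result.
#' @return object of class `derivation_graph`: list with `edges` (data.frame
#'   `parent, child, type, blocks, start, end, ambiguous`), `graph`
#'   (directed `igraph`, one edge per event), `strings`, and
#'   `hypothetical_nodes` (reserved; always empty here).
#' @export
infer_events <- function(seg) {
  stopifnot(inherits(seg, "segment_blocks"))
  strings <- seg$strings
  ids <- names(strings)
  blocks <- seg$blocks
  edges <- list()
  interval_of_run <- function(el, run_blocks) {
    b <- blocks[blocks$element_id == el &
                blocks$block_id %in% run_blocks, , drop = FALSE]
    if (nrow(b) == 0L) return(c(NA_integer_, NA_integer_))
    c(min(b$start), max(b$end))
  }
  for (P in ids) for (C in setdiff(ids, P)) {
    sP <- strings[[P]]; sC <- strings[[C]]
    if (length(sP) == 0L || length(sC) == 0L) next
    run <- .single_insert_run(sP, sC)
    if (!is.null(run) && !any(sC[run] %in% sP)) {
      iv <- interval_of_run(C, sC[run])
      edges[[length(edges) + 1L]] <- data.frame(
        parent = P, child = C, type = "capture",
        blocks = paste(sC[run], collapse = ","),
        start = iv[1], end = iv[2], ambiguous = TRUE,
        stringsAsFactors = FALSE)
    }
    run <- .single_insert_run(sC, sP)   # C = P minus a run
    if (!is.null(run) && !any(sP[run] %in% sC)) {
      iv <- interval_of_run(P, sP[run])
      edges[[length(edges) + 1L]] <- data.frame(
        parent = P, child = C, type = "loss",
        blocks = paste(sP[run], collapse = ","),
        start = iv[1], end = iv[2], ambiguous = TRUE,
        stringsAsFactors = FALSE)
    }
    # C fully embedded in P (and P strictly larger)
    if (length(sC) < length(sP)) {
      nP <- length(sP); nC <- length(sC)
      for (off in 0:(nP - nC)) {
        if (identical(sP[(off + 1L):(off + nC)], sC)) {
          iv <- interval_of_run(P, sC)
          edges[[length(edges) + 1L]] <- data.frame(
            parent = P, child = C, type = "nested_insertion",
            blocks = paste(sC, collapse = ","),
            start = iv[1], end = iv[2], ambiguous = TRUE,
            stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(parent = character(0), child = character(0),
               type = character(0), blocks = character(0),
               start = integer(0), end = integer(0), ambiguous = logical(0),
               stringsAsFactors = FALSE)

  # parsimony orientation: a capture P->C whose inserted run occurs in no
  # third element, while P's configuration is shared by a third element,
  # is oriented (the run is derived in C)
  if (nrow(ed) && length(ids) >= 3L) {
    for (r in which(ed$type == "capture")) {
      run_blocks <- strsplit(ed$blocks[r], ",", fixed = TRUE)[[1]]
      others <- setdiff(ids, c(ed$parent[r], ed$child[r]))
      run_elsewhere <- any(vapply(others, function(o)
        any(run_blocks %in% strings[[o]]), logical(1)))
      parent_shared <- any(vapply(others, function(o)
        all(strings[[ed$parent[r]]] %in% strings[[o]]), logical(1)))
      if (!run_elsewhere && parent_shared) {
        ed$ambiguous[r] <- FALSE
        mirror <- ed$type == "loss" & ed$parent == ed$child[r] &
          ed$child == ed$parent[r] & ed$blocks == ed$blocks[r]
        ed$ambiguous[mirror] <- FALSE
      }
    }
  }

  # internal round-trip check: every edge must replay on the block strings
  ok <- vapply(seq_len(nrow(ed)), function(r) {
    identical(.replay_blocks(strings[[ed$parent[r]]], ed[r, , drop = FALSE],
                             strings[[ed$child[r]]]),
              strings[[ed$child[r]]])
  }, logical(1))
  if (length(ok) && !all(ok)) ed <- ed[ok, , drop = FALSE]

  g <- igraph::graph_from_data_frame(
    ed[, c("parent", "child"), drop = FALSE], directed = TRUE,
    vertices = data.frame(name = ids))
  structure(list(edges = ed, graph = g, strings = strings,
                 hypothetical_nodes = character(0)),
            class = "derivation_graph")
}

# apply one edge's event to a parent block string; the child string fixes
# the edit position. The inserted/deleted run is novel w.r.t. the other
# element, so the common prefix locates the edit exactly.
.replay_blocks <- function(parent, edge, child) {
  run <- strsplit(edge$blocks, ",", fixed = TRUE)[[1]]
  if (edge$type == "capture") {
    p <- .lcp(parent, child)
    append(parent, run, after = p)
  } else if (edge$type == "loss") {
    p <- .lcp(parent, child)
    if (p + length(run) > length(parent)) return(NULL)
    parent[-((p + 1L):(p + length(run)))]
  } else {  # nested_insertion: reading out the child extracts the run
    run
  }
}

#' @export
print.derivation_graph <- function(x, ...) {
  cat("<derivation_graph>", length(x$strings), "elements,",
      nrow(x$edges), "event edges\n")
  if (nrow(x$edges))
    print(utils::head(x$edges[, c("parent", "child", "type", "ambiguous")],
                      20))
  invisible(x)
}

#' Minimal-event derivation paths between two elements
#'
#' Every edge is one event, so minimal-event explanations are shortest
#' directed paths in the derivation graph.
#'
#' @param dg a [infer_events()] result.
#' @param from,to element ids.
#' @return list of character vectors (node sequences); empty when no path.
#' @export
minimal_event_paths <- function(dg, from, to) {
  stopifnot(inherits(dg, "derivation_graph"))
  if (!(from %in% names(dg$strings)) || !(to %in% names(dg$strings)))
    stop("unknown element id")
  sp <- suppressWarnings(
    igraph::all_shortest_paths(dg$graph, from = from, to = to,
                               mode = "out"))
  lapply(sp$vpaths, function(p) igraph::V(dg$graph)$name[as.integer(p)])
}

#' Replay a list of events on a parent sequence
#'
#' Applies capture (insert), loss (delete) and nested_insertion (insert)
#' events in order to a parent DNA string; used to verify inferred
#' histories. Each event is a list with `type`, and either `at` + `seq`
#' (insertions) or `start` + `end` (loss, 0-based half-open, optionally
#' `expect` to check the deleted text).
#'
#' @param parent DNA character string.
#' @param events list of event lists.
#' @return the derived child sequence.
#' @export
replay_events <- function(parent, events) {
  x <- .single_seq_chars(parent)
  for (k in seq_along(events)) {
    ev <- events[[k]]
    bad <- function(msg) stop("event ", k, " (", ev$type, "): ", msg)
    if (ev$type %in% c("capture", "nested_insertion")) {
      if (is.null(ev$at) || is.null(ev$seq)) bad("needs 'at' and 'seq'")
      if (ev$at < 0 || ev$at > nchar(x)) bad("insertion point out of range")
      x <- paste0(.substr0(x, 0L, ev$at), toupper(ev$seq),
                  .substr0(x, ev$at, nchar(x)))
    } else if (ev$type == "loss") {
      if (is.null(ev$start) || is.null(ev$end)) bad("needs 'start' and 'end'")
      if (ev$start < 0 || ev$end > nchar(x) || ev$start >= ev$end)
        bad("interval out of range")
      if (!is.null(ev$expect) &&
          !identical(.substr0(x, ev$start, ev$end), toupper(ev$expect)))
        bad("sequence at interval does not match expected text")
      x <- paste0(.substr0(x, 0L, ev$start), .substr0(x, ev$end, nchar(x)))
    } else bad("unknown event type")
  }
  x
}
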