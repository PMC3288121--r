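# Synthetic genomes with planted helitrons and full ground truth.
#
# The generator states a world: i.i.d. background at a chosen GC, elements
# whose termini are sampled from the strict-pass pattern languages, A...T
# insertion sites, a 16 bp sub-terminal palindrome, captured gene-fragment
# stand-ins copied from the background, decayed (CTAT) pseudo 3'-termini,
# extra internal 5'-termini, and nested insertions. Every planted feature is
# recorded so the caller, termini and homology modules can be scored against
# exact truth without downloads.

#' Random DNA string
#'
#' @param n length in bp.
#' @param gc GC fraction.
#' @return character string.
#' @export
random_dna <- function(n, gc = 0.47) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Sample a random string from a pattern's language
#'
#' Quantifier repeat counts are drawn uniformly, then each position uniformly
#' from its allowed bases, so all match lengths (and the full pattern
#' language) are exercised.
#'
#' @param pattern a [terminus_pattern()].
#' @return character string matching the pattern.
#' @export
sample_pattern_string <- function(pattern) {
  stopifnot(inherits(pattern, "terminus_pattern"))
  out <- character(0)
  for (a in pattern$atoms) {
    reps <- if (a$max > a$min) sample(a$min:a$max, 1L) else a$min
    if (reps > 0L) {
      picks <- a$allow[sample.int(length(a$allow), reps, replace = TRUE)]
      out <- c(out, .DNA_BASES[picks])
    }
  }
  paste(out, collapse = "")
}

#' Simulation configuration
#'
#' Defaults state the documented world: element sizes 128-20,874 bp
#' (log-uniform, matching the observed small-size skew), background GC 0.47,
#' over 90% of elements carrying a captured fragment, 28.7% of helAs with an
#' internal (pseudo) 3'-terminus and 17.6% with an internal 5'-terminus,
#' helBs never multi-termini. Probabilities are realized as deterministic
#' proportions (round(p * n), randomly assigned) so truth fractions are
#' reproducible. Insertion sites are kept at least `min_gap_bp` (default the
#' 20 kb pairing span) apart: closer same-family neighbours would be merged
#' into a single call by the pairing rule itself.
#'
#' @param genome_length background length in bp.
#' @param gc_fraction background GC.
#' @param n_helA,n_helB planted element counts per family.
#' @param element_length_range sampled element length range (bp).
#' @param p_capture fraction of elements carrying a captured fragment.
#' @param capture_length_range captured fragment length range (bp).
#' @param p_pseudo3 fraction of helAs with a planted internal pseudo
#'   3'-terminus (CTAT).
#' @param p_internal5 fraction of helAs with a planted internal 5'-terminus.
#' @param p_nested fraction of elements nested inside another element.
#' @param p_minus fraction of elements planted on the minus strand.
#' @param min_gap_bp minimum distance between insertion sites.
#' @param seed random seed fixing all randomness; `NULL` uses the current
#'   RNG state.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 100000, gc_fraction = 0.47,
                              n_helA = 5, n_helB = 2,
                              element_length_range = c(128, 20874),
                              p_capture = 0.9,
                              capture_length_range = c(300, 1500),
                              p_pseudo3 = 0.287, p_internal5 = 0.176,
                              p_nested = 0.1, p_minus = 0.5,
                              min_gap_bp = 20000, seed = NULL) {
  cfg <- list(genome_length = genome_length, gc_fraction = gc_fraction,
              n_helA = n_helA, n_helB = n_helB,
              element_length_range = element_length_range,
              p_capture = p_capture,
              capture_length_range = capture_length_range,
              p_pseudo3 = p_pseudo3, p_internal5 = p_internal5,
              p_nested = p_nested, p_minus = p_minus,
              min_gap_bp = min_gap_bp, seed = seed)
  probs <- unlist(cfg[c("p_capture", "p_pseudo3", "p_internal5", "p_nested",
                        "p_minus")])
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (genome_length < 1000) stop("genome_length too small")
  if (diff(element_length_range) < 0 || element_length_range[1] < 100)
    stop("bad element_length_range")
  class(cfg) <- "simulation_config"
  cfg
}

# log-uniform integer sample in [lo, hi]
.rlogunif <- function(n, lo, hi) {
  if (hi <= lo) return(rep(as.integer(lo), n))
  as.integer(round(exp(stats::runif(n, log(lo), log(hi)))))
}

# deterministic-proportion assignment: round(p * n) of n, randomly chosen
.assign_frac <- function(n, p) {
  k <- round(p * n)
  flags <- rep(FALSE, n)
  if (k > 0L && n > 0L) flags[sample.int(n, min(k, n))] <- TRUE
  flags
}

# build one element's oriented sequence and relative feature table
.build_element <- function(id, family, target_len, with_capture, with_pseudo3,
                           with_internal5, background, cfg) {
  p5 <- helitron_patterns("strict", family = family)
  five <- sample_pattern_string(p5[[which(vapply(p5, `[[`, "", "end_type") ==
                                          "five_prime")]])
  three <- sample_pattern_string(p5[[which(vapply(p5, `[[`, "", "end_type") ==
                                           "three_prime")]])
  stem <- random_dna(8, 0.5)
  hairpin <- paste0(stem, revcomp(stem))
  captured <- NULL; donor <- c(NA_integer_, NA_integer_)
  if (with_capture) {
    cl <- .rlogunif(1, cfg$capture_length_range[1], cfg$capture_length_range[2])
    ds <- sample.int(nchar(background) - cl, 1L) - 1L
    captured <- .substr0(background, ds, ds + cl)
    donor <- c(ds, ds + cl)
  }
  pseudo <- NULL
  if (with_pseudo3) {
    p <- helitron_patterns("strict", family = "helA")
    real3 <- sample_pattern_string(
      p[[which(vapply(p, `[[`, "", "end_type") == "three_prime")]])
    # decay the conserved CTAG: ...CTAGT -> ...CTATT
    pseudo <- sub("CTAGT$", "CTATT", real3)
  }
  internal5 <- if (with_internal5) sample_pattern_string(
    p5[[which(vapply(p5, `[[`, "", "end_type") == "five_prime")]]) else NULL

  extras <- sum(nchar(captured), nchar(pseudo), nchar(internal5))
  core <- nchar(five) + nchar(three) + nchar(hairpin)
  n_gaps <- 2L + sum(!is.null(captured), !is.null(pseudo),
                     !is.null(internal5))
  need <- core + extras + 15L * n_gaps
  target_len <- max(target_len, need)
  filler_total <- target_len - core - extras
  spare <- filler_total - n_gaps * 15L
  gap_lens <- 15L + tabulate(sample.int(n_gaps, spare, replace = TRUE),
                             n_gaps)

  pieces <- list(five)
  kinds <- data.frame(kind = "terminus_5", len = nchar(five), aux = NA,
                      stringsAsFactors = FALSE)
  gi <- 1L
  add <- function(seq, kind, aux = NA) {
    pieces[[length(pieces) + 1L]] <<- seq
    kinds <<- rbind(kinds, data.frame(kind = kind, len = nchar(seq),
                                      aux = aux, stringsAsFactors = FALSE))
  }
  add(random_dna(gap_lens[gi], cfg$gc_fraction), "filler"); gi <- gi + 1L
  if (!is.null(captured)) {
    add(captured, "captured", paste(donor, collapse = "-"))
    add(random_dna(gap_lens[gi], cfg$gc_fraction), "filler"); gi <- gi + 1L
  }
  if (!is.null(internal5)) {
    add(internal5, "internal_5")
    add(random_dna(gap_lens[gi], cfg$gc_fraction), "filler"); gi <- gi + 1L
  }
  if (!is.null(pseudo)) {
    add(pseudo, "pseudo_3")
    add(random_dna(gap_lens[gi], cfg$gc_fraction), "filler"); gi <- gi + 1L
  }
  add(hairpin, "hairpin")
  add(three, "terminus_3")

  seqs <- unlist(pieces)
  ends <- cumsum(kinds$len)
  feats <- data.frame(kind = kinds$kind, rel_start = c(0L, ends[-length(ends)]),
                      rel_end = ends, aux = kinds$aux,
                      stringsAsFactors = FALSE)
  feats <- feats[feats$kind != "filler", , drop = FALSE]
  list(id = id, family = family, seq = paste(seqs, collapse = ""),
       features = feats, five_seq = five, three_seq = three,
       children = list())
}

# insert a child element into a parent's filler, A...T flanked; returns the
# modified parent (or NULL when no room)
.nest_into <- function(parent, child) {
  Lp <- nchar(parent$seq)
  occupied <- parent$features[, c("rel_start", "rel_end")]
  for (ch in parent$children)
    occupied <- rbind(occupied,
                      data.frame(rel_start = ch$offset,
                                 rel_end = ch$offset + nchar(ch$elem$seq)))
  # candidate insertion points: interior, 2 bp clear of any feature
  gaps <- list()
  bounds <- occupied[order(occupied$rel_start), , drop = FALSE]
  prev <- 0L
  for (i in seq_len(nrow(bounds))) {
    if (bounds$rel_start[i] - prev >= 12L)
      gaps[[length(gaps) + 1L]] <- c(prev + 4L, bounds$rel_start[i] - 4L)
    prev <- max(prev, bounds$rel_end[i])
  }
  if (Lp - prev >= 12L) gaps[[length(gaps) + 1L]] <- c(prev + 4L, Lp - 4L)
  if (!length(gaps)) return(NULL)
  g <- gaps[[sample.int(length(gaps), 1L)]]
  q <- if (g[2] > g[1]) sample(g[1]:g[2], 1L) else g[1]
  Lc <- nchar(child$seq)
  s <- parent$seq
  s <- paste0(.substr0(s, 0L, q - 1L), "A", child$seq, "T",
              .substr0(s, q + 1L, Lp))
  # host bases at q-1 / q were overwritten by A / T; child sits at [q, q+Lc)
  shift <- Lc
  f <- parent$features
  f$rel_start <- ifelse(f$rel_start >= q, f$rel_start + shift, f$rel_start)
  f$rel_end <- ifelse(f$rel_end > q, f$rel_end + shift, f$rel_end)
  parent$features <- f
  for (k in seq_along(parent$children)) {
    if (parent$children[[k]]$offset >= q)
      parent$children[[k]]$offset <- parent$children[[k]]$offset + shift
  }
  parent$seq <- s
  parent$children[[length(parent$children) + 1L]] <-
    list(elem = child, offset = q)
  parent
}

#' Generate a synthetic genome with planted helitrons
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_genome` with `genome` (`DNAStringSet`,
#'   one sequence `chr1`) and `truth`: `elements` (data.frame of absolute
#'   0-based half-open intervals with family, strand, terminus sequences,
#'   flanks, hairpin and nesting parent), `features` (per-element planted
#'   captured / pseudo-3' / internal-5' / hairpin intervals in absolute
#'   coordinates), `events` (simulation-order log) and `config`.
#' @examples
#' g <- generate_genome(simulation_config(genome_length = 20000, n_helA = 1,
#'                                        n_helB = 0, p_nested = 0,
#'                                        element_length_range = c(500, 2000),
#'                                        seed = 7))
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, {
    cfg <- config
    n <- cfg$n_helA + cfg$n_helB
    events <- list()
    log_ev <- function(type, id, detail = "")
      events[[length(events) + 1L]] <<- data.frame(
        step = length(events) + 1L, type = type, element_id = id,
        detail = detail, stringsAsFactors = FALSE)

    background <- random_dna(cfg$genome_length, cfg$gc_fraction)
    if (n == 0L) {
      truth <- list(
        elements = data.frame(element_id = character(0)),
        features = data.frame(element_id = character(0)),
        events = data.frame(step = integer(0), type = character(0),
                            element_id = character(0), detail = character(0)),
        config = cfg)
      g <- Biostrings::DNAStringSet(c(chr1 = background))
      return(structure(list(genome = g, truth = truth),
                       class = "synthetic_genome"))
    }

    fam <- c(rep("helA", cfg$n_helA), rep("helB", cfg$n_helB))
    lens <- .rlogunif(n, cfg$element_length_range[1],
                      cfg$element_length_range[2])
    minus <- .assign_frac(n, cfg$p_minus)
    capt <- .assign_frac(n, cfg$p_capture)
    is_a <- fam == "helA"
    pseudo <- rep(FALSE, n); pseudo[is_a] <- .assign_frac(sum(is_a),
                                                          cfg$p_pseudo3)
    int5 <- rep(FALSE, n); int5[is_a] <- .assign_frac(sum(is_a),
                                                      cfg$p_internal5)
    ids <- sprintf("%s_%02d", fam,
                   as.integer(stats::ave(seq_len(n), fam, FUN = seq_along)))
    elems <- vector("list", n)
    for (i in seq_len(n)) {
      elems[[i]] <- .build_element(ids[i], fam[i], lens[i], capt[i],
                                   pseudo[i], int5[i], background, cfg)
      log_ev("plant", ids[i],
             sprintf("family=%s len=%d capture=%s pseudo3=%s internal5=%s",
                     fam[i], nchar(elems[[i]]$seq), capt[i], pseudo[i],
                     int5[i]))
    }
    names(elems) <- ids

    # nesting: child elements move inside a parent (same family & strand).
    # Arbitrary depth is allowed (an element may nest into an already-nested
    # one); trees are materialized bottom-up so coordinates stay consistent.
    n_nest <- round(cfg$p_nested * n)
    parent_of <- stats::setNames(rep(NA_character_, n), ids)
    root_of <- function(id) {
      while (!is.na(parent_of[[id]])) id <- parent_of[[id]]
      id
    }
    tree_size <- function(root)
      sum(vapply(ids[vapply(ids, function(x) root_of(x) == root, logical(1))],
                 function(x) nchar(elems[[x]]$seq), integer(1)))
    if (n_nest > 0L) {
      for (k in seq_len(n_nest)) {
        free <- ids[is.na(parent_of[ids])]
        placed <- FALSE
        for (child_id in sample(free)) {
          cand <- setdiff(ids, child_id)
          cand <- cand[fam[match(cand, ids)] == fam[match(child_id, ids)] &
                       minus[match(cand, ids)] == minus[match(child_id, ids)]]
          cand <- cand[vapply(cand, function(p) root_of(p) != child_id,
                              logical(1))]
          cand <- cand[vapply(cand, function(p)
            tree_size(root_of(p)) + tree_size(child_id) < 19500, logical(1))]
          if (!length(cand)) next
          parent_of[[child_id]] <- cand[sample.int(length(cand), 1L)]
          placed <- TRUE
          break
        }
        if (!placed) break
      }
    }
    # embed children bottom-up (a child goes in only after its own children)
    pending <- which(!is.na(parent_of))
    while (length(pending)) {
      progressed <- FALSE
      for (ci in pending) {
        child_id <- ids[ci]
        if (child_id %in% parent_of[ids[pending]]) next  # still a pending parent
        parent_id <- parent_of[[child_id]]
        upd <- .nest_into(elems[[parent_id]], elems[[child_id]])
        if (is.null(upd)) {
          message("no room to nest ", child_id, " into ", parent_id,
                  "; left top-level")
          parent_of[[child_id]] <- NA_character_
        } else {
          elems[[parent_id]] <- upd
          log_ev("nested_insertion", child_id, paste0("parent=", parent_id))
        }
        pending <- setdiff(pending, ci)
        progressed <- TRUE
        break
      }
      if (!progressed) break
    }
    top_ids <- ids[is.na(parent_of[ids])]

    # insertion sites in background space, >= min_gap_bp apart
    m <- length(top_ids)
    lo <- cfg$min_gap_bp
    hi <- cfg$genome_length - cfg$min_gap_bp
    if (hi - lo < (m - 1L) * cfg$min_gap_bp)
      stop("cannot fit ", m, " elements ", cfg$min_gap_bp,
           " bp apart in a ", cfg$genome_length,
           " bp background; lower n or min_gap_bp")
    repeat {
      sites <- sort(sample(lo:hi, m))
      if (m <= 1L || all(diff(sites) >= cfg$min_gap_bp)) break
    }
    top_ids <- sample(top_ids)  # random order along the genome

    # host A...T at each site, then splice left to right
    bg <- strsplit(background, "", fixed = TRUE)[[1]]
    for (p in sites) { bg[p] <- "A"; bg[p + 1L] <- "T" }
    background <- paste(bg, collapse = "")
    # host bases: A at 0-based sites[i]-1, T at 0-based sites[i];
    # the element is spliced in between, occupying [sites[i], sites[i]+L)
    pieces <- character(0)
    prev <- 0L
    for (i in seq_len(m)) {
      el <- elems[[top_ids[i]]]
      ins <- if (minus[match(top_ids[i], ids)]) revcomp(el$seq) else el$seq
      pieces <- c(pieces, .substr0(background, prev, sites[i]), ins)
      prev <- sites[i]
    }
    pieces <- c(pieces, .substr0(background, prev, nchar(background)))
    final <- paste(pieces, collapse = "")
    ins_lens <- vapply(top_ids, function(id) nchar(elems[[id]]$seq),
                       integer(1))
    abs_start <- sites + c(0L, cumsum(ins_lens))[seq_len(m)]

    # background -> final coordinate mapping for donor intervals
    bg2final <- function(x) x + vapply(x, function(xx)
      sum(ins_lens[sites <= xx]), numeric(1))

    # recursively record truth rows
    el_rows <- list(); feat_rows <- list()
    place <- function(el, a_start, strand, parent_id) {
      L <- nchar(el$seq)
      a_end <- a_start + L
      orient <- function(rs, re) {
        if (strand == "+") c(a_start + rs, a_start + re)
        else c(a_end - re, a_end - rs)
      }
      hp <- el$features[el$features$kind == "hairpin", ][1, ]
      hpa <- orient(hp$rel_start, hp$rel_end)
      el_rows[[length(el_rows) + 1L]] <<- data.frame(
        element_id = el$id, seq_id = "chr1", start = a_start, end = a_end,
        strand = strand, family = el$family, length = L,
        five_seq = el$five_seq, three_seq = el$three_seq,
        hairpin_start = hpa[1], hairpin_end = hpa[2],
        parent_id = parent_id, stringsAsFactors = FALSE)
      for (r in seq_len(nrow(el$features))) {
        f <- el$features[r, ]
        ab <- orient(f$rel_start, f$rel_end)
        feat_rows[[length(feat_rows) + 1L]] <<- data.frame(
          element_id = el$id, kind = f$kind, start = ab[1], end = ab[2],
          strand = strand, aux = f$aux, stringsAsFactors = FALSE)
      }
      for (ch in el$children) {
        if (strand == "+") {
          ch_start <- a_start + ch$offset
        } else {
          ch_start <- a_end - (ch$offset + nchar(ch$elem$seq))
        }
        place(ch$elem, ch_start, strand, el$id)
      }
    }
    for (i in seq_len(m)) {
      st <- if (minus[match(top_ids[i], ids)]) "-" else "+"
      place(elems[[top_ids[i]]], abs_start[i], st, NA_character_)
    }
    elements <- do.call(rbind, el_rows)
    features <- do.call(rbind, feat_rows)
    # donor coordinates in final space
    cap <- features$kind == "captured" & !is.na(features$aux)
    if (any(cap)) {
      dn <- do.call(rbind, strsplit(features$aux[cap], "-", fixed = TRUE))
      features$donor_start <- NA_real_
      features$donor_end <- NA_real_
      features$donor_start[cap] <- bg2final(as.integer(dn[, 1]))
      features$donor_end[cap] <- bg2final(as.integer(dn[, 2]))
    }
    elements <- elements[order(elements$start), , drop = FALSE]
    rownames(elements) <- NULL
    truth <- list(elements = elements, features = features,
                  events = do.call(rbind, events), config = cfg)
    g <- Biostrings::DNAStringSet(stats::setNames(final, "chr1"))
    structure(list(genome = g, truth = truth), class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("<synthetic_genome>", sum(Biostrings::width(x$genome)), "bp,",
      nrow(x$truth$elements), "planted elements\n")
  invisible(x)
}

#' Write synthetic truth to disk
#'
#' Emits `<prefix>.fasta`, `<prefix>.truth.bed`, `<prefix>.truth.json` and
#' `<prefix>.events.log`.
#'
#' @param sim a [generate_genome()] result.
#' @param prefix output path prefix.
#' @return invisibly, the written paths.
#' @export
write_synthetic <- function(sim, prefix) {
  stopifnot(inherits(sim, "synthetic_genome"))
  paths <- c(fasta = paste0(prefix, ".fasta"),
             bed = paste0(prefix, ".truth.bed"),
             json = paste0(prefix, ".truth.json"),
             log = paste0(prefix, ".events.log"))
  write_genome(sim$genome, paths["fasta"])
  el <- sim$truth$elements
  if (nrow(el)) {
    gr <- GenomicRanges::GRanges(el$seq_id,
                                 IRanges::IRanges(el$start + 1L, el$end),
                                 strand = el$strand)
    names(gr) <- el$element_id
    rtracklayer::export(gr, paths["bed"], format = "BED")
  } else cat("", file = paths["bed"])
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths["json"], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(sim$truth$events, paths["log"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Mutated copies of an element
#'
#' Substitution-only divergence: each site independently mutates to one of
#' the three other bases with the given probability. Supports copy-number
#' tier tests with a binomial identity oracle.
#'
#' @param element element sequence.
#' @param n number of copies.
#' @param divergence per-site substitution probability, in \[0, 0.3\].
#' @param seed optional seed.
#' @return list with `copies` (character vector) and `realized_identity`
#'   (percent, per copy).
#' @export
mutate_copies <- function(element, n, divergence, seed = NULL) {
  stopifnot(divergence >= 0, divergence <= 0.3)
  el <- .single_seq_chars(element)
  .with_seed(seed, {
    L <- nchar(el)
    base <- strsplit(el, "", fixed = TRUE)[[1]]
    copies <- character(n)
    ident <- numeric(n)
    for (i in seq_len(n)) {
      v <- base
      mut <- which(stats::runif(L) < divergence)
      for (m in mut) v[m] <- sample(setdiff(.DNA_BASES, v[m]), 1L)
      copies[i] <- paste(v, collapse = "")
      ident[i] <- 100 * (1 - length(mut) / L)
    }
    list(copies = copies, realized_identity = ident)
  })
}

#' Forward-simulate a stepwise capture/loss history
#'
#' Starts from a random ancestral element and applies `n_events` sequential
#' capture (insert a novel fragment) or loss (delete an internal run)
#' events, keeping every intermediate stage as an element. Event footprints
#' are kept at least `margin` bp from every earlier event's footprint, so
#' each step stays individually discernible: overlapping or adjacent events
#' compress into a single edit and the longer true history is then (rightly)
#' no longer a minimal explanation. The true chain and event list are
#' returned for recovery tests against [decompose_segments()] +
#' [infer_events()].
#'
#' @param n_events number of events (<= 5 is the tested regime).
#' @param base_len ancestral element length (bp).
#' @param p_capture probability an event is a capture (vs loss).
#' @param capture_range,loss_range event size ranges (bp).
#' @param margin minimum distance between event footprints (bp).
#' @param gc background GC.
#' @param seed optional seed.
#' @return list with `elements` (named character vector, e1..e(k+1) in true
#'   order), `events` (list of replayable event lists) and `chain`
#'   (character vector of element ids).
#' @export
simulate_capture_history <- function(n_events = 3, base_len = 2000,
                                     p_capture = 0.7,
                                     capture_range = c(300, 800),
                                     loss_range = c(200, 500), margin = 100,
                                     gc = 0.47, seed = NULL) {
  .with_seed(seed, {
    cur <- random_dna(base_len, gc)
    elements <- c(e1 = cur)
    events <- list()
    foot <- matrix(numeric(0), ncol = 2)  # event footprints, current coords
    clear_of_feet <- function(s, e) {
      !any(foot[, 1] < e + margin & s - margin < foot[, 2])
    }
    shift_feet <- function(at, delta) {
      if (nrow(foot)) {
        foot[foot[, 1] >= at, 1] <<- foot[foot[, 1] >= at, 1] + delta
        foot[foot[, 2] > at, 2] <<- foot[foot[, 2] > at, 2] + delta
      }
    }
    for (k in seq_len(n_events)) {
      L <- nchar(cur)
      ev <- NULL
      for (try in 1:100) {
        if (stats::runif(1) < p_capture || L < loss_range[2] + 400L) {
          sz <- sample(capture_range[1]:capture_range[2], 1L)
          at <- sample(150:(L - 150L), 1L)
          if (!clear_of_feet(at, at)) next
          ev <- list(type = "capture", at = at, seq = random_dna(sz, gc))
          shift_feet(at, sz)
          foot <- rbind(foot, c(at, at + sz))
        } else {
          sz <- sample(loss_range[1]:loss_range[2], 1L)
          st <- sample(150:(L - 150L - sz), 1L)
          if (!clear_of_feet(st, st + sz)) next
          ev <- list(type = "loss", start = st, end = st + sz)
          shift_feet(st + sz, -sz)
          foot <- rbind(foot, c(st, st))
        }
        break
      }
      if (is.null(ev))
        stop("could not place event ", k, " clear of earlier footprints; ",
             "use a longer base element or fewer events")
      cur <- replay_events(cur, list(ev))
      events[[k]] <- ev
      elements[paste0("e", k + 1L)] <- cur
    }
    list(elements = elements, events = events,
         chain = paste0("e", seq_len(n_events + 1L)))
  })
}
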