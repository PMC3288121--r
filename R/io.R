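# Sequence and annotation input/output.
#
# Conventions: internal coordinates are 0-based half-open on the forward
# strand. BED output keeps that convention; GFF3 is 1-based inclusive
# (start + 1). FASTA output of minus-strand features is reverse-complemented.

#' Read a genome from a FASTA file
#'
#' Loads all records, uppercases residues and records soft-masked (lowercase)
#' runs as a mask track. IUPAC ambiguity codes other than N are converted to
#' N with a message; non-IUPAC characters are a parse error naming the line.
#'
#' @param path FASTA file.
#' @return `DNAStringSet`; soft-masked intervals (0-based half-open
#'   data.frame) are attached as `metadata()$mask`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  buf <- character(0)
  flush <- function() {
    if (!is.null(cur)) {
      ids <<- c(ids, cur)
      seqs <<- c(seqs, paste(buf, collapse = ""))
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      flush()
      cur <- trimws(sub("^>", "", ln))
      cur <- strsplit(cur, "[[:space:]]+")[[1]][1]
      if (is.na(cur) || !nzchar(cur))
        stop("malformed FASTA header at line ", i)
      buf <- character(0)
    } else {
      ln <- trimws(ln)
      if (!nzchar(ln)) next
      if (is.null(cur))
        stop("sequence before any FASTA header at line ", i)
      if (grepl("[^ACGTUNRYSWKMBDHVacgtunryswkmbdhv]", ln))
        stop("non-IUPAC character in FASTA at line ", i)
      buf <- c(buf, ln)
    }
  }
  flush()
  if (length(ids) == 0L) {
    warning("empty FASTA file: ", path)
    return(Biostrings::DNAStringSet())
  }
  if (anyDuplicated(ids))
    stop("duplicate sequence id in FASTA: ", ids[duplicated(ids)][1])

  # soft-mask track from lowercase runs, 0-based half-open
  mask <- list()
  for (k in seq_along(seqs)) {
    lc <- gregexpr("[a-z]+", seqs[k])[[1]]
    if (lc[1] != -1L) {
      mask[[length(mask) + 1L]] <- data.frame(
        seq_id = ids[k], start = as.integer(lc) - 1L,
        end = as.integer(lc) + attr(lc, "match.length") - 1L,
        stringsAsFactors = FALSE)
    }
  }
  mask <- if (length(mask)) do.call(rbind, mask) else
    data.frame(seq_id = character(0), start = integer(0), end = integer(0))

  up <- toupper(seqs)
  amb <- gsub("[^ACGTN]", "N", up)
  if (!identical(amb, up))
    message("IUPAC ambiguity codes converted to N")
  out <- Biostrings::DNAStringSet(amb)
  names(out) <- ids
  S4Vectors::metadata(out)$mask <- mask
  out
}

#' Write sequences to FASTA
#'
#' @param seqs `DNAStringSet` or named character vector.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_genome <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(.genome_chars(seqs))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# GFF3 feature type for a call/hit row
.gff_type <- function(df) {
  if (!is.null(df$end_type)) {
    ifelse(df$pass_level == "pseudo", "pseudo_terminus",
           ifelse(df$end_type == "five_prime", "terminus_5", "terminus_3"))
  } else rep("helitron", nrow(df))
}

.calls_granges <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$seq_id,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
  meta_cols <- setdiff(names(df), c("seq_id", "start", "end", "strand",
                                    "three_hits"))
  for (col in meta_cols) S4Vectors::mcols(gr)[[col]] <- df[[col]]
  S4Vectors::mcols(gr)$type <- .gff_type(df)
  gr
}

#' Convert calls or hits to GRanges
#'
#' 1-based `GRanges` (the Bioconductor convention) carrying family, pass
#' level, flags and termini counts as metadata columns.
#' @param x a `helitron_calls` or `terminus_hits` data.frame.
#' @return `GRanges`.
#' @export
calls_to_granges <- function(x) .calls_granges(as.data.frame(x))

#' Write helitron calls or terminus hits to a file
#'
#' @param calls `helitron_calls` or `terminus_hits` data.frame.
#' @param path output file.
#' @param format one of `"bed"` (BED6, 0-based half-open), `"gff3"` (1-based
#'   inclusive), `"tsv"`, `"fasta"` (element substring, reverse-complemented
#'   for minus-strand calls; requires `genome`).
#' @param genome genome sequences, needed for `format = "fasta"`.
#' @return invisibly, `path`.
#' @export
write_calls <- function(calls, path, format = c("bed", "gff3", "tsv", "fasta"),
                        genome = NULL) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown output format"))
  df <- as.data.frame(calls)
  df$three_hits <- NULL
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (format == "fasta") {
    if (is.null(genome)) stop("genome is required for FASTA output")
    G <- .genome_chars(genome)
    if (nrow(df) == 0L) {
      cat("", file = path)
      return(invisible(path))
    }
    seqs <- vapply(seq_len(nrow(df)), function(i) {
      s <- .substr0(G[[df$seq_id[i]]], df$start[i], df$end[i])
      if (df$strand[i] == "-") revcomp(s) else s
    }, character(1))
    ids <- if (!is.null(df$call_id)) df$call_id else
      sprintf("%s:%d-%d(%s)", df$seq_id, df$start, df$end, df$strand)
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    Biostrings::writeXStringSet(out, path)
    return(invisible(path))
  }
  if (nrow(df) == 0L) {
    # rtracklayer cannot export empty annotated GRanges; emit headers only
    cat(if (format == "gff3") "##gff-version 3\n" else "", file = path)
    return(invisible(path))
  }
  gr <- .calls_granges(df)
  if (format == "bed") {
    nm <- if (!is.null(df$call_id)) df$call_id else
      if (!is.null(df$family)) df$family else rep(".", nrow(df))
    if (nrow(df)) names(gr) <- make.unique(nm)
    rtracklayer::export(gr, path, format = "BED")
  } else {
    if (nrow(df) && !is.null(df$family)) gr$Name <- df$family
    rtracklayer::export(gr, path, format = "GFF3")
  }
  invisible(path)
}

#' Read an interval mask from a BED file
#'
#' @param path BED file of known long transposons (retrotransposons etc.).
#' @return data.frame with 0-based half-open `seq_id, start, end`.
#' @export
read_mask_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
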