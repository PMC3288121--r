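# Shared low-level helpers: DNA encoding, reverse complement, 0-based slicing.
# Internal coordinates are 0-based half-open everywhere; conversion to 1-based
# happens only at serialization (GFF3) or when calling substr().

# byte -> base code lookup: A=1, C=2, G=3, T=4, anything else (incl. N) = 0
.DNA_CODE <- local({
  m <- integer(256)
  m[utf8ToInt("A") + 1L] <- 1L
  m[utf8ToInt("C") + 1L] <- 2L
  m[utf8ToInt("G") + 1L] <- 3L
  m[utf8ToInt("T") + 1L] <- 4L
  m
})
.DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
encode_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  .DNA_CODE[utf8ToInt(x) + 1L]
}

#' @noRd
decode_dna <- function(code) {
  out <- rep("N", length(code))
  ok <- code > 0L
  out[ok] <- .DNA_BASES[code[ok]]
  paste(out, collapse = "")
}

#' Reverse complement of a DNA character string
#'
#' N and any non-ACGT letter complement to N.
#' @param x single character string.
#' @return character string, the reverse complement.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  v <- chartr("ACGTacgt", "TGCAtgca", x)
  paste(rev(strsplit(v, "", fixed = TRUE)[[1]]), collapse = "")
}

# reverse complement of an encoded vector (0 stays 0)
.revcomp_enc <- function(e) {
  e <- rev(e)
  ifelse(e == 0L, 0L, 5L - e)
}

# 0-based half-open substring
.substr0 <- function(x, start, end) substr(x, start + 1L, end)

# Coerce a genome to a named uppercase character vector.
# Accepts DNAStringSet/BStringSet, a named character vector, or a single
# unnamed string (named "seq1").
.genome_chars <- function(genome) {
  if (methods::is(genome, "XStringSet")) {
    out <- toupper(as.character(genome))
  } else if (is.character(genome)) {
    out <- toupper(genome)
    if (is.null(names(out)) && length(out) == 1L) names(out) <- "seq1"
  } else {
    stop("genome must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == ""))
    stop("all genome sequences must be named")
  if (anyDuplicated(names(out)))
    stop("duplicate sequence id: ", names(out)[duplicated(names(out))][1])
  out
}

# single query sequence as uppercase character scalar
.single_seq_chars <- function(x) {
  if (methods::is(x, "XStringSet")) {
    stopifnot(length(x) == 1L)
    x <- as.character(x)[[1]]
  } else if (methods::is(x, "XString")) {
    x <- as.character(x)
  }
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}

# run code with a locally-seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# do intervals [s1,e1) and [s2,e2) overlap?
.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
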