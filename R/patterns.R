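# Terminal-motif patterns and their compilation.
#
# Helitron termini are described by motif expressions over the DNA alphabet
# with character classes ([GA]) and bounded quantifiers ({6,8}); "." means any
# one of A/C/G/T. N never matches any position, including wildcards, so calls
# stay conservative on gapped assemblies. Every pattern has a finite maximum
# match length, which bounds the scanning window.

#' Construct a terminus pattern
#'
#' Compiles a motif expression into a `terminus_pattern` object. The supported
#' syntax is: literal `A C G T`, `.` (any single base), `[...]` character
#' classes, and bounded quantifiers `{m}` / `{m,n}` applying to the previous
#' atom. Unbounded quantifiers (`+ * ?`) are rejected.
#'
#' @param family element family, `"helA"` or `"helB"`.
#' @param end_type `"five_prime"` or `"three_prime"`.
#' @param pass_level `"loose"`, `"strict"` or `"pseudo"`.
#' @param pattern motif expression string.
#' @return object of class `terminus_pattern`.
#' @examples
#' p <- terminus_pattern("helA", "five_prime", "strict", "ATCT[ATCG]TACTAC.{5}A")
#' max_match_length(p)
#' @export
terminus_pattern <- function(family, end_type, pass_level, pattern) {
  family <- match.arg(family, c("helA", "helB"))
  end_type <- match.arg(end_type, c("five_prime", "three_prime"))
  pass_level <- match.arg(pass_level, c("loose", "strict", "pseudo"))
  structure(
    list(family = family, end_type = end_type, pass_level = pass_level,
         pattern = pattern, atoms = .parse_motif(pattern)),
    class = "terminus_pattern")
}

# parse a motif expression into a list of atoms:
#   atom = list(allow = integer codes in 1:4, min = reps, max = reps)
.parse_motif <- function(expr) {
  expr <- gsub("[[:space:]]", "", expr)
  chars <- strsplit(expr, "", fixed = TRUE)[[1]]
  atoms <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("A", "C", "G", "T")) {
      atoms[[length(atoms) + 1L]] <- list(allow = match(ch, .DNA_BASES),
                                          min = 1L, max = 1L)
      i <- i + 1L
    } else if (ch == ".") {
      atoms[[length(atoms) + 1L]] <- list(allow = 1:4, min = 1L, max = 1L)
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated character class in pattern: ", expr)
      cls <- chars[(i + 1L):(j - 1L)]
      if (!all(cls %in% .DNA_BASES))
        stop("character class may only contain A/C/G/T: ", expr)
      atoms[[length(atoms) + 1L]] <- list(allow = sort(unique(match(cls, .DNA_BASES))),
                                          min = 1L, max = 1L)
      i <- j + 1L
    } else if (ch == "{") {
      if (length(atoms) == 0L) stop("quantifier without preceding atom: ", expr)
      j <- i + 1L
      while (j <= n && chars[j] != "}") j <- j + 1L
      if (j > n) stop("unterminated quantifier in pattern: ", expr)
      q <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      parts <- strsplit(q, ",", fixed = TRUE)[[1]]
      if (!length(parts) %in% 1:2 || !all(grepl("^[0-9]+$", parts)))
        stop("malformed quantifier {", q, "} in pattern: ", expr)
      lo <- as.integer(parts[1])
      hi <- if (length(parts) == 2L) as.integer(parts[2]) else lo
      if (hi < lo) stop("quantifier maximum below minimum in pattern: ", expr)
      k <- length(atoms)
      atoms[[k]]$min <- lo
      atoms[[k]]$max <- hi
      i <- j + 1L
    } else if (ch %in% c("+", "*", "?")) {
      stop("unbounded quantifier '", ch, "' not supported in pattern: ", expr)
    } else {
      stop("unsupported pattern character '", ch, "' in: ", expr)
    }
  }
  if (length(atoms) == 0L) stop("empty pattern")
  atoms
}

#' @export
print.terminus_pattern <- function(x, ...) {
  cat(sprintf("<terminus_pattern> %s %s [%s]  %s\n", x$family,
              sub("_prime", "'", x$end_type), x$pass_level, x$pattern))
  invisible(x)
}

#' Maximum / minimum match length of a terminus pattern
#'
#' The extreme lengths any match of the pattern can have, computed from its
#' (bounded) quantifiers. `max_match_length()` bounds the scanning window.
#'
#' @param pattern a `terminus_pattern`.
#' @return integer, length in bp.
#' @export
max_match_length <- function(pattern) {
  stopifnot(inherits(pattern, "terminus_pattern"))
  sum(vapply(pattern$atoms, function(a) a$max, integer(1)))
}

#' @rdname max_match_length
#' @export
min_match_length <- function(pattern) {
  stopifnot(inherits(pattern, "terminus_pattern"))
  sum(vapply(pattern$atoms, function(a) a$min, integer(1)))
}

# Enumerate a pattern's fixed-length variants. Each variant is a list of
# allowed-code integer vectors, one per position. Variable quantifiers are
# expanded exhaustively so that downstream scanning reports every distinct
# match length at a start position.
.enumerate_variants <- function(pattern, max_variants = 5000L) {
  reps <- lapply(pattern$atoms, function(a) seq.int(a$min, a$max))
  n_comb <- prod(lengths(reps))
  if (n_comb > max_variants)
    stop("pattern expands to too many variants (", n_comb, ")")
  grid <- expand.grid(reps, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(r) {
    counts <- as.integer(grid[r, ])
    pos <- vector("list", sum(counts))
    k <- 0L
    for (ai in seq_along(pattern$atoms)) {
      if (counts[ai] == 0L) next
      for (rr in seq_len(counts[ai])) {
        k <- k + 1L
        pos[[k]] <- pattern$atoms[[ai]]$allow
      }
    }
    pos
  })
}

#' Does a string match a terminus pattern exactly (anchored)?
#'
#' @param pattern a `terminus_pattern`.
#' @param x character string over A/C/G/T/N.
#' @return logical.
#' @export
pattern_matches <- function(pattern, x) {
  stopifnot(inherits(pattern, "terminus_pattern"))
  e <- encode_dna(toupper(x))
  for (v in .enumerate_variants(pattern)) {
    if (length(v) != length(e)) next
    ok <- TRUE
    for (i in seq_along(v)) {
      if (!(e[i] %in% v[[i]])) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# The nine built-in terminal motif strings: four loose, four strict, and the
# pseudo 3'-terminus consensus for helA (decayed CTAG -> CTAT). The space in
# the printed pseudo quantifier "{6, 8}" is normalized to "{6,8}".
.BUILTIN_PATTERN_TABLE <- data.frame(
  family = c("helA", "helA", "helB", "helB",
             "helA", "helA", "helB", "helB",
             "helA"),
  end_type = c("three_prime", "five_prime", "three_prime", "five_prime",
               "three_prime", "five_prime", "three_prime", "five_prime",
               "three_prime"),
  pass_level = c(rep("loose", 4), rep("strict", 4), "pseudo"),
  pattern = c(
    "CCCGT.{6,8}ACG[GA][GA].{6,8}CTAGT",
    "ATC[TC][ATCG]TA[TC]TA[TCA][ATCG]{5,6}AAG",
    "CGCC.{5,7}GGCG.{8,10}CTAGT",
    "ATC[ATCG]{7,8}TTAAAA",
    "CCGT.GCA[AT]CGCACG[GA]{2}.{7}CTAGT",
    "ATCT[ATCG]TACTAC.{5}A",
    "GCGCCC.{4}GGGCGC.{8}CTAGT",
    "ATC[TGA].{4}[TC][AC]TTAAAA",
    "CCGT[ATCG]GCA[AT]CGCACG[AG]{2}[ATCG]{6,8}CTAT"),
  stringsAsFactors = FALSE)

#' Built-in helitron terminal motif patterns
#'
#' Returns the nine built-in terminus patterns: the four loose-pass and four
#' strict-pass 5'/3' motifs for families helA and helB, plus the pseudo
#' 3'-terminus consensus for helA, whose conserved CTAG has decayed to CTAT.
#'
#' @param pass which pass levels to return; any subset of
#'   `c("loose","strict","pseudo")` or `"all"`.
#' @param family optional family filter (`"helA"`, `"helB"`).
#' @return list of `terminus_pattern` objects.
#' @examples
#' length(helitron_patterns("all")) # 9
#' @export
helitron_patterns <- function(pass = c("loose", "strict"), family = NULL) {
  if (identical(pass, "all")) pass <- c("loose", "strict", "pseudo")
  stopifnot(all(pass %in% c("loose", "strict", "pseudo")))
  tab <- .BUILTIN_PATTERN_TABLE
  tab <- tab[tab$pass_level %in% pass, , drop = FALSE]
  if (!is.null(family)) tab <- tab[tab$family %in% family, , drop = FALSE]
  lapply(seq_len(nrow(tab)), function(i)
    terminus_pattern(tab$family[i], tab$end_type[i], tab$pass_level[i],
                     tab$pattern[i]))
}

#' Read terminus patterns from a plain-text config file
#'
#' One pattern per line, whitespace-separated fields:
#' `family end_type pass_level expression`. Lines starting with `#` and blank
#' lines are ignored. Lets users extend or override the built-in families.
#'
#' @param path file path.
#' @return list of `terminus_pattern` objects.
#' @export
read_patterns <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "[[:space:]]+")[[1]]
    if (length(f) != 4L)
      stop("pattern config line ", i, " must have 4 fields: ", lines[i])
    terminus_pattern(f[1], f[2], f[3], f[4])
  })
  out
}
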