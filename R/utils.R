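#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join right_join inner_join anti_join bind_rows bind_cols n
#'   distinct rename relocate pull
#'   across if_else row_number first slice count
#' @importFrom stats median rnorm rpois runif setNames quantile sd
#' @importFrom utils head tail
NULL

# Base qualities are carried as Phred+33 encoded strings (FASTQ convention);
# these helpers move between that encoding and integer vectors.

#' Convert a Phred+33 quality string to integer qualities
#'
#' @param qual Character vector of quality strings.
#' @return A list of integer vectors, one per input string.
#' @export
qual_to_int <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q) || !nzchar(q)) return(integer(0))
    utf8ToInt(q) - 33L
  })
}

#' Convert integer qualities to a Phred+33 string
#'
#' @param q Integer vector of Phred qualities (0--93).
#' @return A single quality string.
#' @export
int_to_qual <- function(q) {
  if (length(q) == 0) return("")
  intToUtf8(pmin(pmax(as.integer(q), 0L), 93L) + 33L)
}

#' Reverse complement DNA strings
#'
#' @param x Character vector of DNA sequences (ACGTN).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- character(length(x))
  nz <- nzchar(x) & !is.na(x)
  out[!nz] <- x[!nz]
  if (any(nz)) {
    out[nz] <- unname(as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    ))
  }
  out
}

reverse_chars <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# Merge a set of [start, end) intervals on one chromosome into maximal
# non-overlapping intervals. Input need not be sorted.
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- integer(0); oute <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  tibble(start = c(outs, ms), end = c(oute, me))
}

# Runs of positions -> maximal [start, end) intervals. `pos` is a sorted
# integer vector of 0-based positions.
positions_to_intervals <- function(pos) {
  if (length(pos) == 0) return(tibble(start = integer(0), end = integer(0)))
  pos <- sort(unique(as.integer(pos)))
  brk <- which(diff(pos) > 1L)
  s <- pos[c(1L, brk + 1L)]
  e <- pos[c(brk, length(pos))] + 1L
  tibble(start = s, end = e)
}

# Pairwise Hamming distance between equal-length strings `x` (n of them) and
# a set of barcodes `bc` (m of them). Returns an n x m integer matrix.
# Vectorised over x for large read sets.
hamming_matrix <- function(x, bc) {
  n <- length(x); m <- length(bc)
  if (n == 0) return(matrix(integer(0), nrow = 0, ncol = m))
  w <- unique(nchar(c(x, bc)))
  if (length(w) != 1) {
    abort("all sequences must have equal length for Hamming distance")
  }
  xm <- matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
               nrow = n, byrow = TRUE)
  out <- matrix(0L, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    bj <- strsplit(bc[j], "", fixed = TRUE)[[1]]
    out[, j] <- as.integer(w) -
      rowSums(xm == matrix(bj, nrow = n, ncol = w, byrow = TRUE))
  }
  out
}

# Left-align and parsimony-trim an indel allele pair against a reference
# sequence (classic variant normalization): shared trailing bases are
# trimmed (extending left with the preceding reference base when an allele
# would empty), then shared leading bases beyond the anchor are dropped.
# `pos` is the 0-based anchor of `ref_str`.
normalize_variant <- function(refseq, pos, ref_str, alt_str) {
  repeat {
    rl <- nchar(ref_str); al <- nchar(alt_str)
    if (rl > 0 && al > 0 &&
        substr(ref_str, rl, rl) == substr(alt_str, al, al)) {
      if ((rl == 1 || al == 1) && pos > 0) {
        b <- substr(refseq, pos, pos)  # reference base at pos-1
        ref_str <- paste0(b, substr(ref_str, 1, rl - 1))
        alt_str <- paste0(b, substr(alt_str, 1, al - 1))
        pos <- pos - 1L
      } else if (rl > 1 && al > 1) {
        ref_str <- substr(ref_str, 1, rl - 1)
        alt_str <- substr(alt_str, 1, al - 1)
      } else break
      next
    }
    if (rl >= 2 && al >= 2 &&
        substr(ref_str, 1, 1) == substr(alt_str, 1, 1)) {
      ref_str <- substr(ref_str, 2, rl)
      alt_str <- substr(alt_str, 2, al)
      pos <- pos + 1L
      next
    }
    break
  }
  list(pos = pos, ref = ref_str, alt = alt_str)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Deterministic 32-bit sub-seed derived from a master seed and a string key,
# so per-group draws (e.g. per-sample/per-target downsampling) are
# reproducible independent of processing order.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * (seq_len(nchar(key)) %% 31L + 1L))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
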