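# Overlap consensus merging of paired-end reads.
#
# Mate 2 is reverse-complemented, then every ungapped suffix(read1) /
# prefix(read2') overlap of length >= min_overlap is scored as the
# quality-weighted sum of matches minus mismatches (weight = min of the two
# base qualities). The best-scoring overlap whose mismatch fraction is
# <= max_mismatch_frac is consensus-called:
#   * agreeing positions keep the base with quality min(q1 + q2, qual_cap);
#   * disagreeing positions take the higher-quality base with quality
#     |q1 - q2| (equal qualities: mate 1 base, quality 0).
# Score ties break toward the longer overlap. Pairs without an acceptable
# overlap pass through unmerged; non-merging is a valid outcome, not an
# error.

#' Merge one read pair
#'
#' Scalar convenience wrapper around [merge_pairs()].
#'
#' @param seq1,qual1 Mate 1 sequence and Phred+33 quality string.
#' @param seq2,qual2 Mate 2 sequence and quality string (as sequenced, i.e.
#'   reverse strand; reverse complementation happens internally).
#' @param min_overlap Minimum overlap length in bases (default 11).
#' @param max_mismatch_frac Maximum fraction of mismatching overlap
#'   positions (default 0.05).
#' @param qual_cap Consensus quality cap for agreeing bases (default 60).
#' @return One-row tibble with `seq`, `qual`, `merged`, `overlap_len`.
#' @export
merge_pair <- function(seq1, qual1, seq2, qual2, min_overlap = 11L,
                       max_mismatch_frac = 0.05, qual_cap = 60L) {
  merge_pairs(
    tibble(read_id = "r", seq1 = seq1, qual1 = qual1,
           seq2 = seq2, qual2 = qual2),
    min_overlap = min_overlap, max_mismatch_frac = max_mismatch_frac,
    qual_cap = qual_cap
  )
}

#' Merge overlapping read pairs into consensus reads
#'
#' @param pairs Tibble with `read_id`, `seq1`, `qual1`, `seq2`, `qual2`
#'   (extra columns such as `sample_id` are carried through).
#' @param min_overlap Minimum overlap length (default 11).
#' @param max_mismatch_frac Maximum mismatch fraction in the overlap
#'   (default 0.05).
#' @param qual_cap Consensus quality cap (default 60).
#' @return The input tibble with columns `seq`, `qual` (consensus; `NA`
#'   when unmerged), `merged` and `overlap_len` added. Every input pair
#'   appears exactly once.
#' @export
merge_pairs <- function(pairs, min_overlap = 11L, max_mismatch_frac = 0.05,
                        qual_cap = 60L) {
  stopifnot(all(c("seq1", "qual1", "seq2", "qual2") %in% names(pairs)))
  n <- nrow(pairs)
  out_seq <- rep(NA_character_, n)
  out_qual <- rep(NA_character_, n)
  out_len <- rep(0L, n)
  if (n > 0) {
    grp <- paste(nchar(pairs$seq1), nchar(pairs$seq2))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      res <- merge_group(pairs$seq1[idx], pairs$qual1[idx],
                         pairs$seq2[idx], pairs$qual2[idx],
                         min_overlap, max_mismatch_frac, qual_cap)
      out_seq[idx] <- res$seq
      out_qual[idx] <- res$qual
      out_len[idx] <- res$overlap_len
    }
  }
  pairs$seq <- out_seq
  pairs$qual <- out_qual
  pairs$merged <- !is.na(out_seq)
  pairs$overlap_len <- out_len
  pairs
}

# Vectorised merge for pairs with common mate lengths (n1, n2).
merge_group <- function(seq1, qual1, seq2, qual2, min_overlap,
                        max_mismatch_frac, qual_cap) {
  n <- length(seq1)
  n1 <- nchar(seq1[1]); n2 <- nchar(seq2[1])
  s2r <- revcomp(seq2)
  q2r <- reverse_chars(qual2)

  char_mat <- function(x, w) {
    matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
           nrow = length(x), ncol = w, byrow = TRUE)
  }
  qual_mat <- function(x, w) {
    matrix(unlist(lapply(x, utf8ToInt), use.names = FALSE) - 33L,
           nrow = length(x), ncol = w, byrow = TRUE)
  }
  M1 <- char_mat(seq1, n1); Q1 <- qual_mat(qual1, n1)
  M2 <- char_mat(s2r, n2);  Q2 <- qual_mat(q2r, n2)

  best_score <- rep(-Inf, n)
  best_L <- rep(0L, n)
  max_L <- min(n1, n2)
  if (max_L >= min_overlap) {
    for (L in seq.int(min_overlap, max_L)) {
      c1 <- seq.int(n1 - L + 1L, n1)
      c2 <- seq_len(L)
      eq <- M1[, c1, drop = FALSE] == M2[, c2, drop = FALSE]
      qmin <- pmin(Q1[, c1, drop = FALSE], Q2[, c2, drop = FALSE])
      score <- rowSums(qmin * (2 * eq - 1))
      mism_frac <- (L - rowSums(eq)) / L
      better <- mism_frac <= max_mismatch_frac & score >= best_score
      best_score[better] <- score[better]
      best_L[better] <- L   # >= keeps ties on the longer overlap
    }
  }

  out_seq <- rep(NA_character_, n)
  out_qual <- rep(NA_character_, n)
  for (L in setdiff(unique(best_L), 0L)) {
    rows <- which(best_L == L)
    c1 <- seq.int(n1 - L + 1L, n1)
    c2 <- seq_len(L)
    b1 <- M1[rows, c1, drop = FALSE]; p1 <- Q1[rows, c1, drop = FALSE]
    b2 <- M2[rows, c2, drop = FALSE]; p2 <- Q2[rows, c2, drop = FALSE]
    eq <- b1 == b2
    cons_b <- ifelse(eq | p1 >= p2, b1, b2)
    cons_q <- ifelse(eq, pmin(p1 + p2, qual_cap), abs(p1 - p2))
    for (k in seq_along(rows)) {
      i <- rows[k]
      out_seq[i] <- paste0(substr(seq1[i], 1L, n1 - L),
                           paste(cons_b[k, ], collapse = ""),
                           substr(s2r[i], L + 1L, n2))
      out_qual[i] <- paste0(substr(qual1[i], 1L, n1 - L),
                            int_to_qual(cons_q[k, ]),
                            substr(q2r[i], L + 1L, n2))
    }
  }
  list(seq = out_seq, qual = out_qual, overlap_len = best_L)
}
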