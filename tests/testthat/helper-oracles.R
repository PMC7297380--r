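# Independent reference implementations used as oracles. These deliberately
# share no code with the package: plain positionwise loops.

# Consensus merge of one pair at a KNOWN overlap length L: returns the
# merged sequence and integer qualities under the consensus rule.
oracle_consensus <- function(seq1, q1, seq2rc, q2r, L, qual_cap = 60L) {
  n1 <- nchar(seq1); n2 <- nchar(seq2rc)
  s1 <- strsplit(seq1, "")[[1]]; s2 <- strsplit(seq2rc, "")[[1]]
  out_b <- character(0); out_q <- integer(0)
  for (i in seq_len(n1 - L)) {
    out_b <- c(out_b, s1[i]); out_q <- c(out_q, q1[i])
  }
  for (k in seq_len(L)) {
    i1 <- n1 - L + k
    b1 <- s1[i1]; b2 <- s2[k]
    p1 <- q1[i1]; p2 <- q2r[k]
    if (b1 == b2) {
      out_b <- c(out_b, b1); out_q <- c(out_q, min(p1 + p2, qual_cap))
    } else if (p1 >= p2) {
      out_b <- c(out_b, b1); out_q <- c(out_q, abs(p1 - p2))
    } else {
      out_b <- c(out_b, b2); out_q <- c(out_q, abs(p1 - p2))
    }
  }
  for (k in seq.int(L + 1, length.out = n2 - L)) {
    out_b <- c(out_b, s2[k]); out_q <- c(out_q, q2r[k])
  }
  list(seq = paste(out_b, collapse = ""), qual = out_q)
}

# Full scalar re-derivation of the merge decision: scans every candidate
# overlap, applies the acceptance rule and quality-weighted score with
# longer-overlap tie-break, then consensus-calls.
oracle_merge <- function(seq1, qual1, seq2, qual2, min_overlap = 11L,
                         max_mismatch_frac = 0.05, qual_cap = 60L) {
  q1 <- utf8ToInt(qual1) - 33L
  s2r <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq2)))
  q2r <- rev(utf8ToInt(qual2) - 33L)
  n1 <- nchar(seq1); n2 <- nchar(s2r)
  s1 <- strsplit(seq1, "")[[1]]; s2 <- strsplit(s2r, "")[[1]]
  best <- list(score = -Inf, L = 0L)
  for (L in seq.int(min_overlap, min(n1, n2))) {
    if (L > min(n1, n2)) break
    mism <- 0L; score <- 0
    for (k in seq_len(L)) {
      i1 <- n1 - L + k
      w <- min(q1[i1], q2r[k])
      if (s1[i1] == s2[k]) score <- score + w
      else { score <- score - w; mism <- mism + 1L }
    }
    if (mism / L <= max_mismatch_frac && score >= best$score) {
      best <- list(score = score, L = L)
    }
  }
  if (best$L == 0L) return(list(merged = FALSE))
  cons <- oracle_consensus(seq1, q1, s2r, q2r, best$L, qual_cap)
  list(merged = TRUE, overlap_len = best$L, seq = cons$seq,
       qual = cons$qual)
}

# Brute-force genotype likelihood evaluation over reads: obs_class is
# "ref"/"alt"/"other", returns log10 likelihoods per genotype and the GQ.
oracle_genotype <- function(obs_class, qual, ploidy = 2L,
                            error_floor = 1e-4) {
  p_of <- function(cls, allele, eps) {
    if (cls == allele) 1 - eps else eps / 3
  }
  gts <- if (ploidy == 2L) c("0/0", "0/1", "1/1") else c("0", "1")
  ll <- sapply(gts, function(g) {
    tot <- 0
    for (i in seq_along(obs_class)) {
      eps <- min(max(10^(-qual[i] / 10), error_floor), 0.75)
      pr <- p_of(obs_class[i], "ref", eps)
      pa <- p_of(obs_class[i], "alt", eps)
      p <- switch(g,
                  "0/0" = pr, "0" = pr,
                  "0/1" = (pr + pa) / 2,
                  "1/1" = pa, "1" = pa)
      tot <- tot + log10(p)
    }
    tot
  })
  o <- order(ll, decreasing = TRUE)
  list(genotype = gts[o[1]],
       gq_raw = unname(10 * (ll[o[1]] - ll[o[2]])),
       ll = ll)
}

# Per-base reference positions of an alignment, recomputed by a plain
# CIGAR walk (for trim/pileup checks).
oracle_ref_positions <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  rp <- pos
  out <- integer(0)
  for (i in seq_along(ops)) {
    if (ops[i] %in% c("M", "=", "X")) {
      out <- c(out, rp + seq_len(lens[i]) - 1L)
      rp <- rp + lens[i]
    } else if (ops[i] %in% c("D", "N")) {
      rp <- rp + lens[i]
    }
  }
  out
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
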