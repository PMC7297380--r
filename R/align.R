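# Deterministic short-read aligner for small references.
#
# Designed for the read lengths this package works with (merged MIP
# fragments and their mates, ~50-250 bp) against panel-sized references
# (a few to a few hundred kb). Strategy per read, both orientations:
#   1. exact k-mer anchors (default k = 24) sampled across the read locate
#      candidate diagonals;
#   2. candidates are verified ungapped by mismatch counting;
#   3. when anchors disagree on the diagonal (indel) or no ungapped
#      placement is acceptable, a banded window is refined with
#      Biostrings::pairwiseAlignment (pattern-global), which supplies the
#      gapped CIGAR.
# Reads whose anchors hit nowhere are reported unmapped. Penalty = mismatch
# bases + gap bases; alignments with penalty > ceiling(max_penalty_frac *
# length) are rejected. A uniquely best placement gets MAPQ 60; ties get
# MAPQ 0 and the lexicographically first placement. An optional `bwa mem`
# shell-out adapter is provided for full-genome use.

ALN_MAPQ_UNIQUE <- 60L

build_ref_index <- function(ref, k = 24L) {
  stopifnot(!is.null(names(ref)), all(nchar(ref) >= k))
  kmers <- character(0); contig <- character(0); pos <- integer(0)
  for (cn in names(ref)) {
    s <- ref[[cn]]
    n <- nchar(s) - k + 1L
    starts <- seq_len(n)
    kmers <- c(kmers, substring(s, starts, starts + k - 1L))
    contig <- c(contig, rep(cn, n))
    pos <- c(pos, starts - 1L)  # 0-based
  }
  list(k = k, ref = ref,
       map = split(data.frame(contig = contig, pos = pos,
                              stringsAsFactors = FALSE), kmers))
}

# mismatch count between read and ref window starting at 0-based `start`
count_mismatches <- function(read_raw, ref_raw, start) {
  len <- length(read_raw)
  if (start < 0L || start + len > length(ref_raw)) return(NA_integer_)
  sum(read_raw != ref_raw[(start + 1L):(start + len)])
}

align_one <- function(seq, index, max_penalty, n_seeds = 5L) {
  k <- index$k
  len <- nchar(seq)
  orientations <- list(`+` = seq, `-` = revcomp(seq))
  cand <- list()
  for (strand in names(orientations)) {
    s <- orientations[[strand]]
    if (len < k) break
    seed_starts <- unique(pmax(1L, pmin(
      len - k + 1L,
      as.integer(round(seq(1L, len - k + 1L, length.out = n_seeds)))
    )))
    sraw <- charToRaw(s)
    hits_by_contig <- list()
    for (sp in seed_starts) {
      kmer <- substr(s, sp, sp + k - 1L)
      h <- index$map[[kmer]]
      if (is.null(h)) next
      for (j in seq_len(nrow(h))) {
        cn <- h$contig[j]
        diag0 <- h$pos[j] - (sp - 1L)  # implied 0-based read start
        hits_by_contig[[cn]] <- unique(c(hits_by_contig[[cn]], diag0))
      }
    }
    for (cn in names(hits_by_contig)) {
      ref_raw <- charToRaw(index$ref[[cn]])
      diags <- sort(hits_by_contig[[cn]])
      best_mm <- NA_integer_
      for (d in diags) {
        mm <- count_mismatches(sraw, ref_raw, d)
        if (!is.na(mm) && mm <= max_penalty) {
          best_mm <- min(best_mm, mm, na.rm = TRUE)
          cand[[length(cand) + 1L]] <- list(
            chrom = cn, pos = d, strand = strand, penalty = mm,
            cigar = paste0(len, "M"), seq = s
          )
        }
      }
      # refine with a gapped alignment when anchors disagree on the
      # diagonal, when no ungapped placement fits, or when the best
      # ungapped placement still carries several mismatches (an indel
      # near a read end masks the anchor that would reveal the second
      # diagonal but leaves a short mismatched tail)
      need_gapped <- is.na(best_mm) || best_mm > 2L ||
        (length(diags) > 1L && diff(range(diags)) > 0L)
      if (need_gapped) {
        pad <- 16L
        w0 <- max(0L, min(diags) - pad)
        w1 <- min(length(ref_raw), max(diags) + len + pad)
        g <- align_gapped(s, index$ref[[cn]], w0, w1)
        if (!is.null(g) && g$penalty <= max_penalty) {
          cand[[length(cand) + 1L]] <- list(
            chrom = cn, pos = g$pos, strand = strand, penalty = g$penalty,
            cigar = g$cigar, seq = s
          )
        }
      }
    }
  }
  if (length(cand) == 0) return(NULL)
  pen <- vapply(cand, `[[`, numeric(1), "penalty")
  best <- which(pen == min(pen))
  if (length(best) > 1L) {
    keys <- vapply(cand[best], function(x) {
      paste(x$chrom, sprintf("%09d", x$pos), x$strand)
    }, character(1))
    best <- best[order(keys)]
    # distinct placements tied at the best penalty -> ambiguous
    locs <- unique(keys)
    mapq <- if (length(locs) > 1L) 0L else ALN_MAPQ_UNIQUE
    pick <- cand[[best[1]]]
  } else {
    mapq <- ALN_MAPQ_UNIQUE
    pick <- cand[[best]]
  }
  pick$mapq <- mapq
  pick
}

# Pattern-global alignment of `s` against ref[w0, w1) (0-based half-open).
align_gapped <- function(s, ref_seq, w0, w1) {
  window <- substr(ref_seq, w0 + 1L, w1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(s), Biostrings::DNAString(window),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -3, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 2
  )
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  op <- ifelse(ap == "-", "D", ifelse(as_ == "-", "I", "M"))
  r <- rle(op)
  penalty <- sum(op == "D") + sum(op == "I") +
    sum(op == "M" & ap != as_)
  # drop leading/trailing deletions (alignment must start/end on read bases)
  ops <- r$values; lens <- r$lengths
  lead_del <- 0L
  if (ops[1] == "D") {
    lead_del <- lens[1]; ops <- ops[-1]; lens <- lens[-1]
    penalty <- penalty - lead_del
  }
  if (length(ops) > 0 && ops[length(ops)] == "D") {
    penalty <- penalty - lens[length(ops)]
    lens <- lens[-length(ops)]; ops <- ops[-length(ops)]
  }
  if (length(ops) == 0) return(NULL)
  list(
    pos = w0 + Biostrings::start(Biostrings::subject(aln)) - 1L + lead_del,
    cigar = unparse_cigar(ops, lens),
    penalty = penalty
  )
}

#' Align reads to a small reference
#'
#' @param reads Tibble with `read_id`, `seq`, `qual` (plus carried columns
#'   such as `sample_id`).
#' @param ref Named character vector of reference contig sequences, e.g.
#'   from [read_reference()].
#' @param k Anchor k-mer size (default 24).
#' @param max_penalty_frac Maximum (mismatch + gap) bases as a fraction of
#'   read length (default 0.1).
#' @return Alignment tibble (`read_id`, `sample_id`, `chrom`, `pos`,
#'   `mapq`, `strand`, `cigar`, `seq`, `qual`); unmapped reads are kept
#'   with `chrom = NA` so that read counts are conserved. Reverse-strand
#'   rows store the reverse-complemented (reference-oriented) sequence and
#'   reversed qualities.
#' @export
align_reads <- function(reads, ref, k = 24L, max_penalty_frac = 0.1) {
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  index <- build_ref_index(ref, k = k)
  uniq <- unique(reads$seq)
  res <- lapply(uniq, function(s) {
    align_one(s, index, max_penalty = ceiling(max_penalty_frac * nchar(s)))
  })
  names(res) <- uniq
  hit <- res[reads$seq]
  out <- reads
  out$chrom <- vapply(hit, function(h) h$chrom %||% NA_character_,
                      character(1), USE.NAMES = FALSE)
  out$pos <- vapply(hit, function(h) h$pos %||% NA_integer_,
                    integer(1), USE.NAMES = FALSE)
  out$mapq <- vapply(hit, function(h) h$mapq %||% 0L, integer(1),
                     USE.NAMES = FALSE)
  out$strand <- vapply(hit, function(h) h$strand %||% NA_character_,
                       character(1), USE.NAMES = FALSE)
  out$cigar <- vapply(hit, function(h) h$cigar %||% NA_character_,
                      character(1), USE.NAMES = FALSE)
  rev_rows <- !is.na(out$strand) & out$strand == "-"
  out$seq[rev_rows] <- revcomp(reads$seq[rev_rows])
  out$qual[rev_rows] <- reverse_chars(reads$qual[rev_rows])
  if (!"sample_id" %in% names(out)) out$sample_id <- NA_character_
  dplyr::relocate(out, "read_id", "sample_id", "chrom", "pos", "mapq",
                  "strand", "cigar", "seq", "qual")
}

#' Align with an external `bwa mem` (adapter)
#'
#' Thin shell-out for users with a genome-scale reference and `bwa` on the
#' PATH; writes a FASTQ, runs `bwa index`/`bwa mem` with fixed arguments and
#' reads the SAM back. Not used by the built-in pipeline.
#'
#' @param reads Read tibble (`read_id`, `seq`, `qual`).
#' @param ref_fasta Path to the reference FASTA.
#' @param workdir Scratch directory (default `tempdir()`).
#' @return Alignment tibble from [read_sam()].
#' @export
align_reads_bwa <- function(reads, ref_fasta, workdir = tempdir()) {
  if (Sys.which("bwa") == "") abort("bwa not found on PATH")
  fq <- file.path(workdir, "reads.fq")
  write_fastq(reads, fq)
  if (!file.exists(paste0(ref_fasta, ".bwt"))) {
    system2("bwa", c("index", ref_fasta), stdout = FALSE, stderr = FALSE)
  }
  sam <- file.path(workdir, "aln.sam")
  system2("bwa", c("mem", "-v", "1", ref_fasta, fq), stdout = sam,
          stderr = FALSE)
  read_sam(sam)
}

#' Read a reference FASTA as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of upper-case contig sequences.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write a named character vector as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path
  )
  invisible(path)
}
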