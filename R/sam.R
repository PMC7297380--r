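# SAM text I/O and CIGAR arithmetic.
#
# Alignments are tibbles with 0-based `pos`; SAM is 1-based and converted
# only at the file boundary. Sequences are stored reference-oriented (as in
# SAM): reverse-strand alignments carry flag bit 0x10 and the
# reverse-complemented read. The sample tag travels as the RG field.

CIGAR_REF_OPS <- c("M", "D", "N", "=", "X")
CIGAR_READ_OPS <- c("M", "I", "S", "=", "X")

parse_cigar <- function(cigar) {
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))
  purrr::pmap(list(lens, ops, cigar), function(l, o, cg) {
    if (is.na(cg)) return(NULL)
    if (length(l) != length(o) || length(o) == 0) {
      abort(paste0("malformed CIGAR: ", cg))
    }
    list(op = o, len = as.integer(l))
  })
}

unparse_cigar <- function(op, len) {
  keep <- len > 0L
  op <- op[keep]; len <- len[keep]
  if (length(op) == 0) return("*")
  # collapse adjacent equal ops
  r <- rle(op)
  if (any(r$lengths > 1)) {
    grp <- rep(seq_along(r$lengths), r$lengths)
    len <- as.integer(tapply(len, grp, sum))
    op <- r$values
  }
  paste0(len, op, collapse = "")
}

#' Reference span of CIGAR strings
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of reference bases consumed (M/D/N/=/X).
#' @export
cigar_ref_span <- function(cigar) {
  vapply(parse_cigar(cigar), function(cg) {
    if (is.null(cg)) return(NA_integer_)
    sum(cg$len[cg$op %in% CIGAR_REF_OPS])
  }, integer(1))
}

cigar_read_span <- function(cigar) {
  vapply(parse_cigar(cigar), function(cg) {
    if (is.null(cg)) return(NA_integer_)
    sum(cg$len[cg$op %in% CIGAR_READ_OPS])
  }, integer(1))
}

# Per-base walk of one alignment. Returns a tibble with one row per read
# base or deleted reference base:
#   op     M/I/D (S bases are reported as op "S" with refpos NA)
#   qpos   1-based position in the stored read (NA for D)
#   refpos 0-based reference position (for I: the anchor, i.e. the next
#          reference position; for S: NA)
walk_alignment <- function(pos, cigar) {
  cg <- parse_cigar(cigar)[[1]]
  qp <- 0L
  rp <- as.integer(pos)
  op_out <- character(0); qpos <- integer(0); refpos <- integer(0)
  for (i in seq_along(cg$op)) {
    o <- cg$op[i]; l <- cg$len[i]
    if (o %in% c("M", "=", "X")) {
      op_out <- c(op_out, rep("M", l))
      qpos <- c(qpos, qp + seq_len(l))
      refpos <- c(refpos, rp + seq_len(l) - 1L)
      qp <- qp + l; rp <- rp + l
    } else if (o == "I") {
      op_out <- c(op_out, rep("I", l))
      qpos <- c(qpos, qp + seq_len(l))
      refpos <- c(refpos, rep(rp, l))  # anchor: next reference base
      qp <- qp + l
    } else if (o == "D" || o == "N") {
      op_out <- c(op_out, rep("D", l))
      qpos <- c(qpos, rep(NA_integer_, l))
      refpos <- c(refpos, rp + seq_len(l) - 1L)
      rp <- rp + l
    } else if (o == "S") {
      op_out <- c(op_out, rep("S", l))
      qpos <- c(qpos, qp + seq_len(l))
      refpos <- c(refpos, rep(NA_integer_, l))
      qp <- qp + l
    } else if (o == "H" || o == "P") {
      # consumes neither
    } else {
      abort(paste0("unsupported CIGAR op: ", o))
    }
  }
  tibble(op = op_out, qpos = qpos, refpos = refpos)
}

#' Read a SAM text file into an alignment tibble
#'
#' @param path SAM file path.
#' @return Tibble with `read_id`, `sample_id` (from the RG tag, `NA` if
#'   absent), `chrom`, `pos` (0-based), `mapq`, `strand`, `cigar`, `seq`,
#'   `qual`. Unmapped records keep `chrom = NA`.
#' @export
read_sam <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(tibble(read_id = character(0), sample_id = character(0),
                  chrom = character(0), pos = integer(0), mapq = integer(0),
                  strand = character(0), cigar = character(0),
                  seq = character(0), qual = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 11L)
  if (length(bad) > 0) {
    abort(paste0("malformed SAM record at data line ", bad[1]))
  }
  f <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- as.integer(f(2))
  rg <- vapply(fields, function(x) {
    tag <- grep("^RG:Z:", x[-(1:11)], value = TRUE)
    if (length(tag) > 0) sub("^RG:Z:", "", tag[1]) else NA_character_
  }, character(1))
  tibble(
    read_id = f(1),
    sample_id = rg,
    chrom = if_else(f(3) == "*", NA_character_, f(3)),
    pos = as.integer(f(4)) - 1L,
    mapq = as.integer(f(5)),
    strand = if_else(bitwAnd(flag, 16L) > 0L, "-", "+"),
    cigar = f(6),
    seq = f(10),
    qual = f(11)
  )
}

#' Write an alignment tibble as SAM text
#'
#' @param aln Alignment tibble (see [read_sam()] for columns).
#' @param ref_lengths Named integer vector of reference contig lengths for
#'   the `@SQ` header lines.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, ref_lengths, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", names(ref_lengths), "\tLN:", ref_lengths),
    paste0("@RG\tID:", unique(stats::na.omit(aln$sample_id)),
           "\tSM:", unique(stats::na.omit(aln$sample_id)))
  )
  mapped <- !is.na(aln$chrom)
  ord <- order(!mapped, aln$chrom, aln$pos)
  aln <- aln[ord, ]
  mapped <- mapped[ord]
  flag <- if_else(aln$strand == "-" & mapped, 16L, 0L) +
    if_else(mapped, 0L, 4L)
  body <- paste(
    aln$read_id, flag,
    if_else(mapped, aln$chrom, "*"),
    if_else(mapped, aln$pos + 1L, 0L),
    if_else(mapped, aln$mapq, 0L),
    if_else(mapped, aln$cigar, "*"),
    "*", 0L, 0L, aln$seq, aln$qual,
    if_else(is.na(aln$sample_id), "", paste0("RG:Z:", aln$sample_id)),
    sep = "\t"
  )
  body <- sub("\t$", "", body)
  readr::write_lines(c(header, body), path)
  invisible(path)
}
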