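# FASTQ I/O. Reads are held as tibbles with Phred+33 quality strings;
# Biostrings does the file-format work.

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ file (plain or gzipped).
#' @return Tibble with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTQ file not found: ", path))
  # Biostrings warns about dropping its own metadata columns on FASTQ
  # input; nothing of ours is lost
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  tibble(
    read_id = sub("\\s.*$", "", names(x)),
    seq = unname(as.character(x)),
    qual = unname(as.character(Biostrings::quality(x)))
  )
}

#' Write a tibble of reads to FASTQ
#'
#' @param reads Tibble with `read_id`, `seq`, `qual` columns.
#' @param path Output path; `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual)
  )
  names(x) <- reads$read_id
  Biostrings::writeQualityScaledXStringSet(
    x, path, compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' Read paired FASTQ files into a read-pair tibble
#'
#' @param r1,r2 Paths to mate 1 / mate 2 FASTQ.
#' @param i1,i2 Optional paths to index-read FASTQ (dual index uses both).
#' @return Tibble with `read_id`, `seq1`, `qual1`, `seq2`, `qual2` and,
#'   when index files are given, `index1`/`index2`.
#' @export
read_pairs <- function(r1, r2, i1 = NULL, i2 = NULL) {
  m1 <- read_fastq(r1)
  m2 <- read_fastq(r2)
  if (nrow(m1) != nrow(m2) || !all(m1$read_id == m2$read_id)) {
    abort("mate FASTQ files are not in matching read order")
  }
  pairs <- tibble(read_id = m1$read_id,
                  seq1 = m1$seq, qual1 = m1$qual,
                  seq2 = m2$seq, qual2 = m2$qual)
  if (!is.null(i1)) {
    ix <- read_fastq(i1)
    if (!all(ix$read_id == pairs$read_id)) {
      abort("index FASTQ not in matching read order")
    }
    pairs$index1 <- ix$seq
  }
  if (!is.null(i2)) {
    ix <- read_fastq(i2)
    if (!all(ix$read_id == pairs$read_id)) {
      abort("index FASTQ not in matching read order")
    }
    pairs$index2 <- ix$seq
  }
  pairs
}
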