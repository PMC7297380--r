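# Sample demultiplexing by index barcode.
#
# An observed index (or dual-index pair) is assigned to the unique sample
# whose barcode(s) lie within `max_mismatch` Hamming distance per index.
# Ambiguity (two samples tied at the minimum total distance) and
# out-of-tolerance reads are both UNASSIGNED rather than guessed.

#' Assign observed index sequences to samples
#'
#' Vectorised barcode matching against a sample sheet.
#'
#' @param index1 Character vector of observed index-1 sequences.
#' @param index2 Optional character vector of observed index-2 sequences
#'   (required when the sheet is dual-index).
#' @param sheet Sample sheet tibble (see [read_sample_sheet()]).
#' @param max_mismatch Maximum Hamming distance tolerated per index
#'   (default 1).
#' @return Character vector of `sample_id`, `NA` where unassigned.
#' @export
assign_samples <- function(index1, index2 = NULL, sheet, max_mismatch = 1L) {
  sheet <- validate_sample_sheet(sheet)
  dual <- !all(is.na(sheet$barcode2))
  if (dual && is.null(index2)) {
    abort("sample sheet is dual-index but index2 was not provided")
  }
  if (length(unique(nchar(index1))) > 1 ||
      nchar(index1)[1] != nchar(sheet$barcode1)[1]) {
    abort("index1 length does not match sheet barcode length",
          class = "mipseqr_input_error")
  }
  d <- hamming_matrix(toupper(index1), sheet$barcode1)
  ok <- d <= max_mismatch
  if (dual) {
    if (length(unique(nchar(index2))) > 1 ||
        nchar(index2)[1] != nchar(sheet$barcode2)[1]) {
      abort("index2 length does not match sheet barcode length",
            class = "mipseqr_input_error")
    }
    d2 <- hamming_matrix(toupper(index2), sheet$barcode2)
    ok <- ok & (d2 <= max_mismatch)
    d <- d + d2
  }
  big <- 1000000L
  d[!ok] <- big
  rmin <- do.call(pmin, lapply(seq_len(ncol(d)), function(j) d[, j]))
  nmin <- rowSums(d == rmin)
  best <- max.col(-d, ties.method = "first")
  best[rmin >= big | nmin != 1L] <- NA_integer_
  sheet$sample_id[best]
}

#' Demultiplex a read-pair tibble
#'
#' Adds a `sample_id` column (read-group-style sample tag carried by every
#' downstream record); unassigned reads keep `NA`.
#'
#' @param pairs Read-pair tibble with `index1` (and `index2` for dual index)
#'   columns, e.g. from [read_pairs()] or [extract_inline_barcodes()].
#' @param sheet Sample sheet tibble.
#' @param max_mismatch Per-index Hamming tolerance (default 1).
#' @return `pairs` with a `sample_id` column.
#' @export
demultiplex <- function(pairs, sheet, max_mismatch = 1L) {
  if (!"index1" %in% names(pairs)) {
    abort("pairs have no index1 column; read index FASTQ or use inline mode")
  }
  idx2 <- if ("index2" %in% names(pairs)) pairs$index2 else NULL
  pairs$sample_id <- assign_samples(pairs$index1, idx2, sheet, max_mismatch)
  pairs
}

#' Per-sample demultiplexing summary
#'
#' @param pairs Demultiplexed read-pair tibble.
#' @param sheet Sample sheet tibble (so samples with zero reads appear).
#' @return Tibble of `sample_id` (including `"UNASSIGNED"`) and `n_reads`.
#' @export
demux_summary <- function(pairs, sheet) {
  counts <- pairs |>
    mutate(sample_id = dplyr::coalesce(.data$sample_id, "UNASSIGNED")) |>
    count(.data$sample_id, name = "n_reads")
  tibble(sample_id = c(sheet$sample_id, "UNASSIGNED")) |>
    left_join(counts, by = "sample_id") |>
    mutate(n_reads = dplyr::coalesce(.data$n_reads, 0L))
}

#' Extract inline 5' barcodes from read 1
#'
#' Supports the MIP protocol variant with the sample barcode ligated at the
#' 5' end of read 1 instead of a separate index read. The barcode bases are
#' moved into `index1` and trimmed from `seq1`/`qual1` before merging.
#'
#' @param pairs Read-pair tibble.
#' @param barcode_len Barcode length in bases.
#' @return `pairs` with `index1` filled and mate 1 trimmed.
#' @export
extract_inline_barcodes <- function(pairs, barcode_len) {
  stopifnot(barcode_len >= 1)
  if (any(nchar(pairs$seq1) <= barcode_len)) {
    abort("read 1 shorter than inline barcode length",
          class = "mipseqr_input_error")
  }
  pairs |>
    mutate(index1 = substr(.data$seq1, 1L, barcode_len),
           seq1 = substr(.data$seq1, barcode_len + 1L, nchar(.data$seq1)),
           qual1 = substr(.data$qual1, barcode_len + 1L, nchar(.data$qual1)))
}
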