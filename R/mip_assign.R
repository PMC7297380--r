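# Assignment of aligned reads to MIP probes and arm trimming.
#
# A read belongs to the probe whose arm-flanked window it spans: merged
# reads must match both window endpoints within `tol` bases, unmerged mates
# only the endpoint on their arm side (the 5' end in reference
# coordinates). Arm-derived bases are then hard-trimmed from the alignment
# so that probe (not sample) sequence can never feed the pileup — arms hide
# true variation under synthetic primer sequence, so any base they
# contribute is non-evidence.

#' Assign aligned reads to MIP probes
#'
#' @param aln Alignment tibble (see [align_reads()]); a logical `merged`
#'   column marks consensus reads (absent: all treated as merged).
#' @param design A `mip_design` tibble.
#' @param tol Endpoint tolerance in bases (default 5): small indels and
#'   alignment jitter near the arms are tolerated, cross-probe
#'   misassignment is not (probes tile much further apart than `tol`).
#' @return `aln` with `mip_id` (NA when unassigned) and `deviation` (total
#'   endpoint deviation in bases) columns. Ties go to the smallest total
#'   deviation, then the lexicographically smallest `mip_id`.
#' @export
assign_mips <- function(aln, design, tol = 5L) {
  stopifnot(inherits(design, "mip_design"))
  if (!"merged" %in% names(aln)) aln$merged <- TRUE
  aln$mip_id <- NA_character_
  aln$deviation <- NA_integer_
  mapped <- which(!is.na(aln$chrom))
  if (length(mapped) == 0) return(aln)
  ends <- aln$pos + cigar_ref_span(aln$cigar)

  for (cn in unique(aln$chrom[mapped])) {
    pr <- design[design$chrom == cn, ]
    if (nrow(pr) == 0) next
    pr <- pr[order(pr$mip_id), ]
    rows <- mapped[aln$chrom[mapped] == cn]
    ds <- abs(outer(aln$pos[rows], pr$win_start, "-"))
    de <- abs(outer(ends[rows], pr$win_end, "-"))
    m <- aln$merged[rows]
    plus <- aln$strand[rows] == "+"
    # merged: both endpoints constrained; unmerged: 5'-side endpoint only
    valid <- (m & ds <= tol & de <= tol) |
      (!m & plus & ds <= tol) |
      (!m & !plus & de <= tol)
    dev <- ds + de
    dev_un <- ds
    dev_un[!plus, ] <- de[!plus, , drop = FALSE]
    dev[!m, ] <- dev_un[!m, , drop = FALSE]
    big <- .Machine$integer.max
    dev[!valid] <- big
    rmin <- do.call(pmin, lapply(seq_len(ncol(dev)), function(j) dev[, j]))
    pick <- max.col(-dev, ties.method = "first")  # first = smallest mip_id
    ok <- rmin < big
    aln$mip_id[rows[ok]] <- pr$mip_id[pick[ok]]
    aln$deviation[rows[ok]] <- as.integer(rmin[ok])
  }
  aln
}

#' Hard-trim MIP arm bases from assigned alignments
#'
#' Removes every aligned base whose reference position falls outside the
#' assigned probe's scan target (i.e. inside an arm interval), rewrites the
#' CIGAR and advances the alignment start. Insertions at a trim boundary
#' are removed together with the trimmed side; a trim side is only active
#' when the read actually reaches into that arm. Reads left without aligned
#' bases are dropped with a `dropped` marker row count in the
#' `"n_dropped"` attribute.
#'
#' @param aln Assigned alignment tibble (from [assign_mips()]).
#' @param design A `mip_design` tibble.
#' @return Trimmed alignment tibble (assigned, non-empty reads only) with
#'   `trim_left`/`trim_right` columns (read bases removed at each end).
#' @export
trim_arms <- function(aln, design) {
  stopifnot("mip_id" %in% names(aln))
  keep <- !is.na(aln$mip_id)
  out <- aln[keep, ]
  if (nrow(out) == 0) {
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  dmap <- as_tibble(design)[, c("mip_id", "scan_start", "scan_end")]
  out <- left_join(out, dmap, by = "mip_id")
  len <- nchar(out$seq)
  ends <- out$pos + cigar_ref_span(out$cigar)

  simple <- grepl("^[0-9]+M$", out$cigar)
  ns <- pmax(out$pos, out$scan_start)
  ne <- pmin(ends, out$scan_end)
  out$trim_left <- 0L
  out$trim_right <- 0L
  dropped <- rep(FALSE, nrow(out))

  # fast path: pure-match CIGARs are interval intersections
  si <- which(simple)
  empty <- ne[si] - ns[si] < 1L
  dropped[si[empty]] <- TRUE
  si <- si[!empty]
  out$trim_left[si] <- as.integer(ns[si] - out$pos[si])
  out$trim_right[si] <- as.integer(ends[si] - ne[si])
  out$seq[si] <- substr(out$seq[si], out$trim_left[si] + 1L,
                        len[si] - out$trim_right[si])
  out$qual[si] <- substr(out$qual[si], out$trim_left[si] + 1L,
                         len[si] - out$trim_right[si])
  out$cigar[si] <- paste0(ne[si] - ns[si], "M")
  out$pos[si] <- ns[si]

  for (i in which(!simple)) {
    tr <- trim_one_complex(out$pos[i], out$cigar[i], out$seq[i], out$qual[i],
                           out$scan_start[i], out$scan_end[i])
    if (is.null(tr)) {
      dropped[i] <- TRUE
    } else {
      out$pos[i] <- tr$pos; out$cigar[i] <- tr$cigar
      out$seq[i] <- tr$seq; out$qual[i] <- tr$qual
      out$trim_left[i] <- tr$trim_left; out$trim_right[i] <- tr$trim_right
    }
  }
  n_dropped <- sum(dropped)
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " read(s) dropped: no aligned bases left ",
                  "after arm trimming"))
  }
  out <- out[!dropped, ]
  out$scan_start <- NULL; out$scan_end <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

# Per-base walk trim for CIGARs with indels/clips.
trim_one_complex <- function(pos, cigar, seq, qual, scan_start, scan_end) {
  w <- walk_alignment(pos, cigar)
  m <- w$op == "M"
  left_active <- any(m & w$refpos < scan_start)
  right_active <- any(m & w$refpos >= scan_end)
  drop <- w$op == "S"
  if (left_active) {
    drop <- drop | (m & w$refpos < scan_start) |
      (w$op == "D" & w$refpos < scan_start) |
      (w$op == "I" & w$refpos <= scan_start)
  }
  if (right_active) {
    drop <- drop | (m & w$refpos >= scan_end) |
      (w$op == "D" & w$refpos >= scan_end) |
      (w$op == "I" & w$refpos >= scan_end)
  }
  kept <- w[!drop, ]
  if (!any(kept$op == "M")) return(NULL)
  # strip leading/trailing deletions
  mi <- which(kept$op != "D")
  kept <- kept[seq(min(mi), max(mi)), ]
  first_m <- which(kept$op == "M")[1]
  qkeep <- kept$qpos[!is.na(kept$qpos)]
  sc <- strsplit(seq, "")[[1]]
  qc <- strsplit(qual, "")[[1]]
  list(
    pos = kept$refpos[first_m],
    cigar = unparse_cigar(kept$op, rep(1L, nrow(kept))),
    seq = paste(sc[qkeep], collapse = ""),
    qual = paste(qc[qkeep], collapse = ""),
    trim_left = min(qkeep) - 1L,
    trim_right = nchar(seq) - max(qkeep)
  )
}

#' Per-MIP representation statistics
#'
#' Count matrix over samples and probes plus per-probe totals, mean
#' relative abundance and dispersion — the text statistics used to spot
#' under- and over-performing probes in a capture that is by construction
#' highly imbalanced.
#'
#' @param aln Assigned alignment tibble (post [assign_mips()]); only rows
#'   with a `mip_id` and `sample_id` are counted.
#' @param design A `mip_design` tibble (probes with zero reads still
#'   appear).
#' @param samples Optional character vector fixing the sample set (so
#'   zero-read samples appear too).
#' @return A tibble with one row per (sample_id, mip_id): `count` and
#'   `rel_abundance` (count / sample total, 0 for empty samples), with a
#'   per-probe roll-up in the `"per_mip"` attribute (`mip_id`,
#'   `total_count`, `mean_rel_abundance`, `dispersion` = CV across
#'   samples). Retrieve it with [mip_summary()].
#' @export
compute_mip_stats <- function(aln, design, samples = NULL) {
  stopifnot(inherits(design, "mip_design"))
  assigned <- aln |>
    filter(!is.na(.data$mip_id), !is.na(.data$sample_id))
  if (is.null(samples)) samples <- sort(unique(assigned$sample_id))
  if (nrow(assigned) == 0 && length(samples) == 0) {
    abort("no assigned reads and no sample set given")
  }
  grid <- tidyr::expand_grid(sample_id = samples, mip_id = design$mip_id)
  stats <- assigned |>
    count(.data$sample_id, .data$mip_id, name = "count") |>
    right_join(grid, by = c("sample_id", "mip_id")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    group_by(.data$sample_id) |>
    mutate(rel_abundance = if (sum(.data$count) > 0) {
      .data$count / sum(.data$count)
    } else rep(0, n())) |>
    ungroup() |>
    arrange(.data$sample_id, .data$mip_id)
  per_mip <- stats |>
    group_by(.data$mip_id) |>
    summarise(
      total_count = sum(.data$count),
      mean_rel_abundance = mean(.data$rel_abundance),
      dispersion = if_else(mean(.data$rel_abundance) > 0,
                           sd(.data$rel_abundance) /
                             mean(.data$rel_abundance), NA_real_),
      .groups = "drop"
    )
  attr(stats, "per_mip") <- per_mip
  class(stats) <- c("mip_stats", class(stats))
  stats
}

#' Per-probe summary of MIP representation statistics
#'
#' @param stats Result of [compute_mip_stats()].
#' @return Tibble with `mip_id`, `total_count`, `mean_rel_abundance`,
#'   `dispersion`.
#' @export
mip_summary <- function(stats) {
  stopifnot(inherits(stats, "mip_stats"))
  attr(stats, "per_mip")
}

#' Write MIP representation statistics as TSV
#'
#' Wide layout: one row per probe, one count column per sample, then
#' totals and relative-abundance summaries.
#'
#' @param stats Result of [compute_mip_stats()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mip_stats <- function(stats, path) {
  wide <- stats |>
    select("mip_id", "sample_id", "count") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count")
  out <- left_join(wide, mip_summary(stats), by = "mip_id")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
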