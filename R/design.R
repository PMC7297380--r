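# MIP design model.
#
# A design is a tibble with one row per probe. All coordinates are 0-based
# half-open; 1-based coordinates exist only at the MIPgen/VCF/HTML
# boundaries. Probe geometry on the plus strand is
#
#     [ext arm)[   scan target   )[lig arm)
#
# with the extension arm ending at scan_start and the ligation arm starting
# at scan_end; on the minus strand the arm order is mirrored (ligation arm
# upstream of the scan, extension arm downstream). The probe "window" is the
# contiguous interval covered by both arms plus the scan target, i.e. the
# reference footprint of a captured fragment.

MIPGEN_REQUIRED <- c("mip_name", "chr", "ext_probe_sequence",
                     "lig_probe_sequence", "mip_scan_start_position",
                     "mip_scan_stop_position", "probe_strand")

BEDLIKE_REQUIRED <- c("chrom", "scan_start", "scan_end", "mip_id", "strand",
                      "ext_arm_seq", "lig_arm_seq")

PROBE_CLASSES <- c("target", "inversion_ref", "inversion_mut", "sry")

#' Read a MIP design file
#'
#' Parses a probe design table in either the MIPgen picked-MIPs dialect
#' (1-based inclusive scan coordinates, `mip_name`/`chr`/`probe_strand`
#' columns) or a bed-like dialect that is already 0-based half-open. Probe
#' classes (target, inversion_ref, inversion_mut, sry) and inversion event
#' ids are declared in an optional companion table, since MIPgen files carry
#' neither.
#'
#' @param path Path to the design TSV.
#' @param format `"mipgen"` or `"bedlike"`.
#' @param class_path Optional path to a companion TSV with columns
#'   `mip_id`, `probe_class` and (for inversion probes) `event_id`.
#' @return A `mip_design` tibble with columns `mip_id`, `chrom`,
#'   `ext_arm_seq`, `lig_arm_seq`, `scan_start`, `scan_end`, `strand`,
#'   `probe_class`, `event_id`, plus derived `win_start`/`win_end` (the
#'   arm-flanked window) and an attached `target_regions` attribute.
#' @export
read_mip_design <- function(path, format = c("mipgen", "bedlike"),
                            class_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("design file not found: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- if (format == "mipgen") MIPGEN_REQUIRED else BEDLIKE_REQUIRED
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("design file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mipseqr_format_error")
  }
  arm_coord_cols <- c("ext_probe_start", "ext_probe_stop",
                      "lig_probe_start", "lig_probe_stop")
  extra <- setdiff(names(raw), c(required, arm_coord_cols))
  if (format == "mipgen" && length(extra) > 0) {
    inform(paste0("ignoring ", length(extra), " extra design column(s): ",
                  paste(extra, collapse = ", ")))
  }
  if (format == "mipgen" && all(arm_coord_cols %in% names(raw))) {
    check_mipgen_arm_coords(raw)
  }

  probes <- if (format == "mipgen") {
    tibble(
      mip_id      = as.character(raw$mip_name),
      chrom       = as.character(raw$chr),
      ext_arm_seq = toupper(raw$ext_probe_sequence),
      lig_arm_seq = toupper(raw$lig_probe_sequence),
      # MIPgen scan coordinates are 1-based inclusive
      scan_start  = as.integer(raw$mip_scan_start_position) - 1L,
      scan_end    = as.integer(raw$mip_scan_stop_position),
      strand      = as.character(raw$probe_strand)
    )
  } else {
    tibble(
      mip_id      = as.character(raw$mip_id),
      chrom       = as.character(raw$chrom),
      ext_arm_seq = toupper(raw$ext_arm_seq),
      lig_arm_seq = toupper(raw$lig_arm_seq),
      scan_start  = as.integer(raw$scan_start),
      scan_end    = as.integer(raw$scan_end),
      strand      = as.character(raw$strand)
    )
  }

  classes <- if (!is.null(class_path)) {
    cls <- readr::read_tsv(class_path, show_col_types = FALSE,
                           progress = FALSE)
    miss <- setdiff(c("mip_id", "probe_class"), names(cls))
    if (length(miss) > 0) {
      abort(paste0("probe class file is missing column(s): ",
                   paste(miss, collapse = ", ")),
            class = "mipseqr_format_error")
    }
    if (!"event_id" %in% names(cls)) cls$event_id <- NA_character_
    dplyr::select(cls, "mip_id", "probe_class", "event_id")
  } else {
    tibble(mip_id = character(0), probe_class = character(0),
           event_id = character(0))
  }

  probes <- probes |>
    left_join(classes, by = "mip_id") |>
    mutate(
      probe_class = dplyr::coalesce(.data$probe_class, "target"),
      event_id = as.character(.data$event_id)
    )
  new_mip_design(probes)
}

# MIPgen arm coordinates are 1-based inclusive. Arms must sit immediately
# adjacent to (never overlapping) the scan target: on "+" the ext arm ends
# one base before the scan and the lig arm starts one base after it; on "-"
# the arm order is mirrored.
check_mipgen_arm_coords <- function(raw) {
  scan_start1 <- as.integer(raw$mip_scan_start_position)
  scan_stop1 <- as.integer(raw$mip_scan_stop_position)
  plus <- raw$probe_strand == "+"
  up_stop <- if_else(plus, as.integer(raw$ext_probe_stop),
                     as.integer(raw$lig_probe_stop))
  dn_start <- if_else(plus, as.integer(raw$lig_probe_start),
                      as.integer(raw$ext_probe_start))
  bad <- raw$mip_name[up_stop != scan_start1 - 1L | dn_start != scan_stop1 + 1L]
  if (length(bad) > 0) {
    abort(paste0("arm interval not adjacent to scan target for probe(s): ",
                 paste(bad, collapse = ", ")),
          class = "mipseqr_validation_error")
  }
  invisible(TRUE)
}

# Validates probe rows, attaches window coordinates and target regions.
new_mip_design <- function(probes) {
  probes <- as_tibble(probes)
  if (!"event_id" %in% names(probes)) probes$event_id <- NA_character_
  if (!"probe_class" %in% names(probes)) probes$probe_class <- "target"

  if (anyDuplicated(probes$mip_id)) {
    dup <- unique(probes$mip_id[duplicated(probes$mip_id)])
    abort(paste0("duplicate mip_id: ", paste(dup, collapse = ", ")),
          class = "mipseqr_validation_error")
  }
  bad_class <- setdiff(unique(probes$probe_class), PROBE_CLASSES)
  if (length(bad_class) > 0) {
    abort(paste0("unknown probe_class: ", paste(bad_class, collapse = ", ")),
          class = "mipseqr_validation_error")
  }
  bad_strand <- probes$mip_id[!probes$strand %in% c("+", "-")]
  if (length(bad_strand) > 0) {
    abort(paste0("invalid strand for probe(s): ",
                 paste(bad_strand, collapse = ", ")),
          class = "mipseqr_validation_error")
  }

  ext_len <- nchar(probes$ext_arm_seq)
  lig_len <- nchar(probes$lig_arm_seq)
  bad_geom <- probes$mip_id[
    probes$scan_start >= probes$scan_end |
      ext_len < 15L | ext_len > 40L | lig_len < 15L | lig_len > 40L
  ]
  if (length(bad_geom) > 0) {
    abort(paste0("invalid arm/scan geometry for probe(s): ",
                 paste(bad_geom, collapse = ", ")),
          class = "mipseqr_validation_error")
  }

  # arm intervals flank the scan: upstream arm is ext on "+", lig on "-"
  up_len <- if_else(probes$strand == "+", ext_len, lig_len)
  dn_len <- if_else(probes$strand == "+", lig_len, ext_len)
  probes <- probes |>
    mutate(win_start = .data$scan_start - up_len,
           win_end = .data$scan_end + dn_len)
  if (any(probes$win_start < 0)) {
    abort(paste0("arm interval extends before position 0 for probe(s): ",
                 paste(probes$mip_id[probes$win_start < 0], collapse = ", ")),
          class = "mipseqr_validation_error")
  }

  # every inversion_mut probe must share an event with an inversion_ref probe
  mut <- probes[probes$probe_class == "inversion_mut", ]
  ref_events <- unique(probes$event_id[probes$probe_class == "inversion_ref"])
  orphans <- mut$mip_id[is.na(mut$event_id) | !mut$event_id %in% ref_events]
  if (length(orphans) > 0) {
    abort(paste0("inversion_mut probe(s) without a matching inversion_ref ",
                 "event: ", paste(orphans, collapse = ", ")),
          class = "mipseqr_validation_error")
  }

  probes <- arrange(probes, .data$chrom, .data$scan_start, .data$mip_id)
  attr(probes, "target_regions") <- derive_target_regions(probes)
  class(probes) <- c("mip_design", class(probes))
  probes
}

derive_target_regions <- function(probes) {
  tgt <- probes[probes$probe_class == "target", ]
  if (nrow(tgt) == 0) {
    return(tibble(chrom = character(0), start = integer(0),
                  end = integer(0), label = character(0)))
  }
  tgt |>
    group_by(.data$chrom) |>
    dplyr::reframe(merge_intervals(.data$scan_start, .data$scan_end)) |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(label = paste0(.data$chrom, ":", .data$start + 1L, "-",
                          .data$end)) |>
    ungroup()
}

#' Target regions of a MIP design
#'
#' Merged, sorted scan intervals of all `target`-class probes.
#'
#' @param design A `mip_design` tibble.
#' @return Tibble with columns `chrom`, `start`, `end` (0-based half-open)
#'   and `label`.
#' @export
target_regions <- function(design) {
  stopifnot(inherits(design, "mip_design"))
  attr(design, "target_regions")
}

#' Write a MIP design back to disk
#'
#' Writes the MIPgen dialect (1-based inclusive scan coordinates) so that
#' `read_mip_design()` round-trips to an identical design.
#'
#' @param design A `mip_design` tibble.
#' @param path Output TSV path.
#' @param class_path Optional path for the companion probe-class TSV; written
#'   only if any probe is not `target`-class or if given.
#' @return `path`, invisibly.
#' @export
write_mip_design <- function(design, path, class_path = NULL) {
  out <- tibble(
    mip_name = design$mip_id,
    chr = design$chrom,
    ext_probe_sequence = design$ext_arm_seq,
    lig_probe_sequence = design$lig_arm_seq,
    mip_scan_start_position = design$scan_start + 1L,
    mip_scan_stop_position = design$scan_end,
    probe_strand = design$strand
  )
  readr::write_tsv(out, path, progress = FALSE)
  if (!is.null(class_path) || any(design$probe_class != "target")) {
    if (is.null(class_path)) {
      class_path <- file.path(dirname(path), "probe_classes.tsv")
    }
    readr::write_tsv(
      dplyr::select(as_tibble(design), "mip_id", "probe_class", "event_id"),
      class_path, progress = FALSE
    )
  }
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path TSV/CSV with header columns `sample_id`, `barcode1` and
#'   optionally `barcode2` (dual index).
#' @return A tibble with `sample_id`, `barcode1`, `barcode2` (NA when single
#'   index); barcodes upper-cased and length-checked.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) abort(paste0("sample sheet not found: ", path))
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  sheet <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
  validate_sample_sheet(sheet)
}

validate_sample_sheet <- function(sheet) {
  sheet <- as_tibble(sheet)
  miss <- setdiff(c("sample_id", "barcode1"), names(sheet))
  if (length(miss) > 0) {
    abort(paste0("sample sheet is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "mipseqr_format_error")
  }
  if (nrow(sheet) == 0) {
    abort("no samples in sample sheet", class = "mipseqr_validation_error")
  }
  if (!"barcode2" %in% names(sheet)) sheet$barcode2 <- NA_character_
  sheet <- sheet |>
    mutate(sample_id = as.character(.data$sample_id),
           barcode1 = toupper(.data$barcode1),
           barcode2 = toupper(as.character(.data$barcode2))) |>
    dplyr::select("sample_id", "barcode1", "barcode2")

  if (anyDuplicated(sheet$sample_id)) {
    abort(paste0("duplicate sample_id: ",
                 paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
                       collapse = ", ")),
          class = "mipseqr_validation_error")
  }
  for (col in c("barcode1", "barcode2")) {
    bc <- sheet[[col]]
    if (all(is.na(bc))) next
    if (any(is.na(bc))) {
      abort(paste0(col, " must be present for all samples or none"),
            class = "mipseqr_validation_error")
    }
    if (length(unique(nchar(bc))) != 1) {
      abort(paste0(col, " barcodes differ in length"),
            class = "mipseqr_validation_error")
    }
    if (!all(grepl("^[ACGTN]+$", bc))) {
      abort(paste0(col, " contains non-DNA characters"),
            class = "mipseqr_validation_error")
    }
  }
  key <- paste(sheet$barcode1, sheet$barcode2, sep = "|")
  if (anyDuplicated(key)) {
    dup_key <- key[duplicated(key)][1]
    clash <- sheet$sample_id[key == dup_key]
    abort(paste0("duplicate barcode combination shared by samples: ",
                 paste(clash, collapse = ", ")),
          class = "mipseqr_validation_error")
  }
  sheet
}
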