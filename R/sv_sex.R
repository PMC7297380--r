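# Structural-variant (inversion) genotyping by contig counts and sex
# inference from Y-unique (SRY) probe counts.
#
# Recurrent large inversions (e.g. the F8 intron 1 / intron 22 inversions
# behind much of severe hemophilia A) are not callable from short-read
# pileups; instead the design carries junction contigs in reference and
# mutant (inverted) form, all reads are aligned against that contig-only
# reference in a second pass, and per-contig read counts decide the event
# status. Affected patients are hemizygous males, so a near-pure mutant
# signal is expected; a heterozygous-carrier mode is just a lower
# `mut_frac_threshold`.

#' Count reads per structural-variant contig
#'
#' @param aln Alignment tibble against the SV contig reference.
#' @param design A `mip_design` tibble whose inversion probes carry
#'   `event_id` and whose `chrom` names the SV contigs.
#' @param min_mapq Reads below this MAPQ are excluded (default 20).
#' @param samples Optional character vector fixing the sample set, so
#'   samples without any SV-aligned read still appear with zero counts
#'   (and can FAIL the event) rather than dropping out.
#' @return Tibble per (sample_id, contig): `event_id`, `contig_class`
#'   (`ref`/`mut`/`UNKNOWN`), `n_reads`. Contigs present in the alignment
#'   but absent from the design are counted under `UNKNOWN` with a
#'   warning.
#' @export
count_sv_contigs <- function(aln, design, min_mapq = 20L, samples = NULL) {
  contig_map <- as_tibble(design) |>
    filter(.data$probe_class %in% c("inversion_ref", "inversion_mut")) |>
    distinct(.data$chrom, .data$event_id, .data$probe_class) |>
    mutate(contig_class = if_else(.data$probe_class == "inversion_ref",
                                  "ref", "mut")) |>
    select(contig = "chrom", "event_id", "contig_class")
  counted <- aln |>
    filter(!is.na(.data$chrom), .data$mapq >= min_mapq) |>
    count(.data$sample_id, contig = .data$chrom, name = "n_reads")
  unknown <- setdiff(unique(counted$contig), contig_map$contig)
  if (length(unknown) > 0) {
    warn(paste0("contig(s) not in design, counted as UNKNOWN: ",
                paste(unknown, collapse = ", ")))
  }
  if (is.null(samples)) samples <- sort(unique(aln$sample_id))
  grid <- tidyr::expand_grid(sample_id = samples,
                             contig = contig_map$contig)
  grid |>
    left_join(counted, by = c("sample_id", "contig")) |>
    mutate(n_reads = dplyr::coalesce(.data$n_reads, 0L)) |>
    bind_rows(
      counted |> filter(.data$contig %in% unknown)
    ) |>
    left_join(contig_map, by = "contig") |>
    mutate(event_id = dplyr::coalesce(.data$event_id, "UNKNOWN"),
           contig_class = dplyr::coalesce(.data$contig_class, "UNKNOWN")) |>
    arrange(.data$sample_id, .data$event_id, .data$contig_class)
}

#' Call one inversion event from ref/mut read counts
#'
#' Vectorised decision rule: totals under `min_event_reads` FAIL; a mutant
#' fraction at or above `mut_frac_threshold` is INVERTED; at or below
#' `1 - mut_frac_threshold` is REF; anything between is AMBIGUOUS.
#'
#' @param ref_count,mut_count Non-negative read counts.
#' @param min_event_reads Minimum total evidence (default 10).
#' @param mut_frac_threshold Decision fraction (default 0.8 — hemizygous
#'   patients give near-pure mutant signal; use ~0.3 for heterozygous
#'   carrier screening).
#' @return Character vector of `REF`, `INVERTED`, `AMBIGUOUS`, `FAILED`.
#' @export
call_inversion <- function(ref_count, mut_count, min_event_reads = 10L,
                           mut_frac_threshold = 0.8) {
  stopifnot(all(ref_count >= 0), all(mut_count >= 0),
            mut_frac_threshold > 0.5, mut_frac_threshold <= 1)
  total <- ref_count + mut_count
  mut_frac <- if_else(total > 0, mut_count / total, 0)
  dplyr::case_when(
    total < min_event_reads ~ "FAILED",
    mut_frac >= mut_frac_threshold ~ "INVERTED",
    mut_frac <= 1 - mut_frac_threshold ~ "REF",
    TRUE ~ "AMBIGUOUS"
  )
}

#' Inversion calls for all samples and events
#'
#' @param sv_counts Output of [count_sv_contigs()].
#' @param min_event_reads,mut_frac_threshold See [call_inversion()].
#' @return Tibble per (sample_id, event_id): `ref_count`, `mut_count`,
#'   `status`.
#' @export
call_inversions <- function(sv_counts, min_event_reads = 10L,
                            mut_frac_threshold = 0.8) {
  sv_counts |>
    filter(.data$event_id != "UNKNOWN") |>
    group_by(.data$sample_id, .data$event_id) |>
    summarise(
      ref_count = sum(.data$n_reads[.data$contig_class == "ref"]),
      mut_count = sum(.data$n_reads[.data$contig_class == "mut"]),
      .groups = "drop"
    ) |>
    mutate(status = call_inversion(.data$ref_count, .data$mut_count,
                                   min_event_reads, mut_frac_threshold))
}

#' Call sample sex from SRY probe read counts
#'
#' Male when the SRY count clears both an absolute floor and a fraction of
#' the sample's assigned reads; female when it is at most `female_max`
#' (tolerating index hopping / trace contamination); ambiguous between.
#'
#' @param sry_count Reads assigned to SRY-class probes, per sample.
#' @param total_assigned Total assigned reads, per sample.
#' @param abs_threshold Absolute male threshold (default 10).
#' @param rel_threshold Relative male threshold (default 5e-4).
#' @param female_max Maximum SRY reads still called female (default 2).
#' @return Tibble: `sry_count`, `total_assigned`, `sex` in
#'   `male`/`female`/`ambiguous`.
#' @export
call_sex <- function(sry_count, total_assigned, abs_threshold = 10L,
                     rel_threshold = 5e-4, female_max = 2L) {
  stopifnot(all(sry_count >= 0), all(total_assigned >= 0),
            all(sry_count <= total_assigned))
  male_cut <- pmax(abs_threshold, rel_threshold * total_assigned)
  tibble(
    sry_count = as.integer(sry_count),
    total_assigned = as.integer(total_assigned),
    sex = dplyr::case_when(
      sry_count >= male_cut ~ "male",
      sry_count <= female_max ~ "female",
      TRUE ~ "ambiguous"
    )
  )
}

#' Per-sample sex calls from assigned alignments
#'
#' @param aln Assigned alignment tibble (post [assign_mips()]).
#' @param design A `mip_design` tibble with `sry`-class probes.
#' @param ... Passed to [call_sex()].
#' @return Tibble per sample: `sample_id`, `sry_count`, `total_assigned`,
#'   `sex`.
#' @export
call_sex_from_assignments <- function(aln, design, ...) {
  sry_mips <- design$mip_id[design$probe_class == "sry"]
  per_sample <- aln |>
    filter(!is.na(.data$mip_id), !is.na(.data$sample_id)) |>
    group_by(.data$sample_id) |>
    summarise(sry_count = sum(.data$mip_id %in% sry_mips),
              total_assigned = n(), .groups = "drop")
  bind_cols(
    per_sample["sample_id"],
    call_sex(per_sample$sry_count, per_sample$total_assigned, ...)
  )
}

#' Write inversion calls as CSV
#'
#' @param inv_calls Tibble from [call_inversions()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_inversion_calls <- function(inv_calls, path) {
  readr::write_csv(
    inv_calls[, c("sample_id", "event_id", "ref_count", "mut_count",
                  "status")],
    path, progress = FALSE
  )
  invisible(path)
}
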