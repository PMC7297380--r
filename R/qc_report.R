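# Per-sample QC integration, CSV tables and HTML reports.
#
# The roll-up mirrors how a screening lab reads a run: a per-sample quality
# flag with strict priority (Failed Sample > Failed Inversions > Check MIPs
# > OK), per-probe outlier flags against the cross-sample median
# representation, and five CSV tables joinable on the sample id or the
# chrom:pos:ref:alt variant key. HTML reports carry stable element ids so
# tests can compare parsed structure rather than bytes.

#' Flag under- and over-performing MIPs per sample
#'
#' A probe fails for a sample when its read count is below `min_reads` or
#' its relative abundance is below `min_rel_frac` times that probe's
#' median relative abundance across samples; it overperforms above
#' `over_factor` times the median. Only `target`-class probes are judged
#' (SRY probes are legitimately empty in female samples).
#'
#' @param stats [compute_mip_stats()] result over >= 2 samples.
#' @param design A `mip_design` tibble.
#' @param min_reads Absolute count floor (default 10).
#' @param min_rel_frac Relative underperformance factor (default 0.05).
#' @param over_factor Relative overperformance factor (default 20).
#' @return Tibble `sample_id`, `mip_id`, `type` (`failed`/`overperforming`).
#' @export
flag_outlier_mips <- function(stats, design, min_reads = 10L,
                              min_rel_frac = 0.05, over_factor = 20) {
  if (length(unique(stats$sample_id)) < 2) {
    abort("outlier flagging needs statistics over at least 2 samples")
  }
  target_ids <- design$mip_id[design$probe_class == "target"]
  stats |>
    filter(.data$mip_id %in% target_ids) |>
    group_by(.data$mip_id) |>
    mutate(med_rel = median(.data$rel_abundance)) |>
    ungroup() |>
    mutate(
      failed = .data$count < min_reads |
        .data$rel_abundance < min_rel_frac * .data$med_rel,
      over = .data$med_rel > 0 &
        .data$rel_abundance > over_factor * .data$med_rel
    ) |>
    filter(.data$failed | .data$over) |>
    mutate(type = if_else(.data$failed, "failed", "overperforming")) |>
    select("sample_id", "mip_id", "type") |>
    arrange(.data$sample_id, .data$mip_id)
}

#' Assign the per-sample quality flag
#'
#' Strict priority: `Failed Sample` (missing upstream results / no
#' assigned reads) > `Failed Inversions` (any inversion event FAILED) >
#' `Check MIPs` (>= `check_mips_min` failed probes, or target coverage
#' fraction below `pass_frac`) > `OK`.
#'
#' @param has_results Logical: upstream results present and sample has
#'   assigned reads.
#' @param any_failed_inversion Logical: any inversion status == FAILED.
#' @param n_failed_mips Integer count of failed probes for the sample.
#' @param frac_covered Fraction of target bases at callable depth.
#' @param check_mips_min Failed-probe threshold (default 5).
#' @param pass_frac Coverage pass fraction (default 0.95).
#' @return Character vector of flags.
#' @export
assign_sample_flag <- function(has_results, any_failed_inversion,
                               n_failed_mips, frac_covered,
                               check_mips_min = 5L, pass_frac = 0.95) {
  dplyr::case_when(
    !has_results ~ "Failed Sample",
    any_failed_inversion ~ "Failed Inversions",
    n_failed_mips >= check_mips_min | frac_covered < pass_frac ~
      "Check MIPs",
    TRUE ~ "OK"
  )
}

#' Read a benign / known-variant list
#'
#' @param path TSV with columns `chrom`, `pos` (1-based), `ref`, `alt` and
#'   optionally `label`.
#' @return Tibble keyed by 0-based `pos`.
#' @export
read_benign_list <- function(path) {
  b <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("chrom", "pos", "ref", "alt"), names(b))
  if (length(miss) > 0) {
    abort(paste0("benign list is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "mipseqr_format_error")
  }
  if (!"label" %in% names(b)) b$label <- "benign"
  mutate(b, pos = as.integer(.data$pos) - 1L)
}

#' Integrate per-sample QC
#'
#' @param samples Character vector of all samples on the run.
#' @param sex_calls Tibble from [call_sex_from_assignments()].
#' @param inv_calls Tibble from [call_inversions()].
#' @param calls Variant call tibble.
#' @param coverage Tibble from [profile_coverage()].
#' @param outliers Tibble from [flag_outlier_mips()].
#' @param adequate_mean Mean coverage (elsewhere) above which a sample's
#'   zero-coverage intervals are reported as candidate deletions
#'   (default 20).
#' @param check_mips_min,pass_frac See [assign_sample_flag()].
#' @return One row per sample: sex, per-event inversion status
#'   (list-column `inversions`), `n_gt_calls`, `covered_sites`,
#'   `mean_coverage`, `n_het`, `incomplete_regions`, `deletions`,
#'   `failed_mips` (semicolon strings), `flag`.
#' @export
build_sample_qc <- function(samples, sex_calls, inv_calls, calls, coverage,
                            outliers, adequate_mean = 20,
                            check_mips_min = 5L, pass_frac = 0.95) {
  fmt_iv <- function(chrom, iv) {
    if (nrow(iv) == 0) return("")
    paste0(chrom, ":", iv$start + 1L, "-", iv$end, collapse = ";")
  }
  rows <- lapply(samples, function(s) {
    sx <- sex_calls[sex_calls$sample_id == s, ]
    iv <- inv_calls[inv_calls$sample_id == s, ]
    cl <- calls[calls$sample_id == s, ]
    cv <- coverage[coverage$sample_id == s, ]
    fm <- outliers$mip_id[outliers$sample_id == s &
                            outliers$type == "failed"]
    has_results <- nrow(sx) == 1 && nrow(cv) > 0
    mean_cov <- if (nrow(cv) > 0) {
      stats::weighted.mean(cv$mean_coverage, cv$end - cv$start)
    } else 0
    frac_cov <- if (nrow(cv) > 0) {
      stats::weighted.mean(cv$frac_covered, cv$end - cv$start)
    } else 0
    called <- cl[!cl$genotype %in% c("./.", "."), ]
    incomplete <- if (nrow(cv) > 0) {
      paste(Filter(nzchar, purrr::map2_chr(cv$chrom, cv$incomplete,
                                           fmt_iv)), collapse = ";")
    } else ""
    deletions <- if (nrow(cv) > 0 && mean_cov >= adequate_mean) {
      paste(Filter(nzchar, purrr::map2_chr(cv$chrom, cv$zero_cov, fmt_iv)),
            collapse = ";")
    } else ""
    tibble(
      sample_id = s,
      sex = if (nrow(sx) == 1) sx$sex else "unknown",
      sry_count = if (nrow(sx) == 1) sx$sry_count else 0L,
      inversions = list(iv[, setdiff(names(iv), "sample_id")]),
      any_failed_inversion = nrow(iv) > 0 && any(iv$status == "FAILED"),
      n_gt_calls = nrow(called),
      covered_sites = frac_cov,
      mean_coverage = mean_cov,
      n_het = sum(called$genotype == "0/1"),
      incomplete_regions = incomplete,
      deletions = deletions,
      failed_mips = paste(fm, collapse = ";"),
      n_failed_mips = length(fm)
    )
  })
  bind_rows(rows) |>
    mutate(flag = assign_sample_flag(
      .data$sample_id %in% sex_calls$sample_id & .data$mean_coverage > 0,
      .data$any_failed_inversion, .data$n_failed_mips,
      .data$covered_sites, check_mips_min, pass_frac
    ))
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos + 1L, ref, alt, sep = ":")
}

#' Write the result CSV tables
#'
#' Writes `ind_status.csv`, `variant_calls.csv`, `variant_calls_benign.csv`
#' (the benign subset), `variant_annotation.csv` and
#' `inversion_calls.csv`. Tables join on `sample_id` or on the
#' `chrom:pos:ref:alt` variant key; positions in files are 1-based.
#'
#' @param qc [build_sample_qc()] result.
#' @param calls Variant call tibble.
#' @param inv_calls Inversion call tibble.
#' @param outdir Output directory (created if needed).
#' @param benign Optional benign-list tibble ([read_benign_list()]).
#' @param annotation Optional annotation tibble ([read_annotation()]).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_csv_tables <- function(qc, calls, inv_calls, outdir, benign = NULL,
                             annotation = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    ind_status = file.path(outdir, "ind_status.csv"),
    variant_calls = file.path(outdir, "variant_calls.csv"),
    variant_calls_benign = file.path(outdir, "variant_calls_benign.csv"),
    variant_annotation = file.path(outdir, "variant_annotation.csv"),
    inversion_calls = file.path(outdir, "inversion_calls.csv")
  )

  inv_wide <- qc |>
    select("sample_id", "inversions") |>
    tidyr::unnest("inversions") |>
    select("sample_id", "event_id", "status") |>
    tidyr::pivot_wider(names_from = "event_id", values_from = "status")
  ind <- qc |>
    select("sample_id", "sex", "sry_count", "n_gt_calls", "covered_sites",
           "mean_coverage", "n_het", "incomplete_regions", "deletions",
           "failed_mips", "flag") |>
    left_join(inv_wide, by = "sample_id") |>
    relocate(dplyr::any_of(setdiff(names(inv_wide), "sample_id")),
             .after = "sry_count") |>
    mutate(covered_sites = round(.data$covered_sites, 4),
           mean_coverage = round(.data$mean_coverage, 2))
  readr::write_csv(ind, paths["ind_status"], progress = FALSE)

  calls_out <- calls |>
    mutate(variant = variant_key(.data$chrom, .data$pos, .data$ref,
                                 .data$alt),
           benign_flag = if (is.null(benign)) FALSE else {
             .data$variant %in% variant_key(benign$chrom, benign$pos,
                                            benign$ref, benign$alt)
           }) |>
    mutate(pos = .data$pos + 1L) |>
    select("variant", "sample_id", "chrom", "pos", "ref", "alt",
           "genotype", "gq", "ad_ref", "ad_alt", "dp", "filter",
           "benign_flag")
  readr::write_csv(calls_out, paths["variant_calls"], progress = FALSE)
  readr::write_csv(filter(calls_out, .data$benign_flag),
                   paths["variant_calls_benign"], progress = FALSE)

  variants <- calls |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    mutate(variant = variant_key(.data$chrom, .data$pos, .data$ref,
                                 .data$alt))
  ann_cols <- c("gene", "region_label", "cdna_pos", "cds_pos", "hgvs_c",
                "hgvs_p", "rsid", "af_1000g")
  ann_out <- if (!is.null(annotation)) {
    variants |>
      left_join(annotation, by = c("chrom", "pos", "ref", "alt"))
  } else {
    v <- variants
    for (col in ann_cols) v[[col]] <- NA
    v
  }
  ann_out <- ann_out |>
    mutate(pos = .data$pos + 1L) |>
    select("variant", "chrom", "pos", "ref", "alt",
           dplyr::all_of(ann_cols))
  readr::write_csv(ann_out, paths["variant_annotation"], progress = FALSE)

  write_inversion_calls(inv_calls, paths["inversion_calls"])
  invisible(paths)
}
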