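# End-to-end pipeline orchestration.
#
# In-process sequential stages: demultiplex -> merge -> align -> probe
# assignment & arm trimming -> representation stats / sex counts ->
# coverage -> downsampling -> genotyping (internal caller or external VCF)
# -> SV contig pass -> inversion & sex calls -> QC flags -> CSV/VCF/HTML
# outputs. Stage read counts are conserved and logged.

#' Pipeline configuration
#'
#' All tunable thresholds with their defaults; unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A `pipeline_config` list with entries: `max_mismatch` (1,
#'   barcode mismatches per index), `min_overlap` (11) /
#'   `max_mismatch_frac` (0.05) / `qual_cap` (60) for merging, `tol` (5,
#'   probe endpoint tolerance), `cap` (500, downsampling cap per sample
#'   and target), `min_call_depth` (8), `error_floor` (1e-4),
#'   `min_alt_count` (3) / `min_alt_frac` (0.2) for site discovery,
#'   `adequate_mean` (20, mean coverage needed before zero-coverage
#'   intervals count as deletions), `min_mapq` (20, SV pass filter),
#'   `min_event_reads` (10) / `mut_frac_threshold` (0.8) for inversion
#'   calls, `abs_threshold` (10) / `rel_threshold` (5e-4) / `female_max`
#'   (2) for sex calls, `min_reads` (10) / `min_rel_frac` (0.05) /
#'   `over_factor` (20) for MIP outliers, `check_mips_min` (5) /
#'   `pass_frac` (0.95) for sample flags, `hemizygous_x` (FALSE: call
#'   ploidy 1 on X-linked target loci in inferred males), `x_chroms`
#'   (character(0)), and `seed` (1, downsampling).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    max_mismatch = 1L,
    min_overlap = 11L, max_mismatch_frac = 0.05, qual_cap = 60L,
    tol = 5L,
    cap = 500L, min_call_depth = 8L, error_floor = 1e-4,
    min_alt_count = 3L, min_alt_frac = 0.2, adequate_mean = 20,
    min_mapq = 20L, min_event_reads = 10L, mut_frac_threshold = 0.8,
    abs_threshold = 10L, rel_threshold = 5e-4, female_max = 2L,
    min_reads = 10L, min_rel_frac = 0.05, over_factor = 20,
    check_mips_min = 5L, pass_frac = 0.95,
    hemizygous_x = FALSE, x_chroms = character(0),
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")),
          class = "mipseqr_config_error")
  }
  cfg <- utils::modifyList(defaults, over)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline from input files
#'
#' @param r1,r2 Paired FASTQ paths.
#' @param i1,i2 Index FASTQ paths (`NULL` for inline barcodes, see
#'   `inline_barcode_len`).
#' @param design Path to the MIP design TSV (MIPgen dialect).
#' @param probe_classes Optional probe-class companion TSV path.
#' @param sample_sheet Sample sheet path.
#' @param reference Reference FASTA (target loci + SRY contig).
#' @param sv_reference Optional SV contig FASTA (inversion ref/mut
#'   junction contigs).
#' @param outdir Run directory for all outputs.
#' @param config A [pipeline_config()].
#' @param benign Optional benign-list TSV path.
#' @param annotation Optional variant-annotation TSV path.
#' @param external_vcf Optional externally called VCF; replaces the
#'   internal genotyper when given.
#' @param inline_barcode_len Inline 5' barcode length when no index read
#'   exists.
#' @return A `mip_run` object (list of stage tibbles + output paths); see
#'   [tidy.mip_run()], [glance.mip_run()], [autoplot.mip_run()].
#' @export
run_pipeline <- function(r1, r2, i1 = NULL, i2 = NULL, design,
                         probe_classes = NULL, sample_sheet, reference,
                         sv_reference = NULL, outdir,
                         config = pipeline_config(), benign = NULL,
                         annotation = NULL, external_vcf = NULL,
                         inline_barcode_len = NULL) {
  inputs <- c(r1, r2, i1, i2, design, probe_classes, sample_sheet,
              reference, sv_reference, benign, annotation, external_vcf)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in) > 0) {
    abort(paste0("input file(s) not found: ",
                 paste(missing_in, collapse = ", ")),
          class = "mipseqr_config_error")
  }
  dsn <- read_mip_design(design, format = "mipgen",
                         class_path = probe_classes)
  sheet <- read_sample_sheet(sample_sheet)
  ref <- read_reference(reference)
  sv_ref <- if (!is.null(sv_reference)) read_reference(sv_reference)
  pairs <- read_pairs(r1, r2, i1, i2)
  if (is.null(i1)) {
    if (is.null(inline_barcode_len)) {
      abort("no index read given: set inline_barcode_len",
            class = "mipseqr_config_error")
    }
    pairs <- extract_inline_barcodes(pairs, inline_barcode_len)
  }
  run_pipeline_data(pairs, dsn, sheet, ref, sv_ref, outdir, config,
                    benign = if (!is.null(benign)) read_benign_list(benign),
                    annotation = if (!is.null(annotation))
                      read_annotation(annotation),
                    external_vcf = external_vcf)
}

#' Run the pipeline on in-memory inputs
#'
#' The core of [run_pipeline()]; also accepts [simulate_run()] output
#' directly via [run_simulated()].
#'
#' @param pairs Read-pair tibble with `index1` (and optional `index2`).
#' @param design,sheet,ref,sv_ref Parsed design, sample sheet and
#'   references.
#' @param outdir Run directory.
#' @param config A [pipeline_config()].
#' @param benign,annotation Optional parsed benign/annotation tibbles.
#' @param external_vcf Optional external VCF path.
#' @return A `mip_run` object.
#' @export
run_pipeline_data <- function(pairs, design, sheet, ref, sv_ref = NULL,
                              outdir, config = pipeline_config(),
                              benign = NULL, annotation = NULL,
                              external_vcf = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  counts <- list(input_pairs = nrow(pairs))

  # demultiplex
  pairs <- demultiplex(pairs, sheet, max_mismatch = config$max_mismatch)
  dsum <- demux_summary(pairs, sheet)
  readr::write_tsv(dsum, file.path(outdir, "demux_summary.tsv"),
                   progress = FALSE)
  counts$assigned_pairs <- sum(!is.na(pairs$sample_id))
  counts$unassigned_pairs <- sum(is.na(pairs$sample_id))
  assigned <- filter(pairs, !is.na(.data$sample_id))

  # overlap consensus merging
  merged <- merge_pairs(assigned, min_overlap = config$min_overlap,
                        max_mismatch_frac = config$max_mismatch_frac,
                        qual_cap = config$qual_cap)
  counts$merged_pairs <- sum(merged$merged)
  counts$unmerged_pairs <- sum(!merged$merged)

  # alignment input: consensus reads plus unmerged mates
  mg <- filter(merged, .data$merged)
  um <- filter(merged, !.data$merged)
  reads <- bind_rows(
    tibble(read_id = mg$read_id, sample_id = mg$sample_id,
           seq = mg$seq, qual = mg$qual, merged = TRUE),
    tibble(read_id = paste0(um$read_id, "/1"), sample_id = um$sample_id,
           seq = um$seq1, qual = um$qual1, merged = FALSE),
    tibble(read_id = paste0(um$read_id, "/2"), sample_id = um$sample_id,
           seq = um$seq2, qual = um$qual2, merged = FALSE)
  )
  aln <- align_reads(reads, ref)
  counts$mapped_reads <- sum(!is.na(aln$chrom))
  counts$unmapped_reads <- sum(is.na(aln$chrom))

  # probe assignment, arm trimming, representation stats
  aln <- assign_mips(aln, design, tol = config$tol)
  counts$mip_assigned <- sum(!is.na(aln$mip_id))
  stats <- compute_mip_stats(aln, design, samples = sheet$sample_id)
  write_mip_stats(stats, file.path(outdir, "mip_stats.tsv"))
  sex_calls <- call_sex_from_assignments(
    aln, design, abs_threshold = config$abs_threshold,
    rel_threshold = config$rel_threshold, female_max = config$female_max
  )
  readr::write_tsv(sex_calls, file.path(outdir, "sry_counts.tsv"),
                   progress = FALSE)
  trimmed <- trim_arms(aln, design)
  counts$trim_dropped <- attr(trimmed, "n_dropped")
  counts$trimmed_reads <- nrow(trimmed)
  write_sam(trimmed, vapply(ref, nchar, integer(1)),
            file.path(outdir, "trimmed.sam"))

  # coverage (full depth), then capped depth for calling
  target_trimmed <- filter(
    trimmed,
    .data$mip_id %in% design$mip_id[design$probe_class == "target"]
  )
  coverage <- profile_coverage(target_trimmed, design,
                               min_call_depth = config$min_call_depth)
  ds <- downsample_by_target(target_trimmed, cap = config$cap,
                             seed = config$seed)
  counts$reads_for_calling <- nrow(ds)

  ploidy_map <- NULL
  if (isTRUE(config$hemizygous_x) && length(config$x_chroms) > 0) {
    males <- sex_calls$sample_id[sex_calls$sex == "male"]
    ploidy_map <- tidyr::expand_grid(sample_id = males,
                                     chrom = config$x_chroms) |>
      mutate(ploidy = 1L)
  }
  calls <- if (!is.null(external_vcf)) {
    ingest_external_vcf(external_vcf, samples = sheet$sample_id)
  } else {
    call_variants(pileup(ds, ref), ref, samples = sort(unique(ds$sample_id)),
                  ploidy_map = ploidy_map,
                  min_call_depth = config$min_call_depth,
                  error_floor = config$error_floor,
                  min_alt_count = config$min_alt_count,
                  min_alt_frac = config$min_alt_frac)
  }
  write_vcf(calls, vapply(ref, nchar, integer(1)),
            file.path(outdir, "calls.vcf"),
            samples = sort(sheet$sample_id))

  # SV contig pass: all reads against the SV-only reference
  if (!is.null(sv_ref) && length(sv_ref) > 0) {
    sv_aln <- align_reads(reads, sv_ref)
    sv_counts <- count_sv_contigs(sv_aln, design,
                                  min_mapq = config$min_mapq,
                                  samples = sheet$sample_id)
    inv_calls <- call_inversions(
      sv_counts, min_event_reads = config$min_event_reads,
      mut_frac_threshold = config$mut_frac_threshold
    )
  } else {
    sv_counts <- tibble(sample_id = character(0), contig = character(0),
                        n_reads = integer(0), event_id = character(0),
                        contig_class = character(0))
    inv_calls <- tibble(sample_id = character(0), event_id = character(0),
                        ref_count = integer(0), mut_count = integer(0),
                        status = character(0))
  }

  # QC roll-up and reporting
  outliers <- flag_outlier_mips(stats, design, min_reads = config$min_reads,
                                min_rel_frac = config$min_rel_frac,
                                over_factor = config$over_factor)
  qc <- build_sample_qc(sheet$sample_id, sex_calls, inv_calls, calls,
                        coverage, outliers,
                        adequate_mean = config$adequate_mean,
                        check_mips_min = config$check_mips_min,
                        pass_frac = config$pass_frac)
  csv_paths <- write_csv_tables(qc, calls, inv_calls, outdir,
                                benign = benign, annotation = annotation)
  html_paths <- render_reports(qc, calls, inv_calls, coverage, stats,
                               outliers, outdir, benign = benign)

  log <- list(
    package_version = as.character(utils::packageVersion("mipseqr")),
    config = unclass(config),
    counts = counts
  )
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  res <- list(
    design = design, sheet = sheet, demux_summary = dsum, merged = merged,
    aln = aln, trimmed = trimmed, stats = stats, outliers = outliers,
    coverage = coverage, calls = calls, sv_counts = sv_counts,
    inv_calls = inv_calls, sex_calls = sex_calls, qc = qc,
    counts = counts, config = config, outdir = outdir,
    paths = c(csv_paths, html_paths)
  )
  class(res) <- "mip_run"
  res
}

#' Run the pipeline directly on a simulation
#'
#' @param sim Output of [simulate_run()].
#' @param outdir Run directory.
#' @param config A [pipeline_config()].
#' @param ... Passed on to [run_pipeline_data()].
#' @return A `mip_run` object.
#' @export
run_simulated <- function(sim, outdir, config = pipeline_config(), ...) {
  run_pipeline_data(sim$pairs, sim$design, sim$sheet, sim$ref, sim$sv_ref,
                    outdir, config, ...)
}

#' @export
print.mip_run <- function(x, ...) {
  cat("<mip_run>", nrow(x$sheet), "samples,",
      x$counts$input_pairs, "read pairs\n")
  cat("  assigned:", x$counts$assigned_pairs,
      " merged:", x$counts$merged_pairs,
      " MIP-assigned:", x$counts$mip_assigned, "\n")
  cat("  variant call records:", nrow(x$calls),
      " flags:", paste(sprintf("%s=%d", names(table(x$qc$flag)),
                               table(x$qc$flag)), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a pipeline run into its variant calls
#'
#' @param x A `mip_run`.
#' @param ... Unused.
#' @return The variant call tibble.
#' @method tidy mip_run
#' @export
tidy.mip_run <- function(x, ...) x$calls

#' One-row summary of a pipeline run
#'
#' @param x A `mip_run`.
#' @param ... Unused.
#' @return One-row tibble: sample/read totals, assignment and merge
#'   fractions, variant site count, samples flagged OK.
#' @method glance mip_run
#' @export
glance.mip_run <- function(x, ...) {
  tibble(
    n_samples = nrow(x$sheet),
    n_pairs = x$counts$input_pairs,
    frac_assigned = x$counts$assigned_pairs / max(1, x$counts$input_pairs),
    frac_merged = x$counts$merged_pairs / max(1, x$counts$assigned_pairs),
    n_variant_sites = nrow(dplyr::distinct(x$calls, .data$chrom, .data$pos,
                                           .data$alt)),
    n_ok = sum(x$qc$flag == "OK"),
    mean_coverage = mean(x$qc$mean_coverage)
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
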