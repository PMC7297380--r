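# QC flags, CSV tables and HTML reports.

test_that("outlier MIP flagging uses the cross-sample median", {
  d <- toy_design()
  st <- tibble::tibble(
    sample_id = rep(c("S1", "S2", "S3"), each = 4),
    mip_id = rep(c("M01", "M02", "M03", "N01"), 3),
    count = c(100L, 100L, 0L, 100L,
              100L, 100L, 120L, 100L,
              100L, 100L, 110L, 100L)
  ) |>
    dplyr::group_by(sample_id) |>
    dplyr::mutate(rel_abundance = count / sum(count)) |>
    dplyr::ungroup()
  class(st) <- c("mip_stats", class(st))
  fl <- flag_outlier_mips(st, d, min_reads = 10, min_rel_frac = 0.05)
  # zero reads with positive median -> failed for that sample only
  expect_equal(fl$sample_id[fl$mip_id == "M03"], "S1")
  expect_equal(fl$type[fl$mip_id == "M03"], "failed")
  # probes at their median are never flagged
  expect_false(any(fl$mip_id %in% c("M01", "M02", "N01")))
  # strong relative underperformance flags even above min_reads
  st2 <- st
  st2$count[st2$sample_id == "S1" & st2$mip_id == "M03"] <- 11L
  st2 <- st2 |>
    dplyr::group_by(sample_id) |>
    dplyr::mutate(rel_abundance = count / sum(count)) |>
    dplyr::ungroup()
  class(st2) <- c("mip_stats", class(st2))
  fl2 <- flag_outlier_mips(st2, d, min_reads = 10, min_rel_frac = 0.2)
  expect_true(any(fl2$mip_id == "M03" & fl2$sample_id == "S1" &
                    fl2$type == "failed"))
  expect_error(flag_outlier_mips(st[st$sample_id == "S1", ], d),
               "2 samples")
})

test_that("sample flags follow the strict priority order", {
  expect_equal(assign_sample_flag(TRUE, FALSE, 0, 1), "OK")
  expect_equal(assign_sample_flag(TRUE, TRUE, 20, 1), "Failed Inversions")
  expect_equal(assign_sample_flag(TRUE, FALSE, 5, 1), "Check MIPs")
  expect_equal(assign_sample_flag(TRUE, FALSE, 0, 0.5), "Check MIPs")
  expect_equal(assign_sample_flag(FALSE, FALSE, 0, 1), "Failed Sample")
  expect_equal(assign_sample_flag(FALSE, TRUE, 20, 0), "Failed Sample")
  # total and deterministic over randomized inputs
  set.seed(801)
  for (i in 1:200) {
    args <- list(sample(c(TRUE, FALSE), 1), sample(c(TRUE, FALSE), 1),
                 sample(0:30, 1), runif(1))
    f1 <- do.call(assign_sample_flag, args)
    expect_true(f1 %in% c("OK", "Failed Inversions", "Check MIPs",
                          "Failed Sample"))
    expect_identical(do.call(assign_sample_flag, args), f1)
  }
})

test_that("CSV tables have documented headers and join losslessly", {
  run <- small_run()
  outdir <- run$outdir
  ind <- readr::read_csv(file.path(outdir, "ind_status.csv"),
                         show_col_types = FALSE)
  expect_true(all(c("sample_id", "sex", "sry_count", "n_gt_calls",
                    "covered_sites", "mean_coverage", "n_het",
                    "incomplete_regions", "deletions", "failed_mips",
                    "flag") %in% names(ind)))
  expect_setequal(ind$sample_id, run$sheet$sample_id)  # no sample dropped
  vc <- readr::read_csv(file.path(outdir, "variant_calls.csv"),
                        show_col_types = FALSE)
  expect_true(all(c("variant", "sample_id", "chrom", "pos", "ref", "alt",
                    "genotype", "gq", "ad_ref", "ad_alt", "dp", "filter",
                    "benign_flag") %in% names(vc)))
  vb <- readr::read_csv(file.path(outdir, "variant_calls_benign.csv"),
                        show_col_types = FALSE)
  # benign table is a row-wise subset of the calls table
  key <- function(df) paste(df$variant, df$sample_id)
  expect_true(all(key(vb) %in% key(vc)))
  va <- readr::read_csv(file.path(outdir, "variant_annotation.csv"),
                        show_col_types = FALSE)
  # variant <-> annotation join is lossless
  j <- dplyr::left_join(vc, va, by = "variant",
                        suffix = c("", ".ann"))
  expect_equal(nrow(j), nrow(vc))
  expect_true(all(unique(vc$variant) %in% va$variant))
  ic <- readr::read_csv(file.path(outdir, "inversion_calls.csv"),
                        show_col_types = FALSE)
  expect_equal(names(ic), c("sample_id", "event_id", "ref_count",
                            "mut_count", "status"))
})

test_that("benign-listed variants subset into the benign table", {
  run <- small_run()
  calls <- run$calls
  called <- calls[!calls$genotype %in% c("./.", "0/0"), ]
  stopifnot(nrow(called) > 0)
  ben <- tibble::tibble(chrom = called$chrom[1], pos = called$pos[1] + 1L,
                        ref = called$ref[1], alt = called$alt[1],
                        label = "known benign")
  bp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(ben, bp, progress = FALSE)
  outdir <- withr::local_tempdir()
  write_csv_tables(run$qc, calls, run$inv_calls, outdir,
                   benign = read_benign_list(bp))
  vc <- readr::read_csv(file.path(outdir, "variant_calls.csv"),
                        show_col_types = FALSE)
  vb <- readr::read_csv(file.path(outdir, "variant_calls_benign.csv"),
                        show_col_types = FALSE)
  k <- paste(called$chrom[1], called$pos[1] + 1L, called$ref[1],
             called$alt[1], sep = ":")
  expect_true(k %in% vb$variant)
  expect_true(all(vb$variant == k))
  expect_true(any(vc$variant == k & vc$benign_flag))
})

test_that("HTML reports render, cross-link and style variants", {
  skip_if_not_installed("xml2")
  run <- small_run()
  outdir <- run$outdir
  samples <- run$sheet$sample_id
  expect_true(file.exists(file.path(outdir, "summary.html")))
  expect_true(file.exists(file.path(outdir, "report.html")))
  for (s in samples) {
    expect_true(file.exists(file.path(outdir, paste0("ind_", s, ".html"))))
  }
  summary_doc <- xml2::read_html(file.path(outdir, "summary.html"))
  report_doc <- xml2::read_html(file.path(outdir, "report.html"))
  for (doc in list(summary_doc, report_doc)) {
    hrefs <- xml2::xml_attr(xml2::xml_find_all(doc, "//a"), "href")
    for (s in samples) {
      expect_true(paste0("ind_", s, ".html") %in% hrefs)
    }
  }
  # overview table has one row per sample with inversion columns
  rows <- xml2::xml_find_all(report_doc,
                             "//table[@id='sample-overview']/tbody/tr")
  expect_length(rows, length(samples))
  heads <- xml2::xml_text(xml2::xml_find_all(
    report_doc, "//table[@id='sample-overview']//th"))
  expect_true(any(grepl("^INT", heads)))
  expect_true("Status" %in% heads)
  # non-benign variants carry the highlighted class
  spans <- xml2::xml_find_all(report_doc, "//span[@class='deleterious']")
  expect_gt(length(spans), 0)
  # individual pages carry the stable section ids
  ind_doc <- xml2::read_html(file.path(outdir,
                                       paste0("ind_", samples[1], ".html")))
  for (id in c("quality-metrics", "region-coverage", "sv-counts")) {
    expect_length(xml2::xml_find_all(ind_doc,
                                     sprintf("//*[@id='%s']", id)), 1)
  }
})

test_that("benign variants render gray and incomplete regions are listed", {
  skip_if_not_installed("xml2")
  run <- small_run()
  calls <- run$calls
  called <- calls[!calls$genotype %in% c("./.", "0/0"), ]
  ben <- tibble::tibble(chrom = called$chrom[1], pos = called$pos[1],
                        ref = called$ref[1], alt = called$alt[1])
  outdir <- withr::local_tempdir()
  # force an incomplete region into one sample's QC row
  qc <- run$qc
  qc$incomplete_regions[1] <- "targetA:11-40"
  render_reports(qc, calls, run$inv_calls, run$coverage, run$stats,
                 run$outliers, outdir, benign = ben)
  rep_doc <- xml2::read_html(file.path(outdir, "report.html"))
  gray <- xml2::xml_find_all(rep_doc, "//span[@class='benign']")
  expect_gt(length(gray), 0)
  row1 <- xml2::xml_find_first(
    rep_doc, sprintf("//tr[@id='sample-%s']", qc$sample_id[1]))
  expect_match(xml2::xml_text(row1), "targetA:11-40", fixed = TRUE)
  ind_doc <- xml2::read_html(
    file.path(outdir, paste0("ind_", qc$sample_id[1], ".html")))
  expect_length(xml2::xml_find_all(ind_doc, "//*[@id='variant-details']"),
                1)
})
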