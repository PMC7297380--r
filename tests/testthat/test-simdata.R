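# The synthetic-data generator: determinism, geometry, error model, truth.

test_that("contradictory geometry is a config error", {
  expect_error(sim_config(read_len = 15, ext_arm_len = 20),
               class = "mipseqr_config_error")
  expect_error(sim_config(read_len = 200, scan_len = 111),
               class = "mipseqr_config_error")
  expect_error(sim_config(male_frac = 1.5),
               class = "mipseqr_config_error")
})

test_that("the same seed reproduces byte-identical FASTQ outputs", {
  cfg <- sim_config(n_samples = 2L, n_target_mips = 4L,
                    n_inversion_events = 0L, n_sry_probes = 0L,
                    variants_per_sample = 1L, seed = 42L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_run(cfg, dir = d1)
  simulate_run(cfg, dir = d2)
  for (f in c("R1.fastq.gz", "R2.fastq.gz", "I1.fastq.gz")) {
    expect_identical(
      readr::read_file_raw(gzfile(file.path(d1, f))),
      readr::read_file_raw(gzfile(file.path(d2, f)))
    )
  }
  # a different seed changes the reads
  cfg2 <- sim_config(n_samples = 2L, n_target_mips = 4L,
                     n_inversion_events = 0L, n_sry_probes = 0L,
                     variants_per_sample = 1L, seed = 43L)
  d3 <- withr::local_tempdir()
  simulate_run(cfg2, dir = d3)
  expect_false(identical(
    readr::read_file_raw(gzfile(file.path(d1, "R1.fastq.gz"))),
    readr::read_file_raw(gzfile(file.path(d3, "R1.fastq.gz")))
  ))
})

test_that("emitted files parse back with the package's own readers", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  simulate_run(sim$cfg, dir = dir)
  d <- read_mip_design(file.path(dir, "design.tsv"), "mipgen",
                       class_path = file.path(dir, "probe_classes.tsv"))
  expect_equal(nrow(d), nrow(sim$design))
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  expect_equal(sheet$sample_id, sim$sheet$sample_id)
  ref <- read_reference(file.path(dir, "ref.fa"))
  expect_identical(ref, sim$ref)
  pairs <- read_pairs(file.path(dir, "R1.fastq.gz"),
                      file.path(dir, "R2.fastq.gz"),
                      file.path(dir, "I1.fastq.gz"))
  expect_equal(nrow(pairs), nrow(sim$pairs))
  expect_equal(pairs$seq1, sim$pairs$seq1)
})

test_that("every read is a prefix of its probe's arm+scan fragment", {
  # error-free regime: read 1 must be a prefix of the fragment built from
  # reference arms plus the sample's (possibly variant-carrying) scan
  cfg <- sim_config(n_samples = 2L, n_target_mips = 6L,
                    n_inversion_events = 1L, n_sry_probes = 1L,
                    seq_error_rate = 0, variants_per_sample = 2L,
                    seed = 13L)
  sim <- simulate_run(cfg)
  truth <- dplyr::left_join(sim$truth$reads,
                            tibble::as_tibble(sim$design),
                            by = "mip_id")
  all_ref <- c(sim$ref, sim$sv_ref)
  ok <- logical(nrow(sim$pairs))
  for (i in seq_len(nrow(sim$pairs))) {
    tr <- truth[i, ]
    refseq <- all_ref[[tr$chrom]]
    arm_up <- substr(refseq, tr$win_start + 1L, tr$scan_start)
    arm_dn <- substr(refseq, tr$scan_end + 1L, tr$win_end)
    scan_ref <- substr(refseq, tr$scan_start + 1L, tr$scan_end)
    cands <- character(0)
    scans <- scan_ref
    for (h in 1:2) {
      vs <- sim$truth$variants
      vs <- vs[vs$sample_id == tr$sample_id & vs$chrom == tr$chrom &
                 (if (h == 1) vs$on_hap1 else vs$on_hap2), ]
      if (nrow(vs) > 0) {
        vs <- dplyr::mutate(vs, ref_str = ref, alt_str = alt)
        hap <- mipseqr:::apply_variants_seq(refseq, vs)
        a <- mipseqr:::hap_coord(tr$scan_start, vs)
        b <- mipseqr:::hap_coord(tr$scan_end, vs)
        scans <- c(scans, substr(hap, a + 1L, b))
      }
    }
    for (sc in unique(scans)) {
      fr <- paste0(arm_up, sc, arm_dn)
      cands <- c(cands, fr, revcomp(fr))
    }
    ok[i] <- any(startsWith(cands, sim$pairs$seq1[i]))
  }
  expect_true(all(ok))
})

test_that("the observed mismatch rate matches the configured error rate", {
  cfg <- sim_config(n_samples = 2L, n_target_mips = 8L,
                    n_inversion_events = 0L, n_sry_probes = 0L,
                    variants_per_sample = 0L, seq_error_rate = 0.001,
                    seed = 29L)
  sim <- simulate_run(cfg)
  truth <- dplyr::left_join(sim$truth$reads,
                            tibble::as_tibble(sim$design), by = "mip_id")
  mism <- 0L; total <- 0L
  for (i in seq_len(nrow(sim$pairs))) {
    tr <- truth[i, ]
    wseq <- substr(sim$ref[[tr$chrom]], tr$win_start + 1L, tr$win_end)
    if (tr$strand == "-") wseq <- revcomp(wseq)
    r1 <- sim$pairs$seq1[i]
    w1 <- substr(wseq, 1, nchar(r1))
    mism <- mism + sum(strsplit(r1, "")[[1]] != strsplit(w1, "")[[1]])
    total <- total + nchar(r1)
  }
  # the observed count must fall inside the 99% binomial band around the
  # configured rate
  p <- stats::binom.test(mism, total, p = 0.001)$p.value
  expect_gt(p, 0.01)
})

test_that("per-MIP read counts track the log-normal capture factors", {
  sim <- default_sim()
  counts <- sim$truth$reads |>
    dplyr::count(mip_id, name = "n")
  m <- dplyr::inner_join(counts, sim$truth$mip_factors, by = "mip_id")
  m <- m[startsWith(m$mip_id, "MIP"), ]
  expect_gt(stats::cor(m$n, m$factor, method = "spearman"), 0.9)
  # realized dispersion is of the configured log-normal order
  sdlog <- stats::sd(log(m$n))
  expect_gt(sdlog, 0.25)
  expect_lt(sdlog, 0.8)
})

test_that("planted variants lie inside target scan regions and truth is complete", {
  sim <- default_sim()
  tv <- sim$truth$variants
  regions <- target_regions(sim$design)
  for (i in seq_len(nrow(tv))) {
    expect_true(any(regions$chrom == tv$chrom[i] &
                      regions$start <= tv$pos[i] &
                      tv$pos[i] < regions$end))
  }
  expect_equal(nrow(tv),
               sim$cfg$variants_per_sample * sim$cfg$n_samples)
  expect_equal(nrow(sim$truth$reads), nrow(sim$pairs))
  expect_setequal(sim$truth$reads$read_id, sim$pairs$read_id)
})
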