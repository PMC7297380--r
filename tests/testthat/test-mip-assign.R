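# Probe assignment by alignment endpoints, arm trimming and MIP stats.

# toy_design(): M01 scan [40,90), M02 [65,115), M03 [90,140) on ctgA,
# all "+" with 20 bp arms, so windows are [20,110), [45,135), [70,160).

aln_row <- function(read_id, chrom, pos, len, cigar = paste0(len, "M"),
                    merged = TRUE, strand = "+", sample_id = "T01") {
  tibble::tibble(read_id = read_id, sample_id = sample_id, chrom = chrom,
                 pos = as.integer(pos), mapq = 60L, strand = strand,
                 cigar = cigar, seq = strrep("A", len),
                 qual = strrep("I", len), merged = merged)
}

test_that("exact window geometry assigns and trims to the scan target", {
  d <- toy_design()
  aln <- assign_mips(aln_row("r1", "ctgA", 20, 90), d)
  expect_equal(aln$mip_id, "M01")
  expect_equal(aln$deviation, 0L)
  tr <- trim_arms(aln, d)
  expect_equal(tr$trim_left, 20L)
  expect_equal(tr$trim_right, 20L)
  expect_equal(tr$pos, 40L)
  expect_equal(tr$cigar, "50M")
  expect_equal(nchar(tr$seq), 50L)
})

test_that("endpoint deviations within tol assign to the closest probe", {
  d <- toy_design()
  # +1 at start, -2 at end (indel jitter near the arms)
  aln <- assign_mips(aln_row("r1", "ctgA", 21, 87), d, tol = 3)
  # oracle: exhaustive deviation over all ctgA probes
  win <- tibble::as_tibble(d)[d$chrom == "ctgA",
                              c("mip_id", "win_start", "win_end")]
  dev <- abs(21 - win$win_start) + abs(108 - win$win_end)
  valid <- abs(21 - win$win_start) <= 3 & abs(108 - win$win_end) <= 3
  expect_equal(aln$mip_id, win$mip_id[valid][which.min(dev[valid])])
  expect_equal(aln$deviation, as.integer(min(dev[valid])))
  # far away -> unassigned
  far <- assign_mips(aln_row("r2", "ctgA", 600, 90), d)
  expect_true(is.na(far$mip_id))
  # beyond tol on one endpoint -> unassigned for merged reads
  off <- assign_mips(aln_row("r3", "ctgA", 20, 97), d, tol = 5)
  expect_true(is.na(off$mip_id))
})

test_that("unmerged mates are matched on their 5' arm-side endpoint only", {
  d <- toy_design()
  # forward mate: starts at M02's window start, ends mid-scan
  fwd <- assign_mips(aln_row("r1", "ctgA", 45, 60, merged = FALSE), d)
  expect_equal(fwd$mip_id, "M02")
  # reverse mate: ends at M02's window end
  rev <- assign_mips(aln_row("r2", "ctgA", 75, 60, merged = FALSE,
                             strand = "-"), d)
  expect_equal(rev$mip_id, "M02")
})

test_that("reads starting inside the scan are not trimmed at that side", {
  d <- toy_design()
  aln <- assign_mips(aln_row("r1", "ctgA", 50, 60, merged = FALSE), d)
  aln$mip_id <- "M01"  # force: starts mid-scan, runs into the lig arm
  tr <- trim_arms(aln, d)
  expect_equal(tr$trim_left, 0L)
  expect_equal(tr$pos, 50L)
  expect_equal(tr$trim_right, 20L)  # 50+60 = 110 > scan_end 90
})

test_that("deletions spanning the arm boundary leave no aligned arm bases", {
  d <- toy_design()
  # M01 window [20,110): 68M covers [20,88), 4D covers [88,92) crossing the
  # scan/lig boundary at 90, then 18M in the lig arm
  aln <- assign_mips(aln_row("r1", "ctgA", 20, 86,
                             cigar = "68M4D18M"), d)
  expect_equal(aln$mip_id, "M01")
  tr <- trim_arms(aln, d)
  refpos <- oracle_ref_positions(tr$pos, tr$cigar)
  expect_true(all(refpos >= 40 & refpos < 90))
  expect_equal(nchar(tr$seq), mipseqr:::cigar_read_span(tr$cigar))
})

test_that("trimming drops reads with no scan overlap and reports them", {
  d <- toy_design()
  aln <- assign_mips(aln_row("r1", "ctgA", 20, 90), d)
  aln$mip_id <- "M03"  # force bad assignment: scan [90,140), read ends 110
  tr <- trim_arms(aln, d)
  expect_equal(nrow(tr), 1L)  # 20 bases remain in [90,110): kept
  expect_equal(tr$cigar, "20M")
  aln2 <- aln
  aln2$pos <- 0L  # read [0,90) has no overlap with scan [90,140)
  expect_message(tr2 <- trim_arms(aln2, d), "dropped")
  expect_equal(nrow(tr2), 0L)
  expect_equal(attr(tr2, "n_dropped"), 1L)
})

test_that("post-trim aligned positions never touch the assigned probe's arms", {
  run <- small_run()
  d <- run$design
  tr <- run$trimmed
  dmap <- tibble::as_tibble(d)[, c("mip_id", "scan_start", "scan_end")]
  m <- dplyr::left_join(tr, dmap, by = "mip_id")
  for (i in seq_len(nrow(m))) {
    refpos <- oracle_ref_positions(m$pos[i], m$cigar[i])
    expect_true(all(refpos >= m$scan_start[i] & refpos < m$scan_end[i]))
  }
})

test_that("MIP statistics: counts, relative abundance, zero-read probes", {
  d <- toy_design()
  aln <- dplyr::bind_rows(
    aln_row(sprintf("a%02d", 1:10), "ctgA", 20, 90, sample_id = "S1"),
    aln_row(sprintf("b%02d", 1:30), "ctgA", 45, 90, sample_id = "S1"),
    aln_row(sprintf("c%02d", 1:20), "ctgA", 20, 90, sample_id = "S2"),
    aln_row(sprintf("d%02d", 1:60), "ctgA", 45, 90, sample_id = "S2")
  )
  aln <- assign_mips(aln, d)
  st <- compute_mip_stats(aln, d)
  wide <- tidyr::pivot_wider(st[, c("sample_id", "mip_id", "count")],
                             names_from = "mip_id", values_from = "count")
  expect_equal(wide$M01, c(10L, 20L))
  expect_equal(wide$M02, c(30L, 60L))
  expect_equal(st$rel_abundance[st$mip_id == "M02"], c(0.75, 0.75))
  expect_equal(st$rel_abundance[st$mip_id == "M01"], c(0.25, 0.25))
  # probes without reads are present with count 0, and totals conserve
  expect_true(all(c("M03", "N01") %in% st$mip_id))
  expect_equal(sum(st$count), sum(!is.na(aln$mip_id)))
  ms <- mip_summary(st)
  expect_equal(ms$total_count[ms$mip_id == "M03"], 0L)
})

test_that("per-MIP mean abundances recover simulated capture-efficiency ranks", {
  sim <- default_sim()
  run <- default_run()
  ms <- mip_summary(run$stats)
  m <- dplyr::inner_join(ms, sim$truth$mip_factors, by = "mip_id")
  m <- m[startsWith(m$mip_id, "MIP"), ]  # target probes: present in all samples
  expect_gt(stats::cor(m$mean_rel_abundance, m$factor,
                       method = "spearman"), 0.9)
})
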