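# Downsampling, the diallelic pileup genotyper and coverage profiling.

test_that("downsampling is an identity below the cap and seed-reproducible", {
  reads <- tibble::tibble(i = 1:2000)
  expect_identical(downsample(reads[1:40, ], cap = 500, seed = 1),
                   reads[1:40, ])
  a <- downsample(reads, cap = 500, seed = 9)
  b <- downsample(reads, cap = 500, seed = 9)
  expect_equal(nrow(a), 500L)
  expect_identical(a, b)                      # same seed, same subset
  c <- downsample(reads, cap = 500, seed = 10)
  expect_false(identical(a, c))               # different seed, different set
  expect_equal(nrow(downsample(reads, cap = 1, seed = 1)), 1L)
  # the global RNG stream is left untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(downsample(reads, 500, seed = 4)); after <- runif(1)
  expect_equal(before, after)
})

test_that("unanimous and mixed pileup columns genotype correctly", {
  # 30 reference bases at Q30
  cl <- call_site(rep("A", 30), rep(30L, 30), ref_allele = "A")
  expect_equal(cl$genotype, "0/0")
  expect_equal(c(cl$ad_ref, cl$ad_alt), c(30L, 0L))
  want0 <- oracle_genotype(rep("ref", 30), rep(30L, 30))
  expect_equal(cl$gq_raw, want0$gq_raw, tolerance = 1e-9)
  expect_equal(cl$gq, as.integer(round(want0$gq_raw)))
  # 15/15 het at Q30: GQ from brute-force likelihoods
  obs <- c(rep("A", 15), rep("G", 15))
  cl <- call_site(obs, rep(30L, 30), ref_allele = "A")
  want <- oracle_genotype(c(rep("ref", 15), rep("alt", 15)), rep(30L, 30))
  expect_equal(cl$genotype, "0/1")
  expect_equal(cl$genotype, want$genotype)
  expect_equal(cl$gq_raw, want$gq_raw, tolerance = 1e-9)
  # hemizygous: 20 alt / 1 ref at ploidy 1
  cl <- call_site(c(rep("T", 20), "A"), rep(30L, 21), ref_allele = "A",
                  ploidy = 1L)
  expect_equal(cl$genotype, "1")
  want <- oracle_genotype(c(rep("alt", 20), "ref"), rep(30L, 21),
                          ploidy = 1L)
  expect_equal(cl$gq_raw, want$gq_raw, tolerance = 1e-9)
  # depth below min_call_depth is a no-call
  cl <- call_site(rep("A", 5), rep(30L, 5), ref_allele = "A")
  expect_equal(cl$genotype, "./.")
  expect_true(is.na(cl$gq))
})

test_that("GQ matches brute-force likelihood evaluation on random columns", {
  set.seed(601)
  for (i in 1:100) {
    dp <- sample(8:60, 1)
    n_alt <- sample(0:dp, 1)
    quals <- sample(5:45, dp, replace = TRUE)
    ploidy <- sample(c(1L, 2L), 1)
    obs <- c(rep("C", dp - n_alt), rep("T", n_alt))
    # sprinkle in "other" bases
    n_oth <- sample(0:2, 1)
    if (n_oth > 0 && dp - n_alt >= n_oth) {
      obs[seq_len(n_oth)] <- "G"
    }
    cl <- call_site(obs, quals, ref_allele = "C", alt_allele = "T",
                    ploidy = ploidy)
    cls <- ifelse(obs == "C", "ref", ifelse(obs == "T", "alt", "other"))
    want <- oracle_genotype(cls, quals, ploidy = ploidy)
    expect_equal(cl$genotype, want$genotype, info = i)
    expect_equal(cl$gq_raw, want$gq_raw, tolerance = 1e-6, info = i)
  }
})

test_that("equivalent indel gap placements collapse to one left-aligned site", {
  ref <- c(ctg = paste0(strrep("ACGT", 10), "TTTTT", strrep("GATC", 20)))
  # deletion of one T from the homopolymer at [40,45): two gap placements
  aln <- tibble::tibble(
    read_id = c("r1", "r2"), sample_id = "S1", chrom = "ctg",
    pos = c(20L, 20L), mapq = 60L, strand = "+",
    cigar = c("21M1D39M", "23M1D37M"),
    seq = strrep("A", 60), qual = strrep("I", 60)
  )
  pu <- pileup(aln, ref = ref)
  dels <- pu[startsWith(pu$obs, "-"), ]
  expect_equal(nrow(dels), 2L)
  # the ACGT repeat ends in T, so the homopolymer run is [39,45) and the
  # left-aligned anchor is the base before it
  expect_equal(unique(dels$pos), 38L)
  expect_equal(unique(dels$obs), "-1")
})

test_that("variant calling recovers planted alleles per sample", {
  sim <- small_sim()
  run <- small_run()
  rec <- genotype_recovery(sim, run)
  expect_gte(rec$recovery, 0.99)
  # called alt alleles match the planted spelling (left-aligned VCF style)
  tv <- sim$truth$variants
  keys_t <- paste(tv$chrom, tv$pos, tv$ref, tv$alt)
  keys_c <- paste(run$calls$chrom, run$calls$pos, run$calls$ref,
                  run$calls$alt)
  expect_true(all(keys_c %in% keys_t))
})

test_that("coverage profiling finds incomplete and zero-coverage intervals", {
  d <- toy_design()
  # uniform 20x over M01+M02+M03 region via merged reads on each window
  mk <- function(prefix, pos, n, len = 90) {
    tibble::tibble(read_id = sprintf("%s%03d", prefix, seq_len(n)),
                   sample_id = "S1", chrom = "ctgA", pos = as.integer(pos),
                   mapq = 60L, strand = "+", cigar = paste0(len, "M"),
                   seq = strrep("A", len), qual = strrep("I", len),
                   merged = TRUE)
  }
  aln <- dplyr::bind_rows(mk("a", 20, 20), mk("b", 45, 20), mk("c", 70, 20))
  aln <- assign_mips(aln, d)
  tr <- trim_arms(aln, d)
  cov <- profile_coverage(tr, d, min_call_depth = 8)
  expect_equal(nrow(cov), 2L)  # ctgA [40,140) and ctgB [30,80)
  covA <- cov[cov$chrom == "ctgA", ]
  expect_equal(covA$frac_covered, 1)
  expect_equal(nrow(covA$incomplete[[1]]), 0L)
  # depth exactly at the threshold is NOT incomplete (strict <)
  cov8 <- profile_coverage(tr, d, min_call_depth = 20)
  expect_equal(nrow(cov8$incomplete[[which(cov8$chrom == "ctgA")]]), 0L)
  # drop one probe's reads: its unique scan interval has zero coverage
  tr2 <- tr[tr$mip_id != "M03", ]
  cov2 <- profile_coverage(tr2, d, min_call_depth = 8)
  zero <- cov2$zero_cov[[which(cov2$chrom == "ctgA")]]
  expect_equal(zero$start, 115L)  # M03 scan minus M02 overlap
  expect_equal(zero$end, 140L)
  # oracle: per-base depth recomputation from read intervals
  pos <- 40:139
  depth <- vapply(pos, function(p) {
    sum(tr2$pos <= p & tr2$pos + cigar_ref_span(tr2$cigar) > p)
  }, numeric(1))
  expect_equal(zero,
               mipseqr:::positions_to_intervals(pos[depth == 0]))
  # the ctgB region (no reads at all) is fully zero-coverage
  covB <- cov[cov$chrom == "ctgB", ]
  expect_equal(covB$mean_coverage, 0)
  expect_equal(covB$zero_cov[[1]],
               tibble::tibble(start = 30L, end = 80L))
})

test_that("external VCF ingestion normalizes records", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=ctg,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"gq\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "ctg\t100\t.\tA\tG\t50\tPASS\t.\tGT:GQ:AD:DP\t0/1:45:12,10:22",
    "ctg\t200\t.\tC\tT,G\t50\tPASS\t.\tGT:GQ:AD:DP\t1/2:30:2,9,8:19",
    "ctg\t300\t.\tT\t<NON_REF>\t.\t.\tEND=400\tGT:DP\t0/0:35"
  )
  p <- withr::local_tempfile(fileext = ".vcf")
  readr::write_lines(vcf, p)
  calls <- suppressWarnings(ingest_external_vcf(p))
  # simple het passthrough, 0-based position
  r1 <- calls[calls$pos == 99L, ]
  expect_equal(r1$genotype, "0/1")
  expect_equal(c(r1$ad_ref, r1$ad_alt), c(12L, 10L))
  expect_equal(r1$dp, 22L)
  expect_equal(r1$gq, 45L)
  # multi-allelic site splits into two diallelic records
  r2 <- calls[calls$pos == 199L, ]
  expect_equal(nrow(r2), 2L)
  expect_setequal(r2$alt, c("T", "G"))
  expect_equal(r2$genotype[r2$alt == "T"], "0/1")
  expect_equal(r2$ad_alt[r2$alt == "T"], 9L)
  expect_equal(r2$ad_alt[r2$alt == "G"], 8L)
  # gVCF reference block emits no variant call
  expect_false(any(calls$pos == 299L))
})

test_that("internal VCF output is valid and read back by vcfR", {
  run <- small_run()
  p <- file.path(run$outdir, "calls.vcf")
  expect_true(file.exists(p))
  v <- vcfR::read.vcfR(p, verbose = FALSE)
  expect_equal(nrow(v@gt), nrow(dplyr::distinct(run$calls, chrom, pos, alt)))
  gt <- vcfR::extract.gt(v, "GT")
  expect_equal(ncol(gt), nrow(run$sheet))
})
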