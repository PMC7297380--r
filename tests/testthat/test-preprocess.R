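# Demultiplexing and overlap consensus merging.

test_that("barcode assignment follows the Hamming rules", {
  sheet <- toy_sheet(4)
  # exact match
  expect_equal(assign_samples("ACGTACGT", sheet = sheet), "T01")
  # one mismatch, unique at max_mismatch = 1
  expect_equal(assign_samples("ACGTACGA", sheet = sheet, max_mismatch = 1),
               "T01")
  # out of tolerance
  expect_true(is.na(assign_samples("ACGAACGA", sheet = sheet,
                                   max_mismatch = 1)))
  # equidistant between two barcodes -> unassigned
  amb_sheet <- tibble::tibble(sample_id = c("X", "Y"),
                              barcode1 = c("AAAAAAAA", "AAAAAAAT"),
                              barcode2 = NA)
  expect_true(is.na(assign_samples("AAAAAAAC", sheet = amb_sheet,
                                   max_mismatch = 1)))
  # length mismatch is an input error
  expect_error(assign_samples("ACGT", sheet = sheet),
               class = "mipseqr_input_error")
})

test_that("exhaustive Hamming oracle agrees on random indexes", {
  set.seed(401)
  sheet <- toy_sheet(6)
  idx <- vapply(1:300, function(i) random_dna_str(8), character(1))
  got <- assign_samples(idx, sheet = sheet, max_mismatch = 1)
  for (i in seq_along(idx)) {
    d <- vapply(sheet$barcode1, function(b) {
      sum(strsplit(idx[i], "")[[1]] != strsplit(b, "")[[1]])
    }, integer(1))
    ok <- which(d <= 1)
    want <- if (length(ok) > 0 && sum(d == min(d[ok])) == 1) {
      sheet$sample_id[which.min(d)]
    } else NA_character_
    expect_identical(got[i], want)
  }
})

test_that("demultiplexing conserves reads and recovers true samples", {
  sim <- small_sim()
  pairs <- demultiplex(sim$pairs, sim$sheet)
  expect_equal(nrow(pairs), nrow(sim$pairs))  # conservation
  ds <- demux_summary(pairs, sim$sheet)
  expect_equal(sum(ds$n_reads), nrow(sim$pairs))
  truth <- sim$truth$reads
  m <- dplyr::left_join(pairs, truth, by = "read_id",
                        suffix = c(".called", ".true"))
  expect_equal(m$sample_id.called, m$sample_id.true)
})

test_that("dual-index sheets require and use both indexes", {
  sheet <- tibble::tibble(sample_id = c("A", "B"),
                          barcode1 = c("ACGTACGT", "ACGTACGT"),
                          barcode2 = c("AAAAAAAA", "TTTTTTTT"))
  expect_error(assign_samples("ACGTACGT", sheet = sheet), "index2")
  expect_equal(
    assign_samples("ACGTACGT", "TTTTTTTT", sheet = sheet), "B")
})

test_that("inline 5' barcodes are extracted and trimmed before merging", {
  pairs <- tibble::tibble(read_id = "r1",
                          seq1 = paste0("ACGTACGT", strrep("G", 30)),
                          qual1 = strrep("I", 38),
                          seq2 = strrep("C", 30), qual2 = strrep("I", 30))
  out <- extract_inline_barcodes(pairs, 8)
  expect_equal(out$index1, "ACGTACGT")
  expect_equal(out$seq1, strrep("G", 30))
  expect_equal(nchar(out$qual1), 30L)
})

test_that("non-overlapping mates pass through unmerged", {
  p <- merge_pair(random_dna_str(40), strrep("I", 40),
                  random_dna_str(40), strrep("I", 40))
  expect_false(p$merged)
  expect_equal(p$overlap_len, 0L)
  expect_true(is.na(p$seq))
})

test_that("identical 40-base overlap at Q30 gives a 160 bp consensus at Q60", {
  set.seed(402)
  frag <- random_dna_str(160)
  r1 <- substr(frag, 1, 100)
  r2 <- revcomp(substr(frag, 61, 160))
  q30 <- strrep(rawToChar(as.raw(30 + 33)), 100)
  m <- merge_pair(r1, q30, r2, q30)
  expect_true(m$merged)
  expect_equal(m$overlap_len, 40L)
  expect_equal(m$seq, frag)
  q <- qual_to_int(m$qual)[[1]]
  expect_equal(q[61:100], rep(60L, 40))   # q1+q2 capped at 60
  expect_equal(q[c(1:60, 101:160)], rep(30L, 120))
})

test_that("disagreeing overlap bases take the higher-quality base at |q1-q2|", {
  set.seed(403)
  frag <- random_dna_str(60)
  r1 <- substr(frag, 1, 40)
  r2rc <- substr(frag, 21, 60)
  # plant a disagreement at fragment position 30 (overlap position 10):
  # read 1 sees A at Q35, read 2 sees G at Q20
  substr(r1, 30, 30) <- "A"
  substr(r2rc, 10, 10) <- "G"
  q1 <- int_to_qual(rep(35L, 40))
  q2 <- int_to_qual(rep(20L, 40))
  m <- merge_pair(r1, q1, revcomp(r2rc), q2)  # constant quals: reversal moot
  expect_true(m$merged)
  expect_equal(substr(m$seq, 30, 30), "A")
  expect_equal(qual_to_int(m$qual)[[1]][30], 15L)
})

test_that("merging reconstructs error-free simulated fragments exactly", {
  set.seed(404)
  for (i in 1:25) {
    flen <- sample(120:200, 1)
    rlen <- sample(80:110, 1)
    frag <- random_dna_str(flen)
    if (flen - rlen > rlen - 11) next  # ensure overlap >= min_overlap
    r1 <- substr(frag, 1, rlen)
    r2 <- revcomp(substr(frag, flen - rlen + 1, flen))
    q <- int_to_qual(rep(30L, rlen))
    m <- merge_pair(r1, q, r2, q)
    expect_true(m$merged)
    expect_equal(m$seq, frag)
  }
})

test_that("merge matches the scalar positionwise oracle on random pairs", {
  set.seed(405)
  n <- 150
  pairs <- tibble::tibble(
    read_id = sprintf("r%03d", 1:n), seq1 = NA_character_,
    qual1 = NA_character_, seq2 = NA_character_, qual2 = NA_character_
  )
  for (i in 1:n) {
    flen <- sample(130:190, 1)
    frag <- random_dna_str(flen)
    r1 <- substr(frag, 1, 100)
    r2rc <- substr(frag, flen - 99, flen)
    # random sequencing noise on both mates
    mut <- function(s, k) {
      for (j in sample(nchar(s), k)) {
        substr(s, j, j) <- sample(c("A", "C", "G", "T"), 1)
      }
      s
    }
    r1 <- mut(r1, sample(0:3, 1))
    r2rc <- mut(r2rc, sample(0:3, 1))
    pairs$seq1[i] <- r1
    pairs$seq2[i] <- revcomp(r2rc)
    pairs$qual1[i] <- int_to_qual(sample(5:40, 100, replace = TRUE))
    pairs$qual2[i] <- int_to_qual(sample(5:40, 100, replace = TRUE))
  }
  got <- merge_pairs(pairs)
  for (i in 1:n) {
    want <- oracle_merge(pairs$seq1[i], pairs$qual1[i], pairs$seq2[i],
                         pairs$qual2[i])
    expect_equal(got$merged[i], want$merged, info = i)
    if (want$merged) {
      expect_equal(got$overlap_len[i], want$overlap_len, info = i)
      expect_equal(got$seq[i], want$seq, info = i)
      expect_equal(qual_to_int(got$qual[i])[[1]], want$qual, info = i)
    }
  }
})
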