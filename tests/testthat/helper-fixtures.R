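# Shared fixtures: a small design built in code, and memoised simulation
# runs so expensive end-to-end work happens once per session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, fn(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Minimal hand-built design: three overlapping plus-strand probes on one
# contig (arms 20 bp, scans 50 bp starting at 40/65/90) and one
# minus-strand probe on a second contig.
toy_design <- function() {
  probes <- tibble::tibble(
    mip_id = c("M01", "M02", "M03", "N01"),
    chrom = c("ctgA", "ctgA", "ctgA", "ctgB"),
    ext_arm_seq = strrep("A", 20),
    lig_arm_seq = strrep("C", 20),
    scan_start = c(40L, 65L, 90L, 30L),
    scan_end = c(90L, 115L, 140L, 80L),
    strand = c("+", "+", "+", "-"),
    probe_class = "target",
    event_id = NA_character_
  )
  mipseqr:::new_mip_design(probes)
}

toy_sheet <- function(n = 4) {
  tibble::tibble(
    sample_id = sprintf("T%02d", seq_len(n)),
    barcode1 = c("ACGTACGT", "TTTTCCCC", "GGGGAAAA", "CATGCATG",
                 "AACCGGTT", "TGCATGCA")[seq_len(n)],
    barcode2 = NA_character_
  )
}

# Small simulated run (4 samples, 12 target probes) for module tests.
small_sim <- function() {
  memo("small_sim", function() {
    simulate_run(sim_config(n_samples = 4L, n_target_mips = 12L,
                            n_inversion_events = 1L, n_sry_probes = 2L,
                            variants_per_sample = 2L, seed = 11L))
  })
}

small_run <- function() {
  memo("small_run", function() {
    run_simulated(small_sim(), outdir = file.path(tempdir(), "small_run"))
  })
}

# Default study conditions (8 samples, 40 target probes, 50x, Q30) used by
# the acceptance-style checks.
default_sim <- function(seed = 101L) {
  memo(paste0("default_sim_", seed), function() {
    simulate_run(sim_config(seed = seed))
  })
}

default_run <- function(seed = 101L) {
  memo(paste0("default_run_", seed), function() {
    run_simulated(default_sim(seed),
                  outdir = file.path(tempdir(), paste0("default_run_",
                                                       seed)))
  })
}

# Score planted genotypes against pipeline calls at covered sites.
# Coverage at each planted site is recomputed independently from the
# trimmed alignments (interval overlap count), so an undiscovered site at
# callable depth counts as a miss, not as uncovered.
genotype_recovery <- function(sim, run, min_call_depth = 8L) {
  tv <- sim$truth$variants
  tr <- run$trimmed
  spans <- mipseqr::cigar_ref_span(tr$cigar)
  depth_at <- function(s, cn, p) {
    sum(tr$sample_id == s & tr$chrom == cn & tr$pos <= p &
          tr$pos + spans > p)
  }
  tv$depth <- mapply(depth_at, tv$sample_id, tv$chrom, tv$pos)
  calls <- run$calls
  tv$key <- paste(tv$chrom, tv$pos, tv$sample_id)
  calls$key <- paste(calls$chrom, calls$pos, calls$sample_id)
  m <- dplyr::left_join(
    tv, calls[, c("key", "genotype", "alt")],
    by = "key", suffix = c(".t", ".c")
  )
  covered <- m$depth >= min_call_depth
  correct <- covered & !is.na(m$genotype.c) &
    m$genotype.t == m$genotype.c & m$alt.t == m$alt.c
  list(n_planted = nrow(m), n_covered = sum(covered),
       n_correct = sum(correct),
       recovery = sum(correct) / max(1L, sum(covered)))
}
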