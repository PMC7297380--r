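# Truth-annotated synthetic MIP sequencing runs.
#
# The generator emulates a small two-locus capture panel: tiled target
# probes with extension/ligation arms, junction contig pairs for recurrent
# inversion events, Y-unique (SRY) probes for sex, per-sample planted
# SNVs/indels with phased haplotypes, per-MIP log-normal capture
# efficiency (the "highly imbalanced" property MIP panels are notorious
# for), Phred-consistent substitution errors and sample barcodes. Every
# read records its true sample and probe so each pipeline stage can be
# scored exactly.

#' Simulation configuration
#'
#' Defaults describe a desk-scale run: 8 samples, 40 target MIPs with
#' 111 bp scan targets (typical MIP target size), 2 inversion events
#' (INT1/INT22-style junction contig pairs), 5 SRY probes, ~50 read pairs
#' per probe and sample, Q30 substitution errors.
#'
#' @param n_samples Samples on the run (default 8).
#' @param n_target_mips Target-class probes, split over two loci
#'   (default 40).
#' @param ext_arm_len,lig_arm_len Arm lengths in bp (default 20).
#' @param scan_len Scan target length in bp (default 111).
#' @param tile_step Offset between neighbouring scan starts (default 56,
#'   i.e. ~50% overlap so arm-hidden variants are rescued by the
#'   neighbouring probe).
#' @param n_inversion_events Inversion events with ref/mut junction
#'   contigs (default 2, labelled INT1, INT22).
#' @param n_sry_probes Y-unique probes (default 5).
#' @param variants_per_sample Planted variants per sample (default 3).
#' @param indel_fraction Fraction of planted variants that are 1-3 bp
#'   indels rather than SNVs (default 0.2).
#' @param hom_fraction Fraction of planted variants that are homozygous
#'   (default 0.3).
#' @param inversion_carrier_frac Probability a male sample carries each
#'   inversion event (default 0.25).
#' @param male_frac Fraction of male samples (default 0.5).
#' @param capture_sigma Log-normal sigma of per-MIP capture efficiency
#'   (default 0.5).
#' @param read_len Read length (default 100).
#' @param mean_reads_per_mip Mean read pairs per probe and sample
#'   (default 50).
#' @param seq_error_rate Per-base substitution error rate (default 0.001,
#'   consistent with the Q30 base qualities written).
#' @param base_qual Constant base quality (default 30).
#' @param barcode_len Index barcode length (default 8); barcode sets are
#'   generated with pairwise Hamming distance >= 3.
#' @param index_error_rate Per-base substitution rate on the index read
#'   (default 0).
#' @param seed Master seed fixing every draw (default 1).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 8L, n_target_mips = 40L,
                       ext_arm_len = 20L, lig_arm_len = 20L,
                       scan_len = 111L, tile_step = 56L,
                       n_inversion_events = 2L, n_sry_probes = 5L,
                       variants_per_sample = 3L, indel_fraction = 0.2,
                       hom_fraction = 0.3, inversion_carrier_frac = 0.25,
                       male_frac = 0.5, capture_sigma = 0.5,
                       read_len = 100L, mean_reads_per_mip = 50,
                       seq_error_rate = 0.001, base_qual = 30L,
                       barcode_len = 8L, index_error_rate = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(indel_fraction, hom_fraction, inversion_carrier_frac,
             male_frac, seq_error_rate, index_error_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("all rate parameters must lie in [0, 1]",
          class = "mipseqr_config_error")
  }
  if (read_len < max(ext_arm_len, lig_arm_len) + 1L) {
    abort("read length must exceed the arm length",
          class = "mipseqr_config_error")
  }
  if (read_len > ext_arm_len + scan_len + lig_arm_len) {
    abort("read length must not exceed the captured fragment length",
          class = "mipseqr_config_error")
  }
  if (n_samples < 1 || n_target_mips < 2) {
    abort("need at least 1 sample and 2 target probes",
          class = "mipseqr_config_error")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Barcodes with pairwise Hamming distance >= min_dist, by rejection.
sim_barcodes <- function(n, len, min_dist = 3L) {
  out <- character(0)
  while (length(out) < n) {
    b <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    if (length(out) == 0 ||
        all(hamming_matrix(b, out) >= min_dist)) {
      out <- c(out, b)
    }
  }
  out
}

# Apply variants (tibble: pos, type, ref_str, alt_str; 0-based anchors,
# non-overlapping) to one reference string. Returns the mutated haplotype.
apply_variants_seq <- function(refseq, vars) {
  if (nrow(vars) == 0) return(refseq)
  vars <- arrange(vars, dplyr::desc(.data$pos))
  for (i in seq_len(nrow(vars))) {
    p <- vars$pos[i]
    if (vars$type[i] == "SNV") {
      substr(refseq, p + 1L, p + 1L) <- substr(vars$alt_str[i],
                                               nchar(vars$alt_str[i]),
                                               nchar(vars$alt_str[i]))
    } else if (vars$type[i] == "INS") {
      ins <- substr(vars$alt_str[i], 2L, nchar(vars$alt_str[i]))
      refseq <- paste0(substr(refseq, 1L, p + 1L), ins,
                       substr(refseq, p + 2L, nchar(refseq)))
    } else {  # DEL
      dlen <- nchar(vars$ref_str[i]) - 1L
      refseq <- paste0(substr(refseq, 1L, p + 1L),
                       substr(refseq, p + 2L + dlen, nchar(refseq)))
    }
  }
  refseq
}

# Haplotype coordinate of reference coordinate x (0-based): x plus the net
# indel offset of variants acting strictly before x.
hap_coord <- function(x, vars) {
  if (nrow(vars) == 0) return(x)
  delta <- 0L
  for (i in seq_len(nrow(vars))) {
    p <- vars$pos[i]
    if (vars$type[i] == "INS" && p < x) {
      delta <- delta + nchar(vars$alt_str[i]) - 1L
    } else if (vars$type[i] == "DEL") {
      dlen <- nchar(vars$ref_str[i]) - 1L
      delta <- delta - min(dlen, max(0L, x - (p + 1L)))
    }
  }
  x + delta
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  hit <- which(runif(total) < rate)
  if (length(hit) == 0) return(seqs)
  chars <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  subs <- c("A", "C", "G", "T")
  for (h in hit) {
    chars[h] <- sample(setdiff(subs, chars[h]), 1)
  }
  all_str <- paste(chars, collapse = "")
  ends <- cumsum(lens)
  substring(all_str, ends - lens + 1L, ends)
}

#' Simulate a full MIP sequencing run
#'
#' Generates the reference, SV contig reference, MIP design and class
#' tables, sample sheet, paired FASTQ with index reads, and a truth set,
#' optionally writing everything to `dir` in the formats the pipeline
#' consumes.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory; when given, writes `ref.fa`,
#'   `sv_ref.fa`, `design.tsv`, `probe_classes.tsv`, `sample_sheet.tsv`,
#'   `R1.fastq.gz`, `R2.fastq.gz`, `I1.fastq.gz`, `truth.json` and
#'   `truth_reads.tsv`.
#' @return A list: `design`, `sheet`, `ref`, `sv_ref` (named character
#'   vectors), `pairs` (read-pair tibble with `index1`), and `truth`
#'   (list of `samples`, `variants`, `mip_factors`, `reads` tibbles).
#' @export
simulate_run <- function(cfg = sim_config(), dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  arm_e <- cfg$ext_arm_len; arm_l <- cfg$lig_arm_len
  frag_len <- arm_e + cfg$scan_len + arm_l
  margin <- max(arm_e, arm_l) + 40L

  # --- reference loci and tiled target probes ------------------------------
  n_per <- ceiling(cfg$n_target_mips / 2)
  loci <- c("targetA", "targetB")
  ref <- character(0)
  probes <- list()
  mip_i <- 0L
  for (li in seq_along(loci)) {
    n_here <- if (li == 1) n_per else cfg$n_target_mips - n_per
    locus_len <- 2L * margin + cfg$scan_len +
      (n_here - 1L) * cfg$tile_step
    ref[loci[li]] <- random_dna(locus_len)
    for (j in seq_len(n_here)) {
      mip_i <- mip_i + 1L
      ss <- margin + (j - 1L) * cfg$tile_step
      se <- ss + cfg$scan_len
      strand <- if (j %% 2L == 0L) "-" else "+"
      probes[[mip_i]] <- tibble(
        mip_id = sprintf("MIP%03d", mip_i), chrom = loci[li],
        scan_start = ss, scan_end = se, strand = strand,
        probe_class = "target", event_id = NA_character_
      )
    }
  }

  # --- SRY contig and probes ----------------------------------------------
  if (cfg$n_sry_probes > 0) {
    sry_len <- 2L * margin + cfg$scan_len +
      (cfg$n_sry_probes - 1L) * cfg$tile_step
    ref["SRY"] <- random_dna(sry_len)
    for (j in seq_len(cfg$n_sry_probes)) {
      mip_i <- mip_i + 1L
      ss <- margin + (j - 1L) * cfg$tile_step
      probes[[mip_i]] <- tibble(
        mip_id = sprintf("SRY%02d", j), chrom = "SRY",
        scan_start = ss, scan_end = ss + cfg$scan_len, strand = "+",
        probe_class = "sry", event_id = NA_character_
      )
    }
  }

  # --- inversion junction contigs (separate SV reference) ------------------
  event_ids <- if (cfg$n_inversion_events >= 1) {
    c("INT22", "INT1", paste0("INT", seq_len(max(0,
      cfg$n_inversion_events - 2L)) + 100L))[seq_len(cfg$n_inversion_events)]
  } else character(0)
  sv_ref <- character(0)
  for (ev in event_ids) {
    for (cls in c("ref", "mut")) {
      contig <- paste0(ev, "_", cls)
      sv_ref[contig] <- random_dna(2L * margin + cfg$scan_len)
      mip_i <- mip_i + 1L
      probes[[mip_i]] <- tibble(
        mip_id = paste0("INV_", contig), chrom = contig,
        scan_start = margin, scan_end = margin + cfg$scan_len,
        strand = "+",
        probe_class = paste0("inversion_", cls), event_id = ev
      )
    }
  }

  probes <- bind_rows(probes)
  all_ref <- c(ref, sv_ref)
  probes <- probes |>
    mutate(
      ext_arm_seq = NA_character_, lig_arm_seq = NA_character_
    )
  for (i in seq_len(nrow(probes))) {
    cn <- probes$chrom[i]; ss <- probes$scan_start[i]
    se <- probes$scan_end[i]
    up <- substr(all_ref[[cn]], ss - (if (probes$strand[i] == "+") arm_e
                                      else arm_l) + 1L, ss)
    dn <- substr(all_ref[[cn]], se + 1L,
                 se + (if (probes$strand[i] == "+") arm_l else arm_e))
    if (probes$strand[i] == "+") {
      probes$ext_arm_seq[i] <- up; probes$lig_arm_seq[i] <- dn
    } else {
      probes$ext_arm_seq[i] <- revcomp(dn)
      probes$lig_arm_seq[i] <- revcomp(up)
    }
  }
  design <- new_mip_design(probes)

  # --- samples: barcodes, sex, inversion carriers --------------------------
  sample_ids <- sprintf("S%02d", seq_len(cfg$n_samples))
  sheet <- tibble(sample_id = sample_ids,
                  barcode1 = sim_barcodes(cfg$n_samples, cfg$barcode_len),
                  barcode2 = NA_character_)
  sex <- if_else(runif(cfg$n_samples) < cfg$male_frac, "male", "female")
  carriers <- tidyr::expand_grid(sample_id = sample_ids,
                                 event_id = event_ids) |>
    left_join(tibble(sample_id = sample_ids, sex = sex), by = "sample_id") |>
    mutate(carrier = .data$sex == "male" &
             runif(n()) < cfg$inversion_carrier_frac)

  # --- planted variants ----------------------------------------------------
  regions <- target_regions(design)
  # indel alleles span up to 4 reference bases after the anchor; keeping
  # anchors away from the region tail keeps every allele fully inside at
  # least one probe's scan target
  cand_pos <- regions |>
    group_by(.data$chrom) |>
    dplyr::reframe(pos = unlist(purrr::map2(.data$start, .data$end,
                                            ~seq.int(.x, .y - 7L))))
  # planted variants are private to one sample and spaced >= 10 bp apart
  # run-wide, already left-normalized, so every call site is clean and
  # unambiguous to score
  variants <- list()
  taken_chrom <- character(0); taken_pos <- integer(0)
  for (s in sample_ids) {
    for (v in seq_len(cfg$variants_per_sample)) {
      repeat {
        k <- sample.int(nrow(cand_pos), 1L)
        p <- cand_pos$pos[k]; cn <- cand_pos$chrom[k]
        rb <- substr(ref[[cn]], p + 1L, p + 1L)
        if (runif(1) < cfg$indel_fraction) {
          if (runif(1) < 0.5) {
            ins <- paste(sample(c("A", "C", "G", "T"),
                                sample.int(3L, 1L), replace = TRUE),
                         collapse = "")
            type <- "INS"; ref_str <- rb; alt_str <- paste0(rb, ins)
          } else {
            dlen <- sample.int(3L, 1L)
            type <- "DEL"
            ref_str <- substr(ref[[cn]], p + 1L, p + 1L + dlen)
            alt_str <- rb
          }
          nv <- normalize_variant(ref[[cn]], p, ref_str, alt_str)
          p <- nv$pos; ref_str <- nv$ref; alt_str <- nv$alt
        } else {
          type <- "SNV"; ref_str <- rb
          alt_str <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
        }
        in_region <- any(regions$chrom == cn & regions$start + 2L <= p &
                           p <= regions$end - 7L)
        clash <- any(taken_chrom == cn & abs(taken_pos - p) < 10L)
        if (in_region && !clash) break
      }
      taken_chrom <- c(taken_chrom, cn); taken_pos <- c(taken_pos, p)
      genotype <- if (runif(1) < cfg$hom_fraction) "1/1" else "0/1"
      hap <- if (genotype == "1/1") c(1L, 2L) else sample.int(2L, 1L)
      variants[[length(variants) + 1L]] <- tibble(
        sample_id = s, chrom = cn, pos = p, type = type,
        ref = ref_str, alt = alt_str, genotype = genotype,
        on_hap1 = 1L %in% hap, on_hap2 = 2L %in% hap
      )
    }
  }
  variants <- if (length(variants) > 0) bind_rows(variants) else {
    tibble(sample_id = character(0), chrom = character(0), pos = integer(0),
           type = character(0), ref = character(0), alt = character(0),
           genotype = character(0), on_hap1 = logical(0),
           on_hap2 = logical(0))
  }

  # --- per-sample haplotypes per chromosome --------------------------------
  haplo <- list()
  for (s in sample_ids) {
    for (cn in names(ref)) {
      for (h in 1:2) {
        vs <- variants |>
          filter(.data$sample_id == s, .data$chrom == cn,
                 if (h == 1) .data$on_hap1 else .data$on_hap2) |>
          mutate(ref_str = .data$ref, alt_str = .data$alt)
        haplo[[paste(s, cn, h)]] <- list(
          seq = apply_variants_seq(ref[[cn]], vs), vars = vs
        )
      }
    }
  }

  # --- capture efficiency and read generation ------------------------------
  mip_factors <- tibble(
    mip_id = design$mip_id,
    factor = exp(rnorm(nrow(design), -cfg$capture_sigma^2 / 2,
                       cfg$capture_sigma))
  )
  frag <- character(0); frag_sample <- character(0)
  frag_mip <- character(0)
  for (i in seq_len(nrow(design))) {
    pr <- design[i, ]
    fac <- mip_factors$factor[mip_factors$mip_id == pr$mip_id]
    for (k in seq_len(cfg$n_samples)) {
      s <- sample_ids[k]
      emit <- switch(
        pr$probe_class,
        target = TRUE,
        sry = sex[k] == "male",
        inversion_ref = {
          cr <- carriers$carrier[carriers$sample_id == s &
                                   carriers$event_id == pr$event_id]
          !isTRUE(cr[1])
        },
        inversion_mut = {
          cr <- carriers$carrier[carriers$sample_id == s &
                                   carriers$event_id == pr$event_id]
          isTRUE(cr[1])
        }
      )
      if (!emit) next
      n_reads <- rpois(1L, cfg$mean_reads_per_mip * fac)
      if (n_reads == 0) next
      sv_probe <- pr$chrom %in% names(sv_ref)
      if (sv_probe) {
        wseq <- substr(sv_ref[[pr$chrom]], pr$win_start + 1L, pr$win_end)
        frs <- rep(wseq, n_reads)
      } else {
        # arm bases are probe oligo (reference) sequence — sample variants
        # under an arm are invisible there, which is what makes arm
        # trimming necessary; only the scan target is sample-derived
        arm_up <- substr(ref[[pr$chrom]], pr$win_start + 1L, pr$scan_start)
        arm_dn <- substr(ref[[pr$chrom]], pr$scan_end + 1L, pr$win_end)
        hs <- sample.int(2L, n_reads, replace = TRUE)
        frs <- character(n_reads)
        for (h in 1:2) {
          nh <- sum(hs == h)
          if (nh == 0) next
          hp <- haplo[[paste(s, pr$chrom, h)]]
          a <- hap_coord(pr$scan_start, hp$vars)
          b <- hap_coord(pr$scan_end, hp$vars)
          frs[hs == h] <- paste0(arm_up, substr(hp$seq, a + 1L, b),
                                 arm_dn)
        }
      }
      if (pr$strand == "-") frs <- revcomp(frs)
      frag <- c(frag, frs)
      frag_sample <- c(frag_sample, rep(s, n_reads))
      frag_mip <- c(frag_mip, rep(pr$mip_id, n_reads))
    }
  }

  n_total <- length(frag)
  ord <- sample.int(n_total)
  frag <- frag[ord]; frag_sample <- frag_sample[ord]
  frag_mip <- frag_mip[ord]
  read_ids <- sprintf("rd%07d", seq_len(n_total))

  r1 <- substr(frag, 1L, pmin(cfg$read_len, nchar(frag)))
  r2 <- revcomp(substr(frag, pmax(1L, nchar(frag) - cfg$read_len + 1L),
                       nchar(frag)))
  r1 <- inject_errors(r1, cfg$seq_error_rate)
  r2 <- inject_errors(r2, cfg$seq_error_rate)
  qconst <- function(x) {
    vapply(nchar(x), function(n) int_to_qual(rep(cfg$base_qual, n)),
           character(1))
  }
  idx <- sheet$barcode1[match(frag_sample, sheet$sample_id)]
  idx <- inject_errors(idx, cfg$index_error_rate)

  pairs <- tibble(
    read_id = read_ids,
    seq1 = r1, qual1 = qconst(r1),
    seq2 = r2, qual2 = qconst(r2),
    index1 = idx
  )
  truth <- list(
    samples = {
      smp <- tibble(sample_id = sample_ids, sex = sex,
                    barcode1 = sheet$barcode1)
      if (nrow(carriers) > 0) {
        smp <- left_join(
          smp,
          carriers |> select("sample_id", "event_id", "carrier") |>
            tidyr::pivot_wider(names_from = "event_id",
                               values_from = "carrier"),
          by = "sample_id"
        )
      }
      smp
    },
    variants = variants,
    mip_factors = mip_factors,
    reads = tibble(read_id = read_ids, sample_id = frag_sample,
                   mip_id = frag_mip)
  )

  out <- list(design = design, sheet = sheet, ref = ref, sv_ref = sv_ref,
              pairs = pairs, truth = truth, cfg = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_reference(ref, file.path(dir, "ref.fa"))
    write_reference(sv_ref, file.path(dir, "sv_ref.fa"))
    write_mip_design(design, file.path(dir, "design.tsv"),
                     file.path(dir, "probe_classes.tsv"))
    readr::write_tsv(sheet, file.path(dir, "sample_sheet.tsv"),
                     progress = FALSE)
    write_fastq(tibble(read_id = read_ids, seq = pairs$seq1,
                       qual = pairs$qual1), file.path(dir, "R1.fastq.gz"))
    write_fastq(tibble(read_id = read_ids, seq = pairs$seq2,
                       qual = pairs$qual2), file.path(dir, "R2.fastq.gz"))
    write_fastq(tibble(read_id = read_ids, seq = pairs$index1,
                       qual = qconst(pairs$index1)),
                file.path(dir, "I1.fastq.gz"))
    jsonlite::write_json(
      list(samples = truth$samples, variants = truth$variants,
           mip_factors = truth$mip_factors),
      file.path(dir, "truth.json"), dataframe = "rows", na = "null"
    )
    readr::write_tsv(truth$reads, file.path(dir, "truth_reads.tsv"),
                     progress = FALSE)
    out$dir <- dir
  }
  out
}
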