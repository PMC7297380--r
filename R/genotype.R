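# Coverage analysis and diallelic pileup genotyping.
#
# The genotyper is a deliberately simple pileup model over trimmed,
# downsampled reads: at a site, the alternative allele is the most frequent
# non-reference allele (diallelic reduction), per-read error probability is
# eps = max(10^(-Q/10), error_floor), and genotype likelihoods are
#   L(g) = prod_reads P(base | g),  P(base | allele) = 1 - eps  (equal)
#                                                      eps / 3  (otherwise)
# with het likelihood the even mixture of the two allele terms and a
# uniform genotype prior. GQ is the Phred-scaled gap between the best and
# second-best posterior (-10*log10 of the odds of an incorrect call),
# capped at 99. Indels are left-aligned pileup alleles keyed at the anchor
# base; there is no local reassembly — the external-VCF path exists for
# callers that do more.

#' Downsample reads above a coverage cap
#'
#' Caps per-group read counts (the pipeline groups per sample and target
#' region) by a uniform, seed-reproducible random subset; groups at or
#' below `cap` are returned unchanged.
#'
#' @param reads A tibble of reads (any row-per-read tibble).
#' @param cap Maximum rows retained (>= 1).
#' @param seed Integer seed; identical seeds give identical subsets.
#' @return `reads` with at most `cap` rows, original order preserved.
#' @export
downsample <- function(reads, cap, seed) {
  stopifnot(cap >= 1)
  n <- nrow(reads)
  if (n <= cap) return(reads)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  reads[sort(sample.int(n, cap)), ]
}

#' Downsample per sample and capture target
#'
#' Caps coverage per (sample, probe): the probe scan target is the natural
#' "region of excessive coverage" in MIP data, since over-capture is a
#' per-probe phenomenon and a coarser cap would thin legitimately covered
#' neighbours instead.
#'
#' @param aln Assigned, trimmed alignment tibble (uses `mip_id`; reads
#'   without one are grouped per chromosome).
#' @param cap Per-group read cap (default 500).
#' @param seed Master seed; per-group seeds are derived deterministically
#'   so results do not depend on group processing order.
#' @return Downsampled alignment tibble.
#' @export
downsample_by_target <- function(aln, cap = 500L, seed = 1L) {
  grp <- if_else(is.na(aln$mip_id), paste0("chrom:", aln$chrom),
                 aln$mip_id)
  grp <- paste(aln$sample_id, grp, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(aln)), grp), function(idx) {
    if (length(idx) <= cap) return(idx)
    key <- grp[idx[1]]
    idx[sort(downsample(tibble(i = seq_along(idx)), cap,
                        derive_seed(seed, key))$i)]
  }), use.names = FALSE)
  aln[sort(keep), ]
}

#' Build a pileup from trimmed alignments
#'
#' One row per aligned base or indel observation. Insertions and deletions
#' are anchored VCF-style at the reference base immediately before the
#' event.
#'
#' @param aln Trimmed alignment tibble.
#' @param ref Optional named character vector of reference contigs; when
#'   given, indel observations are left-aligned and parsimony-trimmed so
#'   that equivalent gap placements collapse onto one canonical anchor.
#' @return Tibble with `chrom`, `pos` (0-based), `sample_id`, `read_id`,
#'   `obs` (a base, `+SEQ` for an insertion, `-N` for an N-base deletion)
#'   and `qual`.
#' @export
pileup <- function(aln, ref = NULL) {
  aln <- aln[!is.na(aln$chrom), ]
  if (nrow(aln) == 0) {
    return(tibble(chrom = character(0), pos = integer(0),
                  sample_id = character(0), read_id = character(0),
                  obs = character(0), qual = integer(0)))
  }
  simple <- grepl("^[0-9]+M$", aln$cigar)
  parts <- list()

  si <- which(simple)
  if (length(si) > 0) {
    lens <- nchar(aln$seq[si])
    qpos <- sequence(lens)
    ridx <- rep(si, lens)
    parts[[1]] <- tibble(
      chrom = rep(aln$chrom[si], lens),
      pos = rep(aln$pos[si], lens) + qpos - 1L,
      sample_id = rep(aln$sample_id[si], lens),
      read_id = rep(aln$read_id[si], lens),
      obs = unlist(strsplit(aln$seq[si], ""), use.names = FALSE),
      qual = unlist(lapply(aln$qual[si], utf8ToInt), use.names = FALSE) - 33L
    )
  }
  for (i in which(!simple)) {
    w <- walk_alignment(aln$pos[i], aln$cigar[i])
    sc <- strsplit(aln$seq[i], "")[[1]]
    qc <- utf8ToInt(aln$qual[i]) - 33L
    m <- w[w$op == "M", ]
    rows <- tibble(chrom = aln$chrom[i], pos = m$refpos,
                   sample_id = aln$sample_id[i], read_id = aln$read_id[i],
                   obs = sc[m$qpos], qual = qc[m$qpos])
    refseq <- if (!is.null(ref)) ref[[aln$chrom[i]]] else NULL
    ins <- w[w$op == "I", ]
    if (nrow(ins) > 0) {
      for (a in unique(ins$refpos)) {
        qp <- ins$qpos[ins$refpos == a]
        anchor <- a - 1L
        ins_seq <- paste(sc[qp], collapse = "")
        if (!is.null(refseq)) {
          rb <- substr(refseq, anchor + 1L, anchor + 1L)
          nv <- normalize_variant(refseq, anchor, rb, paste0(rb, ins_seq))
          anchor <- nv$pos
          ins_seq <- substr(nv$alt, 2L, nchar(nv$alt))
        }
        rows <- bind_rows(rows, tibble(
          chrom = aln$chrom[i], pos = anchor, sample_id = aln$sample_id[i],
          read_id = aln$read_id[i],
          obs = paste0("+", ins_seq),
          qual = as.integer(round(mean(qc[qp])))
        ))
      }
    }
    del <- w[w$op == "D", ]
    if (nrow(del) > 0) {
      iv <- positions_to_intervals(del$refpos)
      anchors <- iv$start - 1L
      if (!is.null(refseq)) {
        for (k in seq_along(anchors)) {
          nv <- normalize_variant(
            refseq, anchors[k],
            substr(refseq, anchors[k] + 1L, iv$end[k]),
            substr(refseq, anchors[k] + 1L, anchors[k] + 1L)
          )
          anchors[k] <- nv$pos
        }
      }
      rows <- bind_rows(rows, tibble(
        chrom = aln$chrom[i], pos = anchors,
        sample_id = aln$sample_id[i], read_id = aln$read_id[i],
        obs = paste0("-", iv$end - iv$start),
        qual = {
          anchor_q <- qc[match(anchors, m$refpos)]
          as.integer(if_else(is.na(anchor_q), 30L, anchor_q))
        }
      ))
    }
    parts[[length(parts) + 1L]] <- rows
  }
  bind_rows(parts) |> arrange(.data$chrom, .data$pos)
}

# Genotype one sample at one diallelic site from classified observations.
# `obs_class` is "ref"/"alt"/"other"; returns list(genotype, gq_raw, gq).
site_likelihood_call <- function(obs_class, qual, ploidy = 2L,
                                 error_floor = 1e-4) {
  # eps capped at 3/4: a Q0 base is uninformative (uniform over bases),
  # not impossible under the matching allele
  eps <- pmin(pmax(10^(-qual / 10), error_floor), 0.75)
  p_ref <- if_else(obs_class == "ref", 1 - eps, eps / 3)
  p_alt <- if_else(obs_class == "alt", 1 - eps, eps / 3)
  if (ploidy == 2L) {
    ll <- c(
      `0/0` = sum(log10(p_ref)),
      `0/1` = sum(log10((p_ref + p_alt) / 2)),
      `1/1` = sum(log10(p_alt))
    )
  } else {
    ll <- c(`0` = sum(log10(p_ref)), `1` = sum(log10(p_alt)))
  }
  o <- order(ll, decreasing = TRUE)
  gq_raw <- 10 * (ll[o[1]] - ll[o[2]])
  list(genotype = names(ll)[o[1]],
       gq_raw = unname(gq_raw),
       gq = min(99L, as.integer(round(gq_raw))))
}

#' Genotype one pileup column
#'
#' Diallelic likelihood call for a single sample at a single site.
#'
#' @param obs Character vector of per-read observations (bases or indel
#'   alleles as produced by [pileup()]).
#' @param qual Integer Phred qualities, parallel to `obs`.
#' @param ref_allele The reference observation (a base, or the reference
#'   form at an indel anchor).
#' @param alt_allele The alternative observation; defaults to the most
#'   frequent non-reference observation.
#' @param ploidy 2 (diploid) or 1 (hemizygous X in inferred males).
#' @param error_floor Lower bound on the per-read error probability
#'   (default 1e-4).
#' @param min_call_depth Sites with fewer observations are no-calls
#'   (default 8).
#' @return One-row tibble: `genotype`, `gq`, `gq_raw`, `ad_ref`, `ad_alt`,
#'   `dp`, `alt_allele`.
#' @export
call_site <- function(obs, qual, ref_allele, alt_allele = NULL,
                      ploidy = 2L, error_floor = 1e-4,
                      min_call_depth = 8L) {
  stopifnot(length(obs) == length(qual), ploidy %in% c(1L, 2L))
  dp <- length(obs)
  if (is.null(alt_allele)) {
    nonref <- obs[obs != ref_allele]
    alt_allele <- if (length(nonref) == 0) NA_character_ else {
      names(sort(table(nonref), decreasing = TRUE))[1]
    }
  }
  ad_ref <- sum(obs == ref_allele)
  ad_alt <- if (is.na(alt_allele)) 0L else sum(obs == alt_allele)
  if (dp < min_call_depth) {
    return(tibble(genotype = if (ploidy == 2L) "./." else ".",
                  gq = NA_integer_, gq_raw = NA_real_,
                  ad_ref = ad_ref, ad_alt = ad_alt, dp = dp,
                  alt_allele = alt_allele))
  }
  cls <- dplyr::case_when(
    obs == ref_allele ~ "ref",
    !is.na(alt_allele) & obs == alt_allele ~ "alt",
    TRUE ~ "other"
  )
  res <- site_likelihood_call(cls, qual, ploidy = ploidy,
                              error_floor = error_floor)
  tibble(genotype = res$genotype, gq = res$gq, gq_raw = res$gq_raw,
         ad_ref = ad_ref, ad_alt = ad_alt, dp = dp,
         alt_allele = alt_allele)
}

# Site discovery + per-sample genotyping over a pileup.
#
# Candidate sites are positions where some sample shows the same
# non-reference observation in >= min_alt_count reads and >= min_alt_frac
# of its depth; every sample is then genotyped at every candidate site.

#' Call variants from a pileup
#'
#' @param pu Pileup tibble from [pileup()].
#' @param ref Named character vector of reference contigs.
#' @param samples Character vector of samples to genotype (default: all in
#'   the pileup).
#' @param ploidy_map Optional tibble (`sample_id`, `chrom`, `ploidy`) for
#'   hemizygous calling; unlisted combinations are diploid.
#' @param min_call_depth,error_floor See [call_site()].
#' @param min_alt_count,min_alt_frac Site-discovery thresholds (defaults 3
#'   reads and 0.2 of sample depth).
#' @return Tibble of `chrom`, `pos` (0-based anchor), `ref`, `alt`,
#'   `sample_id`, `genotype`, `gq`, `gq_raw`, `ad_ref`, `ad_alt`, `dp`,
#'   `filter` (`PASS` or `LowGQ`).
#' @export
call_variants <- function(pu, ref, samples = NULL, ploidy_map = NULL,
                          min_call_depth = 8L, error_floor = 1e-4,
                          min_alt_count = 3L, min_alt_frac = 0.2) {
  if (is.null(samples)) samples <- sort(unique(pu$sample_id))
  sites <- discover_sites(pu, ref, min_alt_count, min_alt_frac)
  if (nrow(sites) == 0) return(empty_calls())
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    out[[i]] <- genotype_site(pu, sites$chrom[i], sites$pos[i],
                              sites$ref[i], sites$alt[i], sites$obs_alt[i],
                              samples, ploidy_map, min_call_depth,
                              error_floor)
  }
  bind_rows(out) |>
    mutate(filter = if_else(!is.na(.data$gq) & .data$gq < 20,
                            "LowGQ", "PASS")) |>
    arrange(.data$chrom, .data$pos, .data$sample_id)
}

empty_calls <- function() {
  tibble(chrom = character(0), pos = integer(0), ref = character(0),
         alt = character(0), sample_id = character(0),
         genotype = character(0), gq = integer(0), gq_raw = numeric(0),
         ad_ref = integer(0), ad_alt = integer(0), dp = integer(0),
         filter = character(0))
}

ref_base <- function(ref, chrom, pos) {
  substr(ref[[chrom]], pos + 1L, pos + 1L)
}

# Candidate diallelic sites with VCF-style allele spelling.
discover_sites <- function(pu, ref, min_alt_count, min_alt_frac) {
  depth <- pu |>
    filter(!startsWith(.data$obs, "+"), !startsWith(.data$obs, "-")) |>
    count(.data$chrom, .data$pos, .data$sample_id, name = "dp")
  cand <- pu |>
    count(.data$chrom, .data$pos, .data$sample_id, .data$obs,
          name = "n_obs") |>
    left_join(depth, by = c("chrom", "pos", "sample_id")) |>
    mutate(refb = mapply(ref_base, chrom = .data$chrom, pos = .data$pos,
                         MoreArgs = list(ref = ref)),
           is_ref = .data$obs == .data$refb) |>
    filter(!.data$is_ref,
           .data$n_obs >= min_alt_count,
           .data$n_obs >= min_alt_frac * pmax(.data$dp, 1L))
  if (nrow(cand) == 0) {
    return(tibble(chrom = character(0), pos = integer(0),
                  ref = character(0), alt = character(0),
                  obs_alt = character(0)))
  }
  # one alt per site: the observation with the highest total support
  cand |>
    group_by(.data$chrom, .data$pos, .data$obs, .data$refb) |>
    summarise(support = sum(.data$n_obs), .groups = "drop") |>
    group_by(.data$chrom, .data$pos) |>
    arrange(dplyr::desc(.data$support), .data$obs) |>
    slice(1) |>
    ungroup() |>
    mutate(spelled = purrr::pmap(
      list(.data$chrom, .data$pos, .data$obs, .data$refb),
      function(cn, p, o, rb) spell_alleles(ref, cn, p, o, rb)
    )) |>
    tidyr::unnest_wider("spelled") |>
    mutate(obs_alt = .data$obs) |>
    select("chrom", "pos", "ref", "alt", "obs_alt")
}

# VCF spelling of a pileup observation at a 0-based anchor position.
spell_alleles <- function(ref, chrom, pos, obs, refb) {
  if (startsWith(obs, "+")) {
    list(ref = refb, alt = paste0(refb, sub("^\\+", "", obs)))
  } else if (startsWith(obs, "-")) {
    n <- as.integer(sub("^-", "", obs))
    list(ref = substr(ref[[chrom]], pos + 1L, pos + 1L + n), alt = refb)
  } else {
    list(ref = refb, alt = obs)
  }
}

genotype_site <- function(pu, chrom, pos, ref_sp, alt_sp, obs_alt, samples,
                          ploidy_map, min_call_depth, error_floor) {
  col <- pu[pu$chrom == chrom & pu$pos == pos, ]
  is_indel <- startsWith(obs_alt, "+") || startsWith(obs_alt, "-")
  base_obs <- col[!startsWith(col$obs, "+") & !startsWith(col$obs, "-"), ]
  indel_obs <- col[col$obs == obs_alt, ]
  refb <- substr(ref_sp, 1L, 1L)
  out <- vector("list", length(samples))
  for (k in seq_along(samples)) {
    s <- samples[k]
    b <- base_obs[base_obs$sample_id == s, ]
    ploidy <- 2L
    if (!is.null(ploidy_map)) {
      pm <- ploidy_map[ploidy_map$sample_id == s &
                         ploidy_map$chrom == chrom, ]
      if (nrow(pm) > 0) ploidy <- as.integer(pm$ploidy[1])
    }
    if (is_indel) {
      ind <- indel_obs[indel_obs$sample_id == s, ]
      has_indel <- b$read_id %in% ind$read_id
      obs <- if_else(has_indel, "ALT", if_else(b$obs == refb, "REF", "O"))
      cl <- call_site(obs, b$qual, ref_allele = "REF", alt_allele = "ALT",
                      ploidy = ploidy, error_floor = error_floor,
                      min_call_depth = min_call_depth)
    } else {
      cl <- call_site(b$obs, b$qual, ref_allele = refb, alt_allele = obs_alt,
                      ploidy = ploidy, error_floor = error_floor,
                      min_call_depth = min_call_depth)
    }
    cl$sample_id <- s
    out[[k]] <- cl
  }
  bind_rows(out) |>
    mutate(chrom = chrom, pos = pos, ref = ref_sp, alt = alt_sp) |>
    select("chrom", "pos", "ref", "alt", "sample_id", "genotype", "gq",
           "gq_raw", "ad_ref", "ad_alt", "dp")
}

#' Per-sample, per-region coverage profile
#'
#' @param aln Trimmed alignment tibble (pre-downsampling).
#' @param design A `mip_design` tibble.
#' @param min_call_depth Depth below which a base is "incompletely
#'   covered" (strict `<`; default 8).
#' @return Tibble per (sample_id, region label): `mean_coverage`,
#'   `frac_covered` (fraction of bases at or above `min_call_depth`),
#'   and list-columns `incomplete` and `zero_cov` of sub-interval tibbles
#'   (`start`, `end`), with `zero_cov` a subset of `incomplete`.
#' @export
profile_coverage <- function(aln, design, min_call_depth = 8L) {
  regions <- target_regions(design)
  samples <- sort(unique(aln$sample_id))
  pu <- pileup(aln)
  depth <- pu |>
    filter(!startsWith(.data$obs, "+"), !startsWith(.data$obs, "-")) |>
    count(.data$sample_id, .data$chrom, .data$pos, name = "depth")
  out <- list()
  for (s in samples) {
    ds <- depth[depth$sample_id == s, ]
    for (i in seq_len(nrow(regions))) {
      rpos <- seq.int(regions$start[i], regions$end[i] - 1L)
      dsub <- ds[ds$chrom == regions$chrom[i], ]
      d <- dsub$depth[match(rpos, dsub$pos)]
      d[is.na(d)] <- 0L
      out[[length(out) + 1L]] <- tibble(
        sample_id = s,
        chrom = regions$chrom[i],
        region = regions$label[i],
        start = regions$start[i],
        end = regions$end[i],
        mean_coverage = mean(d),
        frac_covered = mean(d >= min_call_depth),
        incomplete = list(positions_to_intervals(rpos[d < min_call_depth])),
        zero_cov = list(positions_to_intervals(rpos[d == 0L]))
      )
    }
  }
  bind_rows(out)
}
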