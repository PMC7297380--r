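# VCF output of internal calls and ingestion of externally called VCF.

#' Write genotype calls as a multi-sample VCF 4.2
#'
#' @param calls Call tibble from [call_variants()].
#' @param ref_lengths Named integer vector of contig lengths.
#' @param path Output `.vcf` path.
#' @param samples Sample column order (default: sorted unique samples in
#'   `calls`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, ref_lengths, path, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(calls$sample_id))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mipseqr",
    paste0("##contig=<ID=", names(ref_lengths), ",length=", ref_lengths,
           ">"),
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FILTER=<ID=LowGQ,Description=\"Genotype quality below 20\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype ",
           "Quality (-10*log10 likelihood of an incorrect call)\">"),
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- character(0)
  if (nrow(calls) > 0) {
    sites <- calls |>
      distinct(.data$chrom, .data$pos, .data$ref, .data$alt) |>
      arrange(.data$chrom, .data$pos)
    body <- vapply(seq_len(nrow(sites)), function(i) {
      sc <- calls[calls$chrom == sites$chrom[i] &
                    calls$pos == sites$pos[i] &
                    calls$alt == sites$alt[i], ]
      gcols <- vapply(samples, function(s) {
        r <- sc[sc$sample_id == s, ]
        if (nrow(r) == 0) return("./.:.:.:.")
        paste(r$genotype[1],
              ifelse(is.na(r$gq[1]), ".", r$gq[1]),
              paste0(r$ad_ref[1], ",", r$ad_alt[1]),
              r$dp[1], sep = ":")
      }, character(1))
      filt <- if (any(sc$filter == "PASS")) "PASS" else sc$filter[1]
      paste(c(sites$chrom[i], sites$pos[i] + 1L, ".", sites$ref[i],
              sites$alt[i], ".", filt, ".", "GT:GQ:AD:DP", gcols),
            collapse = "\t")
    }, character(1))
  }
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Ingest an external VCF/gVCF as genotype calls
#'
#' Alternative calling path: normalizes externally produced calls (e.g.
#' from a haplotype-assembly caller) into the same call tibble the
#' internal genotyper emits. Multi-allelic sites are split into diallelic
#' records; gVCF reference blocks (`<NON_REF>`-only or missing ALT) emit
#' no variant call. Coordinates become 0-based.
#'
#' @param path VCF path (plain or bgzipped).
#' @param samples Optional subset of sample columns to ingest.
#' @return Call tibble (see [call_variants()]); records missing a FORMAT
#'   field carry `NA` there (with one warning per field).
#' @export
ingest_external_vcf <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_calls())
  all_samples <- colnames(v@gt)[-1]
  if (is.null(samples)) samples <- all_samples
  missing_s <- setdiff(samples, all_samples)
  if (length(missing_s) > 0) {
    abort(paste0("sample(s) not in VCF: ", paste(missing_s, collapse = ", ")))
  }
  fmt_or_na <- function(el, warn_field) {
    out <- tryCatch(
      vcfR::extract.gt(v, element = el),
      error = function(e) NULL
    )
    if (is.null(out)) {
      warn(paste0("FORMAT field ", warn_field,
                  " missing; values set to NA"))
      out <- matrix(NA_character_, nrow = nrow(fix),
                    ncol = length(all_samples),
                    dimnames = list(NULL, all_samples))
    }
    if (is.null(dim(out))) {
      out <- matrix(out, nrow = nrow(fix), ncol = length(all_samples),
                    dimnames = list(NULL, all_samples))
    }
    out
  }
  gt <- fmt_or_na("GT", "GT")
  gq <- fmt_or_na("GQ", "GQ")
  ad <- fmt_or_na("AD", "AD")
  dp <- fmt_or_na("DP", "DP")

  recs <- list()
  for (i in seq_len(nrow(fix))) {
    alt_str <- fix$ALT[i]
    if (is.na(alt_str) || alt_str %in% c(".", "<NON_REF>")) next
    alts <- strsplit(alt_str, ",", fixed = TRUE)[[1]]
    alts <- alts[alts != "<NON_REF>"]
    if (length(alts) == 0) next
    for (s in samples) {
      g <- gt[i, s]
      if (is.na(g)) g <- "./."
      g_alleles <- strsplit(g, "[/|]")[[1]]
      ad_s <- ad[i, s]
      ad_i <- if (is.na(ad_s)) integer(0) else {
        suppressWarnings(as.integer(strsplit(ad_s, ",")[[1]]))
      }
      gq_s <- suppressWarnings(as.numeric(gq[i, s]))
      dp_s <- suppressWarnings(as.integer(dp[i, s]))
      for (k in seq_along(alts)) {
        # re-express the genotype against this single alt (allele index k)
        ga <- dplyr::case_when(
          g_alleles == "." ~ ".",
          g_alleles == "0" ~ "0",
          g_alleles == as.character(k) ~ "1",
          TRUE ~ "0"  # other alt alleles fold into ref for this record
        )
        ga <- ga[order(ga == ".", ga)]  # canonical order, "." last
        recs[[length(recs) + 1L]] <- tibble(
          chrom = fix$CHROM[i],
          pos = as.integer(fix$POS[i]) - 1L,
          ref = fix$REF[i],
          alt = alts[k],
          sample_id = s,
          genotype = paste(ga, collapse = "/"),
          gq = as.integer(gq_s),
          gq_raw = gq_s,
          ad_ref = if (length(ad_i) >= 1) ad_i[1] else NA_integer_,
          ad_alt = if (length(ad_i) >= k + 1) ad_i[k + 1] else NA_integer_,
          dp = dp_s,
          filter = if (is.na(fix$FILTER[i]) || fix$FILTER[i] == ".")
            "PASS" else fix$FILTER[i]
        )
      }
    }
  }
  if (length(recs) == 0) return(empty_calls())
  bind_rows(recs) |> arrange(.data$chrom, .data$pos, .data$sample_id)
}

#' Read a variant annotation table
#'
#' Ingests the effect-predictor-style annotation TSV (gene, exon/intron
#' label, cDNA/CDS positions, HGVS transcript/protein, rsID, 1000G allele
#' frequency) keyed by `chrom`, `pos` (1-based in the file), `ref`, `alt`.
#'
#' @param path Annotation TSV path.
#' @return Tibble keyed by 0-based `pos` with the annotation columns,
#'   missing ones filled with `NA`.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0) {
    abort(paste0("annotation file is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "mipseqr_format_error")
  }
  opt <- c("gene", "region_label", "cdna_pos", "cds_pos", "hgvs_c",
           "hgvs_p", "rsid", "af_1000g")
  for (col in opt) if (!col %in% names(ann)) ann[[col]] <- NA
  ann |>
    mutate(pos = as.integer(.data$pos) - 1L) |>
    select(dplyr::all_of(c(need, opt)))
}
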