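# HTML report generation.
#
# Three report types: summary.html (technical cross-sample view: per-sample
# metrics, variant list, MIP performance), report.html (per-sample overview
# table with highlighted putative deleterious variants, benign variants in
# gray, inversion columns, failed MIPs and status) and one
# ind_<sample>.html per sample (quality metrics, variant details,
# per-region coverage, SV counts, outlier MIPs). Element ids are stable so
# consumers and tests can address parsed structure instead of bytes.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_cell <- function(x, class = NULL) {
  cls <- if (is.null(class) || is.na(class) || !nzchar(class)) "" else {
    paste0(" class=\"", class, "\"")
  }
  paste0("<td", cls, ">", x, "</td>")
}

# df columns are rendered in order; html_cols names columns whose content
# is already HTML (not escaped).
html_table <- function(df, id, row_ids = NULL, html_cols = character(0)) {
  head_row <- paste0("<tr>", paste0("<th>", html_escape(names(df)),
                                    "</th>", collapse = ""), "</tr>")
  body <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(names(df), function(cn) {
      val <- df[[cn]][i]
      html_cell(if (cn %in% html_cols) val else html_escape(val))
    }, character(1))
    rid <- if (!is.null(row_ids)) paste0(" id=\"", row_ids[i], "\"") else ""
    paste0("<tr", rid, ">", paste0(cells, collapse = ""), "</tr>")
  }, character(1))
  paste0("<table id=\"", id, "\">\n<thead>", head_row, "</thead>\n<tbody>\n",
         paste0(body, collapse = "\n"), "\n</tbody>\n</table>")
}

html_page <- function(title, body) {
  paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n<title>",
    html_escape(title), "</title>\n<style>\n",
    "table { border-collapse: collapse; margin: 1em 0; }\n",
    "td, th { border: 1px solid #999; padding: 2px 6px; }\n",
    ".benign { color: #888; }\n",
    ".deleterious { background: #ffe08a; font-weight: bold; }\n",
    ".flag-failed { background: #f8b4b4; }\n",
    "</style>\n</head>\n<body>\n", body, "\n</body>\n</html>\n"
  )
}

ind_href <- function(sample_id) paste0("ind_", sample_id, ".html")

sample_link <- function(sample_id) {
  paste0("<a href=\"", ind_href(sample_id), "\">",
         html_escape(sample_id), "</a>")
}

variant_span <- function(variant, benign_flag) {
  cls <- if_else(benign_flag, "benign", "deleterious")
  paste0("<span class=\"", cls, "\" id=\"var-",
         gsub("[^A-Za-z0-9_.-]", "_", variant), "\">",
         html_escape(variant), "</span>")
}

#' Render the HTML reports
#'
#' Writes `summary.html`, `report.html` and one `ind_<sample>.html` per
#' sample into `outdir`; all three types cross-link per sample.
#'
#' @param qc [build_sample_qc()] result.
#' @param calls Variant call tibble with a `benign_flag` column (added
#'   here as FALSE when absent).
#' @param inv_calls Inversion call tibble.
#' @param coverage [profile_coverage()] result.
#' @param stats [compute_mip_stats()] result.
#' @param outliers [flag_outlier_mips()] result.
#' @param outdir Output directory.
#' @param benign Optional benign-list tibble.
#' @return Character vector of written paths, invisibly.
#' @export
render_reports <- function(qc, calls, inv_calls, coverage, stats, outliers,
                           outdir, benign = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  calls <- calls |>
    mutate(variant = variant_key(.data$chrom, .data$pos, .data$ref,
                                 .data$alt))
  calls$benign_flag <- if (is.null(benign)) FALSE else {
    calls$variant %in% variant_key(benign$chrom, benign$pos, benign$ref,
                                   benign$alt)
  }
  called <- filter(calls, !.data$genotype %in% c("./.", ".", "0/0", "0"))

  paths <- character(0)
  paths["summary"] <- file.path(outdir, "summary.html")
  readr::write_file(render_summary(qc, called, stats), paths["summary"])
  paths["report"] <- file.path(outdir, "report.html")
  readr::write_file(render_overview(qc, called), paths["report"])
  for (s in qc$sample_id) {
    p <- file.path(outdir, ind_href(s))
    readr::write_file(
      render_individual(s, qc, called, inv_calls, coverage, outliers), p
    )
    paths[paste0("ind_", s)] <- p
  }
  invisible(paths)
}

render_summary <- function(qc, called, stats) {
  per_sample <- tibble(
    Sample = vapply(qc$sample_id, sample_link, character(1)),
    Sex = qc$sex, GT = qc$n_gt_calls,
    `Ave.Cov` = round(qc$mean_coverage, 1), Hets = qc$n_het,
    Status = qc$flag
  )
  t1 <- html_table(per_sample, id = "sample-summary",
                   row_ids = paste0("sample-", qc$sample_id),
                   html_cols = "Sample")
  vl <- called |>
    group_by(.data$variant, .data$benign_flag) |>
    summarise(
      n_samples = dplyr::n_distinct(.data$sample_id),
      samples = paste(vapply(sort(unique(.data$sample_id)), sample_link,
                             character(1)), collapse = ", "),
      .groups = "drop"
    )
  t2 <- if (nrow(vl) > 0) {
    html_table(
      tibble(Variant = variant_span(vl$variant, vl$benign_flag),
             Samples = vl$n_samples, `Found in` = vl$samples),
      id = "variant-list", html_cols = c("Variant", "Found in")
    )
  } else "<p id=\"variant-list\">No variants called.</p>"
  perf <- mip_summary(stats)
  t3 <- html_table(
    tibble(MIP = perf$mip_id, Total = perf$total_count,
           `Mean rel. abundance` = signif(perf$mean_rel_abundance, 3),
           Dispersion = signif(perf$dispersion, 3)),
    id = "mip-performance"
  )
  html_page("Run summary", paste(
    "<h1>Run summary</h1>",
    "<p><a href=\"report.html\">Per-sample overview</a></p>",
    "<h2>Samples</h2>", t1,
    "<h2>Variant calls</h2>", t2,
    "<h2>MIP performance</h2>", t3, sep = "\n"))
}

render_overview <- function(qc, called) {
  inv <- qc |>
    select("sample_id", "inversions") |>
    tidyr::unnest("inversions")
  events <- sort(unique(inv$event_id))
  rows <- lapply(seq_len(nrow(qc)), function(i) {
    s <- qc$sample_id[i]
    vs <- called[called$sample_id == s, ]
    variants <- if (nrow(vs) == 0) "" else {
      paste(variant_span(vs$variant, vs$benign_flag), collapse = ", ")
    }
    row <- tibble(Sample = sample_link(s), Sex = qc$sex[i],
                  Variants = variants)
    for (ev in events) {
      st <- inv$status[inv$sample_id == s & inv$event_id == ev]
      row[[ev]] <- if (length(st) > 0) st[1] else ""
    }
    row$`Incomplete regions` <- qc$incomplete_regions[i]
    row$`Failed MIPs` <- qc$failed_mips[i]
    row$Status <- qc$flag[i]
    row
  })
  df <- bind_rows(rows)
  t1 <- html_table(df, id = "sample-overview",
                   row_ids = paste0("sample-", qc$sample_id),
                   html_cols = c("Sample", "Variants"))
  html_page("Sample overview", paste(
    "<h1>Sample overview</h1>",
    "<p><a href=\"summary.html\">Run summary</a></p>",
    t1, sep = "\n"))
}

render_individual <- function(s, qc, called, inv_calls, coverage,
                              outliers) {
  q <- qc[qc$sample_id == s, ]
  metrics <- tibble(
    Metric = c("Sample", "Sex", "SRY reads", "Mean coverage",
               "Covered sites", "GT calls", "Het calls", "Status"),
    Value = c(s, q$sex, q$sry_count, round(q$mean_coverage, 1),
              round(q$covered_sites, 4), q$n_gt_calls, q$n_het, q$flag)
  )
  t_metrics <- html_table(metrics, id = "quality-metrics")
  vs <- called[called$sample_id == s, ]
  t_var <- if (nrow(vs) > 0) {
    html_table(
      tibble(Variant = variant_span(vs$variant, vs$benign_flag),
             GT = vs$genotype, GQ = vs$gq,
             AD = paste0(vs$ad_ref, ",", vs$ad_alt), DP = vs$dp,
             Filter = vs$filter),
      id = "variant-details", html_cols = "Variant"
    )
  } else "<p id=\"variant-details\">No variants called.</p>"
  cv <- coverage[coverage$sample_id == s, ]
  t_cov <- html_table(
    tibble(
      Region = cv$region,
      `Mean coverage` = round(cv$mean_coverage, 1),
      `Fraction covered` = round(cv$frac_covered, 4),
      `Incomplete` = vapply(seq_len(nrow(cv)), function(i) {
        iv <- cv$incomplete[[i]]
        if (nrow(iv) == 0) "" else {
          paste0(cv$chrom[i], ":", iv$start + 1L, "-", iv$end,
                 collapse = "; ")
        }
      }, character(1))
    ),
    id = "region-coverage"
  )
  iv <- inv_calls[inv_calls$sample_id == s, ]
  t_sv <- html_table(
    tibble(Event = iv$event_id, `Reference reads` = iv$ref_count,
           `Mutant reads` = iv$mut_count, Status = iv$status),
    id = "sv-counts"
  )
  ol <- outliers[outliers$sample_id == s, ]
  t_ol <- if (nrow(ol) > 0) {
    html_table(tibble(MIP = ol$mip_id, Type = ol$type), id = "mip-outliers")
  } else "<p id=\"mip-outliers\">No outlier MIPs.</p>"
  html_page(paste0("Sample ", s), paste(
    "<h1>Sample ", html_escape(s), "</h1>",
    "<p><a href=\"summary.html\">Run summary</a> | ",
    "<a href=\"report.html\">Overview</a></p>",
    "<h2>Quality metrics</h2>", t_metrics,
    "<h2>Variants</h2>", t_var,
    "<h2>Region coverage</h2>", t_cov,
    "<h2>Structural variant counts</h2>", t_sv,
    "<h2>Outlier MIPs</h2>", t_ol, sep = "\n"))
}
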