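#' Report rendering options
#'
#' @param threshold depth threshold drawn as the horizontal red line in the
#'   per-gene exon charts and used for failing-exon detection.
#' @param base_plots when to include base-level coverage plots:
#'   `"failing-only"` (default; only exons with bases below the threshold),
#'   `"always"`, or `"never"`.
#' @param format `"html"` (structured, inline-SVG figures) or `"pdf"`.
#' @param width,height figure size in inches.
#' @param timestamp include a generation timestamp (off by default so that
#'   two renders of the same inputs are byte-identical).
#' @param comparator threshold comparator, see [metrics_config()].
#' @return object of class `report_spec`.
#' @export
report_spec <- function(threshold = 30, base_plots = c("failing-only",
                                                       "always", "never"),
                        format = c("html", "pdf"), width = 7, height = 3.5,
                        timestamp = FALSE,
                        comparator = c("at-least", "strictly-greater")) {
  base_plots <- match.arg(base_plots)
  format <- match.arg(format)
  comparator <- match.arg(comparator)
  if (threshold < 0) stopf("threshold must be >= 0")
  structure(list(threshold = threshold, base_plots = base_plots,
                 format = format, width = width, height = height,
                 timestamp = isTRUE(timestamp), comparator = comparator),
            class = "report_spec")
}

#' Find exons that fail to reach the coverage threshold
#'
#' An exon fails when at least one of its bases does not meet the depth
#' threshold. For each failing exon the minimum depth, the fraction of
#' below-threshold bases and the contiguous below-threshold sub-intervals
#' (0-based half-open genomic coordinates) are reported.
#'
#' @param profile a `depth_profile`.
#' @param threshold depth threshold (default 30).
#' @param comparator see [metrics_config()].
#' @return data.frame with columns `gene`, `exon_label`, `chrom`, `start`,
#'   `end`, `min_depth`, `frac_below`, and list column `below_intervals`
#'   (each a data.frame `start`, `end`).
#' @export
detect_failing_exons <- function(profile, threshold = 30,
                                 comparator = c("at-least",
                                                "strictly-greater")) {
  stopifnot(inherits(profile, "depth_profile"))
  comparator <- match.arg(comparator)
  rows <- list()
  for (j in seq_along(profile$per_region)) {
    d <- profile$per_region[[j]]
    below <- !meets(d, threshold, comparator)
    if (!any(below)) next
    r <- profile$regions[j, ]
    runs <- rle(below)
    ends_i <- cumsum(runs$lengths)
    starts_i <- ends_i - runs$lengths + 1L
    keep <- runs$values
    rows[[length(rows) + 1L]] <- data.frame(
      gene = r$gene, exon_label = r$exon_label, chrom = r$chrom,
      start = r$start, end = r$end, min_depth = min(d),
      frac_below = mean(below),
      below_intervals = I(list(data.frame(
        start = r$start + starts_i[keep] - 1L,
        end = r$start + ends_i[keep]))),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene = character(), exon_label = character(),
                      chrom = character(), start = integer(),
                      end = integer(), min_depth = integer(),
                      frac_below = numeric(),
                      below_intervals = I(list()),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# render a base-graphics expression to inline-SVG markup (deterministic)
svg_figure <- function(code, width, height) {
  f <- tempfile(fileext = ".svg")
  grDevices::svg(f, width = width, height = height)
  ok <- try(code, silent = TRUE)
  grDevices::dev.off()
  txt <- readLines(f, warn = FALSE)
  unlink(f)
  if (inherits(ok, "try-error")) stop(ok)
  paste(txt[-1], collapse = "\n")        # drop the XML declaration
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

plot_gene_panel <- function(gene, labels, means, threshold) {
  graphics::par(mar = c(5, 4, 2, 1))
  bp <- graphics::barplot(means, names.arg = labels, las = 2,
                          cex.names = if (length(means) > 12) 0.55 else 0.8,
                          col = "steelblue", border = NA,
                          ylim = c(0, max(c(means, threshold)) * 1.1),
                          ylab = "mean depth", main = gene)
  graphics::abline(h = threshold, col = "red", lwd = 1.5)
}

plot_base_level <- function(chrom, start, depth, threshold, title) {
  graphics::par(mar = c(5, 4, 2, 1))
  pos <- start + seq_along(depth)        # 1-based display coordinates
  graphics::plot(pos, depth, type = "l", col = "steelblue", lwd = 1.5,
                 xlab = sprintf("%s position (1-based)", chrom),
                 ylab = "depth", main = title,
                 ylim = c(0, max(c(depth, threshold)) * 1.1))
  graphics::abline(h = threshold, col = "red", lwd = 1.5)
}

plot_cumulative_curve <- function(curve, stability_factor = 0.2) {
  graphics::par(mar = c(5, 4, 2, 1))
  graphics::plot(curve$x, curve$pct, type = "l", lwd = 2, col = "steelblue",
                 xlab = "depth / mean depth", ylab = "% of target bases",
                 main = "Cumulative normalized coverage", ylim = c(0, 100))
  graphics::abline(v = stability_factor, col = "red", lty = 2)
}

#' Render a per-sample coverage report
#'
#' Produces the per-sample capture QC report: general alignment statistics,
#' the metric table, the cumulative normalized coverage curve, one
#' exon-coverage bar chart per gene with a horizontal threshold line, and
#' (depending on the report spec) base-level coverage plots for failing
#' exons. A machine-readable JSON companion holding every plotted number is
#' written next to the report. HTML output with timestamping disabled is a
#' pure function of its inputs (byte-identical re-renders).
#'
#' @param summary a `coverage_summary` for the sample.
#' @param profile the matching `depth_profile`.
#' @param roi the [roi()] the profile was computed over.
#' @param spec a [report_spec()].
#' @param path output file path (`.html` or `.pdf` per `spec$format`).
#' @return `path`, invisibly. The JSON companion is written to
#'   `paste0(path, ".json")`.
#' @export
render_coverage_report <- function(summary, profile, roi,
                                   spec = report_spec(), path) {
  stopifnot(inherits(summary, "coverage_summary"),
            inherits(profile, "depth_profile"), inherits(roi, "roi"))
  if (!length(roi$by_gene)) stopf("ROI has no genes: nothing to report")
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot write report to '%s': %s", path, conditionMessage(e)))
  close(con)

  failing <- detect_failing_exons(profile, spec$threshold, spec$comparator)
  genes <- sort(names(roi$by_gene))      # gene panels in alphabetical order
  gene_data <- lapply(genes, function(g) {
    idx <- roi$by_gene[[g]]
    r <- roi$regions[idx, , drop = FALSE]
    list(gene = g, labels = r$exon_label,
         means = vapply(profile$per_region[idx], mean, 0),
         regions = r, idx = idx)
  })
  base_idx <- switch(spec$base_plots,
    never = integer(),
    always = unlist(lapply(gene_data, `[[`, "idx")),
    `failing-only` = {
      if (!nrow(failing)) integer() else
        which(paste(profile$regions$gene, profile$regions$exon_label) %in%
                paste(failing$gene, failing$exon_label))
    })

  stats_tbl <- data.frame(
    statistic = c("Total records", "Mapped retained reads",
                  "Reads on target"),
    value = c(summary$total_reads, summary$mapped_reads,
              summary$on_target_reads), stringsAsFactors = FALSE)
  metric_tbl <- data.frame(
    metric = c("Mean base coverage",
               sprintf("%% bases with coverage %s %gX",
                       if (spec$comparator == "at-least") ">=" else ">",
                       summary$config$depth_threshold),
               "% reads mapped on target",
               sprintf("%% bases with coverage %s %g x mean",
                       if (spec$comparator == "at-least") ">=" else ">",
                       summary$config$stability_factor)),
    value = c(fmt_cov(summary$mean_base_coverage),
              fmt_pct(summary$pct_bases_ge_T),
              if (is.na(summary$pct_on_target)) "NA" else
                fmt_pct(summary$pct_on_target),
              fmt_pct(summary$stability_pct)), stringsAsFactors = FALSE)

  json <- list(sample_id = summary$sample_id,
               alignment_stats = stats_tbl,
               metrics = list(mean_base_coverage = summary$mean_base_coverage,
                              pct_bases_ge_T = summary$pct_bases_ge_T,
                              pct_on_target = summary$pct_on_target,
                              stability_pct = summary$stability_pct),
               per_exon = data.frame(
                 gene = profile$regions$gene,
                 exon_label = profile$regions$exon_label,
                 chrom = profile$regions$chrom,
                 start = profile$regions$start, end = profile$regions$end,
                 mean_depth = vapply(profile$per_region, mean, 0),
                 stringsAsFactors = FALSE),
               failing_exons = failing[, setdiff(names(failing),
                                                 "below_intervals")],
               cumulative_curve = summary$cumulative_curve,
               base_plots = spec$base_plots,
               n_gene_panels = length(genes))
  jsonlite::write_json(json, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")

  if (spec$format == "pdf") {
    grDevices::pdf(path, width = spec$width, height = spec$height,
                   onefile = TRUE)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::plot.new()
    txt <- c(sprintf("Coverage report: %s", summary$sample_id), "",
             sprintf("%s: %s", stats_tbl$statistic, stats_tbl$value), "",
             sprintf("%s: %s", metric_tbl$metric, metric_tbl$value))
    graphics::text(0, seq(0.95, by = -0.08, length.out = length(txt)), txt,
                   adj = 0, cex = 0.8)
    plot_cumulative_curve(summary$cumulative_curve,
                          summary$config$stability_factor)
    for (gd in gene_data)
      plot_gene_panel(gd$gene, gd$labels, gd$means, spec$threshold)
    for (j in base_idx) {
      r <- profile$regions[j, ]
      plot_base_level(r$chrom, r$start, profile$per_region[[j]],
                      spec$threshold, sprintf("%s %s", r$gene, r$exon_label))
    }
    return(invisible(path))
  }

  h <- c('<!DOCTYPE html>', '<html><head><meta charset="utf-8"/>',
         sprintf('<title>Coverage report: %s</title>',
                 html_escape(summary$sample_id)),
         '<style>body{font-family:sans-serif;max-width:60em;margin:auto}',
         'table{border-collapse:collapse}td,th{border:1px solid #999;',
         'padding:2px 8px}</style></head><body>',
         sprintf('<h1>Coverage report: %s</h1>',
                 html_escape(summary$sample_id)))
  if (spec$timestamp)
    h <- c(h, sprintf('<p class="timestamp">Generated %s</p>',
                      format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  tbl_html <- function(df) {
    c('<table>',
      paste0('<tr>', paste0('<th>', html_escape(names(df)), '</th>',
                            collapse = ''), '</tr>'),
      vapply(seq_len(nrow(df)), function(i)
        paste0('<tr>', paste0('<td>',
                              html_escape(as.character(unlist(df[i, ]))),
                              '</td>', collapse = ''), '</tr>'), ""),
      '</table>')
  }
  h <- c(h, '<section id="alignment-stats"><h2>Alignment statistics</h2>',
         tbl_html(stats_tbl), '</section>',
         '<section id="metrics"><h2>Capture metrics</h2>',
         tbl_html(metric_tbl), '</section>',
         '<section id="cumulative-curve">',
         '<h2>Cumulative normalized coverage</h2>',
         svg_figure(plot_cumulative_curve(summary$cumulative_curve,
                                          summary$config$stability_factor),
                    spec$width, spec$height), '</section>',
         '<h2>Exon coverage per gene</h2>')
  for (gd in gene_data) {
    h <- c(h, sprintf('<section class="gene-panel" data-gene="%s">',
                      html_escape(gd$gene)),
           svg_figure(plot_gene_panel(gd$gene, gd$labels, gd$means,
                                      spec$threshold),
                      spec$width, spec$height),
           '</section>')
  }
  if (length(base_idx)) {
    h <- c(h, '<h2>Base-level coverage</h2>')
    for (j in base_idx) {
      r <- profile$regions[j, ]
      h <- c(h, sprintf('<section class="base-plot" data-exon="%s_%s">',
                        html_escape(r$gene), html_escape(r$exon_label)),
             svg_figure(plot_base_level(r$chrom, r$start,
                                        profile$per_region[[j]],
                                        spec$threshold,
                                        sprintf("%s %s", r$gene,
                                                r$exon_label)),
                        spec$width, spec$height),
             '</section>')
    }
  }
  h <- c(h, '</body></html>')
  writeLines(h, path)
  invisible(path)
}

#' Render a pool-level report
#'
#' Writes the pool aggregation table (per-pool mean +/- SD of each capture
#' metric plus a Total row) and one index-balance bar chart per pool.
#'
#' @param pools a `pool_summary` (see [aggregate_pools()]).
#' @param dist an `index_distribution` (see [index_distribution()]), or
#'   `NULL` to omit the balance charts.
#' @param path output HTML path.
#' @param spec a [report_spec()] (figure size and timestamping only).
#' @return `path`, invisibly; a JSON companion is written alongside.
#' @export
render_pool_report <- function(pools, dist = NULL, path,
                               spec = report_spec()) {
  stopifnot(inherits(pools, "pool_summary"))
  if (!nrow(pools) || !any(pools$pool != "Total"))
    stopf("at least one pool is required")
  disp <- pools
  for (nm in names(disp)) if (is.numeric(disp[[nm]]) && nm != "n")
    disp[[nm]] <- ifelse(is.na(disp[[nm]]), "",
                         formatC(disp[[nm]], format = "f", digits = 2))
  h <- c('<!DOCTYPE html>', '<html><head><meta charset="utf-8"/>',
         '<title>Pool report</title>',
         '<style>table{border-collapse:collapse}td,th{border:1px solid #999;',
         'padding:2px 8px}</style></head><body>',
         '<h1>Pool report</h1>',
         '<section id="pool-table"><h2>Pool summary</h2><table>',
         paste0('<tr>', paste0('<th>', html_escape(names(disp)), '</th>',
                               collapse = ''), '</tr>'),
         vapply(seq_len(nrow(disp)), function(i)
           paste0('<tr>', paste0('<td>',
                                 html_escape(as.character(unlist(disp[i, ]))),
                                 '</td>', collapse = ''), '</tr>'), ""),
         '</table></section>')
  if (!is.null(dist)) {
    stopifnot(inherits(dist, "index_distribution"))
    h <- c(h, '<h2>Read distribution per index</h2>')
    for (p in unique(dist$samples$pool)) {
      g <- dist$samples[dist$samples$pool == p, , drop = FALSE]
      h <- c(h, sprintf('<section class="pool-chart" data-pool="%s">',
                        html_escape(p)),
             svg_figure({
               graphics::par(mar = c(6, 4, 2, 1))
               graphics::barplot(g$pct, names.arg = g$sample_id, las = 2,
                                 col = "darkseagreen", border = NA,
                                 ylab = "% of pool reads",
                                 main = sprintf("Pool %s (n = %d)", p,
                                                nrow(g)))
               graphics::abline(h = 100 / nrow(g), col = "red", lty = 2)
             }, spec$width, spec$height),
             '</section>')
    }
  }
  h <- c(h, '</body></html>')
  writeLines(h, path)
  json <- list(pools = pools,
               index_distribution = if (is.null(dist)) NULL else dist$samples)
  jsonlite::write_json(json, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
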