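#' Construct a region-of-interest (ROI) object from target intervals
#'
#' A ROI is the set of genomic intervals targeted by a capture design.
#' Coordinates follow the BED convention throughout the package: 0-based,
#' half-open `[start, end)`. Regions are grouped by gene; the merged (unique)
#' base count is computed so that overlapping or duplicated design intervals
#' never inflate global metrics.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`, `gene`,
#'   `exon_label` (the last two optional; missing genes become `"UNNAMED"`).
#' @return An object of class `roi`: a list with elements
#'   \describe{
#'     \item{regions}{the validated per-exon table, with a `length` column}
#'     \item{merged}{disjoint intervals per chromosome (`chrom,start,end`)}
#'     \item{merged_bases}{total unique targeted bases}
#'     \item{by_gene}{named list mapping gene to row indices of `regions`,
#'       sorted by (chrom, start) within each gene}
#'   }
#' @export
roi <- function(regions) {
  stopifnot(is.data.frame(regions))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(regions)))
    stopf("regions must have columns %s", paste(need, collapse = ", "))
  regions$chrom <- as.character(regions$chrom)
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (nrow(regions)) {
    if (any(is.na(regions$start) | is.na(regions$end)))
      stopf("non-integer coordinates in regions")
    bad <- which(regions$start < 0L | regions$start >= regions$end)
    if (length(bad))
      stopf("invalid interval at row %d: start=%d end=%d (need 0 <= start < end)",
            bad[1], regions$start[bad[1]], regions$end[bad[1]])
    if (any(!nzchar(regions$chrom) | is.na(regions$chrom)))
      stopf("empty chromosome name in regions")
  }
  if (is.null(regions$gene)) regions$gene <- rep("UNNAMED", nrow(regions))
  regions$gene <- as.character(regions$gene)
  regions$gene[is.na(regions$gene) | !nzchar(regions$gene)] <- "UNNAMED"
  if (is.null(regions$exon_label)) regions$exon_label <- rep("", nrow(regions))
  regions$exon_label <- as.character(regions$exon_label)
  # exons without a label get a sequential index within their gene
  for (g in unique(regions$gene)) {
    idx <- which(regions$gene == g)
    blank <- idx[!nzchar(regions$exon_label[idx])]
    if (length(blank))
      regions$exon_label[blank] <- as.character(match(blank, idx))
  }
  regions$length <- regions$end - regions$start
  rownames(regions) <- NULL

  merged <- merge_intervals(regions)
  by_gene <- lapply(split(seq_len(nrow(regions)), regions$gene), function(i) {
    i[order(regions$chrom[i], regions$start[i])]
  })
  # gene groups keep first-appearance order of genes
  if (nrow(regions))
    by_gene <- by_gene[unique(regions$gene)]
  structure(
    list(regions = regions, merged = merged,
         merged_bases = if (nrow(merged)) sum(merged$end - merged$start) else 0L,
         by_gene = by_gene),
    class = "roi")
}

#' Read a target design from a BED file
#'
#' Parses a 3+ column tab-separated BED file into a [roi()] object. Track,
#' browser and `#` comment lines are skipped. The name field (column 4)
#' encodes gene and exon according to `name_scheme`:
#' \describe{
#'   \item{`"underscore"`}{split on the \emph{last} underscore into
#'     (gene, exon label); names without an underscore become the gene, and
#'     the exon label is a sequential index within the gene}
#'   \item{`"whole"`}{the entire name is the gene; exons are indexed
#'     sequentially}
#' }
#' Lines missing column 4 are assigned gene `"UNNAMED"` with a warning.
#' Duplicate identical lines are collapsed with a warning so per-exon tables
#' are not double counted. Malformed coordinates abort with the line number.
#'
#' @param path path to a BED file.
#' @param name_scheme how to interpret column 4 (see above).
#' @return A [roi()] object; input region order is preserved within genes.
#' @export
parse_bed <- function(path, name_scheme = c("underscore", "whole")) {
  name_scheme <- match.arg(name_scheme)
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(roi(data.frame(chrom = character(), start = integer(),
                          end = integer(), gene = character(),
                          exon_label = character())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_line <- lengths(fields)
  if (any(ncol_line < 3L))
    stopf("BED line %d has fewer than 3 columns", lineno[which(ncol_line < 3L)[1]])
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stopf("BED line %d: non-integer coordinate", lineno[bad[1]])
  bad <- which(start < 0L | start >= end)
  if (length(bad))
    stopf("BED line %d: start (%d) must be < end (%d) and non-negative",
          lineno[bad[1]], start[bad[1]], end[bad[1]])
  name <- vapply(seq_along(fields), function(i)
    if (ncol_line[i] >= 4L) fields[[i]][4L] else NA_character_, "")
  if (anyNA(name))
    warnf("%d BED line(s) lack a name column; assigned gene 'UNNAMED'",
          sum(is.na(name)))
  gene <- rep("UNNAMED", length(name))
  exon <- rep("", length(name))
  has <- !is.na(name) & nzchar(name)
  if (name_scheme == "underscore") {
    us <- regexpr("_[^_]*$", name[has])
    split_ok <- us > 1L
    gene[has][split_ok] <- substr(name[has][split_ok], 1L, us[split_ok] - 1L)
    exon[has][split_ok] <- substring(name[has][split_ok], us[split_ok] + 1L)
    gene[has][!split_ok] <- name[has][!split_ok]
  } else {
    gene[has] <- name[has]
  }
  df <- data.frame(chrom = chrom, start = start, end = end, gene = gene,
                   exon_label = exon, stringsAsFactors = FALSE)
  dup <- duplicated(df)
  if (any(dup)) {
    warnf("collapsed %d duplicate BED line(s)", sum(dup))
    df <- df[!dup, , drop = FALSE]
  }
  roi(df)
}

#' Merge intervals into disjoint per-chromosome intervals
#'
#' Computes the union of the input intervals as sorted, non-overlapping,
#' non-touching half-open intervals, so each genomic base is counted once.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @return data.frame with `chrom`, `start`, `end`, sorted by (chrom, start).
#' @export
merge_intervals <- function(regions) {
  if (!nrow(regions))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  # IRanges is 1-based closed: [start+1, end]
  by_chr <- split(regions, regions$chrom)
  out <- lapply(names(by_chr), function(chr) {
    r <- by_chr[[chr]]
    red <- IRanges::reduce(IRanges::IRanges(start = r$start + 1L, end = r$end))
    data.frame(chrom = chr, start = IRanges::start(red) - 1L,
               end = IRanges::end(red), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a ROI back to a normalized BED file
#'
#' Writes one 4-column line per region, with the name field reassembled as
#' `gene_exonlabel` (matching the `"underscore"` scheme of [parse_bed()]).
#'
#' @param x a [roi()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "roi"))
  r <- x$regions
  lines <- sprintf("%s\t%d\t%d\t%s_%s", r$chrom, r$start, r$end, r$gene,
                   r$exon_label)
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("ROI: %d region(s), %d gene(s), %d unique targeted base(s)\n",
              nrow(x$regions), length(x$by_gene), x$merged_bases))
  invisible(x)
}
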