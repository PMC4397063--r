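#' Read alignment records from a BAM or SAM file
#'
#' Loads the fields needed for coverage computation into a record table.
#' SAM input is converted in a temporary location before reading. Flag
#' booleans follow the SAM specification bit definitions (0x4 unmapped,
#' 0x100 secondary, 0x200 QC fail, 0x400 duplicate, 0x800 supplementary).
#'
#' @param path path to a `.bam` or `.sam` file.
#' @return data.frame of class `panel_alignments` with columns `qname`,
#'   `chrom`, `start` (0-based leftmost reference position), `mapq`,
#'   `cigar`, and logicals `unmapped`, `secondary`, `supplementary`,
#'   `duplicate`, `qc_fail`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stopf("alignment file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  bam <- path
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(path, destination = dest, indexDestination = FALSE,
                       overwrite = TRUE))
  }
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar")))[[1]]
  flag <- res$flag
  out <- data.frame(
    qname = res$qname,
    chrom = as.character(res$rname),
    start = ifelse(is.na(res$pos), NA_integer_, res$pos - 1L),
    mapq = ifelse(is.na(res$mapq), 0L, res$mapq),
    cigar = res$cigar,
    unmapped = bitwAnd(flag, 4L) > 0L,
    secondary = bitwAnd(flag, 256L) > 0L,
    qc_fail = bitwAnd(flag, 512L) > 0L,
    duplicate = bitwAnd(flag, 1024L) > 0L,
    supplementary = bitwAnd(flag, 2048L) > 0L,
    stringsAsFactors = FALSE)
  class(out) <- c("panel_alignments", "data.frame")
  out
}

#' Build an alignment record table in memory
#'
#' Convenience constructor mirroring the columns of [read_alignments()],
#' mainly for tests and simulated inputs.
#'
#' @param chrom,start,cigar vectors of chromosome, 0-based start, CIGAR.
#' @param mapq mapping quality (default 60).
#' @param unmapped,secondary,supplementary,duplicate,qc_fail flag logicals.
#' @param qname read names (default generated).
#' @return a `panel_alignments` data.frame.
#' @export
alignment_records <- function(chrom, start, cigar, mapq = 60L,
                              unmapped = FALSE, secondary = FALSE,
                              supplementary = FALSE, duplicate = FALSE,
                              qc_fail = FALSE, qname = NULL) {
  n <- max(length(chrom), length(start), length(cigar), length(mapq),
           length(unmapped), length(secondary), length(supplementary),
           length(duplicate), length(qc_fail))
  if (length(chrom) == 0L) n <- 0L
  out <- data.frame(
    qname = qname %||% sprintf("r%06d", seq_len(n)),
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.integer(start), n),
    mapq = rep_len(as.integer(mapq), n),
    cigar = rep_len(as.character(cigar), n),
    unmapped = rep_len(unmapped, n), secondary = rep_len(secondary, n),
    qc_fail = rep_len(qc_fail, n), duplicate = rep_len(duplicate, n),
    supplementary = rep_len(supplementary, n), stringsAsFactors = FALSE)
  class(out) <- c("panel_alignments", "data.frame")
  out
}

#' Define an alignment record filter
#'
#' Default settings mirror standard post-deduplication practice: duplicate,
#' secondary, supplementary and QC-fail records are excluded and no mapping
#' quality cut is applied.
#'
#' @param exclude_duplicates,exclude_secondary,exclude_supplementary,exclude_qc_fail
#'   flag exclusions (logical).
#' @param min_mapq minimum mapping quality (>= 0).
#' @return an object of class `read_filter`.
#' @export
read_filter <- function(exclude_duplicates = TRUE, exclude_secondary = TRUE,
                        exclude_supplementary = TRUE, exclude_qc_fail = TRUE,
                        min_mapq = 0L) {
  if (min_mapq < 0) stopf("min_mapq must be >= 0")
  structure(list(exclude_duplicates = isTRUE(exclude_duplicates),
                 exclude_secondary = isTRUE(exclude_secondary),
                 exclude_supplementary = isTRUE(exclude_supplementary),
                 exclude_qc_fail = isTRUE(exclude_qc_fail),
                 min_mapq = as.integer(min_mapq)),
            class = "read_filter")
}

#' Apply a read filter to alignment records
#'
#' A record is retained iff it is mapped, passes every enabled flag
#' exclusion, and has `mapq >= min_mapq`.
#'
#' @param records a `panel_alignments` data.frame.
#' @param filter a [read_filter()].
#' @return logical vector: retained?
#' @export
apply_filter <- function(records, filter = read_filter()) {
  stopifnot(inherits(filter, "read_filter"))
  keep <- !records$unmapped & records$mapq >= filter$min_mapq
  if (filter$exclude_duplicates) keep <- keep & !records$duplicate
  if (filter$exclude_secondary) keep <- keep & !records$secondary
  if (filter$exclude_supplementary) keep <- keep & !records$supplementary
  if (filter$exclude_qc_fail) keep <- keep & !records$qc_fail
  keep
}

# Expand CIGAR strings to reference-covering blocks (0-based half-open).
# Only aligned-match operations (M, =, X) cover bases; D and N consume
# reference without covering; I/S/H/P consume none. Returns a data.frame
# (read, start, end) where `read` indexes the input vector.
cigar_ref_blocks <- function(cigar, start) {
  n <- length(cigar)
  simple <- grepl("^\\d+M$", cigar)
  out <- vector("list", 2L)
  if (any(simple)) {
    len <- as.integer(sub("M$", "", cigar[simple]))
    out[[1]] <- data.frame(read = which(simple), start = start[simple],
                           end = start[simple] + len)
  }
  hard <- which(!simple & !is.na(cigar) & cigar != "*")
  if (length(hard)) {
    toks <- regmatches(cigar[hard], gregexpr("\\d+[MIDNSHP=X]", cigar[hard]))
    pieces <- lapply(seq_along(hard), function(j) {
      tk <- toks[[j]]
      num <- as.integer(substr(tk, 1L, nchar(tk) - 1L))
      op <- substr(tk, nchar(tk), nchar(tk))
      consume <- op %in% c("M", "D", "N", "=", "X")
      ends <- start[hard[j]] + cumsum(num * consume)
      starts <- ends - num * consume
      keep <- op %in% c("M", "=", "X") & num > 0L
      if (!any(keep)) return(NULL)
      data.frame(read = hard[j], start = starts[keep], end = ends[keep])
    })
    out[[2]] <- do.call(rbind, pieces)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(read = integer(), start = integer(), end = integer())
  res[order(res$read, res$start), , drop = FALSE]
}

#' Compute per-base depth over a ROI and on-target read counts
#'
#' Depth at a targeted base is the number of retained records with an
#' aligned-match block (CIGAR M/=/X) containing that base; deletions and
#' skips spanned by a read do not add depth, and clipped bases never cover.
#' Overlapping mates of a pair each contribute depth (no mate-aware
#' deduplication). A record counts as on-target when its aligned span
#' overlaps at least one merged ROI base, optionally after padding the
#' targets.
#'
#' @param records a `panel_alignments` data.frame (from [read_alignments()]
#'   or [alignment_records()]).
#' @param roi a [roi()] object.
#' @param filter a [read_filter()]; the default excludes duplicate,
#'   secondary, supplementary and QC-fail records.
#' @param padding bases added on each side of the merged targets for the
#'   on-target test only (depth is always computed on the unpadded ROI).
#' @return list with elements
#'   \describe{
#'     \item{profile}{a `depth_profile`: `per_region` (one integer vector
#'       per listed region, in region order) and `merged` (one integer
#'       vector per merged interval); bases listed twice in the design
#'       contribute once to `merged`}
#'     \item{counts}{a `read_counts` list: `total_records`,
#'       `mapped_retained`, `on_target`}
#'   }
#' @export
compute_depth <- function(records, roi, filter = read_filter(), padding = 0L) {
  stopifnot(inherits(roi, "roi"))
  keep <- apply_filter(records, filter)
  kept <- records[keep, , drop = FALSE]
  merged <- roi$merged
  roi_chroms <- unique(merged$chrom)
  miss <- setdiff(roi_chroms, unique(records$chrom[!records$unmapped]))
  if (length(miss) && nrow(records))
    warnf("ROI chromosome(s) absent from alignments: %s (depth 0 there)",
          paste(miss, collapse = ", "))

  blocks <- cigar_ref_blocks(kept$cigar, kept$start)
  blocks$chrom <- kept$chrom[blocks$read]

  merged_depth <- vector("list", nrow(merged))
  for (i in seq_len(nrow(merged))) {
    s <- merged$start[i]; e <- merged$end[i]; len <- e - s
    b <- blocks[blocks$chrom == merged$chrom[i] & blocks$start < e &
                  blocks$end > s, , drop = FALSE]
    delta <- integer(len + 1L)
    if (nrow(b)) {
      bs <- pmax(b$start, s) - s + 1L   # first covered 1-based index
      be <- pmin(b$end, e) - s + 1L     # one past last covered index
      # ends clipped to the interval end land at len+1 and never
      # decrement inside the interval
      delta <- tabulate(bs, nbins = len + 1L) - tabulate(be, nbins = len + 1L)
    }
    merged_depth[[i]] <- cumsum(delta)[seq_len(len)]
  }

  # each listed region lies inside exactly one merged interval: slice it
  per_region <- vector("list", nrow(roi$regions))
  for (j in seq_len(nrow(roi$regions))) {
    r <- roi$regions[j, ]
    i <- which(merged$chrom == r$chrom & merged$start <= r$start &
                 merged$end >= r$end)[1]
    off <- r$start - merged$start[i]
    per_region[[j]] <- merged_depth[[i]][(off + 1L):(off + r$length)]
  }

  # on-target: aligned span (first to last covering block) vs padded targets
  on_target <- 0L
  if (nrow(kept)) {
    span_s <- tapply(blocks$start, factor(blocks$read, levels = seq_len(nrow(kept))),
                     min)
    span_e <- tapply(blocks$end, factor(blocks$read, levels = seq_len(nrow(kept))),
                     max)
    hit <- logical(nrow(kept))
    for (i in seq_len(nrow(merged))) {
      s <- merged$start[i] - padding; e <- merged$end[i] + padding
      idx <- which(kept$chrom == merged$chrom[i])
      hit[idx] <- hit[idx] | (!is.na(span_s[idx]) & span_s[idx] < e &
                                span_e[idx] > s)
    }
    on_target <- sum(hit)
  }

  profile <- structure(list(per_region = per_region, merged = merged_depth,
                            regions = roi$regions,
                            merged_intervals = merged),
                       class = "depth_profile")
  counts <- structure(list(total_records = nrow(records),
                           mapped_retained = nrow(kept),
                           on_target = on_target),
                      class = "read_counts")
  list(profile = profile, counts = counts)
}

#' Build a depth profile from known per-region depth vectors
#'
#' Constructs the same `depth_profile` object that [compute_depth()]
#' returns, from externally supplied depths (e.g. parsed per-sample
#' reports, or fixture manifests). Overlapping regions are not supported
#' here: the ROI must already be disjoint.
#'
#' @param roi a [roi()] object with disjoint regions.
#' @param depths either a single integer (uniform depth), a vector of one
#'   depth per region, or a list of full per-base vectors per region.
#' @return a `depth_profile`.
#' @export
profile_from_depths <- function(roi, depths) {
  stopifnot(inherits(roi, "roi"))
  n <- nrow(roi$regions)
  if (roi$merged_bases != sum(roi$regions$length))
    stopf("profile_from_depths requires a ROI with disjoint regions")
  if (is.list(depths)) {
    stopifnot(length(depths) == n)
    per_region <- lapply(seq_len(n), function(j) {
      v <- as.integer(depths[[j]])
      if (length(v) != roi$regions$length[j])
        stopf("depth vector %d has length %d, region has %d bases",
              j, length(v), roi$regions$length[j])
      v
    })
  } else {
    d <- rep_len(as.integer(depths), n)
    per_region <- lapply(seq_len(n), function(j)
      rep(d[j], roi$regions$length[j]))
  }
  # project region depths onto merged intervals (disjoint => concatenation)
  merged <- roi$merged
  merged_depth <- vector("list", nrow(merged))
  for (i in seq_len(nrow(merged))) {
    len <- merged$end[i] - merged$start[i]
    v <- integer(len)
    inside <- which(roi$regions$chrom == merged$chrom[i] &
                      roi$regions$start >= merged$start[i] &
                      roi$regions$end <= merged$end[i])
    for (j in inside) {
      off <- roi$regions$start[j] - merged$start[i]
      v[(off + 1L):(off + roi$regions$length[j])] <- per_region[[j]]
    }
    merged_depth[[i]] <- v
  }
  structure(list(per_region = per_region, merged = merged_depth,
                 regions = roi$regions, merged_intervals = merged),
            class = "depth_profile")
}

#' Extract the merged per-base depth vector from a profile
#'
#' @param profile a `depth_profile`.
#' @return integer vector over all unique targeted bases, in merged
#'   interval order.
#' @export
merged_depths <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  unlist(profile$merged, use.names = FALSE) %||% integer()
}

#' Tabulate flag-category counts over alignment records
#'
#' @param records a `panel_alignments` data.frame.
#' @return data.frame with columns `category`, `count` covering total,
#'   mapped, unmapped, duplicates, secondary, supplementary and QC-fail
#'   records.
#' @export
mapping_stats <- function(records) {
  data.frame(
    category = c("total", "mapped", "unmapped", "duplicates", "secondary",
                 "supplementary", "qc_fail"),
    count = c(nrow(records), sum(!records$unmapped), sum(records$unmapped),
              sum(records$duplicate), sum(records$secondary),
              sum(records$supplementary), sum(records$qc_fail)),
    stringsAsFactors = FALSE)
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("depth profile: %d region(s), %d merged base(s), mean depth %.2f\n",
              length(x$per_region), length(merged_depths(x)),
              mean(merged_depths(x))))
  invisible(x)
}
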