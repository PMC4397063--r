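#' Generate a synthetic multi-gene target design
#'
#' Lays out `n_genes * exons_per_gene` disjoint exons along a single
#' synthetic chromosome, separated by `spacing` bases. Exon lengths are
#' either fixed (`exon_length`) or derived from `total_bases` by even
#' division (the remainder distributed one base at a time over the last
#' exons), so the merged target hits the requested cumulative size
#' exactly. The default shape mirrors a realistic small diagnostic panel:
#' 18 genes, 360 exons, 157 kb of unique target.
#'
#' @param n_genes,exons_per_gene panel shape (each >= 1).
#' @param exon_length fixed exon length, or `NULL` to size from
#'   `total_bases`.
#' @param spacing gap between consecutive exons (>= 1; overlapping
#'   placement is refused).
#' @param total_bases cumulative target size when `exon_length` is `NULL`.
#' @param chrom chromosome name used for the design.
#' @param bed_path optional path: write the design as BED.
#' @return a [roi()] object (deterministic: no randomness involved).
#' @export
generate_roi <- function(n_genes = 18L, exons_per_gene = 20L,
                         exon_length = NULL, spacing = 1000L,
                         total_bases = 157000L, chrom = "chr1",
                         bed_path = NULL) {
  if (n_genes < 1 || exons_per_gene < 1 || spacing < 1)
    stopf("n_genes, exons_per_gene and spacing must all be >= 1 (overlapping placement is not supported)")
  n <- n_genes * exons_per_gene
  if (is.null(exon_length)) {
    base <- total_bases %/% n
    rem <- total_bases %% n
    if (base < 1) stopf("total_bases too small for %d exons", n)
    lens <- rep(base, n)
    if (rem > 0) lens[(n - rem + 1L):n] <- base + 1L
  } else {
    if (exon_length < 1) stopf("exon_length must be >= 1")
    lens <- rep(as.integer(exon_length), n)
  }
  starts <- spacing + c(0L, cumsum(lens + spacing))[seq_len(n)]
  gene <- rep(sprintf("GENE%02d", seq_len(n_genes)), each = exons_per_gene)
  exon <- rep(sprintf("ex%d", seq_len(exons_per_gene)), times = n_genes)
  out <- roi(data.frame(chrom = chrom, start = starts, end = starts + lens,
                        gene = gene, exon_label = exon,
                        stringsAsFactors = FALSE))
  if (!is.null(bed_path)) write_bed(out, bed_path)
  out
}

# write records as a coordinate-sorted SAM file with minimal valid header
write_sam <- function(records, seqlengths, path) {
  ord <- order(match(records$chrom, names(seqlengths)), records$start)
  r <- records[ord, , drop = FALSE]
  flag <- 4L * r$unmapped + 256L * r$secondary + 512L * r$qc_fail +
    1024L * r$duplicate + 2048L * r$supplementary
  rlen <- vapply(regmatches(r$cigar, gregexpr("\\d+(?=[MIS=X])", r$cigar,
                                              perl = TRUE)),
                 function(x) sum(as.integer(x)), 0L)
  seq <- strrep("A", pmax(rlen, 1L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                       as.integer(seqlengths))), con)
  if (nrow(r))
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                       r$qname, flag, r$chrom, r$start + 1L, r$mapq, r$cigar,
                       seq), con)
  invisible(path)
}

#' Generate a synthetic alignment fixture with known ground truth
#'
#' Tiles `depth` layers of single-end reads over every region: within each
#' layer, reads of `read_length` bases are laid end to end from the region
#' start, the last read running into the inter-region gap, so every
#' targeted base of the region receives exactly `depth` retained reads.
#' Off-target reads are placed on a dedicated decoy chromosome so on-target
#' counting is unambiguous, and duplicate-flagged copies of retained reads
#' are added at `duplicate_fraction` (excluded by the default
#' [read_filter()], hence depth-neutral).
#'
#' The returned manifest is computed arithmetically from the construction,
#' independent of the coverage engine, and records the expected read
#' counts, per-region depths and headline metrics.
#'
#' @param roi a [roi()] object with disjoint regions (see [generate_roi()]);
#'   inter-region spacing must be at least `read_length` so overhanging
#'   tile reads cannot touch a neighbouring region.
#' @param depth target depth per region: scalar or one value per region.
#' @param read_length read length in bases (must not exceed any region
#'   length).
#' @param off_target_fraction fraction of retained reads that are
#'   off-target, achieved within one read by rounding.
#' @param duplicate_fraction fraction of duplicate-flagged copies added,
#'   relative to the retained read count.
#' @param seed RNG seed for off-target placement and duplicate choice.
#' @param sam_path optional path: write the fixture as coordinate-sorted SAM.
#' @param cfg [metrics_config()] used for the manifest's expected metrics.
#' @return list with `records` (a `panel_alignments` data.frame),
#'   `seqlengths`, `sam` (path or `NULL`) and `manifest` (list:
#'   `read_counts`, `per_region_depth`, `metrics`).
#' @export
generate_alignments <- function(roi, depth = 30L, read_length = 150L,
                                off_target_fraction = 0,
                                duplicate_fraction = 0, seed = 1L,
                                sam_path = NULL, cfg = metrics_config()) {
  stopifnot(inherits(roi, "roi"))
  regions <- roi$regions
  n <- nrow(regions)
  if (n == 0) stopf("ROI has no regions")
  depth <- rep_len(as.integer(depth), n)
  if (any(depth < 0)) stopf("depths must be >= 0")
  if (off_target_fraction < 0 || off_target_fraction >= 1 ||
      duplicate_fraction < 0 || duplicate_fraction >= 1)
    stopf("fractions must be in [0, 1)")
  if (read_length < 1) stopf("read_length must be >= 1")
  if (any(read_length > regions$length))
    stopf("read length (%d) exceeds a region length (%d): region cannot reach the requested interior depth",
          read_length, min(regions$length))
  gaps <- diff(regions$start) - regions$length[-n]
  if (n > 1 && any(gaps < read_length & gaps >= 0))
    stopf("inter-region spacing must be >= read_length to keep tile overhang off neighbouring regions")

  # on-target layers: every region base covered exactly `depth` times
  starts <- integer(); chroms <- character()
  for (j in seq_len(n)) {
    if (depth[j] == 0) next
    tiles <- regions$start[j] + read_length * (0:(ceiling(regions$length[j] /
                                                            read_length) - 1L))
    starts <- c(starts, rep(tiles, times = depth[j]))
    chroms <- c(chroms, rep(regions$chrom[j], length(tiles) * depth[j]))
  }
  n_on <- length(starts)

  with_seed(seed, {
    n_off <- round(off_target_fraction / (1 - off_target_fraction) * n_on)
    decoy_len <- 1000000L
    if (n_off > 0) {
      off_starts <- sample.int(decoy_len - read_length, n_off, replace = TRUE)
      starts <- c(starts, off_starts)
      chroms <- c(chroms, rep("chrU", n_off))
    }
    n_retained <- n_on + n_off
    rec <- alignment_records(chrom = chroms, start = starts,
                             cigar = rep(sprintf("%dM", read_length),
                                         n_retained),
                             qname = sprintf("r%07d", seq_len(n_retained)))
    n_dup <- round(duplicate_fraction * n_retained)
    if (n_dup > 0) {
      pick <- sample.int(n_retained, n_dup, replace = n_dup > n_retained)
      dup <- rec[pick, , drop = FALSE]
      dup$duplicate <- TRUE
      dup$qname <- sprintf("%s.dup", dup$qname)
      rec <- rbind(rec, dup)
      class(rec) <- c("panel_alignments", "data.frame")
    }
  })

  seqlengths <- vapply(split(regions$end, regions$chrom), max, 0L) +
    read_length + 1000L
  if (any(rec$chrom == "chrU")) seqlengths <- c(seqlengths, chrU = 1000000L)

  sam <- NULL
  if (!is.null(sam_path)) sam <- write_sam(rec, seqlengths, sam_path)

  # ---- manifest: expected values by construction ----
  lens <- regions$length
  total_b <- sum(lens)                      # regions are disjoint
  mu <- sum(as.numeric(lens) * depth) / total_b
  cmp <- function(d, cut) if (cfg$comparator == "at-least") d >= cut else d > cut
  pct_ge_T <- 100 * sum(lens[cmp(depth, cfg$depth_threshold)]) / total_b
  stability <- if (mu == 0) 0 else
    100 * sum(lens[cmp(depth, cfg$stability_factor * mu)]) / total_b
  manifest <- list(
    read_counts = list(total_records = nrow(rec),
                       mapped_retained = n_retained, on_target = n_on),
    per_region_depth = lapply(seq_len(n), function(j) rep(depth[j], lens[j])),
    metrics = list(
      mean_base_coverage = mu,
      pct_bases_ge_T = if (mu == 0) 0 else pct_ge_T,
      stability_pct = stability,
      pct_on_target = if (n_retained > 0) 100 * n_on / n_retained else NA_real_,
      off_target_fraction_realized = if (n_retained > 0) n_off / n_retained
        else NA_real_))
  list(records = rec, seqlengths = seqlengths, sam = sam, manifest = manifest)
}

#' Write a synthetic reference FASTA matching a fixture's chromosomes
#'
#' Sequences are arbitrary (all `A`); the file exists so that SAM headers
#' produced by [generate_alignments()] refer to a resolvable reference.
#'
#' @param seqlengths named vector of chromosome lengths.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(seqlengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(seqlengths)) {
    writeLines(sprintf(">%s synthetic", chr), con)
    remaining <- as.integer(seqlengths[[chr]])
    while (remaining > 0) {
      w <- min(80L, remaining)
      writeLines(strrep("A", w), con)
      remaining <- remaining - w
    }
  }
  invisible(path)
}

#' Generate paired NGS/array genotype fixtures with planted discordance
#'
#' Draws true genotypes at `n_sites` synthetic SNP positions for
#' `n_samples` samples, then plants exactly `round(missing_rate * n_pairs)`
#' missing NGS calls and `round(discordance_rate * n_pairs)` discordant
#' NGS calls among the remainder. The expected per-site concordance table
#' is recorded in the manifest by construction. Sites are placed on the
#' plus strand so the array table needs no harmonization.
#'
#' @param n_sites,n_samples fixture shape (defaults mirror a typical
#'   panel-vs-array comparison: 17 sites, 30 samples).
#' @param discordance_rate,missing_rate rates in [0, 1], summing to <= 1.
#' @param seed RNG seed.
#' @param dir optional directory: write `ngs_genotypes.tsv` (long) and
#'   `array_genotypes.tsv` (site-by-sample, [read_array_genotypes()]
#'   dialect).
#' @return list with `ngs`, `array` (`genotype_calls` tables), `sites`,
#'   `manifest` (expected per-site `concordant`/`compared`/`missing`) and
#'   file `paths` when `dir` is given.
#' @export
generate_genotypes <- function(n_sites = 17L, n_samples = 30L,
                               discordance_rate = 0, missing_rate = 0,
                               seed = 1L, dir = NULL) {
  if (discordance_rate < 0 || missing_rate < 0 ||
      discordance_rate + missing_rate > 1)
    stopf("rates must be >= 0 and sum to <= 1")
  alleles <- c("A", "C", "G", "T")
  with_seed(seed, {
    sites <- data.frame(
      chrom = sprintf("chr%d", sort(sample.int(22L, n_sites, replace = TRUE))),
      pos = sample.int(2e8L, n_sites),
      rsid = sprintf("rs%06d", sample.int(999999L, n_sites)),
      stringsAsFactors = FALSE)
    sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
    key <- paste(sites$chrom, sites$pos)
    while (anyDuplicated(key)) {          # vanishing probability, but exact
      sites$pos <- sites$pos + cumsum(duplicated(key))
      key <- paste(sites$chrom, sites$pos)
    }
    samples <- sprintf("S%02d", seq_len(n_samples))
    grid <- expand.grid(si = seq_len(n_sites), sa = seq_len(n_samples))
    truth1 <- sample(alleles, nrow(grid), replace = TRUE)
    truth2 <- sample(alleles, nrow(grid), replace = TRUE)
    n_pairs <- nrow(grid)
    n_miss <- round(missing_rate * n_pairs)
    n_disc <- round(discordance_rate * n_pairs)
    pick <- sample.int(n_pairs, n_miss + n_disc)
    miss_idx <- pick[seq_len(n_miss)]
    disc_idx <- setdiff(pick, miss_idx)
    ngs1 <- truth1; ngs2 <- truth2
    for (i in disc_idx) {                 # flip to a different unordered pair
      repeat {
        c1 <- sample(alleles, 1); c2 <- sample(alleles, 1)
        if (paste(min(c1, c2), max(c1, c2)) !=
            paste(min(truth1[i], truth2[i]), max(truth1[i], truth2[i]))) break
      }
      ngs1[i] <- c1; ngs2[i] <- c2
    }
    ngs1[miss_idx] <- NA_character_; ngs2[miss_idx] <- NA_character_
  })
  ngs <- genotype_calls(samples[grid$sa], sites$chrom[grid$si],
                        sites$pos[grid$si], ngs1, ngs2,
                        rsid = sites$rsid[grid$si])
  array <- genotype_calls(samples[grid$sa], sites$chrom[grid$si],
                          sites$pos[grid$si], truth1, truth2,
                          rsid = sites$rsid[grid$si])
  miss_site <- tabulate(grid$si[miss_idx], nbins = n_sites)
  disc_site <- tabulate(grid$si[disc_idx], nbins = n_sites)
  manifest <- data.frame(sites,
                         compared = n_samples - miss_site,
                         concordant = n_samples - miss_site - disc_site,
                         missing = miss_site, stringsAsFactors = FALSE)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ngs_path <- file.path(dir, "ngs_genotypes.tsv")
    utils::write.table(ngs, ngs_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    wide <- data.frame(sites, strand = "+", stringsAsFactors = FALSE)
    for (k in seq_len(n_samples)) {
      idx <- (k - 1L) * n_sites + seq_len(n_sites)  # expand.grid: site fastest
      g <- ifelse(is.na(truth1[idx]), "--", paste0(truth1[idx], truth2[idx]))
      wide[[samples[k]]] <- g
    }
    array_path <- file.path(dir, "array_genotypes.tsv")
    utils::write.table(wide, array_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- list(ngs = ngs_path, array = array_path)
  }
  list(ngs = ngs, array = array, sites = sites, manifest = manifest,
       paths = paths)
}
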