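# Independent brute-force oracles. These deliberately avoid the package's
# computation paths: depth is counted by enumerating every covered base,
# CIGARs are walked character by character, filtering is a single inlined
# boolean expression.

# walk a CIGAR string one token at a time; returns covered (start, end)
# reference blocks, 0-based half-open
oracle_cigar_blocks <- function(cigar, start) {
  blocks <- list()
  num <- 0L
  pos <- start
  for (ch in strsplit(cigar, "")[[1]]) {
    if (ch %in% as.character(0:9)) {
      num <- num * 10L + as.integer(ch)
    } else {
      if (ch %in% c("M", "=", "X")) {
        if (num > 0) blocks[[length(blocks) + 1L]] <- c(pos, pos + num)
        pos <- pos + num
      } else if (ch %in% c("D", "N")) {
        pos <- pos + num
      }
      num <- 0L
    }
  }
  blocks
}

oracle_retained <- function(rec, f) {
  !rec$unmapped & rec$mapq >= f$min_mapq &
    !(f$exclude_duplicates & rec$duplicate) &
    !(f$exclude_secondary & rec$secondary) &
    !(f$exclude_supplementary & rec$supplementary) &
    !(f$exclude_qc_fail & rec$qc_fail)
}

# per-base depth over each listed region by exhaustive base enumeration
oracle_region_depths <- function(rec, roi_obj, f = read_filter()) {
  keep <- which(oracle_retained(rec, f))
  cov <- list()  # chrom -> integer positions covered (with multiplicity)
  for (i in keep) {
    for (b in oracle_cigar_blocks(rec$cigar[i], rec$start[i])) {
      if (b[2] > b[1]) {
        chr <- rec$chrom[i]
        cov[[chr]] <- c(cov[[chr]], b[1]:(b[2] - 1L))
      }
    }
  }
  tabs <- lapply(cov, function(p) table(p))
  lapply(seq_len(nrow(roi_obj$regions)), function(j) {
    r <- roi_obj$regions[j, ]
    bases <- r$start:(r$end - 1L)
    tb <- tabs[[r$chrom]]
    d <- integer(length(bases))
    hit <- match(as.character(bases), names(tb))
    d[!is.na(hit)] <- as.integer(tb[hit[!is.na(hit)]])
    d
  })
}

# distinct covered bases of a set of intervals, by explicit base sets
oracle_union_bases <- function(df) {
  length(unique(paste(rep(df$chrom, df$end - df$start),
                      unlist(Map(function(s, e) s:(e - 1L),
                                 df$start, df$end)))))
}

# a small random alignment fixture over a random ROI (for oracle tests)
random_engine_fixture <- function(n_reads = 200, n_regions = 4,
                                  max_base = 3000) {
  starts <- sort(sample.int(max_base, n_regions))
  lens <- sample(20:120, n_regions, replace = TRUE)
  r <- roi(data.frame(chrom = sample(c("chr1", "chr2"), n_regions,
                                     replace = TRUE),
                      start = starts, end = starts + lens,
                      gene = sprintf("G%d", seq_len(n_regions)),
                      exon_label = "ex1"))
  cigars <- vapply(seq_len(n_reads), function(i) {
    n1 <- sample(10:60, 1)
    switch(sample(3, 1),
           sprintf("%dM", n1),
           sprintf("%dM%dD%dM", n1, sample(1:10, 1), sample(5:30, 1)),
           sprintf("%dS%dM%dI%dM", sample(1:8, 1), n1, sample(1:5, 1),
                   sample(5:30, 1)))
  }, "")
  rec <- alignment_records(
    chrom = sample(c("chr1", "chr2"), n_reads, replace = TRUE),
    start = sample.int(max_base + 200, n_reads) - 1L,
    cigar = cigars,
    mapq = sample(c(0L, 10L, 30L, 60L), n_reads, replace = TRUE),
    unmapped = runif(n_reads) < 0.05,
    secondary = runif(n_reads) < 0.1,
    supplementary = runif(n_reads) < 0.05,
    duplicate = runif(n_reads) < 0.15,
    qc_fail = runif(n_reads) < 0.05)
  list(roi = r, records = rec)
}
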