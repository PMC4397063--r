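test_that("apply_filter matches the exhaustively enumerated truth table", {
  flags <- expand.grid(unmapped = c(FALSE, TRUE), secondary = c(FALSE, TRUE),
                       supplementary = c(FALSE, TRUE),
                       duplicate = c(FALSE, TRUE), qc_fail = c(FALSE, TRUE),
                       mapq = c(0L, 20L))
  rec <- alignment_records(chrom = "chr1", start = 0L, cigar = "50M",
                           mapq = flags$mapq, unmapped = flags$unmapped,
                           secondary = flags$secondary,
                           supplementary = flags$supplementary,
                           duplicate = flags$duplicate,
                           qc_fail = flags$qc_fail)
  for (f in list(read_filter(),
                 read_filter(min_mapq = 10),
                 read_filter(exclude_duplicates = FALSE,
                             exclude_secondary = FALSE),
                 read_filter(exclude_supplementary = FALSE,
                             exclude_qc_fail = FALSE, min_mapq = 30))) {
    expect_equal(apply_filter(rec, f), oracle_retained(rec, f))
  }
  # unmapped records are always dropped
  expect_false(any(apply_filter(rec, read_filter(
    exclude_duplicates = FALSE, exclude_secondary = FALSE,
    exclude_supplementary = FALSE, exclude_qc_fail = FALSE))[flags$unmapped]))
})

test_that("compute_depth handles trivial inputs", {
  r <- roi(data.frame(chrom = "chr1", start = 100, end = 110, gene = "G"))
  none <- alignment_records(character(), integer(), character())
  res <- compute_depth(none, r)
  expect_equal(merged_depths(res$profile), rep(0L, 10))
  expect_equal(unclass(res$counts),
               list(total_records = 0L, mapped_retained = 0L,
                    on_target = 0L))
  one <- alignment_records("chr1", 100L, "10M")
  res <- compute_depth(one, r)
  expect_equal(merged_depths(res$profile), rep(1L, 10))
  expect_equal(res$counts$on_target, 1L)
})

test_that("depths equal the brute-force per-base oracle on random fixtures", {
  set.seed(202)
  for (rep in 1:5) {
    fx <- random_engine_fixture(n_reads = 200)
    res <- suppressWarnings(compute_depth(fx$records, fx$roi))
    expect_equal(res$profile$per_region,
                 oracle_region_depths(fx$records, fx$roi))
  }
})

test_that("depth is additive over record sets and monotone in the filter", {
  set.seed(303)
  fx <- random_engine_fixture(n_reads = 160)
  half <- fx$records[1:80, ]; rest <- fx$records[81:160, ]
  class(half) <- class(rest) <- class(fx$records)
  d_all <- suppressWarnings(compute_depth(fx$records, fx$roi))
  d1 <- suppressWarnings(compute_depth(half, fx$roi))
  d2 <- suppressWarnings(compute_depth(rest, fx$roi))
  expect_equal(merged_depths(d_all$profile),
               merged_depths(d1$profile) + merged_depths(d2$profile))

  loose <- read_filter(exclude_duplicates = FALSE, exclude_secondary = FALSE,
                       exclude_supplementary = FALSE,
                       exclude_qc_fail = FALSE, min_mapq = 0)
  d_loose <- suppressWarnings(compute_depth(fx$records, fx$roi, loose))
  for (tight in list(read_filter(), read_filter(min_mapq = 30),
                     read_filter(min_mapq = 60))) {
    d_tight <- suppressWarnings(compute_depth(fx$records, fx$roi, tight))
    expect_true(all(merged_depths(d_tight$profile) <=
                      merged_depths(d_loose$profile)))
    expect_lte(d_tight$counts$on_target, d_loose$counts$on_target)
  }
})

test_that("deletions and clips do not add depth; on-target uses the span", {
  r <- roi(data.frame(chrom = "chr1", start = 100, end = 120, gene = "G"))
  # 5M10D5M starting at 95: covers 95-99 and 110-114; deletion gap 100-109
  rec <- alignment_records("chr1", 95L, "5M10D5M")
  res <- compute_depth(rec, r)
  d <- merged_depths(res$profile)
  expect_equal(d, c(rep(0L, 10), rep(1L, 5), rep(0L, 5)))
  expect_equal(res$counts$on_target, 1L)
  # soft clip consumes no reference: 10S5M at 200 covers 200-204 (off ROI)
  rec <- alignment_records("chr1", 200L, "10S5M")
  res <- compute_depth(rec, r)
  expect_equal(sum(merged_depths(res$profile)), 0L)
  expect_equal(res$counts$on_target, 0L)
  # padding brings a near-miss read on target without changing depth
  res_pad <- compute_depth(rec, r, padding = 100L)
  expect_equal(res_pad$counts$on_target, 1L)
  expect_equal(sum(merged_depths(res_pad$profile)), 0L)
})

test_that("SAM round-trip preserves records, flags and depths", {
  r <- generate_roi(2, 2, exon_length = 120, spacing = 400)
  fx <- generate_alignments(r, depth = 5, read_length = 60,
                            off_target_fraction = 0.2,
                            duplicate_fraction = 0.1, seed = 9,
                            sam_path = withr::local_tempfile(fileext = ".sam"))
  rec <- read_alignments(fx$sam)
  expect_equal(nrow(rec), nrow(fx$records))
  expect_equal(sum(rec$duplicate), sum(fx$records$duplicate))
  res_file <- compute_depth(rec, r)
  res_mem <- compute_depth(fx$records, r)
  expect_equal(res_file$profile$per_region, res_mem$profile$per_region)
  expect_equal(unclass(res_file$counts), unclass(res_mem$counts))
})

test_that("mapping_stats recounts every flag category", {
  set.seed(404)
  fx <- random_engine_fixture(n_reads = 120)
  st <- mapping_stats(fx$records)
  get <- function(k) st$count[st$category == k]
  expect_equal(get("total"), 120)
  expect_equal(get("mapped"), sum(!fx$records$unmapped))
  expect_equal(get("duplicates"), sum(fx$records$duplicate))
  expect_equal(get("secondary"), sum(fx$records$secondary))
  expect_equal(get("supplementary"), sum(fx$records$supplementary))
  expect_lte(get("mapped"), get("total"))

  all_un <- alignment_records(rep("chr1", 10), 0L, "*", unmapped = TRUE)
  st <- mapping_stats(all_un)
  expect_equal(st$count[st$category == "mapped"], 0)
})
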