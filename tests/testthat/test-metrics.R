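uniform_profile <- function(depths_per_region, lens = NULL) {
  n <- length(depths_per_region)
  lens <- lens %||% rep(100L, n)
  starts <- cumsum(c(1000L, head(lens, -1) + 1000L))
  r <- roi(data.frame(chrom = "chr1", start = starts, end = starts + lens,
                      gene = sprintf("G%d", seq_len(n))))
  profile_from_depths(r, depths_per_region)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("summarize_coverage computes the headline metrics", {
  p <- uniform_profile(50L)
  s <- summarize_coverage(p, cfg = metrics_config(30, 0.2))
  expect_equal(s$mean_base_coverage, 50)
  expect_equal(s$pct_bases_ge_T, 100)
  expect_equal(s$stability_pct, 100)

  # 100 bases at 10 and 100 at 100: mu = 55, both cut percentages = 50
  p <- uniform_profile(c(10L, 100L))
  s <- summarize_coverage(p, cfg = metrics_config(30, 0.2))
  expect_equal(s$mean_base_coverage, 55)
  expect_equal(s$pct_bases_ge_T, 50)     # only the 100x half reaches 30
  expect_equal(s$stability_pct, 50)      # 0.2 * 55 = 11 > 10
  expect_equal(s$per_exon_mean, c(10, 100))

  # degenerate sample: all zero
  p <- uniform_profile(0L)
  expect_warning(s <- summarize_coverage(p), "zero mean")
  expect_equal(s$mean_base_coverage, 0)
  expect_equal(s$pct_bases_ge_T, 0)
  expect_equal(s$stability_pct, 0)
})

test_that("on-target percentage derives from retained reads", {
  p <- uniform_profile(10L)
  counts <- list(total_records = 120L, mapped_retained = 100L,
                 on_target = 76L)
  s <- summarize_coverage(p, counts)
  expect_equal(s$pct_on_target, 76)
  counts$mapped_retained <- 0L; counts$on_target <- 0L
  s <- summarize_coverage(p, counts)
  expect_true(is.na(s$pct_on_target))
})

test_that("cumulative curve matches a brute-force recount and anchors", {
  set.seed(11)
  lens <- c(60L, 140L, 80L)
  depths <- lapply(lens, function(l) sample(0:200, l, replace = TRUE))
  starts <- cumsum(c(100L, head(lens, -1) + 500L))
  r <- roi(data.frame(chrom = "chr1", start = starts, end = starts + lens,
                      gene = c("A", "B", "C")))
  p <- profile_from_depths(r, depths)
  grid <- seq(0, 2, by = 0.05)
  curve <- cumulative_normalized_curve(p, grid)
  d <- unlist(depths); mu <- mean(d)
  for (i in seq_along(grid))
    expect_equal(curve$pct[i], 100 * sum(d >= grid[i] * mu) / length(d))
  expect_equal(curve$pct[1], 100)                 # x = 0
  expect_true(all(diff(curve$pct) <= 0))          # non-increasing
  # stability always equals the curve at x = stability_factor
  s <- summarize_coverage(p, cfg = metrics_config(30, 0.2))
  expect_equal(s$stability_pct, curve$pct[curve$x == 0.2])
})

test_that("mean coverage conserves total aligned overlap with the ROI", {
  set.seed(22)
  fx <- random_engine_fixture(n_reads = 150)
  res <- suppressWarnings(compute_depth(fx$records, fx$roi))
  s <- summarize_coverage(res$profile, res$counts)
  # independent overlap total from the oracle depths
  total_overlap <- sum(unlist(oracle_region_depths(fx$records, fx$roi))[
    !duplicated(unlist(Map(function(j) {
      r <- fx$roi$regions[j, ]
      paste(r$chrom, r$start:(r$end - 1L))
    }, seq_len(nrow(fx$roi$regions)))))])
  expect_equal(s$mean_base_coverage, total_overlap / fx$roi$merged_bases)
})

test_that("aggregate_pools computes per-pool mean and n-1 standard deviation", {
  mk <- function(id, cov) {
    p <- uniform_profile(as.integer(cov))
    s <- summarize_coverage(p, list(total_records = 100L,
                                    mapped_retained = 100L,
                                    on_target = 75L), sample_id = id)
    s
  }
  vals <- c(550, 560, 540, 562)
  summaries <- Map(mk, sprintf("s%d", 1:5), c(vals, 300))
  assign <- data.frame(sample_id = sprintf("s%d", 1:5),
                       pool = c(rep("A", 4), "B"))
  agg <- aggregate_pools(summaries, assign)
  a <- agg[agg$pool == "A", ]
  expect_equal(a$n, 4)
  expect_equal(a$mean_base_coverage_mean, 553)
  # hand computation: sqrt((9 + 49 + 169 + 81) / 3)
  expect_equal(a$mean_base_coverage_sd, sqrt(308 / 3))
  expect_equal(round(a$mean_base_coverage_sd, 2), 10.13)
  # single-sample pool: mean is the value, SD omitted
  b <- agg[agg$pool == "B", ]
  expect_equal(b$mean_base_coverage_mean, 300)
  expect_true(is.na(b$mean_base_coverage_sd))
  # Total pools all samples and lies between pool means
  tot <- agg[agg$pool == "Total", ]
  expect_equal(tot$n, 5)
  expect_gte(tot$mean_base_coverage_mean, b$mean_base_coverage_mean)
  expect_lte(tot$mean_base_coverage_mean, a$mean_base_coverage_mean)
  # permutation invariance
  agg2 <- aggregate_pools(summaries[c(3, 5, 1, 4, 2)], assign)
  expect_equal(agg2[order(agg2$pool), ], agg[order(agg$pool), ],
               ignore_attr = TRUE)
  # unknown sample is an error naming it
  expect_error(aggregate_pools(summaries, assign[-2, ]), "s2")
})

test_that("index_distribution converts counts to within-pool percentages", {
  rc <- data.frame(sample_id = sprintf("s%d", 1:4), reads = c(100, 100, 100, 100))
  assign <- data.frame(sample_id = sprintf("s%d", 1:4), pool = "A")
  d <- index_distribution(rc, assign)
  expect_equal(d$samples$pct[d$samples$pool == "A"], rep(25, 4))
  expect_equal(d$pools$uniformity[d$pools$pool == "A"], 0)

  rc$reads <- c(10, 20, 30, 40)
  d <- index_distribution(rc, assign)
  expect_equal(d$samples$pct[d$samples$pool == "A"], c(10, 20, 30, 40))

  set.seed(5)
  rc$reads <- sample.int(1e6, 4)
  assign$pool <- c("A", "A", "B", "B")
  d <- index_distribution(rc, assign)
  for (p in c("A", "B")) {
    g <- d$samples[d$samples$pool == p, ]
    expect_equal(g$pct, 100 * g$reads / sum(g$reads))
    expect_equal(sum(g$pct), 100, tolerance = 1e-9)
  }
  rc$reads <- c(0, 0, 1, 1)
  expect_error(index_distribution(rc, assign), "zero total")
})

test_that("run-budget planner follows the closed-form coverage formula", {
  # nominal MiSeq v2 yield over 96 samples and a 1.6 Mb target gives 30X
  expect_equal(plan_run_budget(4.608e9, 96, 1.6e6), 30)
  expect_equal(plan_run_budget(4.608e9, 48, 1.6e6),
               2 * plan_run_budget(4.608e9, 96, 1.6e6))
  # independent evaluation of the formula with realistic loss fractions
  expect_equal(plan_run_budget(4.5e9, 96, 157e3, 0.766, 0.1),
               4.5e9 * 0.9 * 0.766 / (96 * 157e3))
  expect_error(plan_run_budget(-1, 96, 1.6e6), "positive")
  expect_error(plan_run_budget(4.5e9, 96, 1.6e6, 1.2), "on_target")
})
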