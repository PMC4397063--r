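test_that("shared_sites intersects site lists deterministically", {
  a <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L))
  b <- data.frame(chrom = "chr1", pos = c(40L, 50L))
  expect_equal(nrow(shared_sites(a, b)), 0)
  expect_equal(nrow(shared_sites(a, a)), 3)

  set.seed(7)
  for (rep in 1:10) {
    p1 <- sample.int(200, 40); p2 <- sample.int(200, 40)
    s1 <- data.frame(chrom = "chr2", pos = p1)
    s2 <- data.frame(chrom = "chr2", pos = p2)
    got <- shared_sites(s1, s2)
    expect_equal(sort(got$pos), sort(intersect(p1, p2)))
    expect_false(is.unsorted(got$pos))
  }
  dup <- data.frame(chrom = "chr1", pos = c(10L, 10L))
  expect_error(shared_sites(dup, b), "duplicate")
})

test_that("strand harmonization matches the complement table", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  h <- harmonize_strand("A", "G", "plus")
  expect_equal(c(h$a1, h$a2), c("A", "G"))
  h <- harmonize_strand("A", "G", "minus")
  expect_equal(c(h$a1, h$a2), c("T", "C"))

  # all 10 unordered pairs x 3 strand states against the table oracle
  pairs <- t(combn(c("A", "C", "G", "T"), 2))
  pairs <- rbind(pairs, cbind(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  for (i in seq_len(nrow(pairs))) for (st in c("plus", "minus", "unknown")) {
    a1 <- pairs[i, 1]; a2 <- pairs[i, 2]
    h <- harmonize_strand(a1, a2, st)
    ambiguous <- setequal(c(a1, a2), c(comp[a1], comp[a2]))
    if (st == "plus") {
      expect_equal(c(h$a1, h$a2), c(a1, a2))
    } else if (st == "minus") {
      expect_equal(c(h$a1, h$a2), unname(c(comp[a1], comp[a2])))
    } else if (ambiguous) {
      expect_false(h$comparable)
      expect_true(is.na(h$a1) && is.na(h$a2))
    } else {
      expect_true(h$comparable)
      expect_equal(c(h$a1, h$a2), c(a1, a2))
    }
  }
})

test_that("identical tables are fully concordant; one flip shows up", {
  fx <- generate_genotypes(17, 30, seed = 3)
  ct <- compare_genotypes(fx$ngs, fx$array)
  expect_equal(nrow(ct$per_site), 17)
  expect_equal(ct$per_site$concordant, rep(30L, 17))
  expect_equal(ct$per_site$compared, rep(30L, 17))
  expect_equal(ct$overall$pct, 100)

  ngs2 <- fx$ngs
  i <- which(ngs2$sample_id == "S05" & ngs2$pos == fx$sites$pos[4])
  old <- c(ngs2$a1[i], ngs2$a2[i])
  flip <- setdiff(c("A", "C", "G", "T"), old)[1:2]
  ngs2$a1[i] <- flip[1]; ngs2$a2[i] <- flip[2]
  ct <- compare_genotypes(ngs2, fx$array)
  hit <- ct$per_site$pos == fx$sites$pos[4] &
    ct$per_site$chrom == fx$sites$chrom[4]
  expect_equal(ct$per_site$concordant[hit], 29L)
  expect_equal(ct$per_site$concordant[!hit], rep(30L, 16))
  expect_equal(ct$per_site$discordant_samples[hit], "S05")
})

test_that("planted discordance matches a brute-force pairwise oracle", {
  fx <- generate_genotypes(20, 50, discordance_rate = 0.1,
                           missing_rate = 0.05, seed = 11)
  ct <- compare_genotypes(fx$ngs, fx$array)
  # oracle: direct pairwise comparison of unordered pairs, by row
  norm <- function(t) ifelse(is.na(t$a1), NA,
                             paste(pmin(t$a1, t$a2), pmax(t$a1, t$a2)))
  key <- function(t) paste(t$sample_id, t$chrom, t$pos)
  m <- match(key(fx$ngs), key(fx$array))
  gn <- norm(fx$ngs); ga <- norm(fx$array)[m]
  ok <- !is.na(gn) & !is.na(ga)
  expect_equal(ct$overall$compared, sum(ok))
  expect_equal(ct$overall$concordant, sum(ok & gn == ga))
  # conservation: overall equals the per-site sums
  expect_equal(ct$overall$concordant, sum(ct$per_site$concordant))
  expect_equal(ct$overall$compared, sum(ct$per_site$compared))
  # symmetry of the counts in the two inputs
  ct_rev <- compare_genotypes(fx$array, fx$ngs)
  expect_equal(ct_rev$overall$concordant, ct$overall$concordant)
  expect_equal(ct_rev$overall$compared, ct$overall$compared)
})

test_that("missing calls leave the denominator and are reported apart", {
  ngs <- genotype_calls(c("s1", "s2", "s3"), "chr1", 100L,
                        c("A", NA, "A"), c("G", NA, "A"))
  arr <- genotype_calls(c("s1", "s2", "s3"), "chr1", 100L,
                        c("G", "C", "A"), c("A", "C", "C"))
  ct <- compare_genotypes(ngs, arr)
  expect_equal(ct$per_site$compared, 2L)   # s2 missing on the NGS side
  expect_equal(ct$per_site$concordant, 1L) # s1 unordered-equal, s3 not
  expect_equal(ct$per_site$missing, 1L)
  expect_equal(ct$per_site$discordant_samples, "s3")
})

test_that("hom-ref inference respects the minimum depth rule", {
  ngs <- genotype_calls("s1", "chr1", 100L, "A", "G")
  sites <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                      rsid = c("rs1", "rs2", "rs3"),
                      ref = c("A", "C", "T"))
  depth <- function(s, chrom, pos) if (pos == 200L) 45 else 10
  out <- infer_homref(ngs, sites, "s1", depth, min_depth = 30)
  expect_equal(nrow(out), 3)
  g200 <- out[out$pos == 200L, ]
  expect_equal(c(g200$a1, g200$a2), c("C", "C"))  # covered: hom-ref
  g300 <- out[out$pos == 300L, ]
  expect_true(is.na(g300$a1))                      # under-covered: missing
})

test_that("array TSV and VCF readers feed the comparison", {
  dir <- withr::local_tempdir()
  fx <- generate_genotypes(6, 4, seed = 21, dir = dir)
  arr <- read_array_genotypes(fx$paths$array)
  ct <- compare_genotypes(fx$ngs, arr)
  expect_equal(ct$overall$pct, 100)

  skip_if_not_installed("vcfR")
  vcf <- file.path(dir, "calls.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS01\tS02",
    "chr1\t100\trs1\tA\tG\t50\tPASS\t.\tGT\t0/1\t1/1",
    "chr1\t200\trs2\tC\tT\t50\tPASS\t.\tGT\t0/0\t./.",
    "chr1\t300\trs3\tG\tGA\t50\tPASS\t.\tGT\t0/1\t0/0"), vcf)
  expect_warning(gt <- read_vcf_genotypes(vcf), "non-SNP")
  expect_equal(nrow(gt), 4)  # 2 SNP sites x 2 samples
  s1 <- gt[gt$sample_id == "S01" & gt$pos == 100, ]
  expect_setequal(c(s1$a1, s1$a2), c("A", "G"))
  s2 <- gt[gt$sample_id == "S02" & gt$pos == 200, ]
  expect_true(is.na(s2$a1))
})
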