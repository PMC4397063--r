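#' Build a long-format genotype call table
#'
#' Genotypes are unordered pairs of alleles from {A, C, G, T}; a missing
#' call is an explicit state encoded as `NA` in both allele columns.
#'
#' @param sample_id,chrom,pos,a1,a2 vectors (pos is 1-based).
#' @param rsid optional site identifiers.
#' @return data.frame of class `genotype_calls` with columns `sample_id`,
#'   `chrom`, `pos`, `rsid`, `a1`, `a2`.
#' @export
genotype_calls <- function(sample_id, chrom, pos, a1, a2, rsid = NA_character_) {
  a1 <- toupper(as.character(a1)); a2 <- toupper(as.character(a2))
  ok <- function(a) is.na(a) | a %in% c("A", "C", "G", "T")
  if (!all(ok(a1) & ok(a2)))
    stopf("alleles must be A/C/G/T or missing (NA)")
  if (any(xor(is.na(a1), is.na(a2))))
    stopf("half-missing genotypes are not allowed: set both alleles NA")
  out <- data.frame(sample_id = as.character(sample_id),
                    chrom = as.character(chrom), pos = as.integer(pos),
                    rsid = rep_len(as.character(rsid), length(a1)),
                    a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  class(out) <- c("genotype_calls", "data.frame")
  out
}

#' Sites present in both genotype datasets
#'
#' @param ngs_sites,array_sites data.frames with columns `chrom`, `pos`
#'   (1-based); duplicate positions within one input are an error.
#' @return data.frame of the shared sites, sorted by (chrom, pos).
#' @export
shared_sites <- function(ngs_sites, array_sites) {
  key <- function(s, label) {
    k <- paste(s$chrom, s$pos)
    if (anyDuplicated(k))
      stopf("duplicate site position(s) in %s input: %s", label,
            k[duplicated(k)][1])
    k
  }
  k1 <- key(ngs_sites, "NGS"); k2 <- key(array_sites, "array")
  hit <- ngs_sites[k1 %in% k2, c("chrom", "pos"), drop = FALSE]
  hit <- hit[order(hit$chrom, hit$pos), , drop = FALSE]
  rownames(hit) <- NULL
  hit
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Place array genotypes on the sequencing reference strand
#'
#' Minus-strand genotypes are complemented; plus-strand genotypes pass
#' through. Genotypes with unknown strand whose alleles are
#' strand-ambiguous (A/T or C/G pairs, unchanged under complementation)
#' cannot be harmonized safely and are flagged non-comparable.
#'
#' @param a1,a2 allele vectors (A/C/G/T or NA).
#' @param strand per-genotype annotation: `"plus"`/`"+"`, `"minus"`/`"-"`
#'   or `"unknown"`.
#' @return list with harmonized `a1`, `a2` and logical `comparable`
#'   (FALSE where an unknown-strand ambiguous genotype was dropped to NA).
#' @export
harmonize_strand <- function(a1, a2, strand) {
  strand <- rep_len(as.character(strand), length(a1))
  strand[strand == "+"] <- "plus"; strand[strand == "-"] <- "minus"
  if (!all(strand %in% c("plus", "minus", "unknown")))
    stopf("strand annotation must be plus/minus/unknown")
  minus <- strand == "minus" & !is.na(a1)
  a1[minus] <- COMPLEMENT[a1[minus]]
  a2[minus] <- COMPLEMENT[a2[minus]]
  # ambiguous = the unordered pair maps to itself under complementation
  amb <- !is.na(a1) &
    paste(pmin(a1, a2), pmax(a1, a2)) ==
    paste(pmin(COMPLEMENT[a1], COMPLEMENT[a2]), pmax(COMPLEMENT[a1], COMPLEMENT[a2]))
  drop <- strand == "unknown" & amb
  comparable <- !drop
  a1[drop] <- NA_character_; a2[drop] <- NA_character_
  list(a1 = a1, a2 = a2, comparable = comparable)
}

#' Compare NGS and array genotypes site by site
#'
#' A (sample, site) pair is concordant iff both calls are non-missing and
#' identical as unordered allele pairs. Pairs with a missing call on either
#' side are excluded from the compared denominator and counted separately,
#' so per-site denominators reflect samples genuinely typed by both
#' platforms.
#'
#' @param ngs,array `genotype_calls` tables (see [genotype_calls()]); array
#'   genotypes should already be strand-harmonized
#'   (see [harmonize_strand()] and [read_array_genotypes()]).
#' @return object of class `concordance_table`: list with
#'   \describe{
#'     \item{per_site}{data.frame `chrom`, `pos`, `rsid`, `concordant`,
#'       `compared`, `missing`, `discordant_samples` (comma-separated)}
#'     \item{overall}{list `concordant`, `compared`, `pct`}
#'   }
#' @export
compare_genotypes <- function(ngs, array) {
  for (tb in list(ngs, array)) {
    bad <- !(is.na(tb$a1) | tb$a1 %in% names(COMPLEMENT)) |
      !(is.na(tb$a2) | tb$a2 %in% names(COMPLEMENT))
    if (any(bad)) stopf("allele outside {A,C,G,T,missing} in genotype table")
  }
  gk <- function(tb) paste(tb$sample_id, tb$chrom, tb$pos, sep = "\r")
  m <- match(gk(ngs), gk(array))
  paired <- !is.na(m)
  n <- ngs[paired, , drop = FALSE]
  a <- array[m[paired], , drop = FALSE]
  norm <- function(tb) ifelse(is.na(tb$a1), NA_character_,
                              paste(pmin(tb$a1, tb$a2), pmax(tb$a1, tb$a2)))
  gn <- norm(n); ga <- norm(a)
  missing <- is.na(gn) | is.na(ga)
  conc <- !missing & gn == ga
  site <- paste(n$chrom, n$pos, sep = "\r")
  sites <- unique(data.frame(chrom = n$chrom, pos = n$pos,
                             rsid = ifelse(is.na(n$rsid) | !nzchar(n$rsid),
                                           a$rsid, n$rsid),
                             stringsAsFactors = FALSE))
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  skey <- paste(sites$chrom, sites$pos, sep = "\r")
  per_site <- data.frame(
    sites,
    concordant = vapply(skey, function(k) sum(conc[site == k]), 0L),
    compared = vapply(skey, function(k) sum(!missing[site == k]), 0L),
    missing = vapply(skey, function(k) sum(missing[site == k]), 0L),
    discordant_samples = vapply(skey, function(k)
      paste(sort(n$sample_id[site == k & !missing & !conc]), collapse = ","),
      ""),
    stringsAsFactors = FALSE)
  rownames(per_site) <- NULL
  overall <- list(concordant = sum(per_site$concordant),
                  compared = sum(per_site$compared))
  overall$pct <- if (overall$compared > 0)
    100 * overall$concordant / overall$compared else NA_real_
  structure(list(per_site = per_site, overall = overall),
            class = "concordance_table")
}

#' Fill in homozygous-reference NGS genotypes at well-covered sites
#'
#' Variant callers emit records only where a variant was seen; at an array
#' site with no call the sample is homozygous for the reference allele
#' \emph{provided the site was actually sequenced}. This helper adds
#' hom-ref calls for (sample, site) pairs absent from the NGS table when
#' the site's depth in that sample reaches `min_depth`; under-covered
#' absent sites are left missing.
#'
#' @param ngs a `genotype_calls` table of called variants.
#' @param sites data.frame `chrom`, `pos`, `rsid`, `ref` (reference allele).
#' @param samples character vector of sample ids to complete.
#' @param depth function(sample_id, chrom, pos) -> numeric depth, or a
#'   single number applied to all pairs.
#' @param min_depth minimum depth to accept hom-ref (default 30).
#' @return the completed `genotype_calls` table.
#' @export
infer_homref <- function(ngs, sites, samples, depth, min_depth = 30) {
  stopifnot(all(c("chrom", "pos", "ref") %in% names(sites)))
  depth_fun <- if (is.function(depth)) depth else function(...) depth
  have <- paste(ngs$sample_id, ngs$chrom, ngs$pos, sep = "\r")
  add <- list()
  for (s in samples) for (i in seq_len(nrow(sites))) {
    k <- paste(s, sites$chrom[i], sites$pos[i], sep = "\r")
    if (k %in% have) next
    d <- depth_fun(s, sites$chrom[i], sites$pos[i])
    ref <- toupper(sites$ref[i])
    gt <- if (!is.na(d) && d >= min_depth) c(ref, ref)
          else c(NA_character_, NA_character_)
    add[[k]] <- genotype_calls(s, sites$chrom[i], sites$pos[i], gt[1], gt[2],
                               rsid = sites$rsid[i] %||% NA_character_)
  }
  out <- rbind(ngs, do.call(rbind, add))
  rownames(out) <- NULL
  class(out) <- c("genotype_calls", "data.frame")
  out
}

#' Read array genotypes from a site-by-sample TSV export
#'
#' Expected dialect: a header line, then one row per site with columns
#' `chrom`, `pos`, `rsid`, `strand` (`+`, `-` or `unknown`) followed by one
#' column per sample holding two-letter genotypes (`AG`, `TT`, ...); `--`,
#' `NC` and empty cells are missing. Genotypes are harmonized to the
#' sequencing reference strand via [harmonize_strand()]; unknown-strand
#' ambiguous genotypes become missing.
#'
#' @param path TSV path.
#' @return a `genotype_calls` table (long format).
#' @export
read_array_genotypes <- function(path) {
  tb <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  need <- c("chrom", "pos", "rsid", "strand")
  if (!all(need %in% names(tb)))
    stopf("array genotype TSV must have columns %s then sample columns",
          paste(need, collapse = ", "))
  samples <- setdiff(names(tb), need)
  rows <- list()
  for (s in samples) {
    g <- toupper(tb[[s]])
    miss <- is.na(g) | g %in% c("--", "NC", "")
    a1 <- ifelse(miss, NA_character_, substr(g, 1, 1))
    a2 <- ifelse(miss, NA_character_, substr(g, 2, 2))
    h <- harmonize_strand(a1, a2, tb$strand)
    rows[[s]] <- genotype_calls(s, tb$chrom, as.integer(tb$pos), h$a1, h$a2,
                                rsid = tb$rsid)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("genotype_calls", "data.frame")
  out
}

#' Read diploid SNP genotypes from a VCF
#'
#' Extracts the GT field for biallelic (or multi-allelic, by index) SNP
#' records; non-SNP records are dropped with a warning. Requires the
#' `vcfR` package.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return a `genotype_calls` table.
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("read_vcf_genotypes requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  snp <- nchar(fix$REF) == 1L &
    vapply(alt_list, function(a) all(nchar(a) == 1L), TRUE)
  if (any(!snp)) warnf("dropped %d non-SNP VCF record(s)", sum(!snp))
  rows <- list()
  for (s in colnames(gt)) {
    g <- gt[snp, s]
    toks <- strsplit(ifelse(is.na(g), ".|.", g), "[/|]")
    idx1 <- suppressWarnings(as.integer(vapply(toks, `[`, "", 1L)))
    idx2 <- suppressWarnings(as.integer(vapply(toks, `[`, "", 2L)))
    alleles <- function(i, ref, alt) {
      ifelse(is.na(i), NA_character_,
             ifelse(i == 0L, ref, vapply(seq_along(i), function(j)
               if (is.na(i[j]) || i[j] == 0L) ref[j] else alt[[j]][i[j]], "")))
    }
    ref <- fix$REF[snp]; alt <- alt_list[snp]
    a1 <- alleles(idx1, ref, alt); a2 <- alleles(idx2, ref, alt)
    half <- xor(is.na(a1), is.na(a2))
    a1[half] <- NA_character_; a2[half] <- NA_character_
    rows[[s]] <- genotype_calls(s, fix$CHROM[snp], as.integer(fix$POS[snp]),
                                a1, a2, rsid = fix$ID[snp])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("genotype_calls", "data.frame")
  out
}

#' Write a concordance table to TSV
#'
#' Writes one row per site mirroring the published concordance-table
#' layout (`concordant/compared`), plus a discordance detail file when a
#' path is given.
#'
#' @param x a `concordance_table`.
#' @param path output TSV path.
#' @param detail_path optional path for per-sample discordance details.
#' @return `path`, invisibly.
#' @export
write_concordance <- function(x, path, detail_path = NULL) {
  stopifnot(inherits(x, "concordance_table"))
  ps <- x$per_site
  out <- data.frame(chrom = ps$chrom, pos = ps$pos, rsid = ps$rsid,
                    concordant = sprintf("%d/%d", ps$concordant, ps$compared),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(detail_path)) {
    det <- ps[nzchar(ps$discordant_samples),
              c("chrom", "pos", "rsid", "discordant_samples"), drop = FALSE]
    utils::write.table(det, detail_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("genotype concordance: %d/%d pairs concordant (%.2f%%) over %d site(s)\n",
              x$overall$concordant, x$overall$compared,
              x$overall$pct, nrow(x$per_site)))
  invisible(x)
}
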