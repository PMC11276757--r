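test_that("triploid and diploid genotypes parse with depths and qualities", {
  sheet <- make_sheet(c("s3", "s2"), ploidy = c(3L, 2L))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(
    c("tx1\t5\t.\tA\tG\t50\t.\t.\tGT:DP:AD:GQ\t0/0/1:30:20,10:80\t0/1:40:20,20:70",
      "tx1\t9\t.\tC\tT\t50\t.\t.\tGT:DP:AD:GQ\t./.:.:.:.\t0/0:25:25,0:60"),
    c("s3", "s2"), path)
  x <- read_vcf(path, sheet)
  expect_equal(n_variants(x), 2L)
  expect_equal(unname(x$gt[1, "s3"]), "0/0/1")
  expect_equal(unname(x$dp[1, "s3"]), 30L)
  expect_equal(unname(x$ad[1, "s3"]), "20,10")
  expect_equal(unname(x$gq[1, "s2"]), 70)
  expect_true(is.na(x$gt[2, "s3"]))   # "./." is missing at any ploidy
  expect_equal(x$sites$position, c(5L, 9L))
})

test_that("genotype arity must match declared ploidy", {
  sheet <- make_sheet("s3", ploidy = 3L)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text("tx1\t5\t.\tA\tG\t50\t.\t.\tGT:DP:AD:GQ\t0/1:30:20,10:80",
                 "s3", path)
  expect_error(read_vcf(path, sheet), "arity.*s3")
})

test_that("unknown VCF samples and non-SNP records are handled", {
  sheet <- make_sheet("sA", ploidy = 2L)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text("tx1\t5\t.\tA\tG\t50\t.\t.\tGT:DP:AD:GQ\t0/1:30:20,10:80",
                 "sZ", path)
  expect_error(read_vcf(path, sheet), "sZ")

  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(
    c("tx1\t5\t.\tAT\tG\t50\t.\t.\tGT:DP:AD:GQ\t0/1:30:20,10:80",
      "tx1\t9\t.\tA\tG\t50\t.\t.\tGT:DP:AD:GQ\t0/1:30:20,10:80"),
    "sA", path2)
  expect_warning(x <- read_vcf(path2, sheet), "non-SNP")
  expect_equal(n_variants(x), 1L)
})

test_that("genotypes canonicalise to sorted allele order", {
  expect_equal(canonical_gt("0/1/0"), "0/0/1")
  expect_equal(canonical_gt("1|0"), "0/1")
  expect_equal(canonical_gt(c("2/0/1", "./.")), c("0/1/2", NA))
  sheet <- make_sheet("s3", ploidy = 3L)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text("tx1\t5\t.\tA\tG\t50\t.\t.\tGT:DP:AD:GQ\t0/1/0:30:20,10:80",
                 "s3", path)
  x <- read_vcf(path, sheet)
  expect_equal(unname(x$gt[1, "s3"]), "0/0/1")
})

test_that("write_vcf then read_vcf reproduces records field-for-field", {
  sheet <- make_sheet(c("a", "b"), ploidy = 3L)
  gt <- rbind(c("0/0/1", "0/0/0"), c("0/1/1", NA), c("0/0/1", "0/0/1"))
  x <- make_set(gt, sheet, positions = c(3L, 7L, 12L))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(x, path)
  y <- read_vcf(path, sheet)
  expect_equal(y$sites, x$sites)
  expect_equal(y$gt, x$gt)
  expect_equal(y$dp, x$dp)
  expect_equal(y$gq, x$gq)
  expect_equal(y$ad, x$ad)   # the missing call writes "." and reads back NA
})

test_that("empty SNP sets round-trip as header-only VCFs", {
  sheet <- make_sheet(c("a", "b"), ploidy = 2L)
  x <- make_set(matrix(character(0), 0, 2), sheet)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(x, path)
  expect_true(all(startsWith(readLines(path), "#")))
  y <- read_vcf(path, sheet)
  expect_equal(n_variants(y), 0L)
})

test_that("read_cds validates frame, bounds and ambiguity", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  tab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">t1", "ATGGGATAA", ">t2", "ATGCCCAAATAG"), fa)
  writeLines(c("transcript_id\tcds_start\tcds_end", "t1\t1\t9", "t2\t1\t12"), tab)
  r <- read_cds(fa, tab)
  expect_equal(nrow(r), 2L)
  expect_equal(r$cds_end - r$cds_start + 1L, c(9L, 12L))

  writeLines(c("t1\t2\t9"), tab)   # 8 nt, not a multiple of 3
  expect_error(suppressWarnings(read_cds(fa, tab)), "divisible by 3")
  writeLines(c("t1\t1\t12"), tab)  # beyond the 9-nt sequence
  expect_error(suppressWarnings(read_cds(fa, tab)), "beyond sequence")
  writeLines(c("t1\t1\t9"), tab)   # t2 present in FASTA but not in table
  expect_warning(r2 <- read_cds(fa, tab), "skipped")
  expect_equal(r2$transcript_id, "t1")

  writeLines(c(">t1", "ATGGNATAA"), fa)
  writeLines("t1\t1\t9", tab)
  expect_error(read_cds(fa, tab), "ambiguity")
})

test_that("quality filters drop low-depth, low-GQ, low-QUAL and missing calls", {
  sheet <- make_sheet(c("a", "b"), ploidy = 2L)
  gt <- rbind(c("0/1", "0/1"), c("0/1", "0/1"), c("0/1", NA), c("0/1", "0/1"))
  x <- make_set(gt, sheet)
  x$dp[1, "b"] <- 19L                 # one sample below depth threshold
  x$sites$qual[4] <- 29               # site QUAL below threshold
  f <- apply_quality_filters(x)
  expect_equal(f$sites$position, 2L)  # boundary row 2 (DP 60, GQ 99, QUAL 60) kept
  # thresholds are inclusive
  b <- make_set(rbind(c("0/1", "0/1")), sheet, dp = 20, gq = 30, qual = 30)
  expect_equal(n_variants(apply_quality_filters(b)), 1L)
  # empty in, empty out
  e <- make_set(matrix(character(0), 0, 2), sheet)
  expect_equal(n_variants(apply_quality_filters(e)), 0L)
})

test_that("quality filtering is idempotent and monotone in its thresholds", {
  set.seed(42)
  sheet <- make_sheet(c("a", "b", "c"), ploidy = 2L)
  n <- 200
  gt <- matrix("0/1", n, 3)
  x <- make_set(gt, sheet)
  x$dp[] <- sample(10:40, n * 3, replace = TRUE)
  x$gq[] <- sample(10:50, n * 3, replace = TRUE)
  x$sites$qual <- sample(10:50, n, replace = TRUE)
  f1 <- apply_quality_filters(x)
  f2 <- apply_quality_filters(f1)
  expect_equal(f2$sites, f1$sites)
  prev <- Inf
  for (thr in c(10, 20, 30, 40)) {
    kept <- n_variants(apply_quality_filters(x, min_depth = thr))
    expect_lte(kept, prev)
    prev <- kept
  }
  expect_lte(n_variants(apply_quality_filters(x, min_gq = 40)),
             n_variants(apply_quality_filters(x, min_gq = 20)))
})

test_that("depth tables and sample sheets round-trip", {
  d <- make_depths(matrix(c(25L, 30L, 19L, 50L), 2), c("a", "b"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_depth_table(d, path)
  d2 <- read_depth_table(path)
  expect_equal(as.data.frame(d2), as.data.frame(d))

  sheet <- make_sheet(c("a", "b"), ploidy = c(2L, 3L))
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_sample_sheet(sheet, sp)
  expect_equal(read_sample_sheet(sp), sheet)
  bad <- sheet; bad$ploidy[1] <- 4L
  write_sample_sheet(bad, sp)
  expect_error(read_sample_sheet(sp), "ploidy")
})
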