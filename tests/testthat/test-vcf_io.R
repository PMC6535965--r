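test_that("reader keeps biallelic SNPs and counts skipped records", {
  body <- c(
    "chr1\t100\t.\tA\tG\t.\t.\tQD=20\tGT:DP:GQ\t0/1:30:99\t0/0:28:99",
    "chr1\t200\t.\tC\tT\t.\t.\tQD=20\tGT:DP:GQ\t1/1:30:99\t1/1:28:99",
    "chr1\t300\t.\tG\tGA\t.\t.\tQD=20\tGT:DP:GQ\t0/1:30:99\t0/1:28:99",
    "chr1\t400\t.\tT\tA,C\t.\t.\tQD=20\tGT:DP:GQ\t1/2:30:99\t0/1:28:99",
    "chr1\t500\t.\tT\tA\t.\t.\tQD=20\tGT:DP:GQ\t0/0:30:99\t0/1:28:99")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(toy_vcf_lines(body), path)
  sites <- read_pair_vcf(path, c("wild", "sport"))
  expect_equal(nrow(sites), 3)
  expect_equal(sites$pos, c(100, 200, 500))
  expect_equal(attr(sites, "skip_summary"),
               c(indel = 1L, multiallelic = 1L))
  expect_equal(sites$gt_wild, c("0/1", "1/1", "0/0"))
  expect_equal(sites$dp_sport, c(28, 28, 28))
  expect_equal(sites$QD, rep(20, 3))
})

test_that("missing sample and unsorted input are fatal with context", {
  body <- "chr1\t100\t.\tA\tG\t.\t.\tQD=20\tGT:DP:GQ\t0/1:30:99\t0/0:28:99"
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(toy_vcf_lines(body), path)
  expect_error(read_pair_vcf(path, c("wild", "mutant")),
               "mutant.*available samples.*sport")
  body2 <- c(
    "chr1\t500\t.\tA\tG\t.\t.\tQD=20\tGT:DP:GQ\t0/1:30:99\t0/0:28:99",
    "chr1\t100\t.\tC\tT\t.\t.\tQD=20\tGT:DP:GQ\t0/1:30:99\t0/0:28:99")
  writeLines(toy_vcf_lines(body2), path)
  expect_error(read_pair_vcf(path, c("wild", "sport")),
               "not sorted.*100")
})

test_that("two single-sample VCFs are intersected on scaffold/pos/alleles", {
  w <- withr::local_tempfile(fileext = ".vcf")
  s <- withr::local_tempfile(fileext = ".vcf")
  writeLines(toy_vcf_lines(c(
    "chr1\t100\t.\tA\tG\t.\t.\tQD=20\tGT:DP:GQ\t0/1:30:99",
    "chr1\t200\t.\tC\tT\t.\t.\tQD=20\tGT:DP:GQ\t1/1:31:99",
    "chr1\t300\t.\tG\tA\t.\t.\tQD=20\tGT:DP:GQ\t0/1:32:99"),
    samples = "wild"), w)
  writeLines(toy_vcf_lines(c(
    "chr1\t100\t.\tA\tG\t.\t.\tQD=20\tGT:DP:GQ\t0/0:25:99",
    "chr1\t300\t.\tG\tC\t.\t.\tQD=20\tGT:DP:GQ\t0/1:26:99",
    "chr1\t400\t.\tT\tA\t.\t.\tQD=20\tGT:DP:GQ\t0/1:27:99"),
    samples = "sport"), s)
  sites <- read_pair_vcf(w, c("wild", "sport"), sport_path = s)
  # pos 100 shared; 300 allele-mismatched; 200/400 private
  expect_equal(nrow(sites), 1)
  expect_equal(sites$pos, 100)
  expect_equal(sites$gt_wild, "0/1")
  expect_equal(sites$gt_sport, "0/0")
  expect_equal(sites$dp_sport, 25)
  skip <- attr(sites, "skip_summary")
  expect_equal(unname(skip["allele_mismatch"]), 1L)
  expect_equal(unname(skip["private"]), 2L)
})

test_that("simulated callset round-trips through VCF exactly", {
  sim <- simulate_pair(small_config(11))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_pair_vcf(sim, path)
  back <- read_pair_vcf(path, c("wild", "sport"))
  expect_equal(nrow(back), nrow(sim$sites))
  for (col in c("scaffold", "pos", "ref", "alt", "gt_wild", "gt_sport",
                "dp_wild", "dp_sport", "gq_wild", "gq_sport",
                "QD", "MQ", "FS", "MQRankSum", "ReadPosRankSum",
                "SOR", "ClippingRankSum"))
    expect_equal(back[[col]], sim$sites[[col]], label = col)
  # two-file mode carries the same information
  w <- withr::local_tempfile(fileext = ".vcf")
  s <- withr::local_tempfile(fileext = ".vcf")
  write_pair_vcf(sim, w, sport_path = s)
  back2 <- read_pair_vcf(w, c("wild", "sport"), sport_path = s)
  expect_equal(back2$gt_sport, sim$sites$gt_sport)
  expect_equal(back2$dp_sport, sim$sites$dp_sport)
})

test_that("hard filters fire per rule with first-failure attribution", {
  sim <- simulate_pair(small_config(3))
  sites <- sim$sites
  thr <- hard_filter_thresholds()
  # all-nominal site set passes in full
  res <- apply_hard_filters(sites, thr)
  expect_equal(res$n_pass, nrow(sites))
  # QD just below the bound fails and is attributed to QD
  sites$QD[1] <- 9.9
  res <- apply_hard_filters(sites, thr)
  expect_equal(unname(res$fail_counts["QD"]), 1L)
  expect_equal(res$n_pass, nrow(sites) - 1L)
  # a site failing QD and MQ is attributed to QD only (listed order)
  sites$MQ[1] <- 10
  res <- apply_hard_filters(sites, thr)
  expect_equal(unname(res$fail_counts["QD"]), 1L)
  expect_equal(unname(res$fail_counts["MQ_low"]), 0L)
})

test_that("planted single-rule violations are all caught", {
  set.seed(42)
  sim <- simulate_pair(small_config(4))
  sites <- sim$sites
  thr <- hard_filter_thresholds()
  # plant k violations, one rule each, on distinct sites
  k <- 30
  idx <- sample(nrow(sites), k)
  plant <- list(
    function(i) sites$QD[i] <<- 5,
    function(i) sites$MQ[i] <<- 59.0,
    function(i) sites$MQ[i] <<- 61.0,
    function(i) sites$FS[i] <<- 20,
    function(i) sites$MQRankSum[i] <<- 0.2,
    function(i) sites$ReadPosRankSum[i] <<- -3,
    function(i) sites$SOR[i] <<- 3,
    function(i) sites$ClippingRankSum[i] <<- -0.5,
    function(i) sites$gq_wild[i] <<- 5,
    function(i) sites$gt_sport[i] <<- "./.")
  for (j in seq_along(idx)) plant[[(j %% 10) + 1]](idx[j])
  res <- apply_hard_filters(sites, thr)
  expect_equal(res$n_pass, nrow(sites) - k)
  expect_equal(sum(res$fail_counts), k)
  # oracle: per-site re-evaluation of every condition agrees
  oracle_pass <- vapply(seq_len(nrow(sites)), function(i)
    oracle_filter_pass(sites[i, ], thr), logical(1))
  expect_equal(res$n_pass, sum(oracle_pass))
  expect_equal(res$sites$pos, sites$pos[oracle_pass])
})

test_that("filtering is idempotent and absent metrics are lenient", {
  sim <- simulate_pair(small_config(5))
  sites <- sim$sites
  sites$QD[1:5] <- NA          # absent annotation: rule must not fire
  sites$QD[6] <- 1             # present and bad: fires
  res1 <- apply_hard_filters(sites)
  expect_equal(res1$n_pass, nrow(sites) - 1L)
  expect_equal(res1$n_missing_metric, 5L)
  res2 <- apply_hard_filters(res1$sites)
  expect_equal(res2$n_pass, res1$n_pass)
  expect_equal(res2$sites, res1$sites)
  expect_true(all(res2$fail_counts == 0))
})

test_that("two-sided ReadPosRankSum bound is available but off by default", {
  sim <- simulate_pair(small_config(6))
  sites <- sim$sites
  sites$ReadPosRankSum[1] <- 2.0
  expect_equal(apply_hard_filters(sites)$n_pass, nrow(sites))
  res <- apply_hard_filters(
    sites, hard_filter_thresholds(rprs_one_sided = FALSE))
  expect_equal(unname(res$fail_counts["ReadPosRankSum_high"]), 1L)
})

test_that("BED writer converts to 0-based half-open and round-trips", {
  segs <- tibble::tibble(scaffold = "Pp06", start = 22202387,
                         end = 30767194, n_discordant = 8501L)
  path <- withr::local_tempfile(fileext = ".bed")
  write_segments_bed(segs, path)
  expect_equal(readLines(path), "Pp06\t22202386\t30767194\tLOH_n8501")
  back <- read_segments_bed(path)
  expect_equal(back$start, segs$start)
  expect_equal(back$end, segs$end)
  # independent parser agrees on the interval
  gr <- rtracklayer::import(path)
  expect_equal(GenomicRanges::start(gr), 22202387)
  expect_equal(GenomicRanges::end(gr), 30767194)
})

test_that("BED writer handles empty input and rejects overlaps", {
  path <- withr::local_tempfile(fileext = ".bed")
  write_segments_bed(tibble::tibble(scaffold = character(),
                                    start = double(), end = double()),
                     path)
  expect_true(file.exists(path))
  expect_equal(nrow(read_segments_bed(path)), 0)
  segs <- tibble::tibble(scaffold = c("Pp06", "Pp06"),
                         start = c(100, 500), end = c(600, 900))
  expect_error(write_segments_bed(segs, path), "overlapping")
})
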