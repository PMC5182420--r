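test_that("He is the fraction of called cases that are heterozygous", {
  # 11 cases all homozygous -> He = 0
  gm <- small_matrix(rep("c1", 3), c(10, 20, 30),
                     matrix(rep(c(0L, 2L, 0L), 11), nrow = 3),
                     sprintf("A%02d", 1:11))
  prof <- case_heterozygosity(gm, gm$samples)
  expect_equal(prof$he, c(0, 0, 0))
  # 1 heterozygote among 10 called -> 0.1; all het -> 1.0
  calls <- matrix(0L, nrow = 2, ncol = 10)
  calls[1, 1] <- 1L
  calls[2, ] <- 1L
  gm <- small_matrix(rep("c1", 2), c(5, 6), calls)
  prof <- case_heterozygosity(gm, gm$samples)
  expect_equal(prof$he, c(0.1, 1.0))
  expect_identical(prof$n_called + prof$n_missing,
                   rep(10L, 2))
  expect_error(case_heterozygosity(gm, character(0)), "non-empty")
})

test_that("strict eligibility disqualifies markers with missing case calls", {
  calls <- matrix(0L, nrow = 2, ncol = 4)
  calls[1, 2] <- NA_integer_
  gm <- small_matrix(rep("c1", 2), c(5, 6), calls)
  prof <- case_heterozygosity(gm, gm$samples)
  expect_identical(prof$eligible, c(FALSE, TRUE))
  relaxed <- case_heterozygosity(gm, gm$samples, min_called = 3)
  expect_identical(relaxed$eligible, c(TRUE, TRUE))
})

test_that("runs split on heterozygous markers and on chromosome boundaries", {
  # He pattern 0,0,0,het,0,0 -> runs of 3 and 2
  calls <- matrix(0L, nrow = 6, ncol = 5)
  calls[4, 1] <- 1L
  gm <- small_matrix(rep("c1", 6), c(10, 20, 30, 40, 50, 60), calls)
  prof <- case_heterozygosity(gm, gm$samples)
  runs <- find_runs(prof, gm, scan_params(min_run_snps = 2))
  expect_identical(nrow(runs), 2L)
  expect_identical(runs$snp_count, c(3L, 2L))
  expect_identical(runs$start_bp, c(10L, 50L))
  # identical pattern split across two chromosomes never fuses
  gm2 <- small_matrix(c("c1", "c1", "c1", "c2", "c2", "c2"),
                      c(10, 20, 30, 10, 20, 30),
                      matrix(0L, nrow = 6, ncol = 5))
  prof2 <- case_heterozygosity(gm2, gm2$samples)
  runs2 <- find_runs(prof2, gm2, scan_params(min_run_snps = 2))
  expect_identical(nrow(runs2), 2L)
  expect_true(all(runs2$snp_count == 3L))
})

test_that("span is inclusive and reproduces the printed region arithmetic", {
  calls <- matrix(0L, nrow = 2, ncol = 11)
  gm <- small_matrix(rep("chr29", 2), c(15973319, 20794824), calls,
                     sprintf("A%02d", 1:11))
  prof <- case_heterozygosity(gm, gm$samples)
  runs <- find_runs(prof, gm, scan_params(min_run_snps = 2))
  expect_identical(runs$span_bp, 4821506L)
  expect_gt(runs$span_bp, 4.8e6)
})

test_that("ranking orders by SNP count, then span, deterministically", {
  # two runs with equal snp_count: the longer bp span ranks first
  calls <- matrix(0L, nrow = 7, ncol = 4)
  calls[3, 2] <- 1L
  gm <- small_matrix(rep("c1", 7), c(10, 20, 100, 1000, 5000, 10000, 10010),
                     calls)
  prof <- case_heterozygosity(gm, gm$samples)
  runs <- find_runs(prof, gm, scan_params(min_run_snps = 2))
  expect_identical(runs$snp_count, c(4L, 2L))
  # equal snp_count, different spans: wider run wins the tie
  gm2 <- small_matrix(rep("c1", 5), c(10, 20, 5000, 5010, 9000),
                      matrix(c(0, 0, 1, 0, 0), 5, 4))
  prof2 <- case_heterozygosity(gm2, gm2$samples)
  runs2 <- find_runs(prof2, gm2, scan_params(min_run_snps = 2))
  expect_identical(nrow(runs2), 2L)
  expect_true(all(runs2$snp_count == 2L))
  expect_identical(runs2$start_bp[1], 5010L)  # span 3991 beats span 11
  rep_tab <- rank_report(runs2, top_k = 2)
  expect_identical(rep_tab$rank, 1:2)
  expect_gt(rep_tab$span_bp_inclusive[1], rep_tab$span_bp_inclusive[2])
  # single run is rank 1
  single <- rank_report(runs, top_k = 1)
  expect_identical(single$rank, 1L)
  expect_identical(single$snp_count, 4L)
})

test_that("scanner matches the brute-force interval oracle on random data", {
  withr::with_seed(20, {
    for (rep in 1:60) {
      gm <- random_scan_instance(sample(20:200, 1), sample(2:12, 1),
                                 het_prob = sample(c(0.02, 0.1, 0.3), 1),
                                 missing_prob = sample(c(0, 0.05), 1))
      min_run <- sample(1:3, 1)
      prof <- case_heterozygosity(gm, gm$samples)
      q <- prof$eligible & !is.na(prof$he) & prof$he == 0
      got <- find_runs(prof, gm, scan_params(min_run_snps = min_run))
      got <- got[order(got$start_index), c("chrom", "start_index",
                                          "end_index")]
      rownames(got) <- NULL
      class(got) <- "data.frame"
      want <- oracle_runs(q, prof$chrom, min_run)
      expect_identical(got, want)
    }
  })
})

test_that("adding a heterozygous call can only shrink or split runs", {
  withr::with_seed(77, {
    for (rep in 1:20) {
      gm <- random_scan_instance(80, 6, het_prob = 0.05)
      prof <- case_heterozygosity(gm, gm$samples)
      before <- find_runs(prof, gm, scan_params(min_run_snps = 1))
      if (!nrow(before)) next
      # flip a homozygous call inside the longest run to heterozygous
      i <- sample(before$start_index[1]:before$end_index[1], 1)
      gm$calls[i, 1] <- 1L
      after <- find_runs(case_heterozygosity(gm, gm$samples), gm,
                         scan_params(min_run_snps = 1))
      expect_lte(max(after$snp_count, 0), max(before$snp_count))
      expect_lte(sum(after$snp_count), sum(before$snp_count))
    }
  })
})

test_that("outputs are invariant to case sample order", {
  withr::with_seed(5, {
    gm <- random_scan_instance(60, 8, het_prob = 0.1, missing_prob = 0.05)
    p1 <- case_heterozygosity(gm, gm$samples)
    p2 <- case_heterozygosity(gm, rev(gm$samples))
    expect_identical(p1, p2)
    r1 <- find_runs(p1, gm, scan_params(min_run_snps = 1))
    r2 <- find_runs(p2, gm, scan_params(min_run_snps = 1))
    expect_identical(r1, r2)
  })
})

test_that("shared-allele mode drops runs where cases are homozygous for different alleles", {
  calls <- cbind(c(0L, 0L, 0L), c(0L, 2L, 0L))
  gm <- small_matrix(rep("c1", 3), c(10, 20, 30), calls)
  prof <- case_heterozygosity(gm, gm$samples)
  plain <- find_runs(prof, gm, scan_params(min_run_snps = 1))
  expect_identical(plain$snp_count, 3L)
  expect_false(plain$shared_allele_consistent)
  strict <- find_runs(prof, gm, scan_params(min_run_snps = 1,
                                            require_shared_allele = TRUE))
  expect_identical(strict$snp_count, c(1L, 1L))
})

test_that("the He plot writes a figure, with and without highlights", {
  gm <- withr::with_seed(9, random_scan_instance(50, 5, het_prob = 0.2))
  prof <- case_heterozygosity(gm, gm$samples)
  f1 <- withr::local_tempfile(fileext = ".png")
  he_profile_plot(prof, highlight = NULL, path = f1)
  expect_gt(file.size(f1), 0)
  f2 <- withr::local_tempfile(fileext = ".png")
  he_profile_plot(prof,
                  highlight = list(chrom = prof$chrom[1],
                                   start_bp = prof$pos[2],
                                   end_bp = prof$pos[6]),
                  overlay = prof, path = f2)
  expect_gt(file.size(f2), 0)
})
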