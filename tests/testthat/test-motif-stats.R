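test_that("profiles report counts, occupancy, frequency and ratio correctly", {
  # one 10-nt pyrimidine site in 100 nt, no purine sites possible
  s <- paste0(strrep("A", 45), "TTCTTCTTTC", strrep("G", 45))
  p <- profile_sequence(s)
  expect_equal(p$uc$site_count, 1L)
  expect_equal(p$uc$occupancy, 0.10)
  expect_equal(p$uc$frequency, 10)
  expect_true(is.na(p$ratio_uc_over_ag))

  # 10-nt UC + 5-nt AG in 100 nt -> occupancies 10% / 5%, ratio 2.0
  s2 <- paste0(strrep("C", 20), "N", "AAGAA", "N", strrep("C", 20), "N",
               "TTCTTCTTTC", "N", strrep("G", 41))
  p2 <- profile_sequence(s2)
  expect_equal(p2$uc$occupancy, 0.10)
  expect_equal(p2$ag$occupancy, 0.05)
  expect_equal(p2$ratio_uc_over_ag, 2.0)

  expect_error(profile_sequence(""), "zero-length")
})

test_that("occupancy equals brute-force per-position union coverage", {
  set.seed(13)
  for (i in 1:30) {
    s <- random_seq(sample(50:200, 1), c("T", "C", "T", "C", "A", "G"))
    p <- profile_sequence(s)
    for (cl in c("uc", "ag")) {
      covered <- rep(FALSE, nchar(s))
      st <- p[[cl]]$sites
      if (nrow(st))
        for (k in seq_len(nrow(st)))
          covered[(st$start[k] + 1):st$end[k]] <- TRUE
      expect_equal(p[[cl]]$occupancy, mean(covered), info = s)
    }
  }
})

test_that("length distributions expose counts and a proper CDF", {
  d <- length_distribution(c(5L, 5L, 7L))
  expect_equal(d$n, 3L)
  expect_equal(d$counts, c(2L, 1L))
  expect_equal(d$cdf(5), 2 / 3)
  expect_equal(d$cdf(6), 2 / 3)
  expect_equal(d$cdf(7), 1)
  expect_equal(d$cdf(4), 0)
  expect_equal(length_distribution(integer())$n, 0L)
  d2 <- length_distribution(rep(12L, 141))
  expect_equal(d2$counts, 141L)
  expect_equal(d2$lengths, 12L)
})

test_that("KS distance evaluates discrete CDF sup-differences", {
  d56 <- length_distribution(c(5L, 6L))
  d57 <- length_distribution(c(5L, 7L))
  expect_equal(ks_distance(d56, d56), 0)
  expect_equal(ks_distance(length_distribution(5L),
                           length_distribution(6L)), 1)
  expect_equal(ks_distance(d56, d57), 0.5)  # differ at x = 6
  expect_error(ks_distance(d56, length_distribution(integer())), "non-empty")
  expect_true(motif_lengths_similar(d56, d56))
  expect_false(motif_lengths_similar(d56, d57))
})

test_that("KS distance behaves as a metric on random length distributions", {
  set.seed(14)
  for (i in 1:100) {
    a <- random_length_dist(); b <- random_length_dist()
    c_ <- random_length_dist()
    dab <- ks_distance(a, b)
    expect_equal(dab, ks_distance(b, a))
    expect_gte(dab, 0); expect_lte(dab, 1)
    expect_equal(ks_distance(a, a), 0)
    expect_lte(dab, ks_distance(a, c_) + ks_distance(c_, b) + 1e-12)
  }
})

test_that("cumulative short-motif ratios follow the overlap counting", {
  uc <- motif_criteria("pyrimidine")
  w <- enumerate_motif_windows("uuucuuccuu", uc)
  oracle <- oracle_windows("uuucuuccuu", "pyrimidine")
  oracle_ratio <- mean((oracle$end - oracle$start) >= 5 &
                         (oracle$end - oracle$start) <= 7)
  expect_equal(cumulative_short_motif_ratio(w, c(5L, 7L)), oracle_ratio)
  expect_equal(cumulative_short_motif_ratio(w, c(5L, 100L)), 1)
  w5 <- enumerate_motif_windows("uuucuuccuu", uc, length_range = 5L)
  expect_equal(cumulative_short_motif_ratio(w5, c(5L, 7L)), 1)
  expect_error(cumulative_short_motif_ratio(w5[0, ]), "no motif")
})

test_that("family proportions aggregate lengths per chromosome and family", {
  ann <- read_repeatmasker_out(local_rm_fixture(
    chrom = c("chrX", "chrX", "chr1"),
    start = c(100L, 5000L, 0L), end = c(1100L, 5400L, 200L),
    family = c("LINE/L1", "LINE/L2", "LINE/L1")))
  fp <- family_proportions(ann, c(chrX = 10000, chr1 = 1000))
  l1x <- fp[fp$chrom == "chrX" & fp$repeat_family == "L1", ]
  expect_equal(l1x$proportion, 0.10)
  expect_equal(l1x$n_elements, 1L)
  expect_equal(fp[fp$chrom == "chr1", "proportion"], 0.2)
  expect_false("L2" %in% fp$repeat_family[fp$chrom == "chr1"])
  # proportions sum to <= 1 per chromosome on non-overlapping fixtures
  expect_true(all(tapply(fp$proportion, fp$chrom, sum) <= 1))
  expect_error(family_proportions(ann, c(chrX = 10000)), "chromosome length")
  expect_error(family_proportions(ann, c(chrX = 10000, chr1 = 150)),
               "beyond")
})

test_that("overlapping annotations are summed raw with a warning", {
  ann <- read_repeatmasker_out(local_rm_fixture(
    chrom = c("chrX", "chrX"), start = c(0L, 4L), end = c(8L, 12L),
    family = c("LINE/L1", "LINE/L1")))
  expect_warning(fp <- family_proportions(ann, c(chrX = 100)), "overlap")
  expect_equal(fp$bp, 16L)
})

test_that("length bins are right-closed with 100-bp then 1000-bp widths", {
  b <- line_length_bins(7000)
  expect_equal(bin_label(c(1, 100, 101, 1000, 1001, 2000, 6500), b),
               c("<=100", "<=100", "101-200", "901-1000", "1001-2000",
                 "1001-2000", "6001-7000"))
  expect_error(bin_label(8000, b), "outside")
})

test_that("per-bin sampling is reproducible, capped and exhaustive on small bins", {
  fam <- generate_l1_family(consensus_length = 3000L, n_elements = 300L,
                            seed = 21L)
  bins <- line_length_bins(3000)
  s1 <- sample_by_length_bin(fam$annotations, bins, k = 50L, seed = 5L)
  s2 <- sample_by_length_bin(fam$annotations, bins, k = 50L, seed = 5L)
  s3 <- sample_by_length_bin(fam$annotations, bins, k = 50L, seed = 6L)
  expect_identical(s1, s2)
  expect_false(identical(s1$subfamily, s3$subfamily))
  counts <- table(s1$bin)
  expect_true(all(counts <= 50L))
  avail <- table(bin_label(fam$annotations$length, bins))
  for (b in names(counts))
    expect_equal(unname(counts[b]), unname(min(avail[b], 50L)))
  expect_false(anyDuplicated(s1$subfamily) > 0)
  expect_error(sample_by_length_bin(fam$annotations, numeric(1), 5L, 1L),
               "bin")
})
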