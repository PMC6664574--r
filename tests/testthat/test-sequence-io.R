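test_that("FASTA reading normalizes residues and keeps record order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGU", ">a", "acg", ">b", "TT"), f)
  recs <- read_fasta(f)
  expect_identical(names(recs), c("s1", "a", "b"))
  expect_identical(as.vector(recs), c("ACGT", "ACG", "TT"))
  expect_identical(attr(recs, "alphabet_note"),
                   c("RNA", "DNA", "DNA"))
})

test_that("ambiguity codes collapse to N with a warning; junk is an error", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s", "ACRT"), f)
  expect_warning(recs <- read_fasta(f), "ambiguity")
  expect_identical(as.vector(recs), "ACNT")

  writeLines(c(">s", "AC-T"), f)
  expect_error(suppressWarnings(read_fasta(f)), "illegal residue")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "not found")
  f2 <- withr::local_tempfile(fileext = ".fa")
  file.create(f2)
  expect_error(read_fasta(f2))
})

test_that("FASTA round-trips preserve ids and residues", {
  set.seed(11)
  recs <- vapply(1:100, function(i) random_seq(sample(1:300, 1)),
                 character(1))
  names(recs) <- sprintf("rec%03d", 1:100)
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_identical(names(back), names(recs))
  expect_identical(as.vector(back), as.vector(recs))
  expect_error(write_fasta(character(0), f), "no records")
})

test_that("RepeatMasker .out parsing converts coordinates, strand and family", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW  perc perc perc  query      position in query",
    "score  div. del. ins.  sequence   begin end (left)",
    "",
    " 1000 10.0  1.0  2.0  chrX  1001 2000 (5000) +  L1PA5  LINE/L1  1 1000 (0) 1",
    "  900 11.0  1.0  2.0  chrX  3001 3500 (4000) C  L2a    LINE/L2  1  500 (0) 2",
    "  800 12.0  1.0  2.0  chr1  10   40   (900)  +  AluY   SINE/Alu 1   31 (0) 3"),
    f)
  ann <- read_repeatmasker_out(f)
  expect_equal(nrow(ann), 3L)
  expect_equal(ann$start[1], 1000L)   # 1-based inclusive -> 0-based
  expect_equal(ann$end[1], 2000L)
  expect_equal(ann$length[1], 1000L)
  expect_identical(ann$strand, c("+", "-", "+"))
  expect_identical(ann$repeat_class[1], "LINE")
  expect_identical(ann$repeat_family[2], "L2")
  expect_identical(ann$subfamily[1], "L1PA5")
  expect_identical(ann$chrom, c("chrX", "chrX", "chr1"))
})

test_that("malformed RepeatMasker lines are rejected", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c("header", "header", "", " 1 2 3"), f)
  expect_error(read_repeatmasker_out(f), "fewer than 11")
  writeLines(c(" 1000 1 1 1 chrX one two (5000) + L1 LINE/L1 1 2 (0) 1"), f)
  expect_error(read_repeatmasker_out(f), "non-numeric")
})

test_that("RepeatMasker write/read round-trips synthetic annotations", {
  fam <- generate_l1_family(consensus_length = 2000L, n_elements = 20L,
                            seed = 3L)
  f <- withr::local_tempfile(fileext = ".out")
  write_repeatmasker_out(fam$annotations, f)
  back <- read_repeatmasker_out(f)
  for (col in c("chrom", "start", "end", "strand", "repeat_class",
                "repeat_family", "subfamily", "length"))
    expect_equal(back[[col]], fam$annotations[[col]], info = col)
})

test_that("dot-bracket parsing yields an involution and flags imbalance", {
  p <- parse_dot_bracket("((..))")
  expect_equal(p, c(6L, 5L, NA, NA, 2L, 1L))
  expect_true(all(is.na(parse_dot_bracket("...."))))
  expect_error(parse_dot_bracket("((.)"), "unbalanced")
  expect_error(parse_dot_bracket("(.))"), "unbalanced")
  paired <- which(!is.na(p))
  expect_equal(p[p[paired]], paired)
})

test_that("structure files round-trip through dot-bracket and CT formats", {
  db <- "((((....))))..(((...)))"
  f <- withr::local_tempfile(fileext = ".db")
  writeLines(c(">fix", gsub("[().]", "A", db), db), f)
  p <- read_structure(f)
  expect_equal(p, parse_dot_bracket(db))

  # hand-built CT for the same pairing
  ct <- withr::local_tempfile(fileext = ".ct")
  n <- nchar(db)
  partner <- ifelse(is.na(p), 0L, p)
  writeLines(c(sprintf("%d synthetic fixture", n),
               sprintf("%d A %d %d %d %d", 1:n, 0:(n - 1), c(2:n, 0),
                       partner, 1:n)), ct)
  expect_equal(read_structure(ct), p)

  # asymmetric CT partners are rejected
  bad <- partner
  bad[1] <- 5L
  writeLines(c(sprintf("%d synthetic fixture", n),
               sprintf("%d A %d %d %d %d", 1:n, 0:(n - 1), c(2:n, 0),
                       bad, 1:n)), ct)
  expect_error(read_structure(ct), "symmetric|involution")
})

test_that("sites tables round-trip and BED export matches coordinates", {
  sites <- find_motif_sites("aaTTCTTCTTTCaaAGGAAGAAGGGAaa",
                            motif_criteria("pyrimidine"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_sites_table(sites, tsv, bed_path = bed)
  back <- read_sites_table(tsv)
  expect_equal(back$start, sites$start)
  expect_equal(back$sequence, sites$sequence)
  bed_df <- read.table(bed, sep = "\t")
  expect_equal(bed_df$V2, sites$start)
  expect_equal(bed_df$V3, sites$end)

  # empty site lists still produce a header-only table
  empty <- find_motif_sites("ACG", motif_criteria("pyrimidine"))
  write_sites_table(empty, tsv)
  expect_equal(nrow(read_sites_table(tsv)), 0L)
})
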