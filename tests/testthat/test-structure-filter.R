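test_that("loop classification covers the standard loop taxonomy", {
  # simple hairpin
  st <- classify_positions(parse_dot_bracket("((((....))))"))
  expect_identical(st$loop_label[5:8], rep("hairpin", 4))
  expect_identical(st$loop_label[c(1:4, 9:12)], rep("paired", 8))

  # all exterior
  expect_identical(classify_positions(parse_dot_bracket("...."))$loop_label,
                   rep("exterior", 4))

  # hand-decomposed 15-symbol structure: internal loop around an inner helix
  st2 <- classify_positions(parse_dot_bracket("((..((...))..))"))
  expect_identical(st2$loop_label,
                   c("paired", "paired", "internal", "internal", "paired",
                     "paired", "hairpin", "hairpin", "hairpin", "paired",
                     "paired", "internal", "internal", "paired", "paired"))

  # bulge: unpaired on one side of the branch only
  st3 <- classify_positions(parse_dot_bracket("((.((...))))"))
  expect_identical(st3$loop_label[3], "bulge")

  # multibranch: two child helices inside one loop
  st4 <- classify_positions(parse_dot_bracket("((.((...)).((...)).))"))
  expect_identical(st4$loop_label[3], "multibranch")
  expect_identical(st4$loop_label[11], "multibranch")
  expect_identical(st4$loop_label[19], "multibranch")
})

test_that("pseudoknots and malformed pairings are rejected by name", {
  # crossing pairs (1,3) and (2,4)
  expect_error(classify_positions(c(3L, 4L, 1L, 2L)), "pseudoknot")
  expect_error(classify_positions(c(2L, 3L, 1L)), "involution")
})

test_that("usable length is the longest in-loop single-stranded run", {
  # 7-nt motif entirely inside one hairpin loop
  db <- paste0("....((((", strrep(".", 7), "))))....")
  st <- classify_positions(parse_dot_bracket(db))
  site <- list(start = 8L, end = 15L)
  expect_equal(usable_length(site, st), 7L)

  # isolated single-stranded positions inside a stem -> usable runs of 1
  db3 <- "((((..((.((.((.((....)).)).)).))..))))"
  st3 <- classify_positions(parse_dot_bracket(db3))
  motif <- list(start = 8L, end = 15L)  # positions 9-15: ( . ( ( . ( (
  expect_lte(usable_length(motif, st3), 1L)

  # eligibility: exterior positions do not count by default
  stx <- classify_positions(parse_dot_bracket("......"))
  expect_equal(usable_length(list(start = 0L, end = 6L), stx), 0L)
  expect_equal(usable_length(list(start = 0L, end = 6L), stx,
                             eligible = c("hairpin", "internal", "bulge",
                                          "exterior")), 6L)
  expect_error(usable_length(list(start = 0L, end = 99L), stx), "bounds")
})

test_that("contiguity rule: accessible stretch must sit in one loop instance", {
  # two hairpin loops of 3 and 4 nt separated by a helix; a site spanning
  # both has usable length 4, not 7
  db <- "((...))((....))"
  st <- classify_positions(parse_dot_bracket(db))
  site <- list(start = 0L, end = 15L)
  expect_equal(usable_length(site, st), 4L)
  expect_equal(usable_length(site, st, contiguous = FALSE), 7L)
})

test_that("filtering shows identity and annihilation limits", {
  s <- paste0("A", "TTCTTCTTTC", "A", "TTCTT", "A")
  sites <- find_motif_sites(s, motif_criteria("pyrimidine"))
  expect_equal(nrow(sites), 2L)

  all_open <- classify_positions(rep(NA_integer_, nchar(s)))
  res_open <- filter_sites(sites, all_open, motif_criteria("pyrimidine"),
                           eligible = c("hairpin", "internal", "bulge",
                                        "exterior"))
  expect_true(all(res_open$usable$retained))
  expect_equal(res_open$after$counts, res_open$before$counts)

  # fully paired helix across everything: nothing retained
  n <- nchar(s)
  db <- paste0(strrep("(", n), strrep(".", 3), strrep(")", n))
  stp <- classify_positions(parse_dot_bracket(db))
  res_closed <- filter_sites(sites, stp, motif_criteria("pyrimidine"))
  expect_equal(nrow(res_closed$retained), 0L)
  expect_equal(res_closed$after$n, 0L)
})

test_that("planted 12-nt motifs with forced 7-nt loops keep usable length 7", {
  # nine isolated purine 12-mers; the last 7 nt of each are forced into a
  # hairpin loop, the first 5 sit in the flanking stem
  motif <- "AGGAAGAGGGGA"
  spacing <- 30L
  n_mot <- 9L
  chunks <- character(0)
  starts <- integer(0)
  pos <- 0L
  for (i in seq_len(n_mot)) {
    pad <- strrep("C", spacing)
    chunks <- c(chunks, pad, motif)
    starts <- c(starts, pos + spacing)
    pos <- pos + spacing + nchar(motif)
  }
  chunks <- c(chunks, strrep("C", spacing))
  s <- paste(chunks, collapse = "")
  sites <- find_motif_sites(s, motif_criteria("purine"))
  expect_equal(sites$start, starts)
  loop_spec <- lapply(starts, function(st) c(st + 5L, st + 12L))
  db <- generate_structure_fixture(nchar(s), paired_fraction = 0.4,
                                   loop_spec = loop_spec, stem = 5L,
                                   seed = 2L)
  st <- classify_positions(parse_dot_bracket(db))
  res <- filter_sites(sites, st, motif_criteria("purine"))
  expect_equal(res$usable$usable_length, rep(7L, n_mot))
  expect_equal(nrow(res$retained), n_mot)
  expect_equal(res$after$lengths, 7L)
  expect_equal(res$after$counts, n_mot)
})

test_that("filtering never increases counts or lengths and mirrors on reversal", {
  set.seed(15)
  for (i in 1:20) {
    gen <- generate_motif_sequence(400L, c(uc = 0.10, ag = 0.10),
                                   seed = 100L + i)
    db <- generate_structure_fixture(400L, paired_fraction = 0.5,
                                     seed = 200L + i)
    st <- classify_positions(parse_dot_bracket(db))
    for (cl in c("pyrimidine", "purine")) {
      crit <- motif_criteria(cl)
      sites <- find_motif_sites(gen$sequence, crit)
      if (!nrow(sites)) next
      res <- filter_sites(sites, st, crit)
      expect_lte(nrow(res$retained), nrow(sites))
      expect_true(all(res$usable$usable_length <= res$usable$length))

      # mirror: reverse the structure and the site coordinates
      n <- 400L
      rev_pairing <- rev(ifelse(is.na(st$pairing), NA_integer_,
                                n + 1L - st$pairing))
      str_rev <- classify_positions(rev_pairing)
      sites_rev <- sites
      sites_rev$start <- n - sites$end
      sites_rev$end <- n - sites$start
      res_rev <- filter_sites(sites_rev, str_rev, crit)
      expect_equal(sort(res_rev$usable$usable_length),
                   sort(res$usable$usable_length))
    }
  }
})
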