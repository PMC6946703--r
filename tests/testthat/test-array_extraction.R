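test_that("find_repeats locates exact and mismatched repeats", {
  expect_equal(find_repeats("AAACGTACGTTTT", "ACGTACGT", 0),
               data.frame(start = 2L, end = 10L))
  # two exact repeats separated by a 15 nt spacer
  r <- paste0("AA", FIX_REPEAT, rand_dna_fixed15, FIX_REPEAT, "GG")
  occ <- find_repeats(r, FIX_REPEAT, 0)
  expect_equal(nrow(occ), 2L)
  expect_equal(occ$start[2] - occ$end[1], 15L)
  # one substitution: found at max_mismatch 1, not at 0
  mut <- paste0("AA", mutate_seq(FIX_REPEAT, 5), "GG")
  expect_equal(nrow(find_repeats(mut, FIX_REPEAT, 1)), 1L)
  expect_equal(nrow(find_repeats(mut, FIX_REPEAT, 0)), 0L)
  # degenerate inputs
  expect_equal(nrow(find_repeats("", FIX_REPEAT, 0)), 0L)
  expect_error(find_repeats("ACGT", "", 0), "non-empty")
  expect_error(find_repeats("ACGT", "ACGTACGT", 4), "max_mismatch")
})

test_that("find_repeats agrees with an exhaustive Hamming scan and is monotone", {
  set.seed(101)
  pat <- "ACGTTGCAAC"
  for (i in 1:25) {
    s <- rand_dna(sample(30:120, 1))
    for (mm in 0:2) {
      cand <- oracle_hamming_starts(s, pat, mm)
      got <- find_repeats(s, pat, mm)
      # greedy left-to-right non-overlap over the oracle candidates
      keep <- integer(0); last <- -1L
      for (p in cand) if (p >= last) { keep <- c(keep, p); last <- p + nchar(pat) }
      expect_equal(got$start, keep)
    }
    n0 <- nrow(find_repeats(s, pat, 0))
    n1 <- nrow(find_repeats(s, pat, 1))
    n2 <- nrow(find_repeats(s, pat, 2))
    expect_true(n0 <= n1 && n1 <= n2)
  }
})

test_that("extract_spacers keeps only repeat-flanked gaps within bounds", {
  sp <- "AAAAATTTTTCCCCCGGGGGAAAAATTTTTCCC"  # 33 nt
  pa <- extract_spacers(make_array_read(sp), FIX_REPEAT)
  expect_equal(pa$status, "ok")
  expect_equal(pa$spacers, sp)
  expect_equal(pa$n_repeats, 2L)

  none <- extract_spacers(rand_dna(80), FIX_REPEAT)
  expect_equal(none$status, "no_repeat")
  expect_length(none$spacers, 0L)

  single <- extract_spacers(paste0("AA", FIX_REPEAT, "TT"), FIX_REPEAT)
  expect_equal(single$status, "single_repeat")

  # 3 nt gap outside [25,45]: dropped, array malformed
  bad <- paste0("AA", FIX_REPEAT, "TTT", FIX_REPEAT, sp, FIX_REPEAT)
  pb <- extract_spacers(bad, FIX_REPEAT)
  expect_equal(pb$status, "malformed")
  expect_equal(pb$spacers, sp)
})

test_that("spacers never contain the repeat within the mismatch tolerance", {
  set.seed(77)
  for (i in 1:30) {
    spacers <- replicate(sample(1:4, 1), rand_dna(33))
    pa <- extract_spacers(make_array_read(spacers), FIX_REPEAT, max_mismatch = 2)
    for (s in pa$spacers) {
      expect_length(oracle_hamming_starts(s, FIX_REPEAT, 2), 0L)
    }
  }
})

test_that("call_expansion takes the prefix before the parental anchor", {
  p1 <- rand_dna(33); p2 <- rand_dna(33)
  s1 <- rand_dna(33); s2 <- rand_dna(33)
  parse1 <- function(sp) extract_spacers(make_array_read(sp), FIX_REPEAT)

  a <- call_expansion(parse1(c(s1, p1, p2)), c(p1, p2))
  expect_true(a$is_expanded)
  expect_equal(a$new_spacers, s1)

  b <- call_expansion(parse1(c(p1, p2)), c(p1, p2))
  expect_false(b$is_expanded)
  expect_length(b$new_spacers, 0L)

  c3 <- call_expansion(parse1(c(s1, s2, p1)), c(p1, p2))
  expect_equal(c3$new_spacers, c(s1, s2))

  # unrecognizable anchor: excluded as malformed
  d <- call_expansion(parse1(c(s1, s2)), c(p1, p2))
  expect_equal(d$status, "malformed")

  # anchor tolerated within the mismatch budget
  e <- call_expansion(parse1(c(s1, mutate_seq(p1, c(2, 9)), p2)), c(p1, p2))
  expect_true(e$is_expanded)
  expect_equal(e$new_spacers, s1)
})

test_that("summarize_expansion computes percentages over ok arrays", {
  p1 <- rand_dna(33)
  reads <- c(replicate(98, make_array_read(p1)),
             replicate(2, make_array_read(c(rand_dna(33), p1))))
  names(reads) <- sprintf("r%03d", seq_along(reads))
  parsed <- parse_sample(reads, FIX_REPEAT, p1)
  s <- summarize_expansion(parsed, "demo")
  expect_equal(s$n_arrays_total, 100L)
  expect_equal(s$n_arrays_expanded, 2L)
  expect_equal(s$percent_expanded, 2.0)
  expect_equal(s$n_new_spacers, 2L)

  z <- summarize_expansion(parse_sample(reads[1:5], FIX_REPEAT, p1))
  expect_equal(z$percent_expanded, 0)
  expect_equal(z$n_new_spacers, 0L)

  junk <- parse_sample(c(r1 = rand_dna(60)), FIX_REPEAT, p1)
  expect_error(summarize_expansion(junk), "no usable arrays")
})
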