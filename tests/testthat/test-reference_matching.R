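test_that("match_to_database reports all hits above threshold", {
  set.seed(31)
  plasmid <- rand_dna(5000)
  db <- data.frame(id = "p1", role = "plasmid_db", seq = plasmid,
                   stringsAsFactors = FALSE)
  q <- substr(plasmid, 2001, 2033)
  h <- match_to_database(c(s1 = q), db)
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 100)
  expect_equal(h$coverage, 100)
  expect_equal(c(h$start, h$end), c(2000, 2033))

  # 2 mismatches in 33 nt: identity 93.9 < 95 -> no hit
  q2 <- mutate_seq(q, c(5, 20))
  expect_equal(nrow(match_to_database(c(s1 = q2), db)), 0L)
  expect_equal(nrow(match_to_database(c(s1 = q2), db, min_identity = 90)), 1L)

  # all-hits contract: spacer present in two db entries -> 2 hits
  db2 <- rbind(db, data.frame(id = "p2", role = "plasmid_db",
                              seq = paste0(rand_dna(300), q, rand_dna(300))))
  h2 <- match_to_database(c(s1 = q), db2)
  expect_equal(sort(unique(h2$ref_id)), c("p1", "p2"))
  expect_equal(nrow(h2), 2L)

  expect_error(match_to_database(c(s1 = q), db[0, ]), "empty")
})

test_that("exact matching equals a brute-force substring scan", {
  set.seed(17)
  for (i in 1:20) {
    db <- data.frame(id = c("a", "b"), role = "donor",
                     seq = c(rand_dna(600), rand_dna(900)),
                     stringsAsFactors = FALSE)
    src <- sample(1:2, 1)
    q <- plant_query(db$seq[src], 30, 0)
    if (sample(c(TRUE, FALSE), 1)) q <- oracle_revcomp(q)
    got <- match_to_database(c(q = q), db, 100, 100)
    want <- oracle_exact_hits(q, db)
    got_k <- paste(got$ref_id, got$start, got$strand)
    want_k <- paste(want$ref_id, want$start, want$strand)
    expect_setequal(got_k, want_k)
  }
})

test_that("scramble_spacers permutes composition-preservingly and is seeded", {
  expect_equal(unname(scramble_spacers(c(a = "AAAA"), seed = 1)), "AAAA")
  s <- scramble_spacers(c(x = "ACGT"), seed = 7)
  expect_equal(sort(strsplit(unname(s), "")[[1]]), c("A", "C", "G", "T"))
  expect_identical(scramble_spacers(c(x = "ACGTACGTAC"), seed = 3),
                   scramble_spacers(c(x = "ACGTACGTAC"), seed = 3))
  expect_error(scramble_spacers(c(x = "ACGT")), "seed")
  many <- scramble_spacers(setNames(replicate(50, rand_dna(33)), 1:50), seed = 2)
  expect_equal(nchar(many), rep(33L, 50), ignore_attr = TRUE)
})

test_that("calibrate_threshold picks the smallest null-silencing threshold", {
  set.seed(23)
  plasmid <- rand_dna(5000)
  db <- data.frame(id = "rp4", role = "donor", seq = plasmid,
                   stringsAsFactors = FALSE)
  starts <- sample(4500, 150)
  spacers <- setNames(substring(plasmid, starts, starts + 32), paste0("s", 1:150))
  cal <- calibrate_threshold(spacers, db, seed = 99)
  expect_s3_class(cal, "calibration_curve")
  # scrambled rate is monotone non-increasing in the threshold
  expect_true(all(diff(cal$curve$scrambled_hit_rate) <= 0))
  expect_true(all(cal$curve$real_hit_rate >= 0 & cal$curve$real_hit_rate <= 1))
  # error-free spacers drawn from the db: real rate 1.0 even at grid=100
  cal100 <- calibrate_threshold(spacers, db, seed = 99, grid = 100)
  expect_equal(cal100$curve$real_hit_rate, 1.0)
  expect_error(calibrate_threshold(character(0), db, seed = 1), "no spacers")
  expect_warning(calibrate_threshold(spacers[1:5], db, seed = 1), "fewer than 100")
})

test_that("filter_multi_mapping removes ambiguous spacers and is idempotent", {
  hits <- data.frame(
    spacer_id = c("s1", "s2", "s2", "s3", "s4"),
    ref_id = c("refA", "refA", "refB", "refB", "refC"),
    start = 0L, end = 33L, strand = "+", identity = 100, coverage = 100,
    stringsAsFactors = FALSE)
  f <- filter_multi_mapping(hits)
  expect_equal(sort(unique(f$hits$spacer_id)), c("s1", "s3", "s4"))
  expect_equal(f$n_removed, 1L)
  expect_equal(f$fraction_removed, 0.25)       # 1 of 4 unique spacers
  # idempotent and output subset of input
  f2 <- filter_multi_mapping(f$hits)
  expect_identical(f2$hits, f$hits)
  expect_equal(f2$n_removed, 0L)
  expect_true(all(paste(f$hits$spacer_id, f$hits$ref_id) %in%
                    paste(hits$spacer_id, hits$ref_id)))
  # zero-row input
  f0 <- filter_multi_mapping(hits[0, ])
  expect_equal(f0$fraction_removed, 0)
})
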