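test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  expect_error(sim_config(expansion_rate = 1.2), "expansion_rate")
  expect_error(sim_config(n_reads = 0), "n_reads")
  expect_error(sim_config(repeat_seq = "ACGTN"), "repeat_seq")
  expect_error(sim_config(repeat_seq = "ACGT"), "repeat_seq")
  expect_error(sim_config(donor_lens = c(d1 = 0)), "donor")
  expect_error(sim_config(donor_ids = "nope"), "donor_ids")
  # parental spacers derive deterministically from the seed
  expect_identical(sim_config(seed = 9)$parental_spacers,
                   sim_config(seed = 9)$parental_spacers)
})

test_that("simulate_references is deterministic and non-homologous", {
  cfg <- sim_config(seed = 1, donor_lens = c(rp4 = 5000L))
  r1 <- simulate_references(cfg)
  r2 <- simulate_references(cfg)
  expect_identical(r1, r2)
  # byte-identical FASTA on repeated writes
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(setNames(r1$seq, r1$id), f1)
  write_fasta(setNames(r2$seq, r2$id), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # brute-force 16-mer disjointness between recorder and donor sets
  k16 <- function(s) {
    st <- seq_len(nchar(s) - 15L)
    unique(substring(s, st, st + 15L))
  }
  donor <- r1$seq[r1$id == "rp4"]
  rec <- c(k16(r1$seq[r1$id == "recorder_genome"]),
           k16(r1$seq[r1$id == "recorder_plasmid"]))
  expect_length(intersect(c(k16(donor), k16(oracle_revcomp(donor))), rec), 0L)
})

test_that("simulate_acquisitions enforces counts and matches its knobs", {
  cfg <- sim_config(seed = 2, n_reads = 10000L, expansion_rate = 0.02,
                    multi_acquisition_prob = 0)
  refs <- simulate_references(cfg)
  ev <- simulate_acquisitions(cfg, refs)
  expect_equal(length(unique(ev$read_id)), 200L)   # round(1e4 * 0.02)
  expect_equal(nrow(ev), 200L)

  # zero case
  cfg0 <- sim_config(seed = 2, expansion_rate = 0)
  expect_equal(nrow(simulate_acquisitions(cfg0, refs)), 0L)

  # pam bias: AAG fraction within 3 binomial SD of 0.5 over ~1e4 events
  cfgp <- sim_config(seed = 3, n_reads = 20000L, expansion_rate = 0.5,
                     pam_bias = 0.5, multi_acquisition_prob = 0)
  refsp <- simulate_references(cfgp)
  evp <- simulate_acquisitions(cfgp, refsp)
  aag <- mean(evp$pam == "AAG", na.rm = TRUE)
  n <- sum(!is.na(evp$pam))
  expect_lt(abs(aag - 0.5), 3 * sqrt(0.25 / n) + 1 / 64)

  # event intervals lie inside their sources and lengths agree
  lens <- setNames(nchar(refs$seq), refs$id)
  expect_true(all(ev$start >= 0 & ev$end <= lens[ev$source_ref_id]))
  expect_true(all(ev$end - ev$start == nchar(ev$spacer_seq)))

  # hotspot outside reference errors
  cfgh <- sim_config(seed = 2, hotspot = list(ref_id = "donor1", start = 0,
                                              end = 99999, weight = 5))
  expect_error(simulate_acquisitions(cfgh, refs), "hotspot")
})

test_that("hotspot elevates per-base acquisition density", {
  cfg <- sim_config(seed = 11, n_reads = 8000L, expansion_rate = 0.5,
                    exogenous_fraction = 1, pam_bias = 0,
                    multi_acquisition_prob = 0,
                    donor_lens = c(donor1 = 10000L),
                    hotspot = list(ref_id = "donor1", start = 1000L,
                                   end = 2000L, weight = 5))
  refs <- simulate_references(cfg)
  ev <- simulate_acquisitions(cfg, refs)
  inside <- mean(ev$start >= 1000 & ev$start < 2000)
  # expected fraction = 5*1000 / (5*1000 + 9000) = 0.357
  expect_lt(abs(inside - 5000 / 14000), 0.05)
})

test_that("simulate_reads builds exact arrays and conserves events", {
  cfg <- sim_config(seed = 4, n_reads = 300L, expansion_rate = 0.1,
                    error_rate = 0)
  refs <- simulate_references(cfg)
  ev <- simulate_acquisitions(cfg, refs)
  rd <- simulate_reads(cfg, refs, ev)
  R <- cfg$repeat_seq
  parental_unit <- paste0(R, paste0(cfg$parental_spacers, R, collapse = ""))
  unexp <- setdiff(rd$reads$read_id, ev$read_id)
  # no-noise construction: unexpanded read is leader + repeat + parental unit
  expect_identical(rd$reads$seq[rd$reads$read_id == unexp[1]],
                   paste0(rd$leader, parental_unit))
  # expanded read with k new spacers has parental repeat count + k repeats
  one <- ev$read_id[1]
  k <- sum(ev$read_id == one)
  seq1 <- rd$reads$seq[rd$reads$read_id == one]
  nrep <- nrow(find_repeats(seq1, R, 0))
  expect_equal(nrep, length(cfg$parental_spacers) + 1L + k)
  # conservation: manifest rows == embedded new spacers
  expect_equal(nrow(rd$manifest), nrow(ev))
})

test_that("a full synthetic recording is byte-deterministic", {
  cfg <- sim_config(seed = 5, n_reads = 100L, expansion_rate = 0.1,
                    error_rate = 0.01)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_recording(cfg, dir = d1)
  simulate_recording(cfg, dir = d2)
  for (f in c("reads.fastq", "refs.fasta", "truth.tsv", "config.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})
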