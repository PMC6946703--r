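test_that("normalized_spacer_mapping applies the per-kb per-1000 formula", {
  h <- data.frame(spacer_id = paste0("s", 1:50), ref_id = "p1",
                  stringsAsFactors = FALSE)
  p <- normalized_spacer_mapping(h, c(p1 = 5000, p2 = 2000), 2000)
  expect_equal(p$normalized_spacer_mapping[p$ref_id == "p1"], 5.0)
  expect_equal(p$normalized_spacer_mapping[p$ref_id == "p2"], 0)
  expect_true(p$zero[p$ref_id == "p2"])
  # scale invariance: doubling spacers and total leaves the value unchanged
  h2 <- data.frame(spacer_id = paste0("s", 1:100), ref_id = "p1")
  p2 <- normalized_spacer_mapping(h2, c(p1 = 5000), 4000)
  expect_equal(p2$normalized_spacer_mapping, 5.0)
  expect_error(normalized_spacer_mapping(h, c(p1 = 5000), 0), "total_exogenous")
})

test_that("window_coverage averages depth per window and conserves mass", {
  h1 <- data.frame(start = 50L, end = 83L)
  wc <- window_coverage(h1, 1000L, 200L)
  expect_equal(wc$mean_depth[1], 33 / 200)
  expect_equal(sum(wc$mean_depth[-1]), 0)
  # hit spanning a window boundary splits proportionally
  h2 <- data.frame(start = 190L, end = 223L)
  wc2 <- window_coverage(h2, 1000L, 200L)
  expect_equal(wc2$mean_depth[1:2], c(10 / 200, 23 / 200))
  # last partial window averaged over its own length
  h3 <- data.frame(start = 980L, end = 1010L)
  wc3 <- window_coverage(h3, 1010L, 200L)
  expect_equal(wc3$win_end[6], 1010L)
  expect_equal(wc3$mean_depth[5], 20 / 200)   # bases 980..999
  expect_equal(wc3$mean_depth[6], 10 / 10)    # bases 1000..1009 fully covered
  # conservation on random hits
  set.seed(12)
  st <- sample(0:1960, 400, replace = TRUE)
  hr <- data.frame(start = st, end = pmin(st + sample(20:40, 400, TRUE), 2000L))
  wr <- window_coverage(hr, 2000L, 200L)
  expect_equal(sum(wr$mean_depth * (wr$win_end - wr$win_start)),
               sum(hr$end - hr$start))
})

test_that("call_sample applies the two-gate rule and is monotone", {
  pos <- call_sample("a", 1e6, 0.10, 12, control_percent = 0.03)
  expect_true(pos$is_hgt_positive)
  expect_equal(pos$effective_threshold_percent, 0.09)
  expect_false(call_sample("b", 1e6, 5.0, 9)$is_hgt_positive)
  expect_false(call_sample("c", 1e6, 0.05, 50)$is_hgt_positive)
  # monotone in both arguments
  set.seed(3)
  for (i in 1:20) {
    pe <- runif(1, 0, 0.2); nu <- sample(0:20, 1)
    base <- call_sample("m", 1, pe, nu)$is_hgt_positive
    up1 <- call_sample("m", 1, pe + 0.05, nu)$is_hgt_positive
    up2 <- call_sample("m", 1, pe, nu + 5)$is_hgt_positive
    expect_true(!base || (up1 && up2))
  }
})

test_that("minimal_covering_set finds small covers and assigns spacers", {
  h <- data.frame(
    spacer_id = c("s1", "s2", "s3", "s3", "s4", "s4", "s5"),
    ref_id    = c("A",  "A",  "A",  "B",  "B",  "C",  "C"),
    stringsAsFactors = FALSE)
  cs <- minimal_covering_set(h)
  expect_equal(sort(cs$cover$ref_id), c("A", "C"))  # brute-force optimum is 2
  expect_equal(oracle_min_cover_size(list(A = c("s1","s2","s3"),
                                          B = c("s3","s4"),
                                          C = c("s4","s5")),
                                     paste0("s", 1:5)), 2L)
  expect_equal(sum(cs$cover$n_assigned_spacers), 5L)
  expect_equal(cs$uncovered_spacers, 0L)
  expect_false(is.unsorted(rev(cs$cover$n_assigned_spacers)))

  one <- minimal_covering_set(data.frame(spacer_id = c("s1", "s2"),
                                         ref_id = "A"))
  expect_equal(nrow(one$cover), 1L)

  empty <- minimal_covering_set(h[0, ])
  expect_equal(nrow(empty$cover), 0L)
  expect_equal(empty$uncovered_spacers, 0L)

  # exact mode agrees with greedy here and respects all_spacers universe
  ex <- minimal_covering_set(h, exact = TRUE, all_spacers = paste0("s", 1:7))
  expect_equal(nrow(ex$cover), 2L)
  expect_equal(ex$uncovered_spacers, 2L)
})

test_that("pam_summary extracts strand-aware upstream trinucleotides", {
  ref <- paste0(rand_dna_fixed15, "AAG", "ACGTACGTACGTACGTACGT", "CTT", "GG")
  refs <- data.frame(id = "r", role = "donor", seq = ref,
                     stringsAsFactors = FALSE)
  # "+" protospacer right after the AAG at 0-based [15,18)
  hp <- data.frame(ref_id = "r", start = 18L, end = 38L, strand = "+")
  expect_equal(names(pam_summary(hp, refs)$counts), "AAG")
  # "-" protospacer ending right before the CTT: context revcomp("CTT")="AAG"
  hm <- data.frame(ref_id = "r", start = 18L, end = 38L, strand = "-")
  expect_equal(names(pam_summary(hm, refs)$counts), "AAG")
  # edge hit: inextractable
  he <- data.frame(ref_id = "r", start = 1L, end = 21L, strand = "+")
  s <- pam_summary(he, refs)
  expect_equal(s$n_inextractable, 1L)
  expect_true(is.na(s$aag_fraction))
  both <- pam_summary(rbind(hp, hm, he), refs)
  expect_equal(both$aag_fraction, 1.0)
  expect_equal(both$n_extractable + both$n_inextractable, 3L)
})

test_that("annotate_hits assigns categories by >=1 bp overlap", {
  ann <- data.frame(seqid = "p1", source = "x", type = "CDS",
                    start = c(100L, 300L), end = c(200L, 400L),
                    strand = "+", attributes = "",
                    category = c("conjugation", "replication"),
                    stringsAsFactors = FALSE)
  hits <- data.frame(ref_id = "p1",
                     start = c(120L, 250L, 195L),
                     end = c(150L, 280L, 310L))
  tab <- annotate_hits(hits, ann)
  get <- function(cat) tab$n_hits[tab$category == cat]
  expect_equal(get("conjugation"), 2L)   # inside + spanning
  expect_equal(get("replication"), 1L)   # spanning hit counts in both
  expect_equal(get("intergenic"), 1L)
})

test_that("categorize_provenance partitions unique spacers", {
  mh <- data.frame(spacer_id = c("s1", "s2"))
  ph <- data.frame(spacer_id = c("s2", "s3"))
  pr <- categorize_provenance(c("s1", "s2", "s3", "s4"), mh, ph)
  expect_equal(pr$n, c(1L, 1L, 1L, 1L))
  expect_equal(sum(pr$percent), 100)
  lookup <- setNames(pr$n, pr$category)
  expect_equal(unname(lookup["both"]), 1L)
  expect_equal(unname(lookup["unmatched"]), 1L)
})

test_that("transferred-but-absent plasmids fall in plasmid_only", {
  set.seed(6)
  plasmid <- rand_dna(3000)
  meta <- data.frame(id = "contig1", role = "metagenome", seq = rand_dna(4000),
                     stringsAsFactors = FALSE)
  pdb <- data.frame(id = "plasX", role = "plasmid_db", seq = plasmid,
                    stringsAsFactors = FALSE)
  starts <- sample(2900, 20)
  sp <- setNames(substring(plasmid, starts, starts + 32), paste0("s", 1:20))
  mh <- match_to_database(sp, meta)
  ph <- match_to_database(sp, pdb)
  pr <- categorize_provenance(names(sp), mh, ph)
  expect_equal(pr$n[pr$category == "plasmid_only"], 20L)
})
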