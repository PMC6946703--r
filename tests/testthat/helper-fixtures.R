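# Small in-code fixtures.

FIX_REPEAT <- "GTGTTCCCCGCGCCAGCGGGGATAAACCG"
rand_dna_fixed15 <- "ACGGTTCAATCCGGA"

# Assemble a well-formed array read: leader + R + s1 + R + s2 + R ...
make_array_read <- function(spacers, repeat_seq = FIX_REPEAT,
                            leader = "TTGACAGCCTATTGAAACAA") {
  paste0(leader, repeat_seq, paste0(spacers, repeat_seq, collapse = ""))
}

tiny_recorder_db <- function(seed = 42L) {
  withr::with_seed(seed, {
    data.frame(id = c("recorder_genome", "recorder_plasmid"),
               role = c("recorder_genome", "recorder_plasmid"),
               seq = c(rand_dna(2000L), rand_dna(1200L)),
               stringsAsFactors = FALSE)
  })
}

mutate_seq <- function(seq, pos) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}
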