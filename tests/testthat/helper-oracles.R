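# Independent oracles used to validate the package's own algorithms.
# These deliberately re-derive results by brute force and share no code
# with the implementation paths they check.

# Exhaustive gapless local matcher: slides the query across every diagonal
# of every reference, both strands, and scores identity over aligned query
# columns / coverage as aligned query fraction (equivalent to a gapless
# Smith-Waterman with match +1 / mismatch -1 restricted to full-overlap
# maximization of (coverage, identity)).
oracle_best_match <- function(query, refs) {
  best <- NULL
  rc <- oracle_revcomp(query)
  m <- nchar(query)
  for (ri in seq_len(nrow(refs))) {
    rseq <- refs$seq[ri]
    rraw <- charToRaw(rseq)
    L <- length(rraw)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else rc
      qraw <- charToRaw(q)
      for (d in (-(m - 1L)):(L - 1L)) {      # 0-based offset of query base 1
        pos <- d + seq_len(m)
        keep <- pos >= 1L & pos <= L
        nc <- sum(keep)
        if (nc == 0L) next
        mt <- sum(qraw[keep] == rraw[pos[keep]])
        cov <- 100 * nc / m
        idt <- 100 * mt / nc
        cand <- list(ref_id = refs$id[ri], start = max(d, 0L),
                     end = min(d + m, L), strand = strand,
                     identity = idt, coverage = cov)
        if (is.null(best) ||
            cov > best$coverage ||
            (cov == best$coverage && idt > best$identity) ||
            (cov == best$coverage && idt == best$identity &&
             (cand$ref_id < best$ref_id ||
              (cand$ref_id == best$ref_id && cand$start < best$start)))) {
          best <- cand
        }
      }
    }
  }
  best
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# Exact substring hits (both strands) by brute-force scanning; used to
# check match_to_database at 100/100.
oracle_exact_hits <- function(query, refs) {
  out <- list()
  rc <- oracle_revcomp(query)
  for (ri in seq_len(nrow(refs))) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else rc
      p <- gregexpr(q, refs$seq[ri], fixed = TRUE)[[1]]
      if (p[1] == -1L) next
      for (s in p) {
        out[[length(out) + 1L]] <- data.frame(
          ref_id = refs$id[ri], start = s - 1L, end = s - 1L + nchar(q),
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

# Exhaustive Hamming occurrence scan (candidate repeat starts, 0-based).
oracle_hamming_starts <- function(seq, pat, max_mm) {
  n <- nchar(seq); m <- nchar(pat)
  if (n < m) return(integer(0))
  praw <- charToRaw(pat)
  sraw <- charToRaw(seq)
  starts <- integer(0)
  for (s in 0:(n - m)) {
    if (sum(sraw[s + seq_len(m)] != praw) <= max_mm) starts <- c(starts, s)
  }
  starts
}

# Minimum set-cover cardinality by subset enumeration over integer bit
# masks (requires <= 31 spacers and <= 20 refs).
oracle_min_cover_size <- function(sets, universe) {
  masks <- vapply(sets, function(s) {
    as.integer(sum(bitwShiftL(1L, match(s, universe) - 1L)))
  }, integer(1))
  full <- as.integer(sum(bitwShiftL(1L, seq_along(universe) - 1L)))
  nref <- length(masks)
  for (size in seq_len(nref)) {
    combs <- utils::combn(nref, size)
    for (j in seq_len(ncol(combs))) {
      acc <- 0L
      for (i in combs[, j]) acc <- bitwOr(acc, masks[i])
      if (acc == full) return(size)
    }
  }
  NA_integer_
}

# Random small set-cover instance generator.
random_cover_instance <- function(n_refs, n_spacers) {
  spacers <- paste0("s", seq_len(n_spacers))
  sets <- lapply(seq_len(n_refs), function(i) {
    k <- sample.int(n_spacers, 1L)
    sample(spacers, k)
  })
  # ensure every spacer is coverable
  missing <- setdiff(spacers, unique(unlist(sets)))
  if (length(missing) > 0L) {
    sets[[1]] <- unique(c(sets[[1]], missing))
  }
  names(sets) <- paste0("ref", seq_len(n_refs))
  hits <- do.call(rbind, lapply(names(sets), function(r) {
    data.frame(spacer_id = sets[[r]], ref_id = r, stringsAsFactors = FALSE)
  }))
  list(hits = hits, sets = sets, spacers = spacers)
}

# Plant a query inside a reference with a given number of substitutions;
# returns the mutated query (forward orientation relative to ref).
plant_query <- function(ref_seq, qlen, n_mut) {
  L <- nchar(ref_seq)
  s <- sample.int(L - qlen + 1L, 1L)
  q <- substr(ref_seq, s, s + qlen - 1L)
  if (n_mut > 0L) {
    ch <- strsplit(q, "", fixed = TRUE)[[1]]
    pos <- sample.int(qlen, n_mut)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    q <- paste(ch, collapse = "")
  }
  q
}

# Two-step driver for best_local_match, mirroring the word-size-8-then-5
# search: query at both seed lengths and keep the better result by
# (coverage, identity).  An exact 5-mer seed is guaranteed on any diagonal
# with <= 3 mismatches over >= 25 columns, so planted optima always seed.
best_of_two_seeds <- function(q, db) {
  h8 <- best_local_match(q, db, seed_k = 8)
  h5 <- best_local_match(q, db, seed_k = 5)
  if (is.null(h8)) return(h5)
  if (is.null(h5)) return(h8)
  if (h5$coverage > h8$coverage ||
      (h5$coverage == h8$coverage && h5$identity > h8$identity)) h5 else h8
}

# Chance probability that a uniformly placed protospacer (either strand)
# sits immediately 3' of an AAG on its own strand, for one reference.
oracle_aag_chance <- function(seq, len = 33L) {
  L <- nchar(seq)
  occ <- function(motif) {
    p <- gregexpr(motif, seq, fixed = TRUE)[[1]]
    p[p > 0] - 1L                        # 0-based motif starts
  }
  n_plus <- sum(occ("AAG") + 3L + len <= L)
  n_minus <- sum(occ("CTT") - len >= 0L)
  (n_plus + n_minus) / (2 * (L - len + 1L))
}

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
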