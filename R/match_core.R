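# Internal seed-and-extend matcher.
#
# Queries (spacers, ~33 nt) are matched against reference sequences by exact
# k-mer seeding followed by gapless evaluation of each seeded diagonal: the
# query is laid against the reference at the offset implied by the seed and
# identity is computed over the aligned columns.  This mirrors the semantics
# of global-over-the-query alignment tools:
#   coverage% = aligned query columns / query length * 100
#   identity% = matching columns / aligned query columns * 100
# Coverage drops below 100 only when the query overhangs a reference end.
# Both strands are always searched; minus-strand hits are reported in
# forward-reference coordinates (0-based half-open) with strand "-".

# Build a k-mer position index (1-based starts) for one sequence.
.seed_index <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(list2env(list(), hash = TRUE))
  starts <- seq_len(L - k + 1L)
  list2env(split(starts, substring(seq, starts, starts + k - 1L)),
           hash = TRUE, size = L)
}

# Database index: refs is a data.frame with columns id, seq (role optional).
# Returns a list keyed by ref id with seq, raw bytes, length and the k index.
.build_db_index <- function(refs, k) {
  refs <- as_reference_set(refs)
  out <- lapply(seq_len(nrow(refs)), function(i) {
    s <- refs$seq[i]
    list(id = refs$id[i], seq = s, raw = charToRaw(s), len = nchar(s),
         index = .seed_index(s, k), k = k)
  })
  names(out) <- refs$id
  out
}

# 0-based diagonal offsets (position of query base 1 on the reference,
# minus 1) at which at least one exact k-mer seed of `qseq` matches.
.seed_diagonals <- function(qseq, index_env, k) {
  m <- nchar(qseq)
  if (m < k) return(integer(0))
  js <- seq_len(m - k + 1L)
  seeds <- substring(qseq, js, js + k - 1L)
  ds <- vector("list", length(js))
  for (i in seq_along(js)) {
    p <- get0(seeds[i], envir = index_env, ifnotfound = NULL)
    if (!is.null(p)) ds[[i]] <- p - js[i]
  }
  unique(unlist(ds, use.names = FALSE))
}

# Evaluate diagonals D (0-based query start offsets on the reference).
# Returns aligned column count and match count per diagonal.
.align_diagonals <- function(qraw, rraw, D) {
  m <- length(qraw)
  L <- length(rraw)
  nD <- length(D)
  ncols <- integer(nD)
  matches <- integer(nD)
  interior <- D >= 0L & (D + m) <= L
  if (any(interior)) {
    Di <- D[interior]
    idx <- rep(Di, each = m) + seq_len(m)
    eq <- matrix(rraw[idx], nrow = m) == qraw
    matches[interior] <- as.integer(colSums(eq))
    ncols[interior] <- m
  }
  for (j in which(!interior)) {
    qi <- seq_len(m)
    pos <- D[j] + qi
    keep <- pos >= 1L & pos <= L
    ncols[j] <- sum(keep)
    if (ncols[j] > 0L) {
      matches[j] <- sum(qraw[qi[keep]] == rraw[pos[keep]])
    }
  }
  list(ncols = ncols, matches = matches)
}

.empty_hits <- function() {
  data.frame(spacer_id = character(0), ref_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             identity = numeric(0), coverage = numeric(0),
             stringsAsFactors = FALSE)
}

# All hits of one query against one indexed reference, on both strands,
# passing the identity/coverage thresholds.  Returns a plain list of
# parallel vectors (or NULL) to keep the hot path free of data.frame
# construction.  qraw/qrcraw are raw bytes of the query and its reverse
# complement; qseq/qrc the corresponding strings.
.query_ref_hits <- function(qseq, qrc, qraw, qrcraw, ref,
                            min_identity, min_coverage) {
  m <- nchar(qseq)
  acc_start <- integer(0); acc_end <- integer(0)
  acc_strand <- character(0); acc_id <- numeric(0); acc_cov <- numeric(0)
  strands <- c("+", "-")
  qs <- c(qseq, qrc)
  qr <- list(qraw, qrcraw)
  for (si in 1:2) {
    D <- .seed_diagonals(qs[si], ref$index, ref$k)
    if (length(D) == 0L) next
    al <- .align_diagonals(qr[[si]], ref$raw, D)
    cov <- 100 * al$ncols / m
    idt <- ifelse(al$ncols > 0L, 100 * al$matches / al$ncols, 0)
    keep <- cov >= min_coverage & idt >= min_identity & al$ncols > 0L
    if (!any(keep)) next
    D <- D[keep]
    acc_start <- c(acc_start, pmax(D, 0L))
    acc_end <- c(acc_end, pmin(D + m, ref$len))
    acc_strand <- c(acc_strand, rep(strands[si], length(D)))
    acc_id <- c(acc_id, idt[keep])
    acc_cov <- c(acc_cov, cov[keep])
  }
  if (length(acc_start) == 0L) return(NULL)
  list(start = acc_start, end = acc_end, strand = acc_strand,
       identity = acc_id, coverage = acc_cov)
}

# All hits of many queries against a database index.  `queries` is a named
# character vector (names become spacer_id).  Deterministic ordering:
# (spacer input order, ref index order, start, strand "+" first).
.match_queries <- function(queries, db_idx, min_identity, min_coverage) {
  if (length(queries) == 0L) return(.empty_hits())
  ids <- names(queries)
  if (is.null(ids)) ids <- as.character(seq_along(queries))
  qrc <- revcomp(queries)
  sp <- list(); rf <- list(); st <- list(); en <- list()
  sd <- list(); idv <- list(); cv <- list()
  n_out <- 0L
  for (i in seq_along(queries)) {
    qraw <- charToRaw(queries[[i]])
    qrcraw <- charToRaw(qrc[[i]])
    for (r in seq_along(db_idx)) {
      h <- .query_ref_hits(queries[[i]], qrc[[i]], qraw, qrcraw, db_idx[[r]],
                           min_identity, min_coverage)
      if (is.null(h)) next
      ord <- order(h$start, h$strand)
      n_out <- n_out + 1L
      nh <- length(h$start)
      sp[[n_out]] <- rep(ids[i], nh)
      rf[[n_out]] <- rep(db_idx[[r]]$id, nh)
      st[[n_out]] <- h$start[ord]
      en[[n_out]] <- h$end[ord]
      sd[[n_out]] <- h$strand[ord]
      idv[[n_out]] <- h$identity[ord]
      cv[[n_out]] <- h$coverage[ord]
    }
  }
  if (n_out == 0L) return(.empty_hits())
  res <- data.frame(
    spacer_id = unlist(sp), ref_id = unlist(rf),
    start = unlist(st), end = unlist(en), strand = unlist(sd),
    identity = unlist(idv), coverage = unlist(cv),
    stringsAsFactors = FALSE)
  res <- res[order(match(res$spacer_id, ids), res$ref_id, res$start,
                   res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}
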