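# Synthetic spacer-acquisition recording experiments.
#
# The generator emulates amplicon sequencing of the CRISPR array of a
# recording strain after exposure to donor DNA: a configurable fraction of
# arrays is expanded with new spacers drawn from donor (exogenous) or
# recorder (endogenous) sequences, with an AAG PAM bias and an optional
# acquisition hotspot, then reads are emitted with i.i.d. substitution
# errors and a ground-truth manifest.

# Canonical E. coli K-12 Type I-E direct repeat (29 bp).
.DEFAULT_REPEAT <- "GTGTTCCCCGCGCCAGCGGGGATAAACCG"

#' Configuration of a synthetic recording experiment
#'
#' Defaults reflect a 6-h single-donor conjugation recording: ~1% of arrays
#' expanded, 30-40% of new spacers exogenous, and an AAG PAM preceding about
#' half of all acquisitions.
#'
#' @param seed integer RNG seed; every downstream stage derives its stream
#'   from it, so a config fully determines the experiment.
#' @param n_reads number of sequenced arrays (reads) to emit.
#' @param expansion_rate fraction of arrays carrying at least one new
#'   spacer.  Enforced exactly: `round(n_reads * expansion_rate)` reads are
#'   expanded.
#' @param exogenous_fraction probability that a new spacer derives from a
#'   donor reference rather than the recorder genome/plasmid.
#' @param pam_bias probability that a new spacer is drawn immediately 3' of
#'   an AAG site (on the protospacer strand).
#' @param multi_acquisition_prob probability that an expanded array carries
#'   two new spacers instead of one.
#' @param hotspot optional `list(ref_id=, start=, end=, weight=)`: positions
#'   inside the 0-based half-open interval are sampled at `weight` times the
#'   per-base rate of the rest of that reference.
#' @param error_rate per-base substitution probability applied to reads.
#' @param spacer_len_mean,spacer_len_sd spacer length distribution
#'   (truncated normal, rounded, clipped to `spacer_len_bounds`).
#' @param spacer_len_bounds inclusive length bounds for a valid spacer.
#' @param repeat_seq direct-repeat sequence flanking every spacer.
#' @param leader_len length of the leader stub 5' of the first repeat.
#' @param parental_spacers ordered parental spacers of the unexpanded
#'   array; `NULL` generates `n_parental` random 33-mers from `seed`.
#' @param n_parental number of parental spacers when generating defaults.
#' @param genome_len,plasmid_len lengths of the recorder genome surrogate
#'   (>= 10 kb) and recording plasmid surrogate (>= 1 kb).
#' @param donor_lens named integer vector of donor reference lengths
#'   (>= 1 kb each).
#' @param donor_ids donor ids flagged as transferable; new exogenous
#'   spacers are drawn only from these.  Default: all donors.
#' @param plasmid_weight recorder plasmid:genome weight for endogenous
#'   acquisitions (default 10:1, reflecting the preference for high-copy
#'   replicative plasmids).
#' @return a validated object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_reads = 200, expansion_rate = 0.05)
#' cfg$parental_spacers
sim_config <- function(seed = 1L,
                       n_reads = 10000L,
                       expansion_rate = 0.01,
                       exogenous_fraction = 0.35,
                       pam_bias = 0.5,
                       multi_acquisition_prob = 0.05,
                       hotspot = NULL,
                       error_rate = 0,
                       spacer_len_mean = 33,
                       spacer_len_sd = 1,
                       spacer_len_bounds = c(25L, 45L),
                       repeat_seq = .DEFAULT_REPEAT,
                       leader_len = 20L,
                       parental_spacers = NULL,
                       n_parental = 2L,
                       genome_len = 20000L,
                       plasmid_len = 3000L,
                       donor_lens = c(donor1 = 5000L),
                       donor_ids = NULL,
                       plasmid_weight = 10) {
  seed <- as.integer(seed)
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads <= 0L) stop("n_reads must be > 0", call. = FALSE)
  .assert_fraction(expansion_rate, "expansion_rate")
  .assert_fraction(exogenous_fraction, "exogenous_fraction")
  .assert_fraction(pam_bias, "pam_bias")
  .assert_fraction(multi_acquisition_prob, "multi_acquisition_prob")
  .assert_fraction(error_rate, "error_rate")
  repeat_seq <- toupper(repeat_seq)
  if (!.is_dna(repeat_seq) || nchar(repeat_seq) < 8L) {
    stop("repeat_seq must be ACGT-only and at least 8 bp", call. = FALSE)
  }
  if (length(spacer_len_bounds) != 2L || spacer_len_bounds[1] > spacer_len_bounds[2]) {
    stop("spacer_len_bounds must be c(lo, hi) with lo <= hi", call. = FALSE)
  }
  if (any(!is.finite(donor_lens)) || any(donor_lens < 1000L)) {
    stop("donor reference lengths must be >= 1000 bp", call. = FALSE)
  }
  if (is.null(names(donor_lens)) || any(names(donor_lens) == "")) {
    names(donor_lens) <- paste0("donor", seq_along(donor_lens))
  }
  if (genome_len < 10000L) stop("genome_len must be >= 10 kb", call. = FALSE)
  if (plasmid_len < 1000L) stop("plasmid_len must be >= 1 kb", call. = FALSE)
  if (is.null(donor_ids)) donor_ids <- names(donor_lens)
  if (!all(donor_ids %in% names(donor_lens))) {
    stop("donor_ids must be a subset of names(donor_lens)", call. = FALSE)
  }
  if (!is.null(hotspot)) {
    need <- c("ref_id", "start", "end", "weight")
    if (!is.list(hotspot) || !all(need %in% names(hotspot))) {
      stop("hotspot must be list(ref_id=, start=, end=, weight=)", call. = FALSE)
    }
    if (hotspot$weight <= 0) stop("hotspot weight must be > 0", call. = FALSE)
  }
  if (is.null(parental_spacers)) {
    parental_spacers <- withr::with_seed(seed, random_dna(n_parental, 33L))
  }
  if (length(parental_spacers) < 1L || any(!vapply(parental_spacers, .is_dna, logical(1)))) {
    stop("parental_spacers must be one or more ACGT strings", call. = FALSE)
  }
  cfg <- list(seed = seed, n_reads = n_reads,
              expansion_rate = expansion_rate,
              exogenous_fraction = exogenous_fraction,
              pam_bias = pam_bias,
              multi_acquisition_prob = multi_acquisition_prob,
              hotspot = hotspot, error_rate = error_rate,
              spacer_len_mean = spacer_len_mean,
              spacer_len_sd = spacer_len_sd,
              spacer_len_bounds = as.integer(spacer_len_bounds),
              repeat_seq = repeat_seq,
              leader_len = as.integer(leader_len),
              parental_spacers = unname(parental_spacers),
              genome_len = as.integer(genome_len),
              plasmid_len = as.integer(plasmid_len),
              donor_lens = donor_lens,
              donor_ids = donor_ids,
              plasmid_weight = plasmid_weight)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic recording config\n")
  cat(sprintf("  reads: %d  expansion: %.4g  exogenous: %.4g  pam_bias: %.4g\n",
              x$n_reads, x$expansion_rate, x$exogenous_fraction, x$pam_bias))
  cat(sprintf("  donors: %s  error rate: %.4g  seed: %d\n",
              paste(names(x$donor_lens), collapse = ","), x$error_rate, x$seed))
  invisible(x)
}

#' Simulate recorder and donor reference sequences
#'
#' Generates a recorder genome surrogate, a recording plasmid surrogate and
#' the configured donor references.  All pairs of distinct references are
#' checked to share no 16-mer (either strand); offending donors are
#' resampled, so recorder and donor sets are non-homologous by
#' construction.  Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return reference-set `data.frame` (`id`, `role`, `seq`).
#' @export
simulate_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    genome <- random_dna(1L, config$genome_len)
    plasmid <- random_dna(1L, config$plasmid_len)
    donors <- random_dna(length(config$donor_lens), config$donor_lens)
    names(donors) <- names(config$donor_lens)
    # enforce pairwise non-homology (no shared 16-mer on either strand)
    for (attempt in 1:20) {
      seqs <- c(recorder_genome = genome, recorder_plasmid = plasmid, donors)
      bad <- character(0)
      for (i in seq_along(donors)) {
        others <- seqs[names(seqs) != names(donors)[i]]
        if (any(vapply(others, function(o) .shares_kmer(donors[[i]], o), logical(1)))) {
          bad <- c(bad, names(donors)[i])
        }
      }
      if (.shares_kmer(plasmid, genome)) {
        plasmid <- random_dna(1L, config$plasmid_len)
        next
      }
      if (length(bad) == 0L) break
      donors[bad] <- random_dna(length(bad), config$donor_lens[bad])
    }
    data.frame(
      id = c("recorder_genome", "recorder_plasmid", names(donors)),
      role = c("recorder_genome", "recorder_plasmid",
               rep("donor", length(donors))),
      seq = c(genome, plasmid, unname(donors)),
      stringsAsFactors = FALSE)
  })
}

# AAG-adjacent protospacer start positions (0-based) for one reference and
# strand.  On "+" the protospacer begins right after a forward AAG; on "-"
# the protospacer (forward interval [start, start+len)) ends right before a
# forward CTT, i.e. the AAG sits 5' of the protospacer on the minus strand.
.pam_starts <- function(seq, strand, len) {
  L <- nchar(seq)
  motif <- if (strand == "+") "AAG" else "CTT"
  occ <- .hamming_scan(seq, motif)
  pos0 <- which(occ == 0L) - 1L           # 0-based motif starts
  if (strand == "+") {
    st <- pos0 + 3L
    st[st + len <= L]
  } else {
    st <- pos0 - len
    st[st >= 0L]
  }
}

# Per-base sampling weights for protospacer starts on `ref_id` (length nmax
# = number of admissible starts); hotspot interval gets weight * multiplier.
.start_weights <- function(starts0, ref_id, hotspot) {
  w <- rep(1, length(starts0))
  if (!is.null(hotspot) && identical(hotspot$ref_id, ref_id)) {
    inside <- starts0 >= hotspot$start & starts0 < hotspot$end
    w[inside] <- hotspot$weight
  }
  w
}

#' Simulate spacer-acquisition events
#'
#' Assigns new-spacer acquisition events to exactly
#' `round(n_reads * expansion_rate)` reads.  Each event independently draws
#' exogenous vs endogenous source (Bernoulli `exogenous_fraction`), strand,
#' spacer length, and a protospacer start that respects the AAG PAM bias
#' and the optional hotspot.
#'
#' @param config a [sim_config()].
#' @param refs references from [simulate_references()].
#' @return `data.frame` with one row per event: `read_id`, `source_ref_id`,
#'   `start`, `end` (0-based half-open), `strand`, `pam` (trinucleotide 5'
#'   of the protospacer on its own strand, `NA` at reference edges),
#'   `is_exogenous`, `spacer_seq`.
#' @export
simulate_acquisitions <- function(config, refs) {
  stopifnot(inherits(config, "sim_config"))
  refs <- as_reference_set(refs)
  seqs <- .ref_vector(refs)
  if (!is.null(config$hotspot)) {
    hs <- config$hotspot
    if (!hs$ref_id %in% names(seqs) ||
        hs$start < 0 || hs$end > nchar(seqs[[hs$ref_id]]) || hs$start >= hs$end) {
      stop("hotspot interval outside reference", call. = FALSE)
    }
  }
  n_exp <- round(config$n_reads * config$expansion_rate)
  read_ids <- sprintf("read_%06d", seq_len(config$n_reads))
  if (n_exp == 0L) {
    return(data.frame(read_id = character(0), source_ref_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), pam = character(0),
                      is_exogenous = logical(0), spacer_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  donor_ids <- config$donor_ids
  donor_w <- config$donor_lens[donor_ids]
  rec_ids <- c("recorder_genome", "recorder_plasmid")
  rec_w <- c(1, config$plasmid_weight)
  withr::with_seed(config$seed + 1L, {
    expanded <- sort(sample.int(config$n_reads, n_exp))
    n_new <- 1L + stats::rbinom(n_exp, 1L, config$multi_acquisition_prob)
    total <- sum(n_new)
    ev_read <- rep(read_ids[expanded], n_new)
    is_exo <- stats::runif(total) < config$exogenous_fraction
    src <- character(total)
    if (any(is_exo)) {
      src[is_exo] <- sample(donor_ids, sum(is_exo), replace = TRUE,
                            prob = donor_w)
    }
    if (any(!is_exo)) {
      src[!is_exo] <- sample(rec_ids, sum(!is_exo), replace = TRUE,
                             prob = rec_w)
    }
    len <- as.integer(round(stats::rnorm(total, config$spacer_len_mean,
                                         config$spacer_len_sd)))
    len <- pmin(pmax(len, config$spacer_len_bounds[1]), config$spacer_len_bounds[2])
    strand <- sample(c("+", "-"), total, replace = TRUE)
    pam_draw <- stats::runif(total) < config$pam_bias
    # cache motif positions (0-based) per reference and strand
    motif_pos <- list()
    for (id in unique(src)) {
      motif_pos[[paste0(id, "+")]] <- which(.hamming_scan(seqs[[id]], "AAG") == 0L) - 1L
      motif_pos[[paste0(id, "-")]] <- which(.hamming_scan(seqs[[id]], "CTT") == 0L) - 1L
    }
    hs <- config$hotspot
    start <- integer(total)
    for (i in seq_len(total)) {
      L <- nchar(seqs[[src[i]]])
      hot <- !is.null(hs) && identical(hs$ref_id, src[i])
      cand <- NULL
      if (pam_draw[i]) {
        pos0 <- motif_pos[[paste0(src[i], strand[i])]]
        cand <- if (strand[i] == "+") pos0 + 3L else pos0 - len[i]
        cand <- cand[cand >= 0L & cand + len[i] <= L]
        if (length(cand) == 0L) cand <- NULL
      }
      if (is.null(cand)) {
        if (!hot) {                       # uniform fast path
          start[i] <- sample.int(L - len[i] + 1L, 1L) - 1L
          next
        }
        cand <- 0:(L - len[i])
      }
      if (hot) {
        w <- .start_weights(cand, src[i], hs)
        start[i] <- if (length(cand) == 1L) cand else sample(cand, 1L, prob = w)
      } else {
        start[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
      }
    }
    end <- start + len
    fwd <- substring(seqs[src], start + 1L, end)
    spacer <- ifelse(strand == "+", fwd, revcomp(fwd))
    pam <- .pam_context(seqs, src, start, end, strand)
    data.frame(read_id = ev_read, source_ref_id = src,
               start = start, end = end, strand = strand, pam = pam,
               is_exogenous = is_exo, spacer_seq = spacer,
               stringsAsFactors = FALSE)
  })
}

# PAM trinucleotide 5' of the protospacer on the protospacer strand, NA when
# the context would run off the reference.
.pam_context <- function(seqs, src, start, end, strand) {
  L <- nchar(seqs[src])
  pam <- rep(NA_character_, length(src))
  plus <- strand == "+" & start >= 3L
  pam[plus] <- substring(seqs[src[plus]], start[plus] - 2L, start[plus])
  minus <- strand == "-" & (end + 3L) <= L
  if (any(minus)) {
    pam[minus] <- revcomp(substring(seqs[src[minus]], end[minus] + 1L,
                                    end[minus] + 3L))
  }
  pam
}

#' Simulate amplicon reads of CRISPR arrays
#'
#' Builds one read per array: leader stub, then new spacers
#' (leader-proximal first) and parental spacers, each flanked by the direct
#' repeat; applies i.i.d. substitutions at `error_rate`.
#'
#' @param config a [sim_config()].
#' @param refs references from [simulate_references()] (unused for read
#'   construction but validated against `events`).
#' @param events events from [simulate_acquisitions()].
#' @return list with `reads` (`data.frame`: `read_id`, `seq`), `manifest`
#'   (the events, i.e. ground truth per read) and `leader` (the leader stub
#'   sequence).
#' @export
simulate_reads <- function(config, refs, events) {
  stopifnot(inherits(config, "sim_config"))
  refs <- as_reference_set(refs)
  if (nrow(events) > 0 && !all(events$source_ref_id %in% refs$id)) {
    stop("events reference unknown source ids", call. = FALSE)
  }
  R <- config$repeat_seq
  read_ids <- sprintf("read_%06d", seq_len(config$n_reads))
  parental_unit <- paste0(paste0(config$parental_spacers, R, collapse = ""))
  withr::with_seed(config$seed + 2L, {
    leader <- random_dna(1L, config$leader_len)
    new_by_read <- split(events$spacer_seq, factor(events$read_id, levels = read_ids))
    new_part <- vapply(new_by_read, function(s) {
      if (length(s) == 0L) "" else paste0(s, R, collapse = "")
    }, character(1))
    seqs <- paste0(leader, R, new_part, parental_unit)
    if (config$error_rate > 0) {
      lens <- nchar(seqs)
      nerr <- stats::rbinom(length(seqs), lens, config$error_rate)
      for (i in which(nerr > 0L)) {
        pos <- sample.int(lens[i], nerr[i])
        ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        for (p in pos) {
          ch[p] <- sample(setdiff(.DNA_BASES, ch[p]), 1L)
        }
        seqs[i] <- paste(ch, collapse = "")
      }
    }
    list(reads = data.frame(read_id = read_ids, seq = seqs,
                            stringsAsFactors = FALSE),
         manifest = events,
         leader = leader)
  })
}

#' Run a complete synthetic recording experiment
#'
#' Convenience wrapper chaining [simulate_references()],
#' [simulate_acquisitions()] and [simulate_reads()]; optionally writes
#' `reads.fastq`, `refs.fasta`, `truth.tsv` and `config.json` to a
#' directory.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory.
#' @return list with `config`, `refs`, `events`, `reads`, `manifest`,
#'   `leader`.
#' @export
#' @examples
#' rec <- simulate_recording(sim_config(seed = 7, n_reads = 50,
#'                                      expansion_rate = 0.1))
#' nrow(rec$manifest)
simulate_recording <- function(config, dir = NULL) {
  refs <- simulate_references(config)
  events <- simulate_acquisitions(config, refs)
  rd <- simulate_reads(config, refs, events)
  out <- list(config = config, refs = refs, events = events,
              reads = rd$reads, manifest = rd$manifest, leader = rd$leader)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fastq(stats::setNames(rd$reads$seq, rd$reads$read_id),
                file.path(dir, "reads.fastq"))
    write_fasta(.ref_vector(refs), file.path(dir, "refs.fasta"))
    man <- rd$manifest
    names(man)[names(man) == "source_ref_id"] <- "source_ref"
    utils::write.table(man, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg <- unclass(config)
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}
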