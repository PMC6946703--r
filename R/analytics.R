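# Quantitative read-outs of a recording experiment: normalized spacer
# mapping, window coverage, sample-level HGT calls, minimal covering
# plasmid sets, PAM summaries, annotation categories and provenance.

#' Normalized spacer mapping per reference
#'
#' Spacers per kb of reference per 1000 exogenous spacers, a
#' semi-quantitative proxy for relative transfer frequency.  Each spacer is
#' counted once per (spacer, reference) pair; references with zero spacers
#' are reported explicitly with value 0 and `zero = TRUE`.
#'
#' @param hits filtered hit `data.frame` (after [filter_multi_mapping()]).
#' @param ref_len_by_id named vector of reference lengths in bp.
#' @param total_exogenous total number of exogenous spacers in the sample
#'   (the normalization denominator); must be >= 1.
#' @return `data.frame`: `ref_id`, `ref_len`, `n_spacers`,
#'   `normalized_spacer_mapping`, `zero`.
#' @export
#' @examples
#' normalized_spacer_mapping(
#'   data.frame(spacer_id = paste0("s", 1:50), ref_id = "p1"),
#'   c(p1 = 5000), total_exogenous = 2000)
normalized_spacer_mapping <- function(hits, ref_len_by_id, total_exogenous) {
  if (total_exogenous < 1) {
    stop("total_exogenous must be >= 1", call. = FALSE)
  }
  if (any(ref_len_by_id <= 0)) stop("reference lengths must be > 0", call. = FALSE)
  pairs <- unique(hits[, c("spacer_id", "ref_id")])
  counts <- table(factor(pairs$ref_id, levels = names(ref_len_by_id)))
  n <- as.integer(counts)
  data.frame(ref_id = names(ref_len_by_id),
             ref_len = unname(ref_len_by_id),
             n_spacers = n,
             normalized_spacer_mapping =
               (n / (unname(ref_len_by_id) / 1000)) / (total_exogenous / 1000),
             zero = n == 0L,
             stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Mean per-bp spacer coverage in fixed windows
#'
#' Per-base depth is the number of hit intervals covering the base; each
#' window's value is the mean depth over its own bases, so a hit spanning a
#' boundary contributes proportionally to both windows and the final
#' partial window is averaged over its own length.
#'
#' @param hits hit `data.frame` with 0-based half-open `start`, `end`
#'   (single reference; filter beforehand).
#' @param ref_len reference length in bp.
#' @param window window size in bp (default 200).
#' @return `data.frame`: `win_start`, `win_end`, `mean_depth`.
#' @export
window_coverage <- function(hits, ref_len, window = 200L) {
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  ref_len <- as.integer(ref_len)
  s <- pmax(as.integer(hits$start), 0L)
  e <- pmin(as.integer(hits$end), ref_len)
  delta <- tabulate(s + 1L, nbins = ref_len + 1L) -
    tabulate(e + 1L, nbins = ref_len + 1L)
  depth <- cumsum(delta)[seq_len(ref_len)]
  win <- (seq_len(ref_len) - 1L) %/% as.integer(window)
  mean_depth <- as.numeric(tapply(depth, win, mean))
  ws <- sort(unique(win)) * as.integer(window)
  data.frame(win_start = ws,
             win_end = pmin(ws + as.integer(window), ref_len),
             mean_depth = mean_depth,
             row.names = NULL)
}

#' Sample-level HGT call
#'
#' A sample is HGT-positive when at least `min_spacers` unique exogenous
#' spacers were identified AND the percentage of exogenous spacers is at
#' least `fold` times the no-donor control percentage (default 3 x 0.03% =
#' an effective threshold of 0.09%).
#'
#' @param sample_id sample label.
#' @param n_arrays number of sequenced arrays considered.
#' @param percent_exogenous percent of spacers classified exogenous.
#' @param n_unique_exogenous number of unique exogenous spacers.
#' @param control_percent no-donor control exogenous percentage (protocol
#'   dependent; must be supplied deliberately, default 0.03).
#' @param min_spacers minimum unique exogenous spacers (default 10).
#' @param fold required fold-change over the control (default 3).
#' @return one-row `data.frame` including `effective_threshold_percent` and
#'   the boolean `is_hgt_positive`.
#' @export
#' @examples
#' call_sample("FS01", 1e6, 0.10, 12)
call_sample <- function(sample_id, n_arrays, percent_exogenous,
                        n_unique_exogenous, control_percent = 0.03,
                        min_spacers = 10L, fold = 3) {
  if (control_percent < 0) stop("control_percent must be >= 0", call. = FALSE)
  thr <- fold * control_percent
  data.frame(sample_id = sample_id,
             n_arrays = n_arrays,
             percent_exogenous = percent_exogenous,
             n_unique_exogenous = n_unique_exogenous,
             control_percent = control_percent,
             min_spacers = as.integer(min_spacers),
             fold = fold,
             effective_threshold_percent = thr,
             is_hgt_positive = (n_unique_exogenous >= min_spacers) &
               (percent_exogenous >= thr),
             stringsAsFactors = FALSE)
}

# exact minimum set cover by subset enumeration over <= 20 refs
.exact_cover <- function(sets, universe) {
  nref <- length(sets)
  if (nref > 20L) stop("exact cover limited to <= 20 references", call. = FALSE)
  masks <- vapply(sets, function(s) {
    sum(2^(match(s, universe) - 1L))
  }, numeric(1))
  full <- sum(2^(seq_along(universe) - 1L))
  best <- NULL
  for (size in seq_len(nref)) {
    combs <- utils::combn(nref, size)
    for (j in seq_len(ncol(combs))) {
      sel <- combs[, j]
      # numeric OR via repeated bit arithmetic on doubles (<= 2^53 safe)
      acc <- 0
      for (i in sel) acc <- acc + masks[i] - .bit_and(acc, masks[i])
      if (acc == full) {
        best <- sel
        break
      }
    }
    if (!is.null(best)) break
  }
  best
}

# AND of two non-negative doubles interpreted as bit masks
.bit_and <- function(a, b) {
  res <- 0
  bit <- 1
  while (a > 0 && b > 0) {
    if (a %% 2 >= 1 && b %% 2 >= 1) res <- res + bit
    a <- a %/% 2
    b <- b %/% 2
    bit <- bit * 2
  }
  res
}

#' Minimal covering reference set
#'
#' Finds a small set of references that together cover every spacer with at
#' least one hit, by greedy set cover: repeatedly pick the reference
#' covering the most uncovered spacers (ties by longer reference when
#' lengths are supplied, then lexicographic id).  Each spacer is assigned
#' to the reference that first covered it; rows are re-sorted by assigned
#' spacers, descending.  `exact = TRUE` switches to exhaustive enumeration
#' (<= 20 references).
#'
#' @param hits hit `data.frame` (`spacer_id`, `ref_id`).
#' @param ref_len_by_id optional named lengths used for tie-breaking.
#' @param all_spacers optional universe of spacer ids; spacers without hits
#'   are counted as `uncovered`.
#' @param exact use exhaustive minimum cover instead of greedy.
#' @return object of class `cover_set`: list with `cover` (`data.frame`:
#'   `ref_id`, `n_assigned_spacers`, `cumulative_covered`) and
#'   `uncovered_spacers`.
#' @export
#' @examples
#' h <- data.frame(spacer_id = c("s1","s2","s3","s3","s4","s4","s5"),
#'                 ref_id    = c("A","A","A","B","B","C","C"))
#' minimal_covering_set(h)
minimal_covering_set <- function(hits, ref_len_by_id = NULL,
                                 all_spacers = NULL, exact = FALSE) {
  empty <- data.frame(ref_id = character(0), n_assigned_spacers = integer(0),
                      cumulative_covered = integer(0), stringsAsFactors = FALSE)
  spacers <- unique(hits$spacer_id)
  uncovered_extra <- if (is.null(all_spacers)) 0L else
    length(setdiff(all_spacers, spacers))
  if (length(spacers) == 0L) {
    return(structure(list(cover = empty, uncovered_spacers = uncovered_extra),
                     class = "cover_set"))
  }
  sets <- lapply(split(hits$spacer_id, hits$ref_id), unique)
  ref_ids <- names(sets)
  lens <- if (is.null(ref_len_by_id)) stats::setNames(rep(0, length(ref_ids)), ref_ids)
          else ref_len_by_id[ref_ids]
  lens[is.na(lens)] <- 0
  if (exact) {
    sel <- .exact_cover(sets, spacers)
    chosen <- ref_ids[sel]
    # assignment order: larger sets first for a stable presentation
    chosen <- chosen[order(-vapply(sets[chosen], length, integer(1)),
                           -lens[chosen], chosen)]
  } else {
    chosen <- character(0)
    left <- spacers
    while (length(left) > 0L) {
      gain <- vapply(sets, function(s) length(intersect(s, left)), integer(1))
      if (max(gain) == 0L) break
      cand <- ref_ids[gain == max(gain)]
      pick <- cand[order(-lens[cand], cand)][1]
      chosen <- c(chosen, pick)
      left <- setdiff(left, sets[[pick]])
    }
  }
  assigned <- list()
  covered <- character(0)
  for (r in chosen) {
    assigned[[r]] <- setdiff(sets[[r]], covered)
    covered <- c(covered, assigned[[r]])
  }
  n_assigned <- vapply(assigned, length, integer(1))
  ord <- order(-n_assigned, names(assigned))
  cover <- data.frame(ref_id = names(assigned)[ord],
                      n_assigned_spacers = unname(n_assigned[ord]),
                      stringsAsFactors = FALSE)
  cover$cumulative_covered <- cumsum(cover$n_assigned_spacers)
  structure(list(cover = cover,
                 uncovered_spacers = uncovered_extra +
                   length(setdiff(spacers, covered))),
            class = "cover_set")
}

#' @export
print.cover_set <- function(x, ...) {
  cat(sprintf("Minimal covering set: %d reference(s), %d spacer(s) uncovered\n",
              nrow(x$cover), x$uncovered_spacers))
  print(x$cover, row.names = FALSE)
  invisible(x)
}

#' PAM context summary of protospacer hits
#'
#' For each hit, extracts the trinucleotide immediately 5' of the
#' protospacer on the protospacer strand (reverse-complemented context for
#' minus-strand hits).  Hits whose context would run off the reference are
#' skipped and counted as inextractable.
#'
#' @param hits hit `data.frame` (`ref_id`, `start`, `end`, `strand`).
#' @param refs reference set containing the hit references.
#' @return list: `counts` (named, descending), `aag_fraction`,
#'   `n_extractable`, `n_inextractable`.
#' @export
pam_summary <- function(hits, refs) {
  seqs <- .ref_vector(refs)
  if (nrow(hits) == 0L) {
    return(list(counts = integer(0), aag_fraction = NA_real_,
                n_extractable = 0L, n_inextractable = 0L))
  }
  if (!all(hits$ref_id %in% names(seqs))) {
    stop("hits reference ids absent from refs", call. = FALSE)
  }
  pam <- .pam_context(seqs, hits$ref_id, hits$start, hits$end, hits$strand)
  ok <- !is.na(pam)
  counts <- sort(table(pam[ok]), decreasing = TRUE)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       aag_fraction = if (any(ok)) mean(pam[ok] == "AAG") else NA_real_,
       n_extractable = sum(ok),
       n_inextractable = sum(!ok))
}

#' Count hits per functional annotation category
#'
#' A hit overlapping (by >= 1 bp) an annotated feature inherits the
#' feature's category; hits overlapping no feature count as `intergenic`;
#' a hit spanning several features counts once per feature.
#'
#' @param hits hit `data.frame` (`ref_id`, `start`, `end`; 0-based
#'   half-open).
#' @param annotations annotation `data.frame` from [read_gff3()] (columns
#'   `seqid`, `start`, `end` 0-based half-open, `category`).
#' @return `data.frame` (`category`, `n_hits`) sorted descending.
#' @export
annotate_hits <- function(hits, annotations) {
  cats <- character(0)
  for (rid in unique(hits$ref_id)) {
    h <- hits[hits$ref_id == rid, , drop = FALSE]
    a <- annotations[annotations$seqid == rid, , drop = FALSE]
    if (nrow(a) == 0L) {
      cats <- c(cats, rep("intergenic", nrow(h)))
      next
    }
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(h$start + 1L, h$end),
      IRanges::IRanges(a$start + 1L, a$end))
    qh <- S4Vectors::queryHits(ov)
    cats <- c(cats, a$category[S4Vectors::subjectHits(ov)],
              rep("intergenic", sum(!seq_len(nrow(h)) %in% qh)))
  }
  tab <- sort(table(cats), decreasing = TRUE)
  data.frame(category = names(tab), n_hits = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Provenance categories of exogenous spacers
#'
#' Classifies each unique spacer by where it matched: metagenomic contigs
#' only, both databases, plasmid database only, or neither (`unmatched`).
#' Categories partition the spacers, so percentages sum to 100.
#'
#' @param spacer_ids unique exogenous spacer ids (the universe).
#' @param metagenome_hits,plasmid_hits hit tables from
#'   [match_to_database()] against the two databases (same threshold).
#' @return `data.frame`: `category`, `n`, `percent`.
#' @export
categorize_provenance <- function(spacer_ids, metagenome_hits, plasmid_hits) {
  spacer_ids <- unique(spacer_ids)
  in_m <- spacer_ids %in% metagenome_hits$spacer_id
  in_p <- spacer_ids %in% plasmid_hits$spacer_id
  cat <- ifelse(in_m & in_p, "both",
         ifelse(in_m, "metagenome_only",
         ifelse(in_p, "plasmid_only", "unmatched")))
  lev <- c("metagenome_only", "both", "plasmid_only", "unmatched")
  tab <- table(factor(cat, levels = lev))
  data.frame(category = lev, n = as.integer(tab),
             percent = 100 * as.integer(tab) / max(length(spacer_ids), 1L),
             stringsAsFactors = FALSE)
}
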