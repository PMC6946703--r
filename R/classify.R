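# Endogenous/exogenous spacer classification.
#
# New spacers are filtered against the recorder genome and recording
# plasmid with a two-step homology search: a sensitive-enough first pass
# (seed length 8), then a rescue pass at seed length 5 for spacers with no
# accepted first-pass hit.  A spacer is endogenous if any hit reaches both
# the identity and the coverage threshold (>= 80/80 by default); everything
# else is exogenous, i.e. candidate transferred DNA.

#' Best gapless local match of a short query against a database
#'
#' Seed-and-extend matching (exact seeds of length `seed_k`, gapless
#' diagonal evaluation, both strands).  Identity is computed over aligned
#' query columns and coverage as the aligned fraction of the query; the hit
#' maximizing `(coverage, identity)` is returned, ties broken by lowest
#' reference id then lowest start.
#'
#' @param query query sequence (length >= `seed_k`).
#' @param db reference set (see [as_reference_set()]).
#' @param seed_k exact seed length.
#' @return one-row `data.frame` (`ref_id`, `start`, `end`, `strand`,
#'   `identity`, `coverage`) or `NULL` when nothing seeds.
#' @export
#' @examples
#' db <- c(ref1 = "TTTTTTTTTTACGTACGTACGTACGTTTTTTTTTT")
#' best_local_match("ACGTACGTACGTACGT", db, seed_k = 8)
best_local_match <- function(query, db, seed_k = 8L) {
  if (nchar(query) < seed_k) {
    stop("query shorter than seed_k", call. = FALSE)
  }
  db <- as_reference_set(db)
  if (nrow(db) == 0L) return(NULL)
  idx <- .build_db_index(db, seed_k)
  hits <- .match_queries(c(q = query), idx, min_identity = 0, min_coverage = 0)
  if (nrow(hits) == 0L) return(NULL)
  ord <- order(-hits$coverage, -hits$identity, hits$ref_id, hits$start)
  out <- hits[ord[1], c("ref_id", "start", "end", "strand",
                        "identity", "coverage")]
  rownames(out) <- NULL
  out
}

#' Two-step endogenous filter against the recorder references
#'
#' Pass 1 searches with seed length `seed_steps[1]`; spacers without an
#' accepted hit are re-queried with the more sensitive seed length
#' `seed_steps[2]`.  A spacer is classified `endogenous` iff some hit
#' satisfies identity >= `id_threshold` AND coverage >= `cov_threshold`;
#' otherwise `exogenous`.
#'
#' @param spacers character vector of new-spacer sequences (optionally
#'   named) or a `data.frame` with column `seq`.
#' @param recorder_db reference set containing the recorder genome and
#'   recording plasmid.
#' @param id_threshold,cov_threshold percent thresholds in (0, 100].
#' @param seed_steps two exact seed lengths, first pass then rescue pass.
#' @return `data.frame`: `seq`, `classification` (`endogenous` /
#'   `exogenous`), `best_recorder_identity`, `best_recorder_coverage`
#'   (`NA` for spacers with no accepted hit, as for the non-hit output of
#'   identity-thresholded search tools).
#' @export
two_step_endogenous_filter <- function(spacers, recorder_db,
                                       id_threshold = 80, cov_threshold = 80,
                                       seed_steps = c(8L, 5L)) {
  if (is.data.frame(spacers)) spacers <- spacers$seq
  spacers <- as.character(spacers)
  if (any(c(id_threshold, cov_threshold) <= 0) ||
      any(c(id_threshold, cov_threshold) > 100)) {
    stop("thresholds must lie in (0, 100]", call. = FALSE)
  }
  recorder_db <- as_reference_set(recorder_db)
  n <- length(spacers)
  out <- data.frame(seq = spacers,
                    classification = rep("exogenous", n),
                    best_recorder_identity = rep(NA_real_, n),
                    best_recorder_coverage = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  todo <- seq_len(n)
  for (k in seed_steps) {
    if (length(todo) == 0L) break
    idx <- .build_db_index(recorder_db, as.integer(k))
    qs <- stats::setNames(spacers[todo], as.character(todo))
    # only accepted hits are materialized; spacers without one are the
    # "non-hit" set carried into the next (rescue) pass
    hits <- .match_queries(qs, idx, min_identity = id_threshold,
                           min_coverage = cov_threshold)
    if (nrow(hits) > 0L) {
      hits$i <- as.integer(hits$spacer_id)
      best <- hits[order(hits$i, -hits$coverage, -hits$identity,
                         hits$ref_id, hits$start), ]
      best <- best[!duplicated(best$i), ]
      out$best_recorder_identity[best$i] <- best$identity
      out$best_recorder_coverage[best$i] <- best$coverage
      endo <- unique(hits$i)
      out$classification[endo] <- "endogenous"
      todo <- setdiff(todo, endo)
    }
  }
  out
}

#' Dereplicate spacers into unique records with abundances
#'
#' Exact-sequence grouping (case-insensitive; strands are NOT collapsed).
#' Output is ordered by descending abundance, then lexicographically.
#'
#' @param spacers character vector of spacer sequences.
#' @param sample_id sample label carried into the records.
#' @param classification optional per-spacer classification vector
#'   (propagated to the unique records; must be constant within a group).
#' @return `data.frame`: `spacer_id`, `sequence`, `abundance`, `sample_id`
#'   (+ `classification` if given).
#' @export
#' @examples
#' dereplicate(c("AC", "AC", "GT"))
dereplicate <- function(spacers, sample_id = "sample", classification = NULL) {
  spacers <- toupper(as.character(spacers))
  if (length(spacers) == 0L) {
    out <- data.frame(spacer_id = character(0), sequence = character(0),
                      abundance = integer(0), sample_id = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  tab <- table(spacers)
  seqs <- names(tab)
  ab <- as.integer(tab)
  ord <- order(-ab, seqs)
  seqs <- seqs[ord]
  ab <- ab[ord]
  out <- data.frame(spacer_id = sprintf("sp%05d", seq_along(seqs)),
                    sequence = seqs, abundance = ab, sample_id = sample_id,
                    stringsAsFactors = FALSE)
  if (!is.null(classification)) {
    cls <- tapply(classification, spacers, function(x) x[1])
    out$classification <- unname(cls[out$sequence])
  }
  out
}
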