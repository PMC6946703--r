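# Matching exogenous spacers to target databases, scrambled-spacer null
# calibration, and the community unique-mapping filter.

#' Match spacers against a reference database
#'
#' All hits meeting both the identity and coverage thresholds are reported
#' (not best-only), on both strands, in deterministic order
#' `(spacer_id, ref_id, start)`.  Minus-strand hits are given in forward
#' reference coordinates with strand `"-"`.
#'
#' @param spacers named character vector (names = spacer ids) or a
#'   dereplicated `data.frame` with columns `spacer_id`, `sequence`.
#' @param db reference set (see [as_reference_set()]); must be non-empty.
#' @param min_identity,min_coverage percent thresholds (default 95/95).
#' @param seed_k exact seed length (default 10, the short-query word size
#'   of nucleotide BLAST).
#' @return `data.frame` of hits: `spacer_id`, `ref_id`, `start`, `end`
#'   (0-based half-open), `strand`, `identity`, `coverage`.
#' @export
match_to_database <- function(spacers, db, min_identity = 95,
                              min_coverage = 95, seed_k = 10L) {
  if (is.data.frame(spacers)) {
    spacers <- stats::setNames(spacers$sequence, spacers$spacer_id)
  }
  if (is.null(names(spacers))) {
    names(spacers) <- sprintf("sp%05d", seq_along(spacers))
  }
  db <- as_reference_set(db)
  if (nrow(db) == 0L) stop("database is empty", call. = FALSE)
  idx <- .build_db_index(db, as.integer(seed_k))
  hits <- .match_queries(spacers, idx, min_identity, min_coverage)
  hits[order(match(hits$spacer_id, names(spacers)), hits$ref_id, hits$start), ,
       drop = FALSE] -> hits
  rownames(hits) <- NULL
  hits
}

#' Scramble spacer sequences (composition-preserving null)
#'
#' Each spacer is independently permuted (Fisher-Yates via `sample()`),
#' preserving its length and nucleotide composition.  Used to calibrate the
#' database-match threshold: scrambled spacers should produce no hits at a
#' properly conservative stringency.
#'
#' @param spacers character vector (names preserved).
#' @param seed RNG seed; scrambling must be seeded to be reproducible.
#' @return character vector of scrambled spacers.
#' @export
#' @examples
#' scramble_spacers(c(a = "AAAA", b = "ACGT"), seed = 1)
scramble_spacers <- function(spacers, seed) {
  if (missing(seed)) stop("scramble_spacers requires a seed", call. = FALSE)
  if (is.data.frame(spacers)) {
    spacers <- stats::setNames(spacers$sequence, spacers$spacer_id)
  }
  withr::with_seed(as.integer(seed), {
    out <- vapply(spacers, function(s) {
      paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    }, character(1))
  })
  names(out) <- names(spacers)
  out
}

#' Calibrate the database-match threshold with a scrambled null
#'
#' Computes, over a grid of identity-and-coverage thresholds, the fraction
#' of real and of scrambled spacers with at least one database hit.  The
#' chosen threshold is the smallest grid value at which the scrambled hit
#' rate is exactly 0 while the real hit rate is positive; if no grid value
#' achieves this the maximum is chosen and flagged.
#'
#' @param real_spacers named character vector or dereplicated `data.frame`.
#' @param db target reference set.
#' @param seed seed for the scrambling permutation.
#' @param grid increasing percent thresholds to evaluate.
#' @param seed_k seed length passed to [match_to_database()].
#' @return object of class `calibration_curve`: list with `curve`
#'   (`data.frame`: `threshold`, `real_hit_rate`, `scrambled_hit_rate`),
#'   `chosen_threshold`, `warning` (TRUE when no threshold silenced the
#'   null).
#' @export
calibrate_threshold <- function(real_spacers, db, seed,
                                grid = c(80, 85, 90, 95, 100),
                                seed_k = 10L) {
  if (is.data.frame(real_spacers)) {
    real_spacers <- stats::setNames(real_spacers$sequence,
                                    real_spacers$spacer_id)
  }
  n <- length(real_spacers)
  if (n == 0L) stop("no spacers to calibrate on", call. = FALSE)
  if (n < 100L) {
    warning("fewer than 100 spacers; calibration will be noisy")
  }
  if (is.null(names(real_spacers))) {
    names(real_spacers) <- sprintf("sp%05d", seq_len(n))
  }
  grid <- sort(unique(grid))
  scrambled <- scramble_spacers(real_spacers, seed = seed)
  lo <- min(grid)
  hr <- match_to_database(real_spacers, db, lo, lo, seed_k)
  hs <- match_to_database(scrambled, db, lo, lo, seed_k)
  rate_at <- function(hits, t) {
    pass <- hits$identity >= t & hits$coverage >= t
    length(unique(hits$spacer_id[pass])) / n
  }
  curve <- data.frame(
    threshold = grid,
    real_hit_rate = vapply(grid, function(t) rate_at(hr, t), numeric(1)),
    scrambled_hit_rate = vapply(grid, function(t) rate_at(hs, t), numeric(1)))
  ok <- curve$scrambled_hit_rate == 0 & curve$real_hit_rate > 0
  flag <- !any(ok)
  chosen <- if (flag) max(grid) else min(grid[ok])
  if (flag) {
    warning("no grid threshold silenced the scrambled null; using max(grid)")
  }
  structure(list(curve = curve, chosen_threshold = chosen, warning = flag),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Scrambled-null threshold calibration\n")
  print(x$curve, row.names = FALSE)
  cat(sprintf("chosen threshold: %g%%%s\n", x$chosen_threshold,
              if (x$warning) " (null never silenced)" else ""))
  invisible(x)
}

#' Remove spacers mapping to more than one reference
#'
#' A spacer with hits to more than one distinct reference id is removed
#' entirely (all of its hits), ensuring an unambiguous attribution of HGT
#' events.  The removal fraction is reported over unique spacers with at
#' least one hit; when the hit table carries an `abundance` column an
#' abundance-weighted fraction is reported as well.
#'
#' @param hits hit `data.frame` from [match_to_database()].
#' @return list: `hits` (kept rows), `n_removed` (spacers removed),
#'   `fraction_removed` (over unique spacers with >= 1 hit),
#'   `fraction_removed_weighted` (abundance-weighted, `NA` without an
#'   abundance column).
#' @export
filter_multi_mapping <- function(hits) {
  if (nrow(hits) == 0L) {
    return(list(hits = hits, n_removed = 0L, fraction_removed = 0,
                fraction_removed_weighted = NA_real_))
  }
  nref <- tapply(hits$ref_id, hits$spacer_id,
                 function(r) length(unique(r)))
  multi <- names(nref)[nref > 1L]
  kept <- hits[!hits$spacer_id %in% multi, , drop = FALSE]
  rownames(kept) <- NULL
  fw <- NA_real_
  if (!is.null(hits$abundance)) {
    ab <- tapply(hits$abundance, hits$spacer_id, function(x) x[1])
    fw <- sum(ab[multi]) / sum(ab)
  }
  list(hits = kept,
       n_removed = length(multi),
       fraction_removed = length(multi) / length(nref),
       fraction_removed_weighted = fw)
}
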