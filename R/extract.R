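# Direct-repeat array parsing.
#
# A well-formed amplicon read is leader + (spacer, repeat)* with every
# spacer flanked by two copies of the direct repeat.  Only spacers between
# two repeat occurrences are kept; arrays without a recognizable parental
# anchor are excluded from expansion statistics.

#' Find direct-repeat occurrences in a read
#'
#' Scans left to right for occurrences of `repeat_seq` within Hamming
#' distance `max_mismatch`, greedily accepting non-overlapping matches (an
#' accepted occurrence excludes any overlapping later candidate).  With
#' fixed-length occurrences this greedy scan is optimal, so the number of
#' occurrences is monotone in `max_mismatch`.
#'
#' @param read_seq read sequence.
#' @param repeat_seq direct-repeat sequence (non-empty).
#' @param max_mismatch maximum Hamming distance; must be below half the
#'   repeat length.
#' @return `data.frame` with 0-based half-open columns `start`, `end`,
#'   sorted by `start`.
#' @export
#' @examples
#' find_repeats("AAACGTACGTTTT", "ACGTACGT", 0)
find_repeats <- function(read_seq, repeat_seq, max_mismatch = 2L) {
  if (nchar(repeat_seq) == 0L) stop("repeat_seq must be non-empty", call. = FALSE)
  if (max_mismatch >= nchar(repeat_seq) / 2) {
    stop("max_mismatch must be < half the repeat length", call. = FALSE)
  }
  m <- nchar(repeat_seq)
  mm <- .hamming_scan(read_seq, repeat_seq)
  cand <- which(mm <= max_mismatch)      # 1-based starts
  keep <- integer(0)
  last_end <- 0L
  for (s in cand) {
    if (s >= last_end + 1L) {
      keep <- c(keep, s)
      last_end <- s + m - 1L
    }
  }
  data.frame(start = keep - 1L, end = keep - 1L + m)
}

#' Parse one read into an ordered spacer array
#'
#' Spacers are the substrings strictly between consecutive repeat
#' occurrences.  Gaps with length outside `spacer_len_bounds` are dropped
#' and the array marked `malformed`; fewer than two repeats give status
#' `no_repeat` or `single_repeat` with no spacers.
#'
#' @inheritParams find_repeats
#' @param spacer_len_bounds inclusive `c(lo, hi)` length bounds for a
#'   valid spacer.
#' @param read_id identifier carried through to the result.
#' @return object of class `parsed_array`: list with `read_id`, `spacers`
#'   (leader-proximal first), `n_repeats`, `status` (one of `ok`,
#'   `no_repeat`, `single_repeat`, `malformed`), `is_expanded`,
#'   `new_spacers`.
#' @export
extract_spacers <- function(read_seq, repeat_seq, max_mismatch = 2L,
                            spacer_len_bounds = c(25L, 45L),
                            read_id = NA_character_) {
  occ <- find_repeats(read_seq, repeat_seq, max_mismatch)
  n <- nrow(occ)
  status <- "ok"
  spacers <- character(0)
  if (n == 0L) {
    status <- "no_repeat"
  } else if (n == 1L) {
    status <- "single_repeat"
  } else {
    gs <- occ$end[-n]                    # gap starts (0-based)
    ge <- occ$start[-1]                  # gap ends
    glen <- ge - gs
    ok <- glen >= spacer_len_bounds[1] & glen <= spacer_len_bounds[2]
    if (!all(ok)) status <- "malformed"
    spacers <- substring(read_seq, gs[ok] + 1L, ge[ok])
  }
  structure(list(read_id = read_id, spacers = spacers, n_repeats = n,
                 status = status, is_expanded = NA, new_spacers = character(0)),
            class = "parsed_array")
}

#' @export
print.parsed_array <- function(x, ...) {
  cat(sprintf("<parsed_array %s: status=%s, %d repeats, %d spacers, expanded=%s>\n",
              x$read_id, x$status, x$n_repeats, length(x$spacers),
              as.character(x$is_expanded)))
  invisible(x)
}

# Hamming distance between equal-length strings, Inf if lengths differ.
.hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(charToRaw(a) != charToRaw(b))
}

#' Call array expansion against the parental spacer set
#'
#' Locates the first spacer matching the first parental spacer (Hamming
#' distance at most `parental_match_max_mismatch`); everything before it is
#' new (new spacers integrate at the leader end).  Arrays whose parental
#' anchor cannot be recognized are marked `malformed` and excluded from
#' expansion statistics.
#'
#' @param parsed a `parsed_array` with status `ok`.
#' @param parental_spacers ordered parental spacers (first = leader-proximal).
#' @param parental_match_max_mismatch Hamming tolerance for the anchor.
#' @return the `parsed_array` with `is_expanded` and `new_spacers` filled.
#' @export
call_expansion <- function(parsed, parental_spacers,
                           parental_match_max_mismatch = 2L) {
  stopifnot(inherits(parsed, "parsed_array"))
  if (parsed$status != "ok") {
    stop("call_expansion requires status 'ok'", call. = FALSE)
  }
  anchor <- parental_spacers[[1]]
  idx <- NA_integer_
  exact <- which(parsed$spacers == anchor)
  if (length(exact) > 0L) {
    idx <- exact[1]
  } else if (parental_match_max_mismatch > 0L) {
    for (i in seq_along(parsed$spacers)) {
      if (.hamming(parsed$spacers[i], anchor) <= parental_match_max_mismatch) {
        idx <- i
        break
      }
    }
  }
  if (is.na(idx)) {
    parsed$status <- "malformed"
    parsed$is_expanded <- NA
    parsed$new_spacers <- character(0)
    return(parsed)
  }
  parsed$new_spacers <- parsed$spacers[seq_len(idx - 1L)]
  parsed$is_expanded <- idx > 1L
  parsed
}

#' Parse and expansion-call a whole sample
#'
#' Vectorized driver over many reads: [extract_spacers()] then
#' [call_expansion()] per read.
#'
#' @param reads named character vector of read sequences (names = read ids)
#'   or a `data.frame` with columns `read_id`, `seq`.
#' @inheritParams extract_spacers
#' @inheritParams call_expansion
#' @return `data.frame` with columns `read_id`, `status`, `n_repeats`,
#'   `is_expanded`, `n_new` and list-columns `spacers`, `new_spacers`.
#' @export
parse_sample <- function(reads, repeat_seq, parental_spacers,
                         max_mismatch = 2L, spacer_len_bounds = c(25L, 45L),
                         parental_match_max_mismatch = 2L) {
  if (is.data.frame(reads)) {
    reads <- stats::setNames(reads$seq, reads$read_id)
  }
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(reads))
  res <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    pa <- extract_spacers(reads[[i]], repeat_seq, max_mismatch,
                          spacer_len_bounds, read_id = ids[i])
    if (pa$status == "ok") {
      pa <- call_expansion(pa, parental_spacers, parental_match_max_mismatch)
    }
    res[[i]] <- pa
  }
  data.frame(
    read_id = ids,
    status = vapply(res, `[[`, character(1), "status"),
    n_repeats = vapply(res, `[[`, integer(1), "n_repeats"),
    is_expanded = vapply(res, function(p) {
      if (is.na(p$is_expanded[1])) NA else isTRUE(p$is_expanded)
    }, logical(1)),
    n_new = vapply(res, function(p) length(p$new_spacers), integer(1)),
    spacers = I(lapply(res, `[[`, "spacers")),
    new_spacers = I(lapply(res, `[[`, "new_spacers")),
    stringsAsFactors = FALSE)
}

#' Summarize array expansion for one sample
#'
#' Counts are computed over status-`ok` arrays only (arrays without a
#' recognizable parental anchor or with malformed gaps are excluded).
#'
#' @param parsed `data.frame` from [parse_sample()].
#' @param sample_id sample label.
#' @return one-row `data.frame`: `sample_id`, `n_arrays_total`,
#'   `n_arrays_expanded`, `percent_expanded`, `n_new_spacers`.
#' @export
summarize_expansion <- function(parsed, sample_id = "sample") {
  ok <- parsed[parsed$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0L) {
    stop("no usable arrays (status 'ok') in sample", call. = FALSE)
  }
  n_exp <- sum(ok$is_expanded, na.rm = TRUE)
  data.frame(sample_id = sample_id,
             n_arrays_total = nrow(ok),
             n_arrays_expanded = n_exp,
             percent_expanded = 100 * n_exp / nrow(ok),
             n_new_spacers = sum(ok$n_new),
             stringsAsFactors = FALSE)
}
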