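#' Reference sequence sets
#'
#' A reference set is a plain `data.frame` with columns `id`, `role` and
#' `seq`.  Roles used by the pipeline are `"recorder_genome"`,
#' `"recorder_plasmid"`, `"donor"`, `"plasmid_db"` and `"metagenome"`; any
#' other label is carried through untouched.
#'
#' @param x a reference-set `data.frame`, a named character vector of
#'   sequences, or a `Biostrings::DNAStringSet`.
#' @param role role assigned when `x` carries none (default `"donor"`).
#' @return a validated reference-set `data.frame`.
#' @export
#' @examples
#' as_reference_set(c(plasmidA = "ACGTACGTACGT"))
as_reference_set <- function(x, role = "donor") {
  if (inherits(x, "DNAStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (is.character(x)) {
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
      stop("reference sequences must be named", call. = FALSE)
    }
    x <- data.frame(id = names(x), role = role, seq = unname(x),
                    stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    stop("a reference set needs columns 'id' and 'seq'", call. = FALSE)
  }
  if (is.null(x$role)) x$role <- role
  x$id <- as.character(x$id)
  x$seq <- toupper(as.character(x$seq))
  if (anyDuplicated(x$id)) stop("duplicated reference ids", call. = FALSE)
  bad <- grepl("[^ACGTN]", x$seq)
  if (any(bad)) {
    stop("non-ACGTN characters in reference(s): ",
         paste(x$id[bad], collapse = ", "), call. = FALSE)
  }
  x[, c("id", "role", "seq")]
}

# named character vector id -> sequence
.ref_vector <- function(refs) {
  refs <- as_reference_set(refs)
  stats::setNames(refs$seq, refs$id)
}

# named integer vector id -> length
.ref_lengths <- function(refs) {
  refs <- as_reference_set(refs)
  stats::setNames(nchar(refs$seq), refs$id)
}
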