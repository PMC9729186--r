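#' Identifier shape validation
#'
#' Compounds are keyed by standard InChIKeys (14-10-1 blocks of uppercase
#' letters separated by hyphens) and diseases by UMLS concept unique
#' identifiers (a "C" followed by seven digits). Validation is shape-only:
#' no InChIKey checksum is computed, so large noisy dumps still load and
#' malformed rows are skipped rather than aborting the run.
#'
#' @param x character vector of identifiers.
#' @return logical vector, `TRUE` where the identifier is shape-valid.
#' @examples
#' is_inchikey("BSYNRYMUTXBXSQ-UHFFFAOYSA-N")  # aspirin
#' is_cui("C0027051")                          # myocardial infarction
#' @export
is_inchikey <- function(x) {
  !is.na(x) & grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", x)
}

#' @rdname is_inchikey
#' @export
is_cui <- function(x) {
  !is.na(x) & grepl("^C[0-9]{7}$", x)
}

# Attach reader metadata (row-level warnings, drop counts) to a parsed object.
set_reader_meta <- function(x, warnings, n_dropped, n_duplicates = 0L) {
  attr(x, "reader_meta") <- list(
    warnings     = as.character(warnings),
    n_dropped    = as.integer(n_dropped),
    n_duplicates = as.integer(n_duplicates)
  )
  x
}

#' Retrieve reader metadata
#'
#' All table readers attach per-row warnings and drop/duplicate counts to
#' their return value; this accessor retrieves them.
#'
#' @param x an object returned by one of the `read_*` functions.
#' @return a list with elements `warnings` (character), `n_dropped` and
#'   `n_duplicates` (integers).
#' @export
reader_meta <- function(x) {
  m <- attr(x, "reader_meta", exact = TRUE)
  if (is.null(m)) list(warnings = character(), n_dropped = 0L, n_duplicates = 0L) else m
}
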