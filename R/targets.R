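#' Filter bioactivities to potent compound-target pairs
#'
#' A (compound, target) pair is retained iff at least one quantitative
#' measurement for the pair is at or below the potency threshold (default
#' 1000 nM), or at least one unary record exists for the pair (curated
#' interactions from unary databases count as potent). With
#' `aggregate = "median"` the median of the pair's quantitative
#' measurements is compared to the threshold instead of the single best
#' measurement; unary evidence qualifies the pair under either rule.
#'
#' @param records a bioactivity table from [read_bioactivity_table()].
#' @param threshold_nm potency threshold in nM; must be positive.
#' @param aggregate `"any"` (default) or `"median"`.
#' @return a `data.frame` of unique potent (`compound_id`, `target_id`)
#'   pairs, sorted for reproducibility.
#' @export
filter_potent <- function(records, threshold_nm = 1000,
                          aggregate = c("any", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.numeric(threshold_nm), threshold_nm > 0)
  if (nrow(records) == 0) {
    return(data.frame(compound_id = character(), target_id = character(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(records$compound_id, records$target_id, sep = "\r")
  unary_ok <- tapply(is.na(records$potency_nm), key, any)
  quant_ok <- if (aggregate == "any") {
    tapply(records$potency_nm, key, function(p) {
      p <- p[!is.na(p)]
      length(p) > 0 && min(p) <= threshold_nm
    })
  } else {
    tapply(records$potency_nm, key, function(p) {
      p <- p[!is.na(p)]
      length(p) > 0 && stats::median(p) <= threshold_nm
    })
  }
  keep <- names(unary_ok)[unary_ok | quant_ok]
  if (length(keep) == 0) {
    return(data.frame(compound_id = character(), target_id = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(keep, "\r", fixed = TRUE))
  out <- data.frame(compound_id = parts[, 1], target_id = parts[, 2],
                    stringsAsFactors = FALSE)
  out <- out[order(out$compound_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group potent pairs into per-compound target profiles
#'
#' @param pairs a `data.frame` of (`compound_id`, `target_id`) pairs, e.g.
#'   from [filter_potent()].
#' @return a named list mapping each compound with at least one potent
#'   target to a character vector of unique target accessions; compounds
#'   with no potent target are absent.
#' @export
build_target_profiles <- function(pairs) {
  if (nrow(pairs) == 0) return(structure(list(), names = character()))
  prof <- lapply(split(pairs$target_id, pairs$compound_id),
                 function(t) sort(unique(t)))
  prof[order(names(prof))]
}

#' Overlapping compound-target score (OCTS)
#'
#' The overlap (Szymkiewicz-Simpson) coefficient between the potent-target
#' sets of an approved drug and a candidate compound:
#' `|Drug_T intersect Compound_T| / min(|Drug_T|, |Compound_T|)`.
#' Symmetric, ranges over \[0, 1\], and equals 1 whenever one set contains
#' the other. (The normalization by the smaller set size makes this an
#' overlap coefficient rather than a Jaccard index, which would divide by
#' the union size.)
#'
#' @param drug_targets,compound_targets non-empty character vectors of
#'   target accessions; duplicates are ignored.
#' @return overlap score in \[0, 1\].
#' @export
octs <- function(drug_targets, compound_targets) {
  a <- unique(drug_targets)
  b <- unique(compound_targets)
  if (length(a) == 0 || length(b) == 0) {
    stop(errorCondition("OCTS is undefined for an empty target set",
                        class = "drugrepo_empty_set_error"))
  }
  length(intersect(a, b)) / min(length(a), length(b))
}
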