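#' Composite repurposing score
#'
#' The arithmetic mean of the three component scores: structural Tanimoto
#' similarity (TC), overlapping compound-target score (OCTS) and
#' compound-disease network score (CDS). Ranges over \[0, 1\]; higher means
#' stronger repurposing evidence.
#'
#' @param tc,octs,cds component scores, each in \[0, 1\] (vectorized).
#' @return `(tc + octs + cds) / 3`.
#' @export
drugrepo_score <- function(tc, octs, cds) {
  vals <- c(tc, octs, cds)
  if (any(is.na(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("all component scores must lie in [0, 1]", call. = FALSE)
  }
  (tc + octs + cds) / 3
}

#' Rank repurposing candidates for one disease
#'
#' For every candidate compound, computes per-approved-drug TC and OCTS
#' against each approved drug of the disease, drops (drug, candidate) pairs
#' whose structural similarity falls below `tc_min` before averaging,
#' averages TC and OCTS over the surviving pairs (the multi-drug rule),
#' looks up the candidate's CDS for this disease, combines the three
#' components with [drugrepo_score()], and returns the candidates scoring
#' at least `score_min`, ranked by descending score with ties broken
#' lexicographically by candidate identifier. Approved drugs of the query
#' disease are never returned as candidates (drugs approved for other
#' diseases are legitimate candidates). Candidates lacking a fingerprint or
#' target profile are skipped; their count is in the `n_skipped` attribute.
#'
#' @param disease_id UMLS CUI of the disease.
#' @param indications approved-indication table from [read_indications()].
#' @param profiles named list of potent target profiles from
#'   [build_target_profiles()].
#' @param fingerprints named list of fingerprints from
#'   [fingerprint_compounds()].
#' @param cds_table normalized proximity table from [normalize_cds()]; rows
#'   for this disease are used. May be `NULL`, in which case candidates
#'   without a CDS entry get `cds = 0`.
#' @param tc_min minimum per-pair structural similarity (default 0.2).
#' @param score_min minimum composite score to report (default 0.4).
#' @param candidates optional character vector restricting the candidate
#'   pool; by default every fingerprinted, profiled compound that is not an
#'   approved drug for this disease.
#' @param average_all_pairs if `TRUE`, average TC/OCTS over all approved
#'   drugs rather than only the pairs passing `tc_min` (a candidate still
#'   needs at least one pair with `TC >= tc_min` to survive).
#' @return a `data.frame` with columns `disease_id`, `candidate_id`, `tc`,
#'   `octs`, `cds`, `drugrepo`, `rank`, sorted by decreasing score.
#' @export
repurpose_disease <- function(disease_id, indications, profiles, fingerprints,
                              cds_table, tc_min = 0.2, score_min = 0.4,
                              candidates = NULL, average_all_pairs = FALSE) {
  approved <- indications$drug_id[indications$disease_id == disease_id]
  approved <- intersect(approved, names(profiles))
  approved <- intersect(approved, names(fingerprints))
  if (length(approved) == 0) {
    stop(errorCondition(
      paste0("disease ", disease_id,
             " has no approved drug with a usable target profile"),
      disease_id = disease_id, class = "drugrepo_no_approved_drug_error"))
  }
  all_approved_here <- indications$drug_id[indications$disease_id == disease_id]
  if (is.null(candidates)) {
    candidates <- setdiff(intersect(names(profiles), names(fingerprints)),
                          all_approved_here)
  }
  n_skipped <- sum(!(candidates %in% names(profiles)) |
                     !(candidates %in% names(fingerprints)))
  candidates <- intersect(intersect(candidates, names(profiles)),
                          names(fingerprints))
  candidates <- setdiff(candidates, all_approved_here)

  cds_lookup <- if (is.null(cds_table)) {
    numeric()
  } else {
    rows <- cds_table[cds_table$disease_id == disease_id, , drop = FALSE]
    stats::setNames(rows$cds, rows$compound_id)
  }

  recs <- lapply(candidates, function(cid) {
    tcs <- vapply(approved, function(d)
      tanimoto(fingerprints[[d]], fingerprints[[cid]]), numeric(1))
    ocs <- vapply(approved, function(d)
      octs(profiles[[d]], profiles[[cid]]), numeric(1))
    pass <- tcs >= tc_min
    if (!any(pass)) return(NULL)
    if (average_all_pairs) pass <- rep(TRUE, length(tcs))
    tc_avg <- mean(tcs[pass])
    oc_avg <- mean(ocs[pass])
    cds <- if (cid %in% names(cds_lookup)) unname(cds_lookup[[cid]]) else 0
    data.frame(disease_id = disease_id, candidate_id = cid,
               tc = tc_avg, octs = oc_avg, cds = cds,
               drugrepo = drugrepo_score(tc_avg, oc_avg, cds),
               stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs)) {
    recs <- data.frame(disease_id = character(), candidate_id = character(),
                       tc = numeric(), octs = numeric(), cds = numeric(),
                       drugrepo = numeric(), stringsAsFactors = FALSE)
  }
  recs <- recs[recs$drugrepo >= score_min, , drop = FALSE]
  recs <- recs[order(-recs$drugrepo, recs$candidate_id), , drop = FALSE]
  recs$rank <- seq_len(nrow(recs))
  rownames(recs) <- NULL
  attr(recs, "n_skipped") <- n_skipped
  recs
}
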