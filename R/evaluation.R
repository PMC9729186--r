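#' Per-disease significance of predicted-vs-reference overlap
#'
#' Compares the set of compounds a reference resource associates with a
#' disease (`C_d`) against the set the pipeline repurposes for it (`C_r`),
#' within a universe of `|C_all|` candidate compounds. The expected overlap
#' under random selection is `N_expected = |C_d| * |C_r| / |C_all|` (exact
#' division, no rounding) and the significance is the raw excess
#' `Sig_d = N_overlap - N_expected`. A positive significance means the
#' predictions match the reference more often than chance; it carries no
#' variance or p-value.
#'
#' @param reference_set character vector of compound identifiers associated
#'   with the disease in the reference resource.
#' @param predicted_set character vector of compound identifiers predicted
#'   for the disease.
#' @param universe_size total number of candidate compounds the predictions
#'   were drawn from; must be at least as large as either set.
#' @param disease_id optional disease label carried into the result.
#' @param universe optional character vector of the full universe; when
#'   supplied, set members outside it are reported with a warning.
#' @return a one-row `data.frame` with columns `disease_id`, `n_overlap`,
#'   `n_expected`, `sig`, `n_reference`, `n_predicted`, `n_universe`.
#' @examples
#' # 401 reference compounds, 4921 predictions, 788,078-compound universe:
#' significance_score(paste0("r", 1:401), paste0("p", 1:4921), 788078)$n_expected
#' @export
significance_score <- function(reference_set, predicted_set, universe_size,
                               disease_id = NA_character_, universe = NULL) {
  cd <- unique(reference_set)
  cr <- unique(predicted_set)
  if (universe_size <= 0) stop("universe size must be positive", call. = FALSE)
  if (universe_size < max(length(cd), length(cr))) {
    stop("universe smaller than one of the compound sets", call. = FALSE)
  }
  if (!is.null(universe)) {
    outside <- sum(!(cd %in% universe)) + sum(!(cr %in% universe))
    if (outside > 0) {
      warning(outside, " set member(s) outside the stated universe")
    }
  }
  n_overlap <- length(intersect(cd, cr))
  n_expected <- length(cd) * length(cr) / universe_size
  data.frame(disease_id = disease_id,
             n_overlap = n_overlap,
             n_expected = n_expected,
             sig = n_overlap - n_expected,
             n_reference = length(cd),
             n_predicted = length(cr),
             n_universe = as.integer(universe_size),
             stringsAsFactors = FALSE)
}

#' Hit ratio of predictions across score thresholds
#'
#' For each threshold `t`, considers the predictions with composite score
#' at least `t` and reports the percentage of them that appear in a
#' reference set of (disease, compound) associations (exact pair match).
#' Thresholds attained by no prediction are omitted, since the ratio has an
#' empty denominator there.
#'
#' @param predictions a ranked repurposing table (as from
#'   [repurpose_disease()] rows bound together) with columns `disease_id`,
#'   `candidate_id`, `drugrepo`.
#' @param reference a `data.frame` with columns `disease_id` and
#'   `compound_id` giving the reference associations.
#' @param thresholds numeric vector of score thresholds in \[0, 1\].
#' @return a `data.frame` with columns `threshold`, `n_predicted`,
#'   `n_hits`, `pct`.
#' @export
hit_ratio <- function(predictions, reference,
                      thresholds = seq(0.1, 1, by = 0.1)) {
  stopifnot(all(thresholds >= 0), all(thresholds <= 1))
  ref_key <- paste(reference$disease_id, reference$compound_id)
  pred_key <- paste(predictions$disease_id, predictions$candidate_id)
  is_hit <- pred_key %in% ref_key
  rows <- lapply(thresholds, function(t) {
    sel <- predictions$drugrepo >= t
    n <- sum(sel)
    if (n == 0) return(NULL)
    h <- sum(is_hit & sel)
    data.frame(threshold = t, n_predicted = n, n_hits = h,
               pct = 100 * h / n)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(threshold = numeric(), n_predicted = integer(),
                      n_hits = integer(), pct = numeric())
  }
  rownames(out) <- NULL
  out
}
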