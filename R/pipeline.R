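#' Pipeline run configuration
#'
#' Bundles the five input paths and the scoring thresholds: the potency
#' cutoff in nM below which a bioactivity counts as potent (default 1000),
#' the minimum per-pair structural similarity (default 0.2), the minimum
#' composite score to report (default 0.4), and the CDS normalization mode
#' (global batch by default, per-disease optionally).
#'
#' @param compounds,bioactivities,ppi_edges,disease_genes,indications paths
#'   to the five input tables.
#' @param potency_threshold_nm potency cutoff in nM.
#' @param tc_min minimum structural similarity per (drug, candidate) pair.
#' @param score_min minimum composite score reported.
#' @param cds_normalization `"global"` or `"per_disease"`.
#' @param delim field delimiter for all five inputs.
#' @param out_dir output directory for [run_score()].
#' @return an object of class `run_config`.
#' @export
run_config <- function(compounds, bioactivities, ppi_edges, disease_genes,
                       indications, potency_threshold_nm = 1000,
                       tc_min = 0.2, score_min = 0.4,
                       cds_normalization = c("global", "per_disease"),
                       delim = "\t", out_dir = ".") {
  cds_normalization <- match.arg(cds_normalization)
  stopifnot(potency_threshold_nm > 0, tc_min >= 0, tc_min <= 1,
            score_min >= 0, score_min <= 1)
  paths <- list(compounds = compounds, bioactivities = bioactivities,
                ppi_edges = ppi_edges, disease_genes = disease_genes,
                indications = indications)
  missing <- !vapply(paths, file.exists, logical(1))
  if (any(missing)) {
    stop(errorCondition(
      paste0("input file(s) not found: ",
             paste(unlist(paths[missing]), collapse = ", ")),
      class = "drugrepo_config_error"))
  }
  structure(c(paths, list(potency_threshold_nm = potency_threshold_nm,
                          tc_min = tc_min, score_min = score_min,
                          cds_normalization = cds_normalization,
                          delim = delim, out_dir = out_dir)),
            class = "run_config")
}

#' Run the full repurposing pipeline
#'
#' Loads the five input tables, fingerprints all compounds, applies the
#' potency filter and builds target profiles, computes for every disease
#' the per-pair structural similarities, restricts network proximity to
#' the (candidate, disease) pairs that survive the similarity prefilter,
#' min-max normalizes CDS over the whole run, and ranks candidates per
#' disease by composite score. Diseases with no usable approved drug are
#' skipped and listed in the log. Row counts at every filter stage are
#' recorded so data loss is auditable.
#'
#' @param config a [run_config()].
#' @param write_output write `repurposing.tsv` and `run_log.txt` into
#'   `config$out_dir` (numeric columns at 4 decimal places).
#' @return a list with `predictions` (the ranked table across diseases),
#'   `cds_table`, `profiles`, `fingerprints`, `universe` (scoreable
#'   compound identifiers) and `log` (named counts per stage).
#' @export
run_score <- function(config, write_output = TRUE) {
  stopifnot(inherits(config, "run_config"))
  comp <- read_compound_table(config$compounds, "candidate", config$delim)
  bio  <- read_bioactivity_table(config$bioactivities, config$delim)
  ppi  <- read_ppi_edges(config$ppi_edges, config$delim)
  dmap <- read_disease_genes(config$disease_genes, config$delim)
  ind  <- read_indications(config$indications, config$delim)

  fps <- fingerprint_compounds(comp, quiet = TRUE)
  pairs <- filter_potent(bio, config$potency_threshold_nm)
  profiles <- build_target_profiles(pairs)
  universe <- intersect(names(fps), names(profiles))

  log <- c(compounds_loaded = nrow(comp),
           bioactivity_rows_loaded = nrow(bio),
           potent_pairs = nrow(pairs),
           compounds_with_profile = length(profiles),
           compounds_fingerprinted = length(fps),
           compounds_scoreable = length(universe))

  # prefilter: per disease, candidates with >= 1 approved-drug pair at
  # TC >= tc_min; proximity is computed for exactly those pairs
  prox_pairs <- list()
  skipped_diseases <- character(0)
  for (d in names(dmap)) {
    approved <- intersect(ind$drug_id[ind$disease_id == d], universe)
    if (length(approved) == 0) {
      skipped_diseases <- c(skipped_diseases, d)
      next
    }
    cands <- setdiff(universe, ind$drug_id[ind$disease_id == d])
    keep <- vapply(cands, function(cid)
      any(vapply(approved, function(a)
        tanimoto(fps[[a]], fps[[cid]]), numeric(1)) >= config$tc_min),
      logical(1))
    if (any(keep)) {
      prox_pairs[[d]] <- data.frame(compound_id = cands[keep],
                                    disease_id = d, stringsAsFactors = FALSE)
    }
  }
  log["diseases_skipped_no_drug"] <- length(skipped_diseases)
  prox_pairs <- do.call(rbind, prox_pairs)
  if (is.null(prox_pairs) || nrow(prox_pairs) == 0) {
    stop(errorCondition("no (candidate, disease) pair passes the similarity prefilter",
                        class = "drugrepo_data_error"))
  }
  log["pairs_tc_kept"] <- nrow(prox_pairs)

  prox <- proximity_table(profiles, dmap, ppi, prox_pairs)
  cds_table <- normalize_cds(prox,
                             per_disease = config$cds_normalization == "per_disease")

  preds <- list()
  for (d in unique(cds_table$disease_id)) {
    preds[[d]] <- repurpose_disease(
      d, ind, profiles, fps, cds_table,
      tc_min = config$tc_min, score_min = config$score_min,
      candidates = cds_table$compound_id[cds_table$disease_id == d])
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  log["pairs_score_kept"] <- nrow(predictions)

  if (write_output) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- predictions
    for (cn in c("tc", "octs", "cds", "drugrepo")) {
      out[[cn]] <- sprintf("%.4f", out[[cn]])
    }
    utils::write.table(out, file.path(config$out_dir, "repurposing.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(sprintf("%s: %d", names(log), log),
                 if (length(skipped_diseases) > 0)
                   paste("skipped diseases:",
                         paste(skipped_diseases, collapse = ", "))),
               file.path(config$out_dir, "run_log.txt"))
  }
  list(predictions = predictions, cds_table = cds_table, profiles = profiles,
       fingerprints = fps, universe = universe, log = log)
}

#' Evaluate predictions against a reference association set
#'
#' Computes the per-disease significance of the overlap between predicted
#' and reference compound sets ([significance_score()]) and the hit-ratio
#' curve across score thresholds ([hit_ratio()]).
#'
#' @param predictions ranked repurposing table (from [run_score()]).
#' @param reference `data.frame` with columns `disease_id`, `compound_id`.
#' @param universe_size number of candidate compounds predictions were
#'   drawn from.
#' @param thresholds score thresholds for the hit-ratio curve.
#' @param out_dir if non-`NULL`, writes `significance.tsv` and
#'   `hit_ratio.tsv` there.
#' @return list with `significance` and `hit_ratio` tables.
#' @export
run_evaluate <- function(predictions, reference, universe_size,
                         thresholds = seq(0.1, 1, by = 0.1),
                         out_dir = NULL) {
  sig <- do.call(rbind, lapply(unique(predictions$disease_id), function(d) {
    significance_score(reference$compound_id[reference$disease_id == d],
                       predictions$candidate_id[predictions$disease_id == d],
                       universe_size, disease_id = d)
  }))
  hr <- hit_ratio(predictions, reference, thresholds)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sig_out <- sig
    for (cn in c("n_expected", "sig")) sig_out[[cn]] <- sprintf("%.4f", sig_out[[cn]])
    hr_out <- hr
    hr_out$pct <- sprintf("%.4f", hr_out$pct)
    utils::write.table(sig_out, file.path(out_dir, "significance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(hr_out, file.path(out_dir, "hit_ratio.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(significance = sig, hit_ratio = hr)
}

#' Generate a fixture directory (pipeline entry point)
#'
#' Thin wrapper over [fixture_spec()] + [generate_fixture()].
#'
#' @param out_dir output directory.
#' @param seed RNG seed.
#' @param ... passed to [fixture_spec()].
#' @return invisibly, the list returned by [generate_fixture()].
#' @export
run_fixture <- function(out_dir, seed = 1L, ...) {
  generate_fixture(fixture_spec(seed = seed, ...), out_dir)
}
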