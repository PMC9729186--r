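#' Raw compound-disease network proximity
#'
#' Measures how close a compound's target genes `C_G` sit to a disease's
#' associated genes `D_G` in the protein-protein interaction network, as
#' the bidirectional "closest" average: for every gene in either set, the
#' minimum unweighted shortest-path distance to the other set is taken, and
#' the finite minima are averaged. Genes absent from the graph, or with no
#' path to the other set, contribute no term; `n_terms_used` counts the
#' terms that were averaged (at most `|C_G| + |D_G|`). If no term is finite
#' the proximity is flagged undefined rather than raising an error.
#'
#' @param compound_genes,disease_genes non-empty character vectors of
#'   gene/protein identifiers (same namespace as the graph's vertex names).
#' @param graph an undirected [igraph::igraph], e.g. from
#'   [read_ppi_edges()].
#' @return a list with `raw_distance` (non-negative, `NA` if undefined),
#'   `n_terms_used` and `defined`.
#' @export
raw_proximity <- function(compound_genes, disease_genes, graph) {
  cg <- unique(compound_genes)
  dg <- unique(disease_genes)
  if (length(cg) == 0 || length(dg) == 0) {
    stop(errorCondition("proximity is undefined for an empty gene set",
                        class = "drugrepo_empty_set_error"))
  }
  verts <- igraph::V(graph)$name
  cg_in <- intersect(cg, verts)
  dg_in <- intersect(dg, verts)
  if (length(cg_in) == 0 || length(dg_in) == 0) {
    return(list(raw_distance = NA_real_, n_terms_used = 0L, defined = FALSE))
  }
  d <- igraph::distances(graph, v = cg_in, to = dg_in)
  mins <- c(apply(d, 1, min), apply(d, 2, min))
  mins <- mins[is.finite(mins)]
  if (length(mins) == 0) {
    return(list(raw_distance = NA_real_, n_terms_used = 0L, defined = FALSE))
  }
  list(raw_distance = mean(mins), n_terms_used = length(mins), defined = TRUE)
}

#' Batch proximity for compound profiles against disease gene sets
#'
#' Computes [raw_proximity()] for each requested (compound, disease) pair.
#'
#' @param profiles named list of target profiles from
#'   [build_target_profiles()].
#' @param disease_map a `disease_gene_map` from [read_disease_genes()].
#' @param graph the PPI graph.
#' @param pairs optional `data.frame` with columns `compound_id` and
#'   `disease_id` restricting which pairs are computed; by default the full
#'   cross product.
#' @return a `data.frame` with columns `compound_id`, `disease_id`,
#'   `raw_distance`, `n_terms_used`, `defined`.
#' @export
proximity_table <- function(profiles, disease_map, graph, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- expand.grid(compound_id = names(profiles),
                         disease_id = names(disease_map),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  n <- nrow(pairs)
  raw <- numeric(n); used <- integer(n); def <- logical(n)
  for (i in seq_len(n)) {
    p <- raw_proximity(profiles[[pairs$compound_id[i]]],
                       disease_map[[pairs$disease_id[i]]], graph)
    raw[i] <- p$raw_distance; used[i] <- p$n_terms_used; def[i] <- p$defined
  }
  data.frame(compound_id = pairs$compound_id, disease_id = pairs$disease_id,
             raw_distance = raw, n_terms_used = used, defined = def,
             stringsAsFactors = FALSE)
}

#' Min-max normalize raw proximities into compound-disease scores
#'
#' Maps the batch of raw average distances onto \[0, 1\] with the
#' orientation inverted, so the closest (smallest-distance) pair in the
#' batch scores `cds = 1` and the farthest scores 0:
#' `cds = 1 - (raw - min) / (max - min)`. When all defined raw distances in
#' the batch are equal, every defined entry gets 1; undefined entries
#' (no finite path between the gene sets) get 0. With
#' `per_disease = TRUE` normalization runs within each disease's rows
#' instead of over the whole batch.
#'
#' @param results a proximity table from [proximity_table()].
#' @param per_disease normalize within disease rather than globally.
#' @return the same table with a `cds` column added.
#' @export
normalize_cds <- function(results, per_disease = FALSE) {
  if (nrow(results) == 0) stop("empty proximity batch", call. = FALSE)
  norm_one <- function(df) {
    raw <- df$raw_distance[df$defined]
    if (length(raw) == 0) {
      df$cds <- 0
      return(df)
    }
    rng <- range(raw)
    cds <- if (rng[1] == rng[2]) {
      rep(1, nrow(df))
    } else {
      1 - (df$raw_distance - rng[1]) / (rng[2] - rng[1])
    }
    cds[!df$defined] <- 0
    df$cds <- cds
    df
  }
  if (per_disease) {
    parts <- split(results, results$disease_id)
    out <- do.call(rbind, lapply(parts, norm_one))
    out <- out[order(match(paste(out$compound_id, out$disease_id),
                           paste(results$compound_id, results$disease_id))), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    norm_one(results)
  }
}
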