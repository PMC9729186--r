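# Synthetic fixture generation: seeded, self-consistent toy datasets with
# planted repurposing structure. All identifiers are synthetic (shape-valid
# random InChIKeys, P-style protein accessions, C-style disease CUIs).

# Filler scaffolds: drug-like two/three-ring cores with three substitution
# slots, validated to parse for every substituent in .fixture_subs.
.fixture_scaffolds <- c(
  "c1cc(%s)ccc1C(=O)Nc1ccc(%s)c(%s)c1",
  "c1cc(%s)ccc1S(=O)(=O)Nc1ccc(%s)c(%s)c1",
  "c1cc(%s)ccc1Nc1nc(%s)ccc1C(=O)Nc1ccc(%s)cc1",
  "c1cc(%s)ccc1Oc1ccc(%s)cc1C(=O)Nc1ccc(%s)cc1",
  "c1cc(%s)ccc1Cc1ccc(%s)c(%s)c1",
  "c1cc(%s)ccc1NC(=O)Nc1ccc(%s)c(%s)c1",
  "c1cc(%s)cc(%s)c1C(=O)Nc1ccc2c(c1)cc(%s)[nH]2",
  "c1cc(%s)ccc1C(=O)Nc1ccc2ncc(%s)cc2c1%s",
  "c1cc(%s)ccc1CN1CCN(CC1)c1ccc(%s)c(%s)c1",
  "c1cc(%s)ccc1C(=O)N1CCC(CC1)Nc1ncc(%s)cc1%s",
  "c1cc(%s)ccc1c1cc(%s)nc(n1)Nc1ccc(%s)cc1",
  "c1cc(%s)ccc1NC(=O)c1cc(%s)sc1%s",
  "c1cc(%s)ccc1NC(=O)c1cc(%s)on1%s",
  "c1cc(%s)ccc1n1cc(%s)c(n1)c1ccc(%s)cc1",
  "c1cc(%s)ccc1C(=O)Nc1nc2cc(%s)ccc2s1%s",
  "c1cc(%s)ccc1C(=O)Nc1nc2cc(%s)ccc2[nH]1%s",
  "c1cc(%s)ccc1CNC(=O)c1ccc2OCOc2c1%s%s",
  "c1cc(%s)ccc1N1CCOC(C1)c1ccc(%s)c(%s)c1",
  "c1cc(%s)ccc1C#Cc1ccc(%s)c(%s)c1",
  "c1cc(%s)ccc1C(=O)Oc1ccc(%s)c(%s)c1"
)

# Planted scaffolds: larger four-ring cores reserved for planted
# drug/candidate pairs, so a single substituent-level edit leaves the
# shared substructure dominant (ECFP4 Tanimoto stays high for every
# substituent draw). Disjoint from the filler list, so no filler compound
# shares a planted pair's scaffold.
.fixture_planted_scaffolds <- c(
  "c1cc(%s)ccc1Nc1nc(%s)cc(%s)c1C(=O)Nc1ccc(cc1)N1CCN(C)CC1",
  "c1cc(%s)cc(%s)c1C(=O)Nc1ccc(cc1)c1nc2cc(%s)ccc2[nH]1",
  "c1cc(%s)ccc1C(=O)Nc1cc(%s)c(cc1%s)Nc1ncnc2ccccc12",
  "c1cc(%s)ccc1Oc1ccc(cc1)CN1CCC(CC1)NC(=O)c1cc(%s)c(cc1%s)OC",
  "c1cc(%s)ccc1S(=O)(=O)N1CCN(CC1)c1ccc(%s)c(c1)C(=O)Nc1ccc(%s)cn1"
)

.fixture_subs  <- c("C", "CC", "O", "N", "F", "Cl", "Br", "OC", "C(C)C",
                    "C(=O)O", "C(=O)N", "CO", "CN", "C(F)(F)F")
.fixture_bulky <- c("CC", "OC", "C(C)C", "C(=O)O", "C(=O)N", "CO", "CN",
                    "C(F)(F)F")
.fixture_small <- c("C", "F", "Cl")

random_inchikey <- function(n) {
  keys <- character(0)
  while (length(keys) < n) {
    k <- vapply(seq_len(n - length(keys)), function(i) {
      paste0(paste(sample(LETTERS, 14, replace = TRUE), collapse = ""), "-",
             paste(sample(LETTERS, 10, replace = TRUE), collapse = ""), "-",
             sample(LETTERS, 1))
    }, character(1))
    keys <- unique(c(keys, k))
  }
  keys
}

#' Specify a synthetic fixture
#'
#' Describes a seeded toy dataset with planted repurposing structure: for
#' each planted pair, one approved drug is built on a large reserved
#' scaffold, one candidate shares that scaffold up to a single
#' substituent-level edit (when `shared_scaffold` is `TRUE`) and shares the
#' configured fraction of the drug's potent targets, the disease's gene set
#' equals the candidate's target set, and one decoy candidate shares
#' neither scaffold nor targets, with its targets placed on a pendant chain
#' far from the disease genes in the PPI graph.
#'
#' @param seed integer RNG seed; the whole fixture is reproducible from it.
#' @param n_candidates,n_drugs,n_diseases,n_targets,n_ppi_nodes dataset
#'   dimensions (positive integers). `n_ppi_nodes` counts the core graph
#'   before decoy chains are attached.
#' @param planted list of planted pairs; each element is a list with
#'   `disease` (index in `1:n_diseases`, unique across entries), `overlap`
#'   (target-overlap fraction in \[0, 1\]) and `shared_scaffold` (logical).
#' @param potency_mix fraction of quantitative bioactivity records drawn
#'   above the 1000 nM potency threshold.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_candidates = 30L, n_drugs = 6L,
                         n_diseases = 3L, n_targets = 40L,
                         n_ppi_nodes = 120L,
                         planted = list(list(disease = 1L, overlap = 1,
                                             shared_scaffold = TRUE)),
                         potency_mix = 0.3) {
  stopifnot(n_candidates > 0, n_drugs > 0, n_diseases > 0, n_targets > 0,
            n_ppi_nodes > 0, potency_mix >= 0, potency_mix <= 1)
  if (n_ppi_nodes < n_targets) {
    stop("n_ppi_nodes must be at least n_targets", call. = FALSE)
  }
  for (p in planted) {
    stopifnot(is.list(p), p$disease >= 1, p$disease <= n_diseases,
              p$overlap >= 0, p$overlap <= 1, is.logical(p$shared_scaffold))
  }
  if (anyDuplicated(vapply(planted, `[[`, numeric(1), "disease"))) {
    stop("planted diseases must be unique", call. = FALSE)
  }
  if (n_candidates < 2 * length(planted)) {
    stop("need at least two candidates (planted + decoy) per planted pair",
         call. = FALSE)
  }
  if (n_drugs < length(planted)) {
    stop("need at least one drug per planted pair", call. = FALSE)
  }
  if (n_targets < 14) {
    stop("n_targets too small to draw disjoint drug/candidate target sets",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 n_candidates = as.integer(n_candidates),
                 n_drugs = as.integer(n_drugs),
                 n_diseases = as.integer(n_diseases),
                 n_targets = as.integer(n_targets),
                 n_ppi_nodes = as.integer(n_ppi_nodes),
                 planted = planted,
                 potency_mix = potency_mix),
            class = "fixture_spec")
}

#' Generate a synthetic fixture
#'
#' Writes the five tabular inputs (compounds, bioactivities, PPI edges,
#' disease genes, indications) plus a JSON ground-truth manifest into
#' `out_dir`. Every file passes its corresponding reader with zero
#' warnings, and the run is byte-reproducible from the spec's seed. The
#' planted drug/candidate/decoy pairs are additionally backed by unary
#' (curated) bioactivity records so the planted structure survives any
#' potency mix.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the file `paths` and the `manifest`.
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  n_pl <- length(spec$planted)
  drug_ids <- random_inchikey(spec$n_drugs)
  cand_ids <- random_inchikey(spec$n_candidates)
  # reserve slots: first n_pl candidates planted, next n_pl are decoys
  planted_cand <- cand_ids[seq_len(n_pl)]
  decoy_cand <- cand_ids[n_pl + seq_len(n_pl)]
  planted_drug <- drug_ids[seq_len(n_pl)]
  disease_ids <- sprintf("C%07d", sample(1e6:(1e7 - 1), spec$n_diseases))

  target_pool <- sprintf("P%05d", 10000 + seq_len(spec$n_targets))

  ## SMILES assembly --------------------------------------------------------
  smiles <- character(0)
  mk <- function(tpl, s1, s2, s3) sprintf(tpl, s1, s2, s3)
  planted_scaf <- sample(.fixture_planted_scaffolds, n_pl, replace = TRUE)
  for (i in seq_len(n_pl)) {
    s1 <- sample(.fixture_bulky, 1); s2 <- sample(.fixture_bulky, 1)
    s3 <- sample(.fixture_small, 1)
    smiles[planted_drug[i]] <- mk(planted_scaf[i], s1, s2, s3)
    if (isTRUE(spec$planted[[i]]$shared_scaffold)) {
      s3b <- sample(setdiff(.fixture_small, s3), 1)
      smiles[planted_cand[i]] <- mk(planted_scaf[i], s1, s2, s3b)
    } else {
      smiles[planted_cand[i]] <- mk(sample(.fixture_scaffolds, 1),
                                    sample(.fixture_subs, 1),
                                    sample(.fixture_subs, 1),
                                    sample(.fixture_subs, 1))
    }
    smiles[decoy_cand[i]] <- mk(sample(.fixture_scaffolds, 1),
                                sample(.fixture_subs, 1),
                                sample(.fixture_subs, 1),
                                sample(.fixture_subs, 1))
  }
  filler <- setdiff(c(drug_ids, cand_ids), names(smiles))
  for (id in filler) {
    smiles[id] <- mk(sample(.fixture_scaffolds, 1),
                     sample(.fixture_subs, 1),
                     sample(.fixture_subs, 1),
                     sample(.fixture_subs, 1))
  }

  ## target assignment ------------------------------------------------------
  targets <- list()
  for (id in drug_ids) targets[[id]] <- sample(target_pool, sample(4:7, 1))
  overlap_achieved <- numeric(n_pl)
  for (i in seq_len(n_pl)) {
    dt <- targets[[planted_drug[i]]]
    f <- spec$planted[[i]]$overlap
    k <- round(f * length(dt))
    if (f > 0 && k == 0) k <- 1
    extra_pool <- setdiff(target_pool, dt)
    if (length(extra_pool) < length(dt) - k) {
      stop("target pool too small for requested overlap fraction",
           call. = FALSE)
    }
    ct <- c(sample(dt, k), if (k < length(dt)) sample(extra_pool, length(dt) - k))
    targets[[planted_cand[i]]] <- ct
    overlap_achieved[i] <- k / length(dt)
  }
  # decoy targets live on dedicated pendant-chain nodes, far from everything
  chain_len <- 8L
  decoy_chains <- lapply(seq_len(n_pl), function(i)
    sprintf("P9%04d", (i - 1) * chain_len + seq_len(chain_len)))
  for (i in seq_len(n_pl)) {
    targets[[decoy_cand[i]]] <- decoy_chains[[i]][(chain_len - 2):chain_len]
  }
  for (id in setdiff(cand_ids, c(planted_cand, decoy_cand))) {
    targets[[id]] <- sample(target_pool, sample(2:6, 1))
  }

  ## indications and disease genes -----------------------------------------
  ind <- data.frame(drug_id = character(), disease_id = character(),
                    stringsAsFactors = FALSE)
  filler_drugs <- setdiff(drug_ids, planted_drug)
  for (j in seq_len(spec$n_diseases)) {
    pl_i <- which(vapply(spec$planted, `[[`, numeric(1), "disease") == j)
    if (length(pl_i) == 1) {
      # planted diseases get exactly their planted drug, so the candidate's
      # scores against it are not diluted by unrelated approved drugs
      drugs_here <- planted_drug[pl_i]
    } else if (length(filler_drugs) > 0) {
      n_extra <- sample(1:min(3, length(filler_drugs)), 1)
      drugs_here <- sample(filler_drugs, n_extra)
    } else {
      drugs_here <- character(0)
    }
    ind <- rbind(ind, data.frame(drug_id = drugs_here,
                                 disease_id = disease_ids[j],
                                 stringsAsFactors = FALSE))
  }
  dis_genes <- list()
  for (j in seq_len(spec$n_diseases)) {
    pl_i <- which(vapply(spec$planted, `[[`, numeric(1), "disease") == j)
    dis_genes[[disease_ids[j]]] <- if (length(pl_i) == 1) {
      sort(targets[[planted_cand[pl_i]]])
    } else {
      sort(sample(target_pool, sample(3:8, 1)))
    }
  }

  ## PPI graph: spanning tree over core nodes + shortcuts + decoy chains ----
  n_extra_nodes <- spec$n_ppi_nodes - spec$n_targets
  extra_nodes <- if (n_extra_nodes > 0)
    sprintf("P%05d", 50000 + seq_len(n_extra_nodes)) else character(0)
  core <- sample(c(target_pool, extra_nodes))
  edges <- cbind(core[-1], core[sapply(2:length(core), function(i)
    sample(i - 1, 1))])
  n_shortcuts <- length(core)
  sc_a <- sample(core, n_shortcuts, replace = TRUE)
  sc_b <- sample(core, n_shortcuts, replace = TRUE)
  keep <- sc_a != sc_b
  edges <- rbind(edges, cbind(sc_a[keep], sc_b[keep]))
  for (i in seq_len(n_pl)) {
    ch <- decoy_chains[[i]]
    anchor <- if (length(extra_nodes) > 0) sample(extra_nodes, 1)
              else sample(core, 1)
    edges <- rbind(edges, cbind(anchor, ch[1]),
                   cbind(ch[-length(ch)], ch[-1]))
  }
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- edges[!duplicated(ekey), , drop = FALSE]
  edge_df <- data.frame(protein_a = pmin(edges[, 1], edges[, 2]),
                        protein_b = pmax(edges[, 1], edges[, 2]),
                        stringsAsFactors = FALSE)
  edge_df <- edge_df[order(edge_df$protein_a, edge_df$protein_b), ]

  ## bioactivity records ----------------------------------------------------
  pinned <- c(planted_drug, planted_cand, decoy_cand)
  bio <- list()
  for (id in names(targets)) {
    for (t in sort(targets[[id]])) {
      above <- stats::runif(1) < spec$potency_mix
      pot <- if (above) round(stats::runif(1, 1001, 9000), 1)
             else round(stats::runif(1, 5, 999), 1)
      bio[[length(bio) + 1]] <- data.frame(
        compound_id = id, target_id = t,
        potency_nm = format(pot, scientific = FALSE, trim = TRUE),
        source = "assay", stringsAsFactors = FALSE)
      if (id %in% pinned) {
        bio[[length(bio) + 1]] <- data.frame(
          compound_id = id, target_id = t, potency_nm = "",
          source = "curated", stringsAsFactors = FALSE)
      }
    }
  }
  bio <- do.call(rbind, bio)
  bio <- bio[order(bio$compound_id, bio$target_id, bio$source), ]

  ## write files ------------------------------------------------------------
  all_ids <- sort(c(drug_ids, cand_ids))
  comp_df <- data.frame(compound_id = all_ids, smiles = smiles[all_ids],
                        stringsAsFactors = FALSE)
  dg_df <- data.frame(
    disease_id = rep(names(dis_genes), lengths(dis_genes)),
    gene_id = unlist(dis_genes, use.names = FALSE),
    stringsAsFactors = FALSE)
  ind <- ind[order(ind$drug_id, ind$disease_id), ]

  paths <- list(
    compounds     = file.path(out_dir, "compounds.tsv"),
    bioactivities = file.path(out_dir, "bioactivities.tsv"),
    ppi_edges     = file.path(out_dir, "ppi_edges.tsv"),
    disease_genes = file.path(out_dir, "disease_genes.tsv"),
    indications   = file.path(out_dir, "indications.tsv"),
    manifest      = file.path(out_dir, "manifest.json"))
  wt <- function(df, path) utils::write.table(df, path, sep = "\t",
                                              quote = FALSE, row.names = FALSE)
  wt(comp_df, paths$compounds)
  wt(bio, paths$bioactivities)
  wt(edge_df, paths$ppi_edges)
  wt(dg_df, paths$disease_genes)
  wt(ind, paths$indications)

  manifest <- list(
    seed = spec$seed,
    n_candidates = spec$n_candidates, n_drugs = spec$n_drugs,
    n_diseases = spec$n_diseases, n_targets = spec$n_targets,
    n_ppi_nodes = spec$n_ppi_nodes, potency_mix = spec$potency_mix,
    disease_ids = disease_ids,
    drug_ids = drug_ids,
    candidate_ids = cand_ids,
    planted = lapply(seq_len(n_pl), function(i) list(
      disease_id = disease_ids[spec$planted[[i]]$disease],
      drug_id = planted_drug[i],
      candidate_id = planted_cand[i],
      decoy_id = decoy_cand[i],
      overlap_config = spec$planted[[i]]$overlap,
      overlap_achieved = overlap_achieved[i],
      shared_scaffold = spec$planted[[i]]$shared_scaffold)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(paths = paths, manifest = manifest))
}
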