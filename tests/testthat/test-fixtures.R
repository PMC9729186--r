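test_that("fixture specs validate their constraints", {
  expect_s3_class(fixture_spec(), "fixture_spec")
  expect_error(fixture_spec(n_targets = 5), "n_targets")
  expect_error(fixture_spec(n_ppi_nodes = 10, n_targets = 40), "n_ppi_nodes")
  expect_error(fixture_spec(planted = list(
    list(disease = 9, overlap = 1, shared_scaffold = TRUE))), "disease")
  expect_error(fixture_spec(n_candidates = 1), "decoy")
  expect_error(fixture_spec(planted = list(
    list(disease = 1, overlap = 1, shared_scaffold = TRUE),
    list(disease = 1, overlap = 0.5, shared_scaffold = FALSE))), "unique")
})

test_that("the same spec and seed reproduce byte-identical files", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  generate_fixture(fixture_spec(seed = 33), d1)
  generate_fixture(fixture_spec(seed = 33), d2)
  for (f in c("compounds.tsv", "bioactivities.tsv", "ppi_edges.tsv",
              "disease_genes.tsv", "indications.tsv", "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed changes the data
  d3 <- file.path(tempdir(), "det3")
  generate_fixture(fixture_spec(seed = 34), d3)
  expect_false(identical(readLines(file.path(d1, "compounds.tsv")),
                         readLines(file.path(d3, "compounds.tsv"))))
})

test_that("every generated file passes its reader with zero warnings", {
  fx <- generate_fixture(fixture_spec(seed = 12), file.path(tempdir(), "clean"))
  objs <- list(read_compound_table(fx$paths$compounds),
               read_bioactivity_table(fx$paths$bioactivities),
               read_ppi_edges(fx$paths$ppi_edges),
               read_disease_genes(fx$paths$disease_genes),
               read_indications(fx$paths$indications))
  for (o in objs) {
    expect_equal(reader_meta(o)$warnings, character(0))
    expect_equal(reader_meta(o)$n_dropped, 0)
  }
  # all SMILES parse
  fps <- fingerprint_compounds(objs[[1]], quiet = TRUE)
  expect_equal(attr(fps, "n_failed"), 0)
})

test_that("planted OCTS equals the configured overlap fraction", {
  for (f in c(0.25, 0.5, 1)) {
    fx <- generate_fixture(
      fixture_spec(seed = 21, planted = list(
        list(disease = 1, overlap = f, shared_scaffold = TRUE))),
      file.path(tempdir(), paste0("ov", f * 100)))
    pl <- fx$manifest$planted[[1]]
    bio <- read_bioactivity_table(fx$paths$bioactivities)
    prof <- build_target_profiles(filter_potent(bio))
    got <- octs(prof[[pl$drug_id]], prof[[pl$candidate_id]])
    expect_equal(got, pl$overlap_achieved)
    expect_equal(pl$overlap_achieved, f, tolerance = 0.2)
  }
})

test_that("potency mix 1 leaves only unary-backed pairs after filtering", {
  fx <- generate_fixture(fixture_spec(seed = 13, potency_mix = 1),
                         file.path(tempdir(), "allmix"))
  bio <- read_bioactivity_table(fx$paths$bioactivities)
  expect_true(all(bio$potency_nm > 1000, na.rm = TRUE))
  pairs <- filter_potent(bio)
  # survivors are exactly the pairs with unary evidence (the pinned
  # planted drug, planted candidate and decoy)
  unary_pairs <- unique(paste(bio$compound_id[is.na(bio$potency_nm)],
                              bio$target_id[is.na(bio$potency_nm)]))
  expect_setequal(paste(pairs$compound_id, pairs$target_id), unary_pairs)
  pl <- fx$manifest$planted[[1]]
  expect_setequal(unique(bio$compound_id[is.na(bio$potency_nm)]),
                  c(pl$drug_id, pl$candidate_id, pl$decoy_id))
})

test_that("the planted disease's genes coincide with the planted targets", {
  fx <- generate_fixture(fixture_spec(seed = 19), file.path(tempdir(), "dg"))
  pl <- fx$manifest$planted[[1]]
  dmap <- read_disease_genes(fx$paths$disease_genes)
  bio <- read_bioactivity_table(fx$paths$bioactivities)
  prof <- build_target_profiles(filter_potent(bio))
  expect_setequal(dmap[[pl$disease_id]], prof[[pl$candidate_id]])
  # and they all live in the PPI graph, at raw distance zero
  g <- read_ppi_edges(fx$paths$ppi_edges)
  p <- raw_proximity(prof[[pl$candidate_id]], dmap[[pl$disease_id]], g)
  expect_equal(p$raw_distance, 0)
})
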