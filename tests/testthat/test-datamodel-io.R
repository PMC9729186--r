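test_that("compound reader parses well-formed rows and flags bad ones", {
  expect_error(read_compound_table(tempfile()), "not found")

  comp <- read_compound_table(compound_file_3rows())
  expect_equal(nrow(comp), 3)
  expect_equal(reader_meta(comp)$warnings, character(0))
  expect_equal(comp$role, rep("candidate", 3))

  # duplicate among 4 rows collapses to first occurrence
  p <- write_tsv_text(c("compound_id\tsmiles",
                        paste0(ik(1), "\tCCO"),
                        paste0(ik(2), "\tCC"),
                        paste0(ik(1), "\tCCCC"),
                        paste0(ik(3), "\tCCC")))
  comp <- read_compound_table(p)
  expect_equal(nrow(comp), 3)
  expect_equal(reader_meta(comp)$n_duplicates, 1)
  expect_equal(comp$smiles[comp$compound_id == ik(1)], "CCO")

  # malformed identifier is rejected and reported with its row number
  p <- write_tsv_text(c("compound_id\tsmiles",
                        "not-an-inchikey\tCCO",
                        paste0(ik(2), "\tCC")))
  comp <- read_compound_table(p)
  expect_equal(nrow(comp), 1)
  expect_match(reader_meta(comp)$warnings, "row 1.*not-an-inchikey")

  expect_error(read_compound_table(write_tsv_text(c("id\tsmiles", "x\ty"))),
               "compound_id")
  expect_error(read_compound_table(
    write_tsv_text(c("compound_id\tsmiles", "bad\tCCO"))), "no valid")
})

test_that("bioactivity reader separates quantitative, unary and bad rows", {
  p <- write_tsv_text(c("compound_id\ttarget_id\tpotency_nm\tsource",
                        paste0(ik(1), "\tP00001\t500\tassay"),
                        paste0(ik(1), "\tP00002\t\t"),
                        paste0(ik(1), "\tP00003\t-3\tassay"),
                        paste0(ik(1), "\tP00004\tabc\tassay")))
  bio <- read_bioactivity_table(p)
  expect_equal(nrow(bio), 2)
  expect_equal(bio$potency_nm[bio$target_id == "P00001"], 500)
  expect_true(is.na(bio$potency_nm[bio$target_id == "P00002"]))
  expect_equal(bio$source[bio$target_id == "P00002"], "unary")
  expect_equal(reader_meta(bio)$n_dropped, 2)
  expect_match(reader_meta(bio)$warnings[1], "row 3")
})

test_that("PPI reader collapses reversed duplicates and drops self-loops", {
  p <- write_tsv_text(c("protein_a\tprotein_b", "a\tb", "b\ta", "b\tc"))
  g <- read_ppi_edges(p)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::vcount(g), 3)

  p <- write_tsv_text(c("protein_a\tprotein_b", "a\ta", "a\tb"))
  g <- read_ppi_edges(p)
  expect_equal(igraph::ecount(g), 1)
  expect_match(reader_meta(g)$warnings, "self-loop")

  # a path of 5 chained edges has 6 nodes
  p <- write_tsv_text(c("protein_a\tprotein_b",
                        paste(letters[1:5], letters[2:6], sep = "\t")))
  g <- read_ppi_edges(p)
  expect_equal(igraph::ecount(g), 5)
  expect_equal(igraph::vcount(g), 6)

  expect_error(read_ppi_edges(write_tsv_text(c("a\tb", "x\tx"))), "no edges")
})

test_that("disease-gene reader groups by CUI and validates shapes", {
  p <- write_tsv_text(c("disease_id\tgene_id",
                        "C0000001\tg1", "C0000001\tg2",
                        "C0000002\tg1", "C0000002\tg3"))
  m <- read_disease_genes(p)
  expect_length(m, 2)
  expect_equal(m[["C0000001"]], c("g1", "g2"))

  p <- write_tsv_text(c("disease_id\tgene_id", "12345\tg1", "C0000009\tg1"))
  m <- read_disease_genes(p)
  expect_length(m, 1)
  expect_match(reader_meta(m)$warnings, "12345")
})

test_that("indication reader deduplicates (drug, disease) pairs", {
  p <- write_tsv_text(c("drug_id\tdisease_id",
                        paste0(ik(1), "\tC0000001"),
                        paste0(ik(1), "\tC0000001"),
                        paste0(ik(2), "\tC0000002")))
  ind <- read_indications(p)
  expect_equal(nrow(ind), 2)
  expect_equal(reader_meta(ind)$n_duplicates, 1)
})

test_that("write-then-read round-trips every format and readers are deterministic", {
  fx <- generate_fixture(fixture_spec(seed = 11), file.path(tempdir(), "rt"))
  strip <- function(x) { attr(x, "reader_meta") <- NULL; x }

  comp <- read_compound_table(fx$paths$compounds)
  p2 <- tempfile(); write_compound_table(comp, p2)
  expect_identical(strip(read_compound_table(p2)), strip(comp))

  bio <- read_bioactivity_table(fx$paths$bioactivities)
  p2 <- tempfile(); write_bioactivity_table(bio, p2)
  expect_identical(strip(read_bioactivity_table(p2)), strip(bio))

  g <- read_ppi_edges(fx$paths$ppi_edges)
  p2 <- tempfile(); write_ppi_edges(g, p2)
  g2 <- read_ppi_edges(p2)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)

  dm <- read_disease_genes(fx$paths$disease_genes)
  p2 <- tempfile(); write_disease_genes(dm, p2)
  expect_identical(strip(read_disease_genes(p2)), strip(dm))

  ind <- read_indications(fx$paths$indications)
  p2 <- tempfile(); write_indications(ind, p2)
  expect_identical(strip(read_indications(p2)), strip(ind))

  # determinism: same file, same records in same order
  expect_identical(read_compound_table(fx$paths$compounds), comp)
})
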