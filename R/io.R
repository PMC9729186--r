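#' @importFrom utils read.delim write.table
NULL

# Shared low-level reader: delimiter-separated text with a mandatory header.
read_table_checked <- function(path, required, delim = "\t") {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- read.delim(path, sep = delim, header = TRUE,
                   colClasses = "character", check.names = FALSE,
                   na.strings = NULL, quote = "", comment.char = "")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a compound table
#'
#' Parses a delimiter-separated file with columns `compound_id` (standard
#' InChIKey) and `smiles`. Rows whose identifier is not shape-valid are
#' skipped and reported, with their row numbers, in the reader metadata
#' (see [reader_meta()]); duplicated identifiers are collapsed to the first
#' occurrence.
#'
#' @param path path to the file.
#' @param role `"candidate"` or `"approved_drug"`; recorded in the `role`
#'   column of the result.
#' @param delim field delimiter; tab by default.
#' @return a `data.frame` with columns `compound_id`, `smiles`, `role` and
#'   reader metadata attached.
#' @export
read_compound_table <- function(path, role = c("candidate", "approved_drug"),
                                delim = "\t") {
  role <- match.arg(role)
  df <- read_table_checked(path, c("compound_id", "smiles"), delim)
  warnings <- character()

  ok <- is_inchikey(df$compound_id) & nzchar(df$smiles)
  if (any(!ok)) {
    warnings <- c(warnings, sprintf(
      "row %d: invalid compound_id or empty smiles ('%s')",
      which(!ok), df$compound_id[!ok]))
  }
  df <- df[ok, , drop = FALSE]

  dup <- duplicated(df$compound_id)
  n_dup <- sum(dup)
  if (n_dup > 0) {
    warnings <- c(warnings, sprintf("%d duplicate compound_id row(s) collapsed to first occurrence", n_dup))
    df <- df[!dup, , drop = FALSE]
  }
  if (nrow(df) == 0) {
    stop("no valid compound rows in ", path, call. = FALSE)
  }
  out <- data.frame(compound_id = df$compound_id, smiles = df$smiles,
                    role = role, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  set_reader_meta(out, warnings, sum(!ok), n_dup)
}

#' Read a bioactivity table
#'
#' Parses compound-target bioactivity records with columns `compound_id`,
#' `target_id` and optionally `potency_nm` (nM) and `source`. A row with an
#' empty potency cell becomes a unary record (curated interaction with no
#' quantitative measurement); rows with a non-numeric or non-positive potency
#' are rejected with row-level warnings.
#'
#' @inheritParams read_compound_table
#' @return a `data.frame` with columns `compound_id`, `target_id`,
#'   `potency_nm` (numeric, `NA` for unary records) and `source`, with
#'   reader metadata attached.
#' @export
read_bioactivity_table <- function(path, delim = "\t") {
  df <- read_table_checked(path, c("compound_id", "target_id"), delim)
  warnings <- character()

  pot_raw <- if ("potency_nm" %in% names(df)) df$potency_nm else rep("", nrow(df))
  src <- if ("source" %in% names(df)) df$source else rep("", nrow(df))

  is_unary <- !nzchar(trimws(pot_raw))
  pot <- suppressWarnings(as.numeric(pot_raw))
  bad <- !is_unary & (is.na(pot) | pot <= 0)
  if (any(bad)) {
    warnings <- c(warnings, sprintf(
      "row %d: potency '%s' is not a positive number; row rejected",
      which(bad), pot_raw[bad]))
  }
  bad_id <- !is_inchikey(df$compound_id) | !nzchar(df$target_id)
  if (any(bad_id & !bad)) {
    warnings <- c(warnings, sprintf(
      "row %d: invalid compound_id or empty target_id; row rejected",
      which(bad_id & !bad)))
  }
  keep <- !bad & !bad_id
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0) {
    stop("no valid bioactivity rows in ", path, call. = FALSE)
  }
  src <- src[keep]
  src[!nzchar(src)] <- ifelse(is_unary[keep][!nzchar(src)], "unary", "quantitative")
  out <- data.frame(compound_id = df$compound_id,
                    target_id   = df$target_id,
                    potency_nm  = ifelse(is_unary[keep], NA_real_, pot[keep]),
                    source      = src,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  set_reader_meta(out, warnings, sum(!keep))
}

#' Read a protein-protein interaction edge list
#'
#' Parses a two-column undirected edge list into a simple graph. Self-loops
#' are dropped with a warning; duplicate edges (including reversed
#' duplicates) are collapsed; the node set is the union of all endpoint
#' identifiers. The gene/protein namespace must match the `target_id`
#' namespace of the bioactivity table -- identifiers are treated as opaque
#' strings and the caller is responsible for harmonization.
#'
#' @inheritParams read_compound_table
#' @return an [igraph::igraph] undirected simple graph, with reader
#'   metadata attached.
#' @export
read_ppi_edges <- function(path, delim = "\t") {
  df <- read_table_checked(path, character(), delim)
  if (ncol(df) < 2) {
    stop("PPI edge list must have at least two columns: ", path, call. = FALSE)
  }
  a <- df[[1]]; b <- df[[2]]
  warnings <- character()
  loops <- a == b
  if (any(loops)) {
    warnings <- c(warnings, sprintf("row %d: self-loop (%s) dropped", which(loops), a[loops]))
  }
  a2 <- a[!loops]; b2 <- b[!loops]
  if (length(a2) == 0) {
    stop("no edges in PPI file ", path, call. = FALSE)
  }
  key <- paste(pmin(a2, b2), pmax(a2, b2), sep = "\r")
  dup <- duplicated(key)
  g <- igraph::graph_from_edgelist(cbind(a2[!dup], b2[!dup]), directed = FALSE)
  set_reader_meta(g, warnings, sum(loops), sum(dup))
}

#' Read disease-gene associations
#'
#' Parses rows of (`disease_id`, `gene_id`) into a per-disease gene-set map.
#' Disease identifiers must be shape-valid UMLS CUIs; invalid rows are
#' skipped with warnings.
#'
#' @inheritParams read_compound_table
#' @return a named list (class `disease_gene_map`) mapping each disease CUI
#'   to a character vector of unique gene identifiers, with reader metadata
#'   attached.
#' @export
read_disease_genes <- function(path, delim = "\t") {
  df <- read_table_checked(path, c("disease_id", "gene_id"), delim)
  warnings <- character()
  ok <- is_cui(df$disease_id) & nzchar(df$gene_id)
  if (any(!ok)) {
    warnings <- c(warnings, sprintf(
      "row %d: invalid disease CUI '%s' or empty gene_id; row rejected",
      which(!ok), df$disease_id[!ok]))
  }
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0) {
    stop("no valid disease-gene rows in ", path, call. = FALSE)
  }
  map <- lapply(split(df$gene_id, df$disease_id), function(g) sort(unique(g)))
  map <- map[order(names(map))]
  class(map) <- "disease_gene_map"
  set_reader_meta(map, warnings, sum(!ok))
}

#' Read approved drug indications
#'
#' Parses rows of (`drug_id`, `disease_id`): each row states that the drug
#' (InChIKey) is approved for the disease (UMLS CUI). Duplicated pairs are
#' collapsed with a warning; rows failing identifier shape validation are
#' skipped.
#'
#' @inheritParams read_compound_table
#' @return a `data.frame` with columns `drug_id` and `disease_id`, one row
#'   per unique approved indication, with reader metadata attached.
#' @export
read_indications <- function(path, delim = "\t") {
  df <- read_table_checked(path, c("drug_id", "disease_id"), delim)
  warnings <- character()
  ok <- is_inchikey(df$drug_id) & is_cui(df$disease_id)
  if (any(!ok)) {
    warnings <- c(warnings, sprintf(
      "row %d: invalid drug_id '%s' or disease_id '%s'; row rejected",
      which(!ok), df$drug_id[!ok], df$disease_id[!ok]))
  }
  df <- df[ok, , drop = FALSE]
  dup <- duplicated(paste(df$drug_id, df$disease_id))
  if (any(dup)) {
    warnings <- c(warnings, sprintf("%d duplicate (drug, disease) row(s) collapsed", sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  if (nrow(df) == 0) {
    stop("no valid indication rows in ", path, call. = FALSE)
  }
  out <- data.frame(drug_id = df$drug_id, disease_id = df$disease_id,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  set_reader_meta(out, warnings, sum(!ok), sum(dup))
}

#' Write parsed collections back to their tabular formats
#'
#' Inverse of the corresponding readers: writing a parsed collection and
#' re-reading it yields an identical collection (round-trip property).
#'
#' @param x the parsed object.
#' @param path output file path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(x, path, delim = "\t") {
  write.table(x[, c("compound_id", "smiles")], path, sep = delim,
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_compound_table
#' @export
write_bioactivity_table <- function(x, path, delim = "\t") {
  out <- x
  out$potency_nm <- ifelse(is.na(x$potency_nm), "",
                           format(x$potency_nm, trim = TRUE, scientific = FALSE))
  write.table(out, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_compound_table
#' @export
write_ppi_edges <- function(x, path, delim = "\t") {
  el <- igraph::as_edgelist(x)
  el <- data.frame(protein_a = pmin(el[, 1], el[, 2]),
                   protein_b = pmax(el[, 1], el[, 2]),
                   stringsAsFactors = FALSE)
  el <- el[order(el$protein_a, el$protein_b), , drop = FALSE]
  write.table(el, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_compound_table
#' @export
write_disease_genes <- function(x, path, delim = "\t") {
  df <- data.frame(
    disease_id = rep(names(x), lengths(x)),
    gene_id    = unlist(x, use.names = FALSE),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_compound_table
#' @export
write_indications <- function(x, path, delim = "\t") {
  write.table(x[, c("drug_id", "disease_id")], path, sep = delim,
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
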