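#' ECFP4 structural fingerprint of a molecule
#'
#' Computes the extended-connectivity circular fingerprint of radius 2
#' (ECFP4) for a SMILES string, folded to a fixed-length bit vector by the
#' OpenBabel backend. The fingerprint is a sparse representation: the sorted
#' positions of set bits plus the total length. ECFP is invariant to atom
#' ordering, so different SMILES writings of the same molecule yield
#' identical fingerprints.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `ecfp` with elements `on` (sorted 1-based
#'   positions of set bits), `nbits` (vector length) and `n_on`.
#' @seealso [tanimoto()], [fingerprint_compounds()]
#' @export
ecfp4_fingerprint <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (!nzchar(smiles)) {
    stop(errorCondition(paste0("unparseable SMILES: '", smiles, "'"),
                        smiles = smiles, class = "drugrepo_smiles_error"))
  }
  bits <- tryCatch({
    mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)
    ChemmineOB::fingerprint_OB(mol, "ECFP4")
  }, error = function(e) {
    stop(errorCondition(paste0("unparseable SMILES: '", smiles, "'"),
                        smiles = smiles, class = "drugrepo_smiles_error"))
  })
  on <- which(bits != 0)
  structure(list(on = on, nbits = length(bits), n_on = length(on)),
            class = "ecfp")
}

#' @export
print.ecfp <- function(x, ...) {
  cat(sprintf("<ECFP4 fingerprint: %d/%d bits set>\n", x$n_on, x$nbits))
  invisible(x)
}

#' Fingerprint a compound table
#'
#' Computes ECFP4 fingerprints for every compound in a parsed compound
#' table. Compounds whose SMILES fail to parse are excluded; their count is
#' reported in the `n_failed` attribute and their identifiers in `failed`.
#'
#' @param compounds a compound table from [read_compound_table()], or any
#'   data.frame with `compound_id` and `smiles` columns.
#' @param quiet suppress the per-run message about failed structures.
#' @return a named list of `ecfp` fingerprints keyed by compound identifier.
#' @export
fingerprint_compounds <- function(compounds, quiet = FALSE) {
  fps <- list()
  failed <- character()
  for (i in seq_len(nrow(compounds))) {
    fp <- tryCatch(ecfp4_fingerprint(compounds$smiles[i]),
                   drugrepo_smiles_error = function(e) NULL)
    if (is.null(fp)) {
      failed <- c(failed, compounds$compound_id[i])
    } else {
      fps[[compounds$compound_id[i]]] <- fp
    }
  }
  if (length(failed) > 0 && !quiet) {
    message(length(failed), " compound(s) excluded: SMILES failed to parse")
  }
  attr(fps, "n_failed") <- length(failed)
  attr(fps, "failed") <- failed
  fps
}

#' Tanimoto similarity between two fingerprints
#'
#' `TC = N_AC / (N_A + N_C - N_AC)` where `N_A` and `N_C` are the numbers of
#' substructure bits set in each fingerprint and `N_AC` the number set in
#' both. Ranges over \[0, 1\]; symmetric; 1 for identical non-empty
#' fingerprints. When both fingerprints are empty the ratio is 0/0 and the
#' similarity is defined as 0, so structureless records never rank as
#' perfect matches.
#'
#' @param fp_a,fp_c fingerprints from [ecfp4_fingerprint()].
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(fp_a, fp_c) {
  stopifnot(inherits(fp_a, "ecfp"), inherits(fp_c, "ecfp"))
  if (fp_a$nbits != fp_c$nbits) {
    stop("fingerprint length mismatch: ", fp_a$nbits, " vs ", fp_c$nbits,
         call. = FALSE)
  }
  n_ac <- length(intersect(fp_a$on, fp_c$on))
  denom <- fp_a$n_on + fp_c$n_on - n_ac
  if (denom == 0) return(0)
  n_ac / denom
}

# Construct an ecfp object from explicit bit positions (used by tests and
# the fingerprint cache reader).
ecfp_from_bits <- function(on, nbits) {
  on <- sort(unique(as.integer(on)))
  stopifnot(all(on >= 1), all(on <= nbits))
  structure(list(on = on, nbits = as.integer(nbits), n_on = length(on)),
            class = "ecfp")
}
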