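# Independent oracles and in-code fixtures shared across test files.

# Shape-valid synthetic InChIKeys for hand-built tables.
ik <- function(i) {
  stopifnot(i >= 1, i <= 26)
  paste0(paste(rep(LETTERS[i], 14), collapse = ""), "-",
         paste(rep(LETTERS[i], 10), collapse = ""), "-", LETTERS[i])
}

write_tsv_text <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Fingerprint built from explicit bit positions (no chemistry involved).
fp_bits <- function(on, nbits = 64) drugrepo:::ecfp_from_bits(on, nbits)

# Positionwise-loop Tanimoto oracle on dense 0/1 vectors.
tanimoto_loop <- function(a, b) {
  stopifnot(length(a) == length(b))
  n_ab <- 0L; n_a <- 0L; n_b <- 0L
  for (i in seq_along(a)) {
    if (a[i] == 1) n_a <- n_a + 1L
    if (b[i] == 1) n_b <- n_b + 1L
    if (a[i] == 1 && b[i] == 1) n_ab <- n_ab + 1L
  }
  if (n_a + n_b - n_ab == 0) return(0)
  n_ab / (n_a + n_b - n_ab)
}

# Brute-force BFS over an edge list (matrix of character endpoint pairs);
# returns the full distance matrix over `nodes`, Inf where unreachable.
bfs_all_pairs <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  d <- matrix(Inf, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (s in nodes) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[!is.finite(d[s, nxt])]
      if (length(nxt) == 0) break
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# Oracle for the bidirectional closest-average proximity, from the
# brute-force distance matrix.
proximity_oracle <- function(cg, dg, nodes, edges) {
  d <- bfs_all_pairs(nodes, edges)
  cg <- intersect(unique(cg), nodes)
  dg <- intersect(unique(dg), nodes)
  if (length(cg) == 0 || length(dg) == 0) return(NA_real_)
  mins <- c(vapply(cg, function(g) min(d[g, dg]), numeric(1)),
            vapply(dg, function(g) min(d[g, cg]), numeric(1)))
  mins <- mins[is.finite(mins)]
  if (length(mins) == 0) return(NA_real_)
  mean(mins)
}

# Random Erdos-Renyi style graph for property tests; returns the node set,
# the edge list and the corresponding igraph.
random_test_graph <- function(n_nodes, p_edge) {
  nodes <- sprintf("g%02d", seq_len(n_nodes))
  all_pairs <- t(combn(nodes, 2))
  sel <- stats::runif(nrow(all_pairs)) < p_edge
  edges <- all_pairs[sel, , drop = FALSE]
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(nodes, igraph::V(g)$name)),
                            name = setdiff(nodes, igraph::V(g)$name))
  list(nodes = nodes, edges = edges, graph = g)
}

# In-memory scoring scenario built from constructed fingerprints; no
# chemistry engine involved. One approved drug A; candidate X is a
# structure+target twin, Y is structurally unrelated, Z is intermediate.
scoring_scenario <- function() {
  d <- "C0000001"
  A <- ik(1)
  X <- ik(2); Y <- ik(3); Z <- ik(4)
  fps <- list(fp_bits(1:20), fp_bits(1:20), fp_bits(c(1:2, 21:38)),
              fp_bits(c(1:10, 21:30)))
  names(fps) <- c(A, X, Y, Z)
  profiles <- list(c("P1", "P2", "P3", "P4"),
                   c("P1", "P2", "P3", "P4"),
                   c("P1", "P2"),
                   c("P3", "P4", "P5"))
  names(profiles) <- c(A, X, Y, Z)
  ind <- data.frame(drug_id = A, disease_id = d, stringsAsFactors = FALSE)
  cds <- data.frame(compound_id = c(X, Y, Z), disease_id = d,
                    cds = c(1, 0.8, 0.5), stringsAsFactors = FALSE)
  list(d = d, A = A, X = X, Y = Y, Z = Z, fps = fps,
       profiles = profiles, ind = ind, cds = cds)
}

# A tiny five-file dataset written through the package's own writers is
# overkill for reader unit tests; these hand-written literal files pin the
# exact on-disk format instead.
compound_file_3rows <- function() write_tsv_text(c(
  "compound_id\tsmiles",
  paste0(ik(1), "\tCCO"),
  paste0(ik(2), "\tc1ccccc1"),
  paste0(ik(3), "\tCC(=O)O")))
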