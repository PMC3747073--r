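# Protein structure networks: residues are nodes; two residues are joined
# when their normalized side-chain atom-contact density (interaction
# strength, in %) exceeds a cutoff. Hubs, k-cliques and clique-percolation
# communities mark structurally stable residue blocks; over conformational
# ensembles only cliques intact in more than a persistence fraction of the
# frames are retained.

#' Default per-residue-type interaction normalization values
#'
#' Residue-type normalization constants from the classical protein
#' structure network lineage: the expected maximum number of side-chain
#' contact pairs a residue type makes, used to put interaction strengths of
#' large and small side chains on a common percentage scale.
#'
#' @return Named numeric vector over the 20 amino-acid 3-letter codes.
#' @export
psn_normalization <- function() {
  c(ALA = 55.7551, ARG = 93.7891, ASN = 73.4097, ASP = 75.1507,
    CYS = 54.9528, GLN = 78.1301, GLU = 78.8288, GLY = 47.3129,
    HIS = 83.7357, ILE = 67.9452, LEU = 72.2517, LYS = 69.6096,
    MET = 69.2569, PHE = 93.3082, PRO = 51.3310, SER = 61.3946,
    THR = 63.7075, TRP = 106.7030, TYR = 100.7190, VAL = 62.3673)
}

# Side-chain atom coordinates of residue i; glycine (or any residue without
# side-chain atoms) falls back to its CA so it stays visible to the network.
sidechain_coords <- function(structure, i) {
  sc <- structure$sidechain[[i]]
  if (is.null(sc) || nrow(sc) == 0L) {
    m <- structure$xyz[i, , drop = FALSE]
    rownames(m) <- "CA"
    return(m)
  }
  sc
}

# Normalization value for residue serial index i (1-based row index).
norm_value <- function(structure, i, normalization, fallback) {
  if (identical(normalization, "raw")) return(100)
  type <- structure$residues$resid[i]
  v <- normalization[type]
  if (is.na(v)) {
    if (is.null(fallback)) {
      stop(sprintf("no normalization value for residue type %s (serial %d)", type, i - 1L))
    }
    v <- fallback
  }
  unname(v)
}

#' Interaction strength between two residues
#'
#' `I_ij = 100 * n_ij / sqrt(N_i * N_j)` where `n_ij` counts side-chain atom
#' pairs within `contact_distance_A` and `N_i` is the normalization value of
#' residue type i. Glycine contributes its CA as the side-chain fallback.
#'
#' @param structure A `coarse_structure`.
#' @param i,j 1-based residue row indices (serial index + 1).
#' @param contact_distance_A Atom-pair contact distance in Angstrom (default 4.5).
#' @param normalization Named per-type vector (default [psn_normalization()]),
#'   or `"raw"` for `N = 100` so that `I_ij = n_ij`.
#' @param fallback Normalization value for unknown residue types (default
#'   `NULL`: unknown types are an error).
#' @return Interaction strength in percent.
#' @export
interaction_strength <- function(structure, i, j, contact_distance_A = 4.5,
                                 normalization = psn_normalization(),
                                 fallback = NULL) {
  a <- sidechain_coords(structure, i)
  b <- sidechain_coords(structure, j)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  nij <- sum(d2 <= contact_distance_A^2 + 1e-9)
  100 * nij / sqrt(norm_value(structure, i, normalization, fallback) *
                   norm_value(structure, j, normalization, fallback))
}

#' Build a protein structure network
#'
#' Edges join residue pairs with interaction strength strictly greater than
#' `i_min` (percent). Sequence neighbours (`|i - j| < 2` within a chain) are
#' excluded so trivially covalent contacts do not dominate the network.
#'
#' @param structure A `coarse_structure` with side-chain atoms (glycine falls
#'   back to CA).
#' @param i_min Interaction-strength cutoff in percent (default 3.0, strict
#'   inequality; the empirically useful range is 2-4%).
#' @inheritParams interaction_strength
#' @return A `contact_network` with `edges` (data frame `i`, `j` 0-based
#'   serials, `strength`), `n`, `i_min`, `contact_distance_A`.
#' @export
build_psn <- function(structure, i_min = 3.0, contact_distance_A = 4.5,
                      normalization = psn_normalization(), fallback = NULL) {
  stopifnot(inherits(structure, "coarse_structure"))
  n <- n_residues(structure)
  res <- structure$residues
  # prescreen by CA distance: side chains cannot touch across a wide gap
  reach <- vapply(seq_len(n), function(i) {
    sc <- sidechain_coords(structure, i)
    sqrt(max(rowSums((sc - matrix(structure$xyz[i, ], nrow(sc), 3, byrow = TRUE))^2)))
  }, 0)
  d <- ca_dist(structure)
  lim <- outer(reach, reach, "+") + contact_distance_A
  cand <- which(upper.tri(d) & d <= lim, arr.ind = TRUE)
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    same_chain <- res$chain[i] == res$chain[j]
    if (same_chain && abs(res$resno[j] - res$resno[i]) < 2L) next
    s <- interaction_strength(structure, i, j, contact_distance_A,
                              normalization, fallback)
    if (s > i_min) {
      rows[[length(rows) + 1L]] <- c(i - 1L, j - 1L, s)
    }
  }
  edges <- if (length(rows) > 0L) {
    m <- do.call(rbind, rows)
    data.frame(i = as.integer(m[, 1L]), j = as.integer(m[, 2L]), strength = m[, 3L])
  } else {
    data.frame(i = integer(0), j = integer(0), strength = numeric(0))
  }
  structure(list(edges = edges, n = n, i_min = i_min,
                 contact_distance_A = contact_distance_A,
                 structure = structure),
            class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf("Protein structure network: %d residues, %d edge(s) (I > %.1f%%)\n",
              x$n, nrow(x$edges), x$i_min))
  invisible(x)
}

psn_igraph <- function(network) {
  g <- igraph::make_empty_graph(n = network$n, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(network$n) - 1L)
  if (nrow(network$edges) > 0L) {
    g <- igraph::add_edges(g, rbind(network$edges$i + 1L, network$edges$j + 1L))
  }
  g
}

#' Hub residues of a protein structure network
#'
#' Hubs are highly connected residues with more than three connections
#' (degree >= 4).
#'
#' @param network A `contact_network`.
#' @return A `hub_set` with `hubs` (0-based serials) and the full `degrees`
#'   table.
#' @export
find_hubs <- function(network) {
  g <- psn_igraph(network)
  deg <- igraph::degree(g)
  degrees <- data.frame(serial = seq_len(network$n) - 1L, degree = as.integer(deg))
  structure(list(hubs = degrees$serial[degrees$degree > 3L], degrees = degrees),
            class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("Hub set: %d hub(s) (degree > 3) of %d residues\n",
              length(x$hubs), nrow(x$degrees)))
  invisible(x)
}

# All k-cliques of a contact network as a list of sorted 0-based serial vectors.
k_cliques <- function(network, k) {
  g <- psn_igraph(network)
  cl <- igraph::cliques(g, min = k, max = k)
  lapply(cl, function(x) sort(as.integer(names(x))))
}

# Percolate cliques: communities are connected components of the clique
# adjacency graph where two cliques are adjacent when sharing >= min_shared
# nodes. Returns list(communities = list of node sets, membership = clique ->
# community id).
percolate <- function(cliques, min_shared) {
  m <- length(cliques)
  if (m == 0L) return(list(communities = list(), membership = integer(0)))
  adj <- matrix(FALSE, m, m)
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (b <= a) next
      if (length(intersect(cliques[[a]], cliques[[b]])) >= min_shared) {
        adj[a, b] <- adj[b, a] <- TRUE
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  communities <- lapply(seq_len(comp$no), function(cid) {
    sort(unique(unlist(cliques[comp$membership == cid])))
  })
  ord <- order(-vapply(communities, length, 0L))
  remap <- match(comp$membership, ord)
  list(communities = communities[ord], membership = remap)
}

overlap_shared <- function(k, overlap_rule = c("k-2", "k-1")) {
  overlap_rule <- match.arg(overlap_rule)
  if (overlap_rule == "k-1") k - 1L else k - 2L
}

#' k-clique percolation communities
#'
#' Enumerates all complete k-node subgraphs and merges cliques into
#' communities by percolation: two k-cliques belong to one community when they
#' are linked by a chain of cliques in which each adjacent pair shares at
#' least `k-1` or `k-2` nodes (the `overlap_rule`).
#'
#' @param network A `contact_network`.
#' @param k Clique size (default 3).
#' @param overlap_rule `"k-2"` (default: for k = 3, cliques sharing one node
#'   percolate) or `"k-1"`.
#' @param persistence Optional per-clique persistence fractions (used by
#'   [persistence_filter()]).
#' @return A `community_set` with `cliques` (list of 0-based serial vectors),
#'   `communities` (list of node sets), `membership`, `k`, `overlap_rule`,
#'   `persistence`.
#' @export
clique_communities <- function(network, k = 3, overlap_rule = c("k-2", "k-1"),
                               persistence = NULL) {
  stopifnot(k >= 3)
  overlap_rule <- match.arg(overlap_rule)
  cliques <- k_cliques(network, k)
  new_community_set(cliques, k, overlap_rule, persistence)
}

new_community_set <- function(cliques, k, overlap_rule, persistence = NULL,
                              community_persistence = NULL) {
  per <- percolate(cliques, overlap_shared(k, overlap_rule))
  structure(list(cliques = cliques, communities = per$communities,
                 membership = per$membership, k = k,
                 overlap_rule = overlap_rule, persistence = persistence,
                 community_persistence = community_persistence),
            class = "community_set")
}

#' @export
print.community_set <- function(x, ...) {
  cat(sprintf("Community set: %d %d-clique(s) in %d community(ies) [overlap %s]\n",
              length(x$cliques), x$k, length(x$communities), x$overlap_rule))
  invisible(x)
}

#' Persistence-filtered cliques and communities over an ensemble
#'
#' A clique is intact in a frame when all its edges exist in that frame's
#' protein structure network. Candidate k-cliques are enumerated from the
#' union network over frames; only cliques intact in strictly more than
#' `min_fraction` of the frames are retained, and communities are the
#' percolation unions of the retained cliques.
#'
#' @param ensemble A `structure_ensemble` with at least 2 frames.
#' @param i_min,contact_distance_A,normalization,fallback Passed to
#'   [build_psn()] per frame.
#' @param k,overlap_rule Passed to [clique_communities()].
#' @param min_fraction Persistence threshold (default 0.75, strict `>`).
#' @return A `community_set` whose `persistence` element holds the per-clique
#'   intact fractions of the retained cliques.
#' @export
persistence_filter <- function(ensemble, i_min = 3.0, k = 3,
                               overlap_rule = c("k-2", "k-1"),
                               min_fraction = 0.75,
                               contact_distance_A = 4.5,
                               normalization = psn_normalization(),
                               fallback = NULL) {
  stopifnot(inherits(ensemble, "structure_ensemble"), length(ensemble$frames) >= 2L)
  overlap_rule <- match.arg(overlap_rule)
  nets <- lapply(ensemble$frames, build_psn, i_min = i_min,
                 contact_distance_A = contact_distance_A,
                 normalization = normalization, fallback = fallback)
  edge_keys <- lapply(nets, function(nw) paste(nw$edges$i, nw$edges$j))
  union_edges <- unique(do.call(rbind, lapply(nets, function(nw) nw$edges[, c("i", "j")])))
  union_net <- structure(list(edges = union_edges, n = n_residues(ensemble),
                              i_min = i_min,
                              contact_distance_A = contact_distance_A,
                              structure = ensemble$frames[[1L]]),
                         class = "contact_network")
  cand <- k_cliques(union_net, k)
  frac <- vapply(cand, function(cl) {
    need <- combn(cl, 2L)
    keys <- paste(need[1L, ], need[2L, ])
    mean(vapply(edge_keys, function(ek) all(keys %in% ek), TRUE))
  }, 0)
  keep <- frac > min_fraction
  new_community_set(cand[keep], k, overlap_rule, persistence = frac[keep])
}

#' Clique and community count summary
#'
#' One row per input: number of k-cliques, number of percolation communities
#' and mean community size. `structure_ensemble` inputs are persistence
#' filtered; single structures are analysed as-is.
#'
#' @param structures List of `coarse_structure` / `structure_ensemble`
#'   objects (optionally named).
#' @param ... Passed to [clique_communities()] / [persistence_filter()]
#'   (e.g. `i_min`, `k`, `overlap_rule`, `min_fraction`).
#' @return Data frame with columns `label`, `n_cliques`, `n_communities`,
#'   `mean_community_size`.
#' @export
count_summary <- function(structures, ...) {
  if (inherits(structures, c("coarse_structure", "structure_ensemble"))) {
    structures <- list(structures)
  }
  stopifnot(length(structures) >= 1L)
  args <- list(...)
  rows <- lapply(seq_along(structures), function(idx) {
    x <- structures[[idx]]
    lbl <- names(structures)[idx]
    if (is.null(lbl) || lbl == "") lbl <- x$label
    cs <- if (inherits(x, "structure_ensemble")) {
      do.call(persistence_filter, c(list(x), args))
    } else {
      psn_args <- args[names(args) %in% c("i_min", "contact_distance_A", "normalization", "fallback")]
      cc_args <- args[names(args) %in% c("k", "overlap_rule")]
      do.call(clique_communities, c(list(do.call(build_psn, c(list(x), psn_args))), cc_args))
    }
    sizes <- vapply(cs$communities, length, 0L)
    data.frame(label = lbl, n_cliques = length(cs$cliques),
               n_communities = length(cs$communities),
               mean_community_size = if (length(sizes) > 0L) mean(sizes) else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
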