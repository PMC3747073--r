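# Independent oracles and fixture builders shared across the suite.

# --- PDB text fixtures -------------------------------------------------------

pdb_line <- function(eleno, elety, resid, chain, resno, xyz, b = 0, alt = " ") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          eleno, paste0(" ", elety), alt, resid, chain, resno,
          xyz[1], xyz[2], xyz[3], 1, b)
}

# Minimal single-chain CA-only PDB text (no END record, so blocks can be
# concatenated into multi-chain fixtures).
ca_pdb_text <- function(resno, xyz, resid = "ALA", chain = "A", eleno_start = 1L) {
  lines <- vapply(seq_along(resno), function(i) {
    pdb_line(eleno_start + i - 1L, "CA", resid, chain, resno[i], xyz[i, ])
  }, "")
  paste(lines, collapse = "\n")
}

# --- graph fixtures and brute-force community oracle -------------------------

# Random simple graph as a 0-based edge data frame.
random_edges <- function(n, p) {
  pairs <- t(combn(n, 2L))
  keep <- runif(nrow(pairs)) < p
  data.frame(i = pairs[keep, 1L] - 1L, j = pairs[keep, 2L] - 1L)
}

# Wrap an arbitrary edge list as a contact_network (strengths are nominal).
edges_as_psn <- function(n, edges) {
  structure(list(edges = cbind(edges, strength = rep(100, nrow(edges))),
                 n = n, i_min = 0, contact_distance_A = 4.5, structure = NULL),
            class = "contact_network")
}

# Exhaustive clique-percolation oracle: test every k-subset for completeness,
# then merge by transitive closure of the shared-node relation.
brute_communities <- function(n, edges, k, min_shared) {
  amat <- matrix(FALSE, n, n)
  if (nrow(edges) > 0L) {
    amat[cbind(edges$i + 1L, edges$j + 1L)] <- TRUE
    amat[cbind(edges$j + 1L, edges$i + 1L)] <- TRUE
  }
  subsets <- if (n >= k) combn(n, k) else matrix(integer(0), nrow = k)
  cliques <- list()
  for (c_ in seq_len(ncol(subsets))) {
    s <- subsets[, c_]
    pp <- combn(s, 2L)
    if (all(amat[cbind(pp[1L, ], pp[2L, ])])) {
      cliques[[length(cliques) + 1L]] <- s - 1L
    }
  }
  m <- length(cliques)
  if (m == 0L) return(list(cliques = list(), communities = list()))
  parent <- seq_len(m)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (b > a && length(intersect(cliques[[a]], cliques[[b]])) >= min_shared) {
      parent[find(a)] <- find(b)
    }
  }
  roots <- vapply(seq_len(m), find, 0L)
  communities <- lapply(unique(roots), function(r) {
    sort(unique(unlist(cliques[roots == r])))
  })
  list(cliques = cliques, communities = communities)
}

# Canonical string form of a community list for set comparison.
canon_communities <- function(comms) {
  sort(vapply(comms, function(x) paste(sort(x), collapse = ","), ""))
}

# --- Monte-Carlo random-walk commute oracle ----------------------------------

# Expected i -> j -> i round-trip step count on an undirected graph, estimated
# by simulation. Returns mean and standard error.
mc_commute <- function(edges, n, from, to, n_walks = 20000) {
  nbr <- lapply(seq_len(n), function(v) integer(0))
  for (r in seq_len(nrow(edges))) {
    a <- edges$i[r] + 1L; b <- edges$j[r] + 1L
    nbr[[a]] <- c(nbr[[a]], b); nbr[[b]] <- c(nbr[[b]], a)
  }
  steps <- numeric(n_walks)
  for (w in seq_len(n_walks)) {
    pos <- from; target <- to; k <- 0L
    repeat {
      ns <- nbr[[pos]]
      pos <- ns[sample.int(length(ns), 1L)]
      k <- k + 1L
      if (pos == target) {
        if (target == from) break
        target <- from
      }
    }
    steps[w] <- k
  }
  list(mean = mean(steps), se = sd(steps) / sqrt(n_walks))
}

# --- exhaustive decoy oracle -------------------------------------------------

# Population mean and sd of the decoy energy distribution by full enumeration
# over ordered type pairs and distance bins.
exhaustive_decoy_stats <- function(types, potential, distances, n_bins = 20) {
  comp <- table(types) / length(types)
  bins <- allosteer:::distance_bins(distances, n_bins)
  ta <- rep(names(comp), each = length(comp) * length(bins$mids))
  tb <- rep(rep(names(comp), each = length(bins$mids)), times = length(comp))
  d <- rep(bins$mids, times = length(comp)^2)
  w <- rep(as.numeric(comp), each = length(comp) * length(bins$mids)) *
    rep(rep(as.numeric(comp), each = length(bins$mids)), times = length(comp)) *
    rep(bins$prob, times = length(comp)^2)
  e <- pair_energy(potential, ta, tb, d)
  mu <- sum(w * e)
  list(mean = mu, sd = sqrt(sum(w * (e - mu)^2)))
}

# --- geometric fixtures ------------------------------------------------------

# Triangle of contact-capable residues at serials 0, 2, 4 (side length 7 A,
# wide angles: no cross-talk between realized contacts), with spacer residues
# 1, 3, 5 parked far away. Candidate contact edges are exactly
# (0,2), (0,4), (2,4).
triangle_base <- function(side = 7) {
  h <- side * sqrt(3) / 2
  xyz <- rbind(c(0, 0, 0),        # 0: triangle vertex
               c(50, 0, 0),       # 1: spacer
               c(side, 0, 0),     # 2: triangle vertex
               c(60, 0, 0),       # 3: spacer
               c(side / 2, h, 0), # 4: triangle vertex
               c(70, 0, 0))       # 5: spacer
  coarse_structure(xyz, label = "triangle")
}

# Tetrahedral K4 block at serials 0, 2, 4, 6 (edge 6.5 A) plus far spacers:
# candidate edges are exactly the six block pairs.
k4_base <- function(edge = 6.5) {
  a <- edge
  xyz <- rbind(c(0, 0, 0),
               c(100, 0, 0),
               c(a, 0, 0),
               c(110, 0, 0),
               c(a / 2, a * sqrt(3) / 2, 0),
               c(120, 0, 0),
               c(a / 2, a * sqrt(3) / 6, a * sqrt(6) / 3),
               c(130, 0, 0))
  coarse_structure(xyz, label = "k4-block")
}

k4_members <- c(0L, 2L, 4L, 6L)
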