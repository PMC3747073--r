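make_sc <- function(...) {
  m <- rbind(...)
  rownames(m) <- paste0("SG", seq_len(nrow(m)))
  m
}

test_that("interaction strength follows the normalized atom-pair count", {
  # residues 1 and 2: 2 side-chain atoms each, all 4 cross pairs within 4.5 A
  sc <- list(make_sc(c(0, 0, 0), c(0, 0, 1)),
             make_sc(c(3, 0, 0), c(3, 0, 1)),
             NULL)
  s <- coarse_structure(rbind(c(0, 0, 0), c(3, 0, 0), c(40, 0, 0)),
                        resid = c("ALA", "SER", "GLY"), sidechain = sc)
  expect_equal(interaction_strength(s, 1, 2, normalization = "raw"), 4)
  # custom normalization: n = 4, N_i = 64, N_j = 100 -> 100*4/80 = 5
  expect_equal(interaction_strength(s, 1, 2, normalization = c(ALA = 64, SER = 100)), 5)
  # n = 2 at N = 100: keep only one atom within range on one side
  sc2 <- sc; sc2[[2]] <- make_sc(c(3, 0, 0))
  s2 <- coarse_structure(s$xyz, resid = s$residues$resid, sidechain = sc2)
  expect_equal(interaction_strength(s2, 1, 2, normalization = c(ALA = 100, SER = 100)), 2)
  # distant residues: zero
  expect_equal(interaction_strength(s, 1, 3, normalization = "raw"), 0)
  # unknown type errors without a fallback, works with one
  expect_error(interaction_strength(s, 1, 2, normalization = c(ALA = 64)), "SER")
  expect_equal(interaction_strength(s, 1, 2, normalization = c(ALA = 64), fallback = 100), 5)
})

test_that("glycine falls back to its CA atom", {
  s <- coarse_structure(rbind(c(0, 0, 0), c(20, 0, 0), c(3, 0, 0)),
                        resid = "GLY")
  expect_equal(interaction_strength(s, 1, 3, normalization = "raw"), 1)
})

test_that("PSN edges require strictly I > i_min and ignore sequence neighbours", {
  base <- triangle_base()
  edges <- allosteer:::candidate_contact_edges(base)
  s <- make_contact_ensemble(base, edges, matrix(TRUE, 1, nrow(edges)))$frames[[1]]
  net <- build_psn(s, i_min = 3, normalization = "raw")
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$strength > 3))
  # boundary: i_min exactly at the realized strength drops the edge
  smax <- max(net$edges$strength)
  net_eq <- build_psn(s, i_min = smax, normalization = "raw")
  expect_lt(nrow(net_eq$edges), 3L)
  # i_min = 100: edgeless
  expect_equal(nrow(build_psn(s, i_min = 100, normalization = "raw")$edges), 0L)
  # sweep: edge count is monotone non-increasing in i_min
  counts <- vapply(c(2, 3, 4), function(im)
    nrow(build_psn(s, i_min = im, normalization = "raw")$edges), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("PSN edge set is invariant under residue reordering", {
  base <- k4_base()
  edges <- allosteer:::candidate_contact_edges(base)
  s <- make_contact_ensemble(base, edges, matrix(TRUE, 1, nrow(edges)))$frames[[1]]
  net <- build_psn(s, i_min = 3, normalization = "raw")
  # reverse residue order (author numbering travels with the residues)
  n <- n_residues(s)
  perm <- rev(seq_len(n))
  s2 <- s
  s2$residues <- s$residues[perm, ]
  s2$xyz <- s$xyz[perm, ]
  s2$sidechain <- s$sidechain[perm]
  s2$residues$serial <- seq_len(n) - 1L
  net2 <- build_psn(s2, i_min = 3, normalization = "raw")
  canon <- function(net, map) {
    a <- map[net$edges$i + 1L]; b <- map[net$edges$j + 1L]
    sort(paste(pmin(a, b), pmax(a, b)))
  }
  expect_equal(canon(net2, perm - 1L), canon(net, seq_len(n) - 1L))
})

test_that("hub calls sit exactly at the degree > 3 boundary", {
  star4 <- edges_as_psn(5, data.frame(i = rep(0L, 4), j = 1:4))
  hs <- find_hubs(star4)
  expect_equal(hs$hubs, 0L)
  k4e <- data.frame(t(combn(0:3, 2)))
  names(k4e) <- c("i", "j")
  expect_length(find_hubs(edges_as_psn(4, k4e))$hubs, 0L)   # degree 3: not hubs
  k5e <- data.frame(t(combn(0:4, 2)))
  names(k5e) <- c("i", "j")
  expect_length(find_hubs(edges_as_psn(5, k5e))$hubs, 5L)
})

test_that("clique communities match hand counts on canonical graphs", {
  k4e <- data.frame(t(combn(0:3, 2)))
  names(k4e) <- c("i", "j")
  cs <- clique_communities(edges_as_psn(4, k4e), k = 3, overlap_rule = "k-1")
  expect_length(cs$cliques, 4L)
  expect_length(cs$communities, 1L)
  expect_equal(cs$communities[[1]], 0:3)

  # two triangles sharing one node
  bow <- data.frame(i = c(0, 0, 1, 2, 2, 3), j = c(1, 2, 2, 3, 4, 4))
  cs1 <- clique_communities(edges_as_psn(5, bow), k = 3, overlap_rule = "k-2")
  expect_length(cs1$communities, 1L)
  cs2 <- clique_communities(edges_as_psn(5, bow), k = 3, overlap_rule = "k-1")
  expect_length(cs2$communities, 2L)

  # triangle-free graph
  c4 <- data.frame(i = c(0, 1, 2, 3), j = c(1, 2, 3, 0))
  cs0 <- clique_communities(edges_as_psn(4, c4), k = 3)
  expect_length(cs0$cliques, 0L)
  expect_length(cs0$communities, 0L)
})

test_that("clique percolation agrees with brute-force enumeration on random graphs", {
  set.seed(11)
  for (trial in 1:60) {
    n <- sample(4:12, 1)
    edges <- random_edges(n, runif(1, 0.2, 0.7))
    net <- edges_as_psn(n, edges)
    for (rule in c("k-2", "k-1")) {
      for (k in c(3L, 4L)) {
        got <- clique_communities(net, k = k, overlap_rule = rule)
        want <- brute_communities(n, edges, k, if (rule == "k-1") k - 1L else k - 2L)
        expect_equal(canon_communities(got$communities),
                     canon_communities(want$communities),
                     info = sprintf("trial %d n %d k %d rule %s", trial, n, k, rule))
      }
    }
  }
})

test_that("persistence threshold is strict at 0.75: 8/10 kept, 7/10 dropped", {
  base <- triangle_base()
  edges <- allosteer:::candidate_contact_edges(base)
  stopifnot(nrow(edges) == 3L)
  # all three edges on in 8 frames; edge 1 missing in the last two
  sched8 <- matrix(TRUE, 10, 3)
  sched8[9:10, 1] <- FALSE
  ens8 <- make_contact_ensemble(base, edges, sched8)
  cs8 <- persistence_filter(ens8, i_min = 3, normalization = "raw", min_fraction = 0.75)
  expect_length(cs8$cliques, 1L)
  expect_equal(cs8$persistence, 0.8)
  expect_equal(cs8$communities[[1]], c(0L, 2L, 4L))

  sched7 <- matrix(TRUE, 10, 3)
  sched7[8:10, 1] <- FALSE
  cs7 <- persistence_filter(make_contact_ensemble(base, edges, sched7),
                            i_min = 3, normalization = "raw", min_fraction = 0.75)
  expect_length(cs7$cliques, 0L)
})

test_that("persistence_filter limits match per-frame unions and intersections", {
  base <- k4_base()
  edges <- allosteer:::candidate_contact_edges(base)
  set.seed(3)
  sched <- matrix(runif(10 * nrow(edges)) < 0.6, 10)
  ens <- make_contact_ensemble(base, edges, sched)
  nets <- lapply(ens$frames, build_psn, i_min = 3, normalization = "raw")
  # min_fraction = 0: union of per-frame clique sets
  cs0 <- persistence_filter(ens, i_min = 3, normalization = "raw", min_fraction = 0)
  per_frame <- unique(unlist(lapply(nets, function(nw) {
    vapply(allosteer:::k_cliques(nw, 3L), paste, "", collapse = ",")
  })))
  expect_setequal(vapply(cs0$cliques, paste, "", collapse = ","), per_frame)
  # min_fraction -> 1: subset of the edge-intersection graph's cliques
  cs1 <- persistence_filter(ens, i_min = 3, normalization = "raw", min_fraction = 0.999)
  common <- Reduce(intersect, lapply(nets, function(nw) paste(nw$edges$i, nw$edges$j)))
  for (cl in cs1$cliques) {
    pp <- combn(cl, 2L)
    expect_true(all(paste(pp[1, ], pp[2, ]) %in% common))
  }
})

test_that("a seeded high-persistence block is recovered and nothing else", {
  base <- k4_base()
  ens <- make_persistence_ensemble(base, stable_region = k4_members,
                                   p_stable = 0.95, p_background = 0.3,
                                   n_frames = 100, rng_seed = 71)
  cs <- persistence_filter(ens, i_min = 3, normalization = "raw",
                           min_fraction = 0.75)
  expect_gt(length(cs$communities), 0L)
  for (comm in cs$communities) {
    expect_true(all(comm %in% k4_members))
  }
  expect_true(all(cs$persistence > 0.75))
})

test_that("count summaries track designed contact enrichment", {
  base <- k4_base()
  edges <- allosteer:::candidate_contact_edges(base)
  full <- make_contact_ensemble(base, edges, matrix(TRUE, 1, nrow(edges)))$frames[[1]]
  # unbound variant: drop half the contacts
  sparse_sched <- matrix(c(TRUE, TRUE, TRUE, rep(FALSE, nrow(edges) - 3L)), 1)
  sparse <- make_contact_ensemble(base, edges, sparse_sched)$frames[[1]]
  tab <- count_summary(list(unbound = sparse, complex = full),
                       i_min = 3, normalization = "raw", k = 3)
  expect_equal(tab$label, c("unbound", "complex"))
  expect_gte(tab$n_cliques[2], tab$n_cliques[1])
  expect_gte(tab$n_communities[2], tab$n_communities[1])
  expect_equal(tab$n_cliques[2], 4L)      # K4 holds four 3-cliques
  expect_equal(tab$n_communities[2], 1L)
  expect_equal(tab$mean_community_size[2], 4)
  # edgeless input
  bare <- coarse_structure(rbind(c(0, 0, 0), c(40, 0, 0), c(80, 0, 0)))
  tab0 <- count_summary(list(bare), i_min = 3, normalization = "raw")
  expect_equal(tab0$n_cliques, 0L)
  expect_equal(tab0$n_communities, 0L)
})
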