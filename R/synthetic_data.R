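# Synthetic structures and ensembles with known ground truth. These are the
# package's testbed: bead chains and rings with closed-form elastic spectra,
# two-domain dumbbells with a hinge linker, ensembles with designed per-edge
# contact persistence, and helical folds with planted frustration. Every
# generator is deterministic given its arguments (and seed, where one is
# taken); ground truth travels on the returned object as the
# `"ground_truth"` attribute.

#' Construct a coarse structure from bead coordinates
#'
#' Low-level constructor for synthetic structures: one residue per bead,
#' optional side-chain pseudo-atoms.
#'
#' @param xyz N x 3 matrix of CA coordinates in Angstrom.
#' @param resid Residue types (3-letter codes, recycled).
#' @param chain Chain identifiers (recycled).
#' @param resno Author residue numbers (default 1..N within input order).
#' @param sidechain Optional list (length N) of m x 3 coordinate matrices
#'   with atom-name rownames.
#' @param label Structure label.
#' @return A `coarse_structure`.
#' @export
coarse_structure <- function(xyz, resid = "ALA", chain = "A", resno = NULL,
                             sidechain = NULL, label = "synthetic") {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, all(is.finite(xyz)))
  n <- nrow(xyz)
  if (is.null(resno)) resno <- seq_len(n)
  if (is.null(sidechain)) sidechain <- vector("list", n)
  residues <- data.frame(chain = rep_len(chain, n), resno = as.integer(resno),
                         insert = "", resid = rep_len(resid, n),
                         stringsAsFactors = FALSE)
  new_coarse_structure(residues, xyz, sidechain, label = label)
}

#' Bead chain with path or ring topology
#'
#' Evenly spaced beads: a straight chain, or a ring whose chord between
#' consecutive beads equals `spacing_A`. With nearest-neighbour-only
#' connectivity a ring of N beads has the closed-form elastic spectrum
#' `4 sin^2(pi k / N)`.
#'
#' @param n Number of beads (>= 3).
#' @param spacing_A Consecutive-bead spacing in Angstrom (default 3.8).
#' @param topology `"path"` or `"ring"`.
#' @return A `coarse_structure`.
#' @export
make_chain <- function(n, spacing_A = 3.8, topology = c("path", "ring")) {
  stopifnot(n >= 3)
  topology <- match.arg(topology)
  xyz <- if (topology == "path") {
    cbind(spacing_A * (seq_len(n) - 1L), 0, 0)
  } else {
    r <- spacing_A / (2 * sin(pi / n))
    th <- 2 * pi * (seq_len(n) - 1L) / n
    cbind(r * cos(th), r * sin(th), 0)
  }
  coarse_structure(xyz, label = paste0(topology, n))
}

#' Two-domain dumbbell with a flexible linker
#'
#' Two mirror-symmetric compact bead clusters joined by an extended linker.
#' The slowest elastic mode separates the domains with opposite signs and the
#' fluctuation minima (hinge candidates) fall inside the linker. Ground
#' truth: `attr(x, "ground_truth")$linker` holds the 0-based linker serials,
#' `$domain1` / `$domain2` the domain serials.
#'
#' @param n_per_domain Beads per domain (>= 8).
#' @param linker_len Linker beads (default 4).
#' @param domain_spacing_A Grid spacing inside each domain, i.e. domain
#'   compactness (default 4.5).
#' @param linker_spacing_A Bead spacing along the linker (default 3.8).
#' @return A `coarse_structure` with ground-truth attribute.
#' @export
make_dumbbell <- function(n_per_domain = 12, linker_len = 4,
                          domain_spacing_A = 4.5, linker_spacing_A = 3.8) {
  stopifnot(n_per_domain >= 8, linker_len >= 1)
  m <- ceiling(n_per_domain^(1 / 3))
  grid <- expand.grid(z = 0:(m - 1L), y = 0:(m - 1L), x = 0:(m - 1L))
  grid <- grid[order(grid$x, grid$y, grid$z), c("x", "y", "z")]
  d1 <- as.matrix(grid[seq_len(n_per_domain), ]) * domain_spacing_A
  anchor <- d1[n_per_domain, ]  # max-x bead joins the linker
  lk <- t(vapply(seq_len(linker_len), function(k) {
    anchor + c(k * linker_spacing_A, 0, 0)
  }, numeric(3)))
  x_mid <- anchor[1L] + (linker_len + 1L) * linker_spacing_A / 2
  d2 <- d1[rev(seq_len(n_per_domain)), , drop = FALSE]
  d2[, 1L] <- 2 * x_mid - d2[, 1L]
  xyz <- rbind(d1, lk, d2)
  out <- coarse_structure(xyz, label = "dumbbell")
  n <- n_per_domain
  attr(out, "ground_truth") <- list(
    domain1 = 0:(n - 1L),
    linker = n:(n + linker_len - 1L),
    domain2 = (n + linker_len):(2L * n + linker_len - 1L)
  )
  out
}

# Candidate side-chain contact edges of a bead structure: same-chain pairs at
# sequence separation >= 2 whose CA distance allows a realized contact.
candidate_contact_edges <- function(base, max_ca_A = 7.5) {
  d <- ca_dist(base)
  res <- base$residues
  idx <- which(upper.tri(d) & d <= max_ca_A, arr.ind = TRUE)
  keep <- abs(res$resno[idx[, 2L]] - res$resno[idx[, 1L]]) >= 2L |
    res$chain[idx[, 1L]] != res$chain[idx[, 2L]]
  idx <- idx[keep, , drop = FALSE]
  data.frame(i = idx[, 1L] - 1L, j = idx[, 2L] - 1L, distance = d[idx])
}

# Realize a frame: for each scheduled-on edge, both residues get a pair of
# side-chain pseudo-atoms pointing at the partner, leaving an atom-atom gap
# of ~3.2 A (< the 4.5 A contact distance, giving 4 contact atom pairs).
realize_frame <- function(base, edges, on) {
  n <- n_residues(base)
  sc <- lapply(seq_len(n), function(i) NULL)
  add_atom <- function(i, xyz) {
    cur <- sc[[i]]
    nm <- paste0("SG", if (is.null(cur)) 1L else nrow(cur) + 1L)
    sc[[i]] <<- rbind(cur, matrix(xyz, 1L, 3L, dimnames = list(nm, NULL)))
  }
  for (e in which(on)) {
    i <- edges$i[e] + 1L; j <- edges$j[e] + 1L
    a <- base$xyz[i, ]; b <- base$xyz[j, ]
    d <- sqrt(sum((b - a)^2))
    u <- (b - a) / d
    perp <- if (abs(u[3L]) < 0.9) c(-u[2L], u[1L], 0) else c(0, -u[3L], u[2L])
    perp <- perp / sqrt(sum(perp^2)) * 0.2
    r <- (d - 3.2) / 2
    add_atom(i, a + u * r + perp); add_atom(i, a + u * r - perp)
    add_atom(j, b - u * r + perp); add_atom(j, b - u * r - perp)
  }
  out <- base
  out$sidechain <- sc
  out
}

#' Deterministic contact ensemble from an edge schedule
#'
#' Realizes each frame of an ensemble by placing side-chain pseudo-atoms so
#' that exactly the scheduled candidate edges form side-chain contacts (at
#' the default 4.5 A atom-contact distance, with raw normalization and
#' `i_min` = 3).
#'
#' @param base A `coarse_structure` of bead positions (no side chains needed).
#' @param edges Candidate edge table (`i`, `j` 0-based serials), e.g. from
#'   the `candidate_edges` attribute of [make_persistence_ensemble()] output.
#' @param schedule Logical matrix, frames x edges: `TRUE` realizes the edge
#'   in that frame.
#' @return A `structure_ensemble`.
#' @export
make_contact_ensemble <- function(base, edges, schedule) {
  schedule <- as.matrix(schedule)
  stopifnot(ncol(schedule) == nrow(edges), nrow(schedule) >= 1L)
  frames <- lapply(seq_len(nrow(schedule)), function(f) {
    realize_frame(base, edges, schedule[f, ])
  })
  as_structure_ensemble(frames, label = paste0(base$label, "-ensemble"))
}

#' Ensemble with designed per-edge contact persistence
#'
#' Emulates a set of simulation snapshots: candidate side-chain contacts
#' inside `stable_region` are realized independently per frame with
#' probability `p_stable`, all other candidate contacts with
#' `p_background`. Ground truth (`attr(x, "ground_truth")`): the stable and
#' background edge tables and the schedule actually drawn.
#'
#' @param base A `coarse_structure` of bead positions.
#' @param stable_region 0-based serial indices of the designed stable block.
#' @param p_stable Per-frame contact probability inside the block (default 0.95).
#' @param p_background Contact probability elsewhere (default 0.3).
#' @param n_frames Number of frames (default 100).
#' @param rng_seed Integer seed (required; output is deterministic given it).
#' @return A `structure_ensemble` with ground-truth attribute.
#' @export
make_persistence_ensemble <- function(base, stable_region, p_stable = 0.95,
                                      p_background = 0.3, n_frames = 100,
                                      rng_seed) {
  stopifnot(0 <= p_background, p_background < p_stable, p_stable <= 1,
            n_frames >= 2)
  if (missing(rng_seed)) stop("ensemble generation requires an explicit rng_seed")
  edges <- candidate_contact_edges(base)
  stable <- edges$i %in% stable_region & edges$j %in% stable_region
  p <- ifelse(stable, p_stable, p_background)
  schedule <- with_seed(rng_seed, function() {
    matrix(runif(n_frames * nrow(edges)) < rep(p, each = n_frames),
           nrow = n_frames)
  })
  out <- make_contact_ensemble(base, edges, schedule)
  attr(out, "ground_truth") <- list(
    stable_edges = edges[stable, , drop = FALSE],
    background_edges = edges[!stable, , drop = FALSE],
    schedule = schedule, candidate_edges = edges
  )
  out
}

#' Helical fold with planted frustration
#'
#' An ideal helix (radius 2.3 A, rise 1.5 A, 100 degrees per residue) whose
#' native contacts are exactly the (i, i+3) and (i, i+4) pairs. Background
#' residues cycle through types of near-identical hydropathy, so random
#' native pairs score as neutral; each planted "optimal" pair is assigned the
#' potential's minimum-energy type pair (ties broken lexicographically) and
#' each planted "frustrated" pair its maximum-energy pair. Ground truth: the
#' planted pair lists and expected categories.
#'
#' @param n Number of residues (default 80, minimum 10).
#' @param optimal_pairs,frustrated_pairs Lists (or 2-column matrices) of
#'   0-based serial pairs; each pair must be a native contact of the helix
#'   and the planted pairs must be disjoint. `NULL` (default) plants one
#'   optimal pair in the first helix quarter and one frustrated pair in the
#'   last.
#' @param potential A `contact_potential` (default [contact_potential()]).
#' @param background Residue types cycled over unplanted positions.
#' @return A `coarse_structure` with ground-truth attribute.
#' @export
make_frustration_design <- function(n = 80,
                                    optimal_pairs = NULL,
                                    frustrated_pairs = NULL,
                                    potential = contact_potential(),
                                    background = c("SER", "THR", "GLY", "TRP")) {
  stopifnot(n >= 10)
  if (is.null(optimal_pairs)) {
    a <- max(1L, n %/% 4L)
    optimal_pairs <- list(c(a, a + 4L))
  }
  if (is.null(frustrated_pairs)) {
    b <- min(n - 6L, 3L * n %/% 4L)
    frustrated_pairs <- list(c(b, b + 4L))
  }
  as_pairs <- function(p) {
    if (is.matrix(p)) p <- lapply(seq_len(nrow(p)), function(r) p[r, ])
    lapply(p, as.integer)
  }
  optimal_pairs <- as_pairs(optimal_pairs)
  frustrated_pairs <- as_pairs(frustrated_pairs)
  planted <- unlist(c(optimal_pairs, frustrated_pairs))
  if (anyDuplicated(planted)) stop("planted pairs must be disjoint")
  th <- (seq_len(n) - 1L) * 100 * pi / 180
  xyz <- cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * (seq_len(n) - 1L))
  resid <- rep_len(background, n)
  ex <- extreme_pairs(potential)
  for (p in optimal_pairs) resid[p + 1L] <- ex$min
  for (p in frustrated_pairs) resid[p + 1L] <- ex$max
  out <- coarse_structure(xyz, resid = resid, label = "frustration-design")
  contacts <- native_contacts(out)
  ckey <- paste(contacts$i, contacts$j)
  for (p in c(optimal_pairs, frustrated_pairs)) {
    if (!(paste(min(p), max(p)) %in% ckey)) {
      stop(sprintf("planted pair (%d, %d) is not a native contact of the helix", p[1L], p[2L]))
    }
  }
  attr(out, "ground_truth") <- list(
    optimal_pairs = optimal_pairs, frustrated_pairs = frustrated_pairs,
    expected = c(optimal = "minimal", frustrated = "high")
  )
  out
}

#' Write generator ground truth to TSV
#'
#' Serializes the `"ground_truth"` attribute of a synthetic object into one
#' or more TSV files next to `stem` (one file per component).
#'
#' @param x Object carrying a `"ground_truth"` attribute.
#' @param stem Output path stem; files are written as `<stem>_<name>.tsv`.
#' @return Character vector of written paths, invisibly.
#' @export
write_ground_truth <- function(x, stem) {
  gt <- attr(x, "ground_truth")
  if (is.null(gt)) stop("object carries no ground-truth attribute")
  paths <- character(0)
  for (nm in names(gt)) {
    v <- gt[[nm]]
    path <- paste0(stem, "_", nm, ".tsv")
    if (is.data.frame(v)) {
      write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (is.matrix(v)) {
      write.table(as.data.frame(v), path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (is.list(v)) {
      lines <- vapply(v, function(e) paste(e, collapse = "\t"), "")
      writeLines(lines, path)
    } else {
      writeLines(paste(v, collapse = "\t"), path)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}
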