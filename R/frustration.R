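# Local frustration profiling. Each native contact is scored as a Z-score of
# its native pair energy against ~1000 structural decoys in which both the
# residue identities and the contact distance are randomized. Contacts with
# Z >= 0.78 are minimally frustrated (the native pair is substantially more
# stabilizing than typical decoys), Z < -1 highly frustrated, in between
# neutral.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

# Kyte-Doolittle hydropathy over the 20 amino acids.
KD_HYDROPATHY <- c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
                   GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
                   LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
                   SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2)

#' Construct a pairwise contact potential
#'
#' A contact potential is a symmetric 20x20 residue-type energy matrix
#' modulated by a distance well: full weight inside `well_A`, tapering
#' linearly to zero at `cutoff_A`. The default energy matrix is
#' hydrophobicity-derived, `e(a,b) = -(h_a + h_b) / 2` on the Kyte-Doolittle
#' scale, so burial of hydrophobic pairs stabilizes (unique minimum Ile-Ile)
#' and pairing the most polar types destabilizes (unique maximum Arg-Arg).
#' Any symmetric finite matrix over the 20 types can be substituted.
#'
#' @param energy Symmetric 20x20 numeric matrix with dimnames over the
#'   3-letter codes; default the hydrophobicity-derived matrix.
#' @param well_A Full-weight well radius in Angstrom (default 6.5).
#' @param cutoff_A Distance at which the potential vanishes (default 8.0).
#' @param name Potential label.
#' @return A `contact_potential`.
#' @export
contact_potential <- function(energy = NULL, well_A = 6.5, cutoff_A = 8.0,
                              name = "hydropathy-well") {
  if (is.null(energy)) {
    h <- KD_HYDROPATHY[AA3]
    energy <- -outer(h, h, "+") / 2
    dimnames(energy) <- list(AA3, AA3)
  }
  stopifnot(is.matrix(energy), nrow(energy) == ncol(energy),
            all(is.finite(energy)), isTRUE(all.equal(energy, t(energy))),
            well_A < cutoff_A)
  structure(list(energy = energy, well_A = well_A, cutoff_A = cutoff_A,
                 name = name),
            class = "contact_potential")
}

#' @export
print.contact_potential <- function(x, ...) {
  cat(sprintf("Contact potential '%s': %d types, well %.1f A, cutoff %.1f A\n",
              x$name, nrow(x$energy), x$well_A, x$cutoff_A))
  invisible(x)
}

# Distance modulation: 1 inside the well, linear taper to 0 at the cutoff.
potential_well <- function(potential, d) {
  w <- (potential$cutoff_A - d) / (potential$cutoff_A - potential$well_A)
  pmin(pmax(w, 0), 1)
}

#' Evaluate a contact potential
#'
#' @param potential A `contact_potential`.
#' @param type_a,type_b 3-letter residue type codes (vectorized).
#' @param distance Contact distances in Angstrom (vectorized).
#' @return Energies in the potential's arbitrary units.
#' @export
pair_energy <- function(potential, type_a, type_b, distance) {
  e <- potential$energy[cbind(type_a, type_b)]
  e * potential_well(potential, distance)
}

# Minimum- and maximum-energy type pairs at full well weight; ties broken
# lexicographically.
extreme_pairs <- function(potential) {
  e <- potential$energy
  nm <- rownames(e)
  pick <- function(idx) {
    cand <- which(e == e[idx], arr.ind = TRUE)
    cand <- t(apply(cand, 1L, sort))
    cand <- cand[order(nm[cand[, 1L]], nm[cand[, 2L]]), , drop = FALSE]
    c(nm[cand[1L, 1L]], nm[cand[1L, 2L]])
  }
  list(min = pick(which.min(e)), max = pick(which.max(e)))
}

#' Native contacts of a structure
#'
#' All residue pairs at sequence separation `|i - j| >= min_seq_sep` (serial
#' indices) whose CA-CA distance is at most `contact_cutoff_A`.
#'
#' @param structure A `coarse_structure`.
#' @param contact_cutoff_A Contact distance cutoff in Angstrom (default 8.0).
#' @param min_seq_sep Minimum serial-index separation (default 3).
#' @return Data frame with columns `i`, `j` (0-based serials), `distance`.
#' @export
native_contacts <- function(structure, contact_cutoff_A = 8.0, min_seq_sep = 3) {
  d <- ca_dist(structure)
  n <- nrow(d)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  idx <- which(upper.tri(d) & sep >= min_seq_sep & d <= contact_cutoff_A,
               arr.ind = TRUE)
  out <- data.frame(i = idx[, 1L] - 1L, j = idx[, 2L] - 1L, distance = d[idx])
  out[order(out$i, out$j), , drop = FALSE]
}

# Run fn() under a private RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Empirical native-contact distance distribution, discretized to bin
# midpoints; decoy distances are drawn from it.
distance_bins <- function(distances, n_bins = 20) {
  rng <- range(distances)
  if (diff(rng) == 0) {
    return(list(mids = rng[1L], prob = 1))
  }
  br <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  cnt <- tabulate(findInterval(distances, br, rightmost.closed = TRUE), n_bins)
  mids <- (br[-1L] + br[-length(br)]) / 2
  keep <- cnt > 0
  list(mids = mids[keep], prob = cnt[keep] / sum(cnt))
}

#' Decoy energies for one contact
#'
#' Draws `n_decoys` structural decoys by sampling two residue types from the
#' structure's composition and a contact distance from the empirical
#' native-contact distance distribution (20 bins), then evaluates the
#' potential. Deterministic given `rng_seed`; the caller's RNG state is left
#' untouched.
#'
#' @param structure A `coarse_structure`.
#' @param potential A `contact_potential`.
#' @param n_decoys Number of decoys (default 1000).
#' @param rng_seed Integer seed (required).
#' @param contacts Optional precomputed [native_contacts()] table.
#' @return Numeric vector of decoy energies; degenerate draws (single type
#'   and single distance) carry attribute `degenerate = TRUE`.
#' @export
decoy_set <- function(structure, potential, n_decoys = 1000, rng_seed,
                      contacts = NULL) {
  stopifnot(n_decoys >= 2)
  if (missing(rng_seed)) stop("decoy generation requires an explicit rng_seed")
  if (is.null(contacts)) contacts <- native_contacts(structure)
  comp <- structure$residues$resid
  bins <- distance_bins(contacts$distance)
  e <- with_seed(rng_seed, function() {
    ta <- sample(comp, n_decoys, replace = TRUE)
    tb <- sample(comp, n_decoys, replace = TRUE)
    d <- bins$mids[sample.int(length(bins$mids), n_decoys, replace = TRUE,
                              prob = bins$prob)]
    pair_energy(potential, ta, tb, d)
  })
  if (length(unique(comp)) == 1L && length(bins$mids) == 1L) {
    attr(e, "degenerate") <- TRUE
  }
  e
}

#' Frustration index of a native contact
#'
#' `F = (mean(decoys) - native_energy) / sd(decoys)`: positive when the
#' native pair is more stabilizing than typical decoys (minimally
#' frustrated), negative when less stabilizing (frustrated).
#'
#' @param native_energy Native pair energy.
#' @param decoy_energies Numeric decoy energy vector (sd must be > 0).
#' @return The frustration Z-score.
#' @export
frustration_index <- function(native_energy, decoy_energies) {
  s <- sd(decoy_energies)
  if (!is.finite(s) || s == 0) {
    stop("decoy energies have zero spread; frustration index undefined")
  }
  (mean(decoy_energies) - native_energy) / s
}

#' Classify frustration indices
#'
#' `F >= minimal` (default 0.78, boundary inclusive) is minimally frustrated;
#' `F < high` (default -1, strict) is highly frustrated; the remainder is
#' neutral.
#'
#' @param f Numeric vector of frustration indices.
#' @param minimal Lower bound of the minimally frustrated class.
#' @param high Upper (exclusive) bound of the highly frustrated class.
#' @return Factor with levels `minimal`, `neutral`, `high`.
#' @export
classify_frustration <- function(f, minimal = 0.78, high = -1) {
  out <- ifelse(f >= minimal, "minimal", ifelse(f < high, "high", "neutral"))
  factor(out, levels = c("minimal", "neutral", "high"))
}

#' Local frustration profile of a structure
#'
#' Scores every native contact: native pair energy at the observed CA-CA
#' distance, decoy mean and spread, frustration Z-score and category.
#'
#' @param structure A `coarse_structure`.
#' @param potential A `contact_potential` (default [contact_potential()]).
#' @param contact_cutoff_A,min_seq_sep Native contact definition, see
#'   [native_contacts()].
#' @param n_decoys Decoys per contact (default 1000).
#' @param rng_seed Integer seed (required; profiles are bit-reproducible).
#' @param thresholds Classification thresholds, see [classify_frustration()].
#' @return A `frustration_profile`: data frame `contacts` with per-contact
#'   columns (`i`, `j`, `distance`, `native_energy`, `decoy_mean`,
#'   `decoy_sd`, `index`, `category`), plus `potential`, `n_decoys`,
#'   `rng_seed`, `thresholds`.
#' @export
frustration_profile <- function(structure, potential = contact_potential(),
                                contact_cutoff_A = 8.0, min_seq_sep = 3,
                                n_decoys = 1000, rng_seed,
                                thresholds = c(minimal = 0.78, high = -1)) {
  if (missing(rng_seed)) stop("frustration profiling requires an explicit rng_seed")
  contacts <- native_contacts(structure, contact_cutoff_A, min_seq_sep)
  res <- structure$residues
  m <- nrow(contacts)
  native <- decoy_mean <- decoy_sd <- idx <- numeric(m)
  for (r in seq_len(m)) {
    ti <- res$resid[contacts$i[r] + 1L]
    tj <- res$resid[contacts$j[r] + 1L]
    native[r] <- pair_energy(potential, ti, tj, contacts$distance[r])
    dec <- decoy_set(structure, potential, n_decoys,
                     rng_seed = rng_seed + r, contacts = contacts)
    decoy_mean[r] <- mean(dec)
    decoy_sd[r] <- sd(dec)
    idx[r] <- frustration_index(native[r], dec)
  }
  contacts$native_energy <- native
  contacts$decoy_mean <- decoy_mean
  contacts$decoy_sd <- decoy_sd
  contacts$index <- idx
  contacts$category <- classify_frustration(idx, thresholds[["minimal"]],
                                            thresholds[["high"]])
  structure(list(contacts = contacts, potential = potential,
                 n_decoys = n_decoys, rng_seed = rng_seed,
                 thresholds = thresholds, structure = structure),
            class = "frustration_profile")
}

#' @export
print.frustration_profile <- function(x, ...) {
  tab <- table(x$contacts$category)
  cat(sprintf("Frustration profile: %d contact(s) — %d minimal, %d neutral, %d high\n",
              nrow(x$contacts), tab[["minimal"]], tab[["neutral"]], tab[["high"]]))
  invisible(x)
}

#' Per-residue frustration density
#'
#' For each residue, counts the contacts of each frustration category whose
#' midpoint (between the two CA atoms) lies within `radius_A` of the
#' residue's CA — the per-residue view of how stabilizing or conflicted a
#' residue's local contact environment is.
#'
#' @param profile A `frustration_profile`.
#' @param structure The profiled `coarse_structure` (defaults to the one on
#'   the profile).
#' @param radius_A Counting radius in Angstrom (default 5).
#' @return A `frustration_density` data frame: one row per residue with
#'   columns `serial`, `chain`, `resno`, `n_minimal`, `n_neutral`, `n_high`.
#' @export
frustration_density <- function(profile, structure = NULL, radius_A = 5) {
  stopifnot(inherits(profile, "frustration_profile"))
  if (is.null(structure)) structure <- profile$structure
  res <- structure$residues
  n <- nrow(res)
  counts <- matrix(0L, n, 3L, dimnames = list(NULL, c("minimal", "neutral", "high")))
  ct <- profile$contacts
  if (nrow(ct) > 0L) {
    mid <- (structure$xyz[ct$i + 1L, , drop = FALSE] +
            structure$xyz[ct$j + 1L, , drop = FALSE]) / 2
    for (r in seq_len(nrow(ct))) {
      dd <- sqrt(rowSums((structure$xyz - matrix(mid[r, ], n, 3L, byrow = TRUE))^2))
      near <- which(dd <= radius_A)
      cat_r <- as.character(ct$category[r])
      counts[near, cat_r] <- counts[near, cat_r] + 1L
    }
  }
  out <- data.frame(serial = res$serial, chain = res$chain, resno = res$resno,
                    n_minimal = counts[, "minimal"],
                    n_neutral = counts[, "neutral"],
                    n_high = counts[, "high"])
  class(out) <- c("frustration_density", class(out))
  out
}
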