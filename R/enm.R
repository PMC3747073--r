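# Gaussian network model: Kirchhoff matrix, mode spectrum, fluctuations and
# cross-correlations. Residues within the cutoff are joined by springs of
# uniform force constant gamma; equilibrium dynamics follow from the
# eigendecomposition of the Kirchhoff (graph Laplacian) matrix.

#' Build the elastic (Gaussian) network of a structure
#'
#' Connects every residue pair whose CA-CA distance is at most `cutoff_rc`
#' (inclusive) by a spring of uniform force constant. The Kirchhoff matrix
#' holds -1 for connected off-diagonal pairs and the coordination number on
#' the diagonal; `spring_gamma` and `kBT` scale fluctuation amplitudes only.
#'
#' @param structure A `coarse_structure`.
#' @param cutoff_rc Interaction cutoff distance in Angstrom (default 7.0).
#' @param spring_gamma Uniform spring force constant (default 1, arbitrary units).
#' @param kBT Thermal energy (default 1, arbitrary units).
#' @return An `elastic_network` with elements `kirchhoff`, `cutoff_rc`,
#'   `spring_gamma`, `kBT`, `n_springs`, `structure`.
#' @export
build_network <- function(structure, cutoff_rc = 7.0, spring_gamma = 1, kBT = 1) {
  stopifnot(inherits(structure, "coarse_structure"), cutoff_rc > 0)
  n <- n_residues(structure)
  d <- ca_dist(structure)
  if (any(d[upper.tri(d)] == 0)) {
    warning("coincident CA coordinates for distinct residues; pair kept connected")
  }
  adj <- (d <= cutoff_rc)
  diag(adj) <- FALSE
  k <- -1 * adj
  diag(k) <- colSums(adj)
  structure(
    list(kirchhoff = k, cutoff_rc = cutoff_rc, spring_gamma = spring_gamma,
         kBT = kBT, n_springs = sum(adj) / 2L, structure = structure),
    class = "elastic_network"
  )
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("Elastic network: %d residues, %d springs, cutoff %.1f A\n",
              nrow(x$kirchhoff), x$n_springs, x$cutoff_rc))
  invisible(x)
}

#' Eigendecomposition of the elastic network
#'
#' Returns the full spectrum in ascending eigenvalue order. Eigenvector signs
#' are fixed so the largest-magnitude component of each mode is positive,
#' making serialized outputs deterministic. Eigenvalues below
#' `zero_tol * max(eigenvalue)` are flagged as zero modes; their count equals
#' the number of connected components of the contact graph.
#'
#' @param network An `elastic_network`.
#' @param zero_tol Relative tolerance for flagging zero modes (default 1e-8).
#' @return A `mode_spectrum` with `values`, `vectors` (columns), `n_zero`,
#'   and the generating `network`.
#' @export
decompose <- function(network, zero_tol = 1e-8) {
  stopifnot(inherits(network, "elastic_network"))
  e <- eigen(network$kirchhoff, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(vecs))) {
    peak <- which.max(abs(vecs[, k]))
    if (vecs[peak, k] < 0) vecs[, k] <- -vecs[, k]
  }
  n_zero <- sum(vals < zero_tol * max(vals, zero_tol))
  structure(
    list(values = vals, vectors = vecs, n_zero = n_zero, network = network),
    class = "mode_spectrum"
  )
}

#' @export
print.mode_spectrum <- function(x, ...) {
  cat(sprintf("Mode spectrum: %d modes (%d zero), lowest nonzero eigenvalue %.4g\n",
              length(x$values), x$n_zero,
              if (x$n_zero < length(x$values)) x$values[x$n_zero + 1L] else NA))
  invisible(x)
}

#' Indices of the lowest-frequency nonzero modes
#'
#' @param spectrum A `mode_spectrum`.
#' @param n Number of modes wanted; `NULL` selects all nonzero modes. Requests
#'   beyond the available `N - n_zero` modes are clamped with a warning.
#' @return Integer indices into the ascending spectrum.
#' @export
nonzero_modes <- function(spectrum, n = NULL) {
  all_nz <- seq.int(spectrum$n_zero + 1L, length(spectrum$values))
  if (is.null(n)) return(all_nz)
  if (n > length(all_nz)) {
    warning(sprintf("requested %d modes but only %d nonzero modes exist; clamped", n, length(all_nz)))
    n <- length(all_nz)
  }
  all_nz[seq_len(n)]
}

check_mode_selection <- function(spectrum, modes) {
  bad <- modes[modes <= spectrum$n_zero | modes > length(spectrum$values)]
  if (length(bad) > 0L) {
    stop(sprintf("mode selection includes zero or out-of-range mode(s): %s",
                 paste(bad, collapse = ", ")))
  }
  modes
}

# Mode-summed covariance (3 kBT / gamma) * sum_k lambda_k^-1 u_k u_k^T.
mode_covariance <- function(spectrum, modes) {
  net <- spectrum$network
  u <- spectrum$vectors[, modes, drop = FALSE]
  li <- 1 / spectrum$values[modes]
  (3 * net$kBT / net$spring_gamma) * (u %*% (li * t(u)))
}

#' Per-residue mean-square fluctuations
#'
#' MSF of residue i over a set of modes:
#' `msf_i = (3 kBT / gamma) * sum_k lambda_k^-1 u_k[i]^2`. Over all nonzero
#' modes this equals `(3 kBT / gamma) * diag(pinv(Kirchhoff))`.
#'
#' @param spectrum A `mode_spectrum`.
#' @param modes Integer mode indices into the ascending spectrum (1-based;
#'   must exclude zero modes). Default: all nonzero modes.
#' @return A `mobility_profile` with `msf`, `nmsf` and `modes_used`.
#' @export
mean_square_fluctuations <- function(spectrum, modes = NULL) {
  if (is.null(modes)) modes <- nonzero_modes(spectrum)
  modes <- check_mode_selection(spectrum, modes)
  msf <- diag(mode_covariance(spectrum, modes))
  msf[msf < 0] <- 0  # clip eigen round-off
  new_mobility_profile(msf, modes, normalization = "none")
}

new_mobility_profile <- function(msf, modes, normalization = c("none", "max", "sum")) {
  normalization <- match.arg(normalization)
  nmsf <- switch(normalization,
                 none = msf,
                 max = if (max(msf) > 0) msf / max(msf) else msf,
                 sum = if (sum(msf) > 0) msf / sum(msf) else msf)
  structure(list(msf = msf, nmsf = nmsf, modes_used = modes,
                 normalization = normalization),
            class = "mobility_profile")
}

#' Residue cross-correlation map
#'
#' Raw covariances `<dR_i . dR_j>` summed over the selected modes, and their
#' normalization `C_ij = raw_ij / sqrt(raw_ii raw_jj)` in `[-1, 1]` with unit
#' diagonal. With truncated mode sets a residue can have zero self-variance;
#' such entries are reported as 0 and flagged in the logical `mask`.
#'
#' @inheritParams mean_square_fluctuations
#' @return A `correlation_map` with `raw`, `normalized`, `mask`, `modes_used`.
#' @export
cross_correlations <- function(spectrum, modes = NULL) {
  if (is.null(modes)) modes <- nonzero_modes(spectrum)
  modes <- check_mode_selection(spectrum, modes)
  raw <- mode_covariance(spectrum, modes)
  v <- diag(raw)
  undef <- v <= .Machine$double.eps * max(v)
  s <- sqrt(pmax(v, 0))
  s[undef] <- 1  # placeholder; masked below
  nor <- raw / outer(s, s)
  mask <- outer(undef, undef, "|")
  nor[mask] <- 0
  nor <- pmin(pmax(nor, -1), 1)
  dg <- rep(1, length(v)); dg[undef] <- 0
  diag(nor) <- dg
  structure(list(raw = raw, normalized = nor, mask = mask, modes_used = modes),
            class = "correlation_map")
}

#' Normalized mean-square fluctuation (NMSF) profile
#'
#' Mobility over the `n_modes` lowest-frequency nonzero modes — the standard
#' low-mode view of collective motions (single slowest mode, 3-mode and
#' 10-mode averages are the common presets; 20 low modes is the analysis
#' default elsewhere in the package). The profile is normalized to unit
#' maximum by default (unit sum optionally). Interior stationary points are
#' reported: local maxima mark flexible sites, local minima mark hinge
#' candidates.
#'
#' @param spectrum A `mode_spectrum`.
#' @param n_modes Number of lowest nonzero modes to average (default 3).
#' @param normalization `"max"` (profile in \[0,1\]) or `"sum"`.
#' @param site_band Depth filter for stationary-point calls, as a fraction of
#'   the profile range (default 0.1): a local minimum only counts as a hinge
#'   candidate when it lies within `site_band` of the profile minimum, and a
#'   local maximum as a flexible site within `site_band` of the profile
#'   maximum. This suppresses the shallow ripples every near-rigid region
#'   shows and keeps the deep anchoring minima and dominant peaks.
#' @return A `mobility_profile` with additional elements `flexible_sites` and
#'   `hinge_candidates` (0-based serial indices).
#' @export
nmsf_profile <- function(spectrum, n_modes = 3, normalization = c("max", "sum"),
                         site_band = 0.1) {
  stopifnot(n_modes >= 1)
  normalization <- match.arg(normalization)
  modes <- nonzero_modes(spectrum, n_modes)
  msf <- diag(mode_covariance(spectrum, modes))
  msf[msf < 0] <- 0
  prof <- new_mobility_profile(msf, modes, normalization)
  y <- prof$nmsf
  sp <- stationary_points(y)
  band <- site_band * diff(range(y))
  sp$maxima <- sp$maxima[y[sp$maxima] >= max(y) - band]
  sp$minima <- sp$minima[y[sp$minima] <= min(y) + band]
  prof$flexible_sites <- sp$maxima - 1L
  prof$hinge_candidates <- sp$minima - 1L
  prof
}

# Discrete stationary points of a profile (1-based indices); plateaus are
# resolved by comparing against the nearest differing neighbours.
stationary_points <- function(y) {
  n <- length(y)
  maxima <- integer(0); minima <- integer(0)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      l <- i - 1L; while (l > 1L && y[l] == y[i]) l <- l - 1L
      r <- i + 1L; while (r < n && y[r] == y[i]) r <- r + 1L
      if (y[l] == y[i] || y[r] == y[i]) next
      if (y[l] < y[i] && y[r] < y[i]) maxima <- c(maxima, i)
      if (y[l] > y[i] && y[r] > y[i]) minima <- c(minima, i)
    }
  }
  list(maxima = maxima, minima = minima)
}

#' Write a dense matrix as TSV with serial-index headers
#'
#' @param m Numeric matrix (N x N or N x k).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_matrix_tsv <- function(m, file) {
  colnames(m) <- seq_len(ncol(m)) - 1L
  write.table(m, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
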