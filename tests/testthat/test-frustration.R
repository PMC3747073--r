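test_that("native contacts respect sequence separation and the distance cutoff", {
  # 10-bead extended chain at 3.8 A spacing: |i-j| >= 3 implies >= 11.4 A
  ext <- make_chain(10, spacing_A = 3.8)
  expect_equal(nrow(native_contacts(ext)), 0L)
  # two residues: nothing at separation >= 3
  two <- coarse_structure(rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(nrow(native_contacts(two)), 0L)
  # designed (1, 5) pair at 6 A (0-based serials 1 and 5)
  xyz <- rbind(c(0, 0, 0), c(0, 30, 0), c(0, 60, 0), c(0, 90, 0),
               c(0, 120, 0), c(6, 30, 0))
  s <- coarse_structure(xyz)
  nc <- native_contacts(s)
  expect_equal(nrow(nc), 1L)
  expect_equal(c(nc$i, nc$j), c(1L, 5L))
  expect_equal(nc$distance, 6)
  # helix fixture: contacts are exactly the (i, i+3) and (i, i+4) pairs
  fd <- make_frustration_design(n = 20)
  sep <- native_contacts(fd)$j - native_contacts(fd)$i
  expect_setequal(unique(sep), c(3L, 4L))
  expect_equal(nrow(native_contacts(fd)), 17L + 16L)
})

test_that("decoys are seed-reproducible and leave the session RNG untouched", {
  fd <- make_frustration_design(n = 30)
  pot <- contact_potential()
  set.seed(123); before <- .Random.seed
  d1 <- decoy_set(fd, pot, n_decoys = 200, rng_seed = 5)
  expect_identical(.Random.seed, before)
  d2 <- decoy_set(fd, pot, n_decoys = 200, rng_seed = 5)
  expect_identical(d1, d2)
  d3 <- decoy_set(fd, pot, n_decoys = 200, rng_seed = 6)
  expect_false(identical(d1, d3))
  expect_error(decoy_set(fd, pot, n_decoys = 200), "rng_seed")
})

test_that("constant potentials give constant decoys; degenerate input is flagged", {
  fd <- make_frustration_design(n = 30)
  flat <- contact_potential(energy = matrix(-1, 20, 20,
                                            dimnames = list(allosteer:::AA3, allosteer:::AA3)),
                            well_A = 100, cutoff_A = 101)
  d <- decoy_set(fd, flat, n_decoys = 50, rng_seed = 1)
  expect_equal(unique(round(d, 12)), -1)
  # single type, single distance
  one <- coarse_structure(rbind(c(0, 0, 0), c(0, 40, 0), c(0, 80, 0), c(6, 0, 0)),
                          resid = "ALA")
  dd <- decoy_set(one, contact_potential(), n_decoys = 10, rng_seed = 2)
  expect_true(isTRUE(attr(dd, "degenerate")))
})

test_that("Monte-Carlo decoy statistics match exhaustive enumeration", {
  # two-letter alphabet, two distance bins
  xyz <- rbind(c(0, 0, 0), c(0, 30, 0), c(0, 60, 0), c(5, 0, 0),
               c(0, 90, 0), c(7.5, 60, 0))
  s <- coarse_structure(xyz, resid = c("ILE", "ALA", "ILE", "ALA", "ILE", "ALA"))
  nc <- native_contacts(s)
  stopifnot(nrow(nc) == 2L, length(unique(nc$distance)) == 2L)
  pot <- contact_potential()
  n_dec <- 4000
  d <- decoy_set(s, pot, n_decoys = n_dec, rng_seed = 9, contacts = nc)
  oracle <- exhaustive_decoy_stats(s$residues$resid, pot, nc$distance)
  se_mean <- oracle$sd / sqrt(n_dec)
  expect_lt(abs(mean(d) - oracle$mean), 3 * se_mean)
  # sd agrees loosely (sampling error of sd ~ sd/sqrt(2n))
  expect_lt(abs(sd(d) - oracle$sd), 4 * oracle$sd / sqrt(2 * n_dec))
})

test_that("frustration index arithmetic and classification boundaries are exact", {
  expect_equal(frustration_index(1, c(0, 2, 2, 0)), 0)
  # decoys {0,2}: mean 1, sd ~ 1; use the exact two-point sample
  dec <- c(0, 2)
  expect_equal(frustration_index(-1, dec), (1 - (-1)) / sd(dec))
  expect_equal(frustration_index(-1, dec), sqrt(2), tolerance = 1e-12)
  expect_error(frustration_index(0, c(1, 1, 1)), "zero spread")

  expect_equal(as.character(classify_frustration(c(0.78, 0.779, 0, -1, -1.01, 2))),
               c("minimal", "neutral", "neutral", "neutral", "high", "minimal"))
})

test_that("planted optimal and frustrated pairs classify as designed", {
  fd <- make_frustration_design(n = 60)
  gt <- attr(fd, "ground_truth")
  fp <- frustration_profile(fd, n_decoys = 1000, rng_seed = 17)
  key <- paste(fp$contacts$i, fp$contacts$j)
  for (p in gt$optimal_pairs) {
    r <- match(paste(min(p), max(p)), key)
    expect_gte(fp$contacts$index[r], 0.78)
    expect_equal(as.character(fp$contacts$category[r]), "minimal")
  }
  for (p in gt$frustrated_pairs) {
    r <- match(paste(min(p), max(p)), key)
    expect_lt(fp$contacts$index[r], -1)
    expect_equal(as.character(fp$contacts$category[r]), "high")
  }
  # background contacts are mostly neutral
  planted <- unlist(c(gt$optimal_pairs, gt$frustrated_pairs))
  bg <- !(fp$contacts$i %in% planted | fp$contacts$j %in% planted)
  frac_neutral <- mean(fp$contacts$category[bg] == "neutral")
  expect_gt(frac_neutral, 0.5)
})

test_that("profiles are bit-reproducible for a fixed seed", {
  fd <- make_frustration_design(n = 40)
  f1 <- frustration_profile(fd, n_decoys = 300, rng_seed = 4)
  f2 <- frustration_profile(fd, n_decoys = 300, rng_seed = 4)
  expect_identical(f1$contacts, f2$contacts)
})

test_that("random native pairs mostly score within one decoy sd", {
  fd <- make_frustration_design()
  pot <- contact_potential()
  nc <- native_contacts(fd)
  hits <- vapply(1:50, function(seed) {
    dec <- decoy_set(fd, pot, n_decoys = 500, rng_seed = 100 + seed, contacts = nc)
    native <- allosteer:::with_seed(9000 + seed, function() sample(dec, 1))
    abs(frustration_index(native, dec)) < 1
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("frustration density counts contacts near both partners and conserves totals", {
  # single contact between serials 0 and 3, midpoint 3 A from each CA
  xyz <- rbind(c(0, 0, 0), c(0, 40, 0), c(0, 80, 0), c(6, 0, 0), c(0, 120, 0))
  s <- coarse_structure(xyz, resid = c("ILE", "SER", "THR", "ILE", "GLY"))
  fp <- frustration_profile(s, n_decoys = 200, rng_seed = 3)
  stopifnot(nrow(fp$contacts) == 1L)
  den <- frustration_density(fp, radius_A = 5)
  totals <- den$n_minimal + den$n_neutral + den$n_high
  expect_equal(totals, c(1L, 0L, 0L, 1L, 0L))
  cat_col <- paste0("n_", as.character(fp$contacts$category[1]))
  expect_equal(den[[cat_col]][1], 1L)
  # contact-free structure: all-zero densities
  bare <- make_chain(10, spacing_A = 3.8)
  fp0 <- list(contacts = native_contacts(bare), structure = bare)
  fp0$contacts$category <- classify_frustration(numeric(0))
  class(fp0) <- "frustration_profile"
  den0 <- frustration_density(fp0, structure = bare)
  expect_true(all(den0$n_minimal + den0$n_neutral + den0$n_high == 0L))
  # density totals equal per-residue nearby-contact counts on the helix
  fd <- make_frustration_design(n = 25)
  fpd <- frustration_profile(fd, n_decoys = 100, rng_seed = 8)
  dend <- frustration_density(fpd)
  mids <- (fd$xyz[fpd$contacts$i + 1L, ] + fd$xyz[fpd$contacts$j + 1L, ]) / 2
  expected <- vapply(seq_len(n_residues(fd)), function(i) {
    sum(sqrt(rowSums((mids - matrix(fd$xyz[i, ], nrow(mids), 3, byrow = TRUE))^2)) <= 5)
  }, 0L)
  expect_equal(dend$n_minimal + dend$n_neutral + dend$n_high, expected)
})
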