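# Comparative pipeline: run the elastic-network, communication, contact
# network and frustration analyses on an unbound structure and its complex,
# restricted to the shared residues, and report signed differences
# (complex - unbound, computed once).

#' Map residues shared by two structures
#'
#' Matches residues on the (chain, author number, insertion code, type)
#' quadruple. Residues present in only one structure — extra chains, point
#' mutations — are listed unmatched.
#'
#' @param a,b `coarse_structure` objects (conventionally unbound, complex).
#' @return A `residue_mapping`: data frame `pairs` with 0-based `serial_a`,
#'   `serial_b`, plus `unmatched_a`, `unmatched_b` residue tables.
#' @export
map_common_residues <- function(a, b) {
  ka <- residue_key(a$residues)
  kb <- residue_key(b$residues)
  idx <- match(ka, kb)
  hit <- !is.na(idx)
  if (!any(hit)) stop("no residues shared between the two structures")
  structure(
    list(pairs = data.frame(serial_a = which(hit) - 1L, serial_b = idx[hit] - 1L),
         unmatched_a = a$residues[!hit, , drop = FALSE],
         unmatched_b = b$residues[-idx[hit], , drop = FALSE]),
    class = "residue_mapping"
  )
}

#' @export
print.residue_mapping <- function(x, ...) {
  cat(sprintf("Residue mapping: %d shared, %d/%d unmatched\n",
              nrow(x$pairs), nrow(x$unmatched_a), nrow(x$unmatched_b)))
  invisible(x)
}

default_params <- function() {
  list(cutoff_rc = 7.0, n_modes = 20, min_separation_A = 20, cp_quantile = 0.05,
       cp_threshold = NULL, i_min = 3.0, k = 3, overlap_rule = "k-2",
       min_fraction = 0.75, contact_distance_A = 4.5, contact_cutoff_A = 8.0,
       n_decoys = 1000, radius_A = 5, rng_seed = 1L)
}

merge_params <- function(config) {
  p <- default_params()
  unknown <- setdiff(names(config), names(p))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown parameter key(s): %s", paste(unknown, collapse = ", ")))
  }
  p[names(config)] <- config
  p
}

pair_key <- function(pairs) paste(pairs$serial_i, pairs$serial_j)

#' Compare an unbound structure with its complex
#'
#' Runs the selected analyses on both inputs and reports differences on the
#' shared residue mapping, with the fixed sign convention complex - unbound:
#' per-residue mobility delta, cross-correlation difference matrix, gained
#' and lost effective-communicator pairs, clique/community count table and
#' frustration category fractions. Each difference is computed once, so
#' self-comparison yields exact zeros.
#'
#' @param unbound,complex `coarse_structure` objects.
#' @param analyses Subset of `c("gnm", "cp", "psn", "frustration")`.
#' @param config Named list of parameter overrides (see `run_config()` for
#'   the keys; defaults are the package's standard settings: 7.0 A elastic
#'   cutoff, 20 low modes, 20 A communicator separation, 3.0% interaction
#'   strength, k = 3 cliques, 1000 decoys, 5 A density radius).
#' @return A `comparison_report`.
#' @export
compare_structures <- function(unbound, complex,
                               analyses = c("gnm", "cp", "psn", "frustration"),
                               config = list()) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  p <- merge_params(config)
  map <- map_common_residues(unbound, complex)
  ia <- map$pairs$serial_a + 1L
  ib <- map$pairs$serial_b + 1L
  out <- list(mapping = map, params = p, analyses = analyses,
              labels = c(unbound = unbound$label, complex = complex$label))

  net_a <- build_network(unbound, cutoff_rc = p$cutoff_rc)
  net_b <- build_network(complex, cutoff_rc = p$cutoff_rc)
  spec_a <- decompose(net_a)
  spec_b <- decompose(net_b)

  if ("gnm" %in% analyses) {
    prof_a <- nmsf_profile(spec_a, n_modes = p$n_modes)
    prof_b <- nmsf_profile(spec_b, n_modes = p$n_modes)
    out$mobility_delta <- prof_b$nmsf[ib] - prof_a$nmsf[ia]
    cc_a <- cross_correlations(spec_a, nonzero_modes(spec_a, min(p$n_modes, n_residues(unbound) - 1L)))
    cc_b <- cross_correlations(spec_b, nonzero_modes(spec_b, min(p$n_modes, n_residues(complex) - 1L)))
    out$correlation_delta <- cc_b$normalized[ib, ib] - cc_a$normalized[ia, ia]
    out$profiles <- list(unbound = prof_a, complex = prof_b)
  }
  if ("cp" %in% analyses) {
    cp_a <- effective_pairs(commute_times(net_a), unbound,
                            threshold = p$cp_threshold, quantile = p$cp_quantile,
                            min_separation_A = p$min_separation_A)
    cp_b <- effective_pairs(commute_times(net_b), complex,
                            threshold = p$cp_threshold, quantile = p$cp_quantile,
                            min_separation_A = p$min_separation_A)
    # restate pairs in mapping coordinates before set comparison
    remap <- function(cp, serials, side) {
      keep <- cp$pairs$serial_i %in% serials & cp$pairs$serial_j %in% serials
      pr <- cp$pairs[keep, , drop = FALSE]
      conv <- match(c(pr$serial_i, pr$serial_j), serials)
      m <- matrix(conv, ncol = 2L)
      paste(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]))
    }
    keys_a <- remap(cp_a, map$pairs$serial_a)
    keys_b <- remap(cp_b, map$pairs$serial_b)
    out$communicators <- list(
      unbound = cp_a, complex = cp_b,
      gained = setdiff(keys_b, keys_a), lost = setdiff(keys_a, keys_b)
    )
  }
  if ("psn" %in% analyses) {
    out$psn_counts <- count_summary(
      setNames(list(unbound, complex), c(unbound$label, complex$label)),
      i_min = p$i_min, k = p$k, overlap_rule = p$overlap_rule,
      contact_distance_A = p$contact_distance_A
    )
  }
  if ("frustration" %in% analyses) {
    frac <- function(x) {
      fp <- frustration_profile(x, contact_cutoff_A = p$contact_cutoff_A,
                                n_decoys = p$n_decoys, rng_seed = p$rng_seed)
      tb <- table(fp$contacts$category)
      as.numeric(tb) / max(sum(tb), 1L)
    }
    fa <- frac(unbound); fb <- frac(complex)
    out$frustration_fractions <- data.frame(
      structure = c(unbound$label, complex$label),
      minimal = c(fa[1L], fb[1L]), neutral = c(fa[2L], fb[2L]),
      high = c(fa[3L], fb[3L])
    )
  }
  class(out) <- "comparison_report"
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Comparison report: %s vs %s (%d shared residues; analyses: %s)\n",
              x$labels[["complex"]], x$labels[["unbound"]],
              nrow(x$mapping$pairs), paste(x$analyses, collapse = ", ")))
  if (!is.null(x$mobility_delta)) {
    cat(sprintf("  mobility delta (complex - unbound): mean %.4g, range [%.4g, %.4g]\n",
                mean(x$mobility_delta), min(x$mobility_delta), max(x$mobility_delta)))
  }
  if (!is.null(x$communicators)) {
    cat(sprintf("  communicator pairs: %d gained, %d lost\n",
                length(x$communicators$gained), length(x$communicators$lost)))
  }
  invisible(x)
}

#' Run a configured comparative analysis
#'
#' Reads a YAML configuration declaring the inputs and parameters, runs
#' [compare_structures()] and serializes the report into a reproducible run
#' directory (TSV matrices and tables, a JSON summary, and a log of every
#' parameter and seed used). Running twice with the same configuration
#' produces byte-identical outputs.
#'
#' Recognized top-level keys: `unbound`, `complex` (PDB paths; required),
#' `outdir` (required), `analyses` (default all four), and any parameter from
#' the defaults table: `cutoff_rc`, `n_modes`, `min_separation_A`,
#' `cp_quantile`, `cp_threshold`, `i_min`, `k`, `overlap_rule`,
#' `min_fraction`, `contact_distance_A`, `contact_cutoff_A`, `n_decoys`,
#' `radius_A`, `rng_seed`. Unknown keys are an error.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return The `comparison_report`, invisibly; side effect: files under
#'   `outdir`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  required <- c("unbound", "complex", "outdir")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys) > 0L) {
    stop(sprintf("config is missing required key(s): %s",
                 paste(missing_keys, collapse = ", ")))
  }
  analyses <- config$analyses
  if (is.null(analyses)) analyses <- c("gnm", "cp", "psn", "frustration")
  params <- config[setdiff(names(config), c(required, "analyses"))]
  p <- merge_params(params)  # validates keys early

  unbound <- read_structure(config$unbound)
  complex <- read_structure(config$complex)
  rep <- compare_structures(unbound, complex, analyses = analyses, config = params)

  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- c(sprintf("allosteer run (package %s)", as.character(utils::packageVersion("allosteer"))),
           sprintf("unbound: %s", config$unbound),
           sprintf("complex: %s", config$complex),
           sprintf("analyses: %s", paste(analyses, collapse = ",")),
           vapply(names(p), function(k) sprintf("param %s: %s", k,
                   paste(format(p[[k]]), collapse = ",")), ""))
  writeLines(log, file.path(outdir, "run_log.txt"))

  if (!is.null(rep$mobility_delta)) {
    write.table(data.frame(serial_a = rep$mapping$pairs$serial_a,
                           serial_b = rep$mapping$pairs$serial_b,
                           mobility_delta = rep$mobility_delta),
                file.path(outdir, "mobility_delta.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(rep$correlation_delta, file.path(outdir, "correlation_delta.tsv"))
  }
  if (!is.null(rep$communicators)) {
    write.table(rep$communicators$unbound$pairs,
                file.path(outdir, "cp_pairs_unbound.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(rep$communicators$complex$pairs,
                file.path(outdir, "cp_pairs_complex.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(rep$psn_counts)) {
    write.table(rep$psn_counts, file.path(outdir, "psn_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(rep$frustration_fractions)) {
    write.table(rep$frustration_fractions,
                file.path(outdir, "frustration_fractions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- list(
    schema_version = "1.0",
    labels = as.list(rep$labels),
    n_shared_residues = nrow(rep$mapping$pairs),
    analyses = analyses,
    params = p,
    mobility_delta_mean = if (!is.null(rep$mobility_delta)) mean(rep$mobility_delta) else NULL,
    communicators_gained = if (!is.null(rep$communicators)) length(rep$communicators$gained) else NULL,
    communicators_lost = if (!is.null(rep$communicators)) length(rep$communicators$lost) else NULL
  )
  jsonlite::write_json(summary[!vapply(summary, is.null, TRUE)],
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(rep)
}
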