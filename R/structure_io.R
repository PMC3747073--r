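# Residue-level structure model: one node per residue, anchored at the CA atom,
# with side-chain atoms retained for contact-network construction.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

new_coarse_structure <- function(residues, xyz, sidechain, label = "structure") {
  stopifnot(nrow(residues) == nrow(xyz), nrow(residues) == length(sidechain))
  if (nrow(residues) < 2L) {
    stop("a coarse structure needs at least 2 residues")
  }
  residues$serial <- seq_len(nrow(residues)) - 1L
  rownames(residues) <- NULL
  structure(
    list(residues = residues, xyz = unname(as.matrix(xyz)),
         sidechain = sidechain, label = label),
    class = "coarse_structure"
  )
}

#' Number of residues in a structure or ensemble
#'
#' @param x A `coarse_structure` or `structure_ensemble`.
#' @return Integer residue count.
#' @export
n_residues <- function(x) {
  if (inherits(x, "structure_ensemble")) x <- x$frames[[1L]]
  nrow(x$residues)
}

#' @export
print.coarse_structure <- function(x, ...) {
  cat(sprintf("Coarse structure '%s': %d residues, %d chain(s), %s side-chain atoms\n",
              x$label, n_residues(x), length(unique(x$residues$chain)),
              sum(vapply(x$sidechain, function(s) if (is.null(s)) 0L else nrow(s), 0L))))
  invisible(x)
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("Structure ensemble '%s': %d frames x %d residues\n",
              x$label, length(x$frames), n_residues(x)))
  invisible(x)
}

residue_key <- function(res) {
  paste(res$chain, res$resno, res$insert, res$resid, sep = "|")
}

#' Read a PDB file into the coarse residue model
#'
#' Parses a PDB file (or literal PDB text) and reduces it to one node per
#' residue: the CA coordinate plus any side-chain heavy atoms. HETATM records,
#' waters, hydrogens and alternate locations other than `' '`/`'A'` are
#' discarded; residues without a CA atom are dropped with a warning. Residues
#' are ordered chain-then-author-number (insertion codes included in the key)
#' and assigned consecutive 0-based serial indices, so author-numbering gaps
#' are compressed; a gap report is emitted as a message.
#'
#' @param pdb Path to a PDB file, or a character string containing PDB text.
#' @param model `"all"` (default) to read every MODEL — returning a
#'   [structure_ensemble] when more than one is present — or a single integer
#'   selecting one model.
#' @param label Label stored on the returned object; defaults to the file name.
#' @return A `coarse_structure`, or a `structure_ensemble` for multi-model
#'   input with `model = "all"`.
#' @export
read_structure <- function(pdb, model = "all", label = NULL) {
  path <- pdb
  if (length(pdb) > 1L || grepl("\n", pdb[1L]) || grepl("^(ATOM|HETATM|MODEL|HEADER|REMARK)", pdb[1L])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(paste(pdb, collapse = "\n"), path)
    on.exit(unlink(path), add = TRUE)
    if (is.null(label)) label <- "pdb-text"
  }
  if (is.null(label)) label <- sub("\\.pdb$", "", basename(path))
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)

  at <- p$atom
  keep <- at$type == "ATOM" &
    !(at$resid %in% c("HOH", "WAT", "DOD")) &
    (is.na(at$alt) | at$alt %in% c("", " ", "A")) &
    !grepl("^[0-9]*H", at$elety)
  at$row <- seq_len(nrow(at))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no protein ATOM records found")
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""

  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  # chain-then-author-number ordering of distinct residues
  u <- !duplicated(key)
  ord <- order(at$chain[u], at$resno[u], at$insert[u])
  ukey <- key[u][ord]

  ca_row <- integer(0); res_rows <- list(); res_meta <- list()
  dropped <- character(0)
  for (k in ukey) {
    rows <- at[key == k, , drop = FALSE]
    ca <- rows[rows$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0L) {
      dropped <- c(dropped, paste0(rows$resid[1L], " ", k))
      next
    }
    ca_row <- c(ca_row, ca$row[1L])
    sc <- rows[!(rows$elety %in% BACKBONE_ATOMS), , drop = FALSE]
    res_rows[[length(res_rows) + 1L]] <- sc$row
    res_meta[[length(res_meta) + 1L]] <-
      data.frame(chain = rows$chain[1L], resno = rows$resno[1L],
                 insert = rows$insert[1L], resid = rows$resid[1L],
                 stringsAsFactors = FALSE)
  }
  if (length(dropped) > 0L) {
    warning(sprintf("dropped %d residue(s) without a CA atom: %s",
                    length(dropped), paste(head(dropped, 5L), collapse = ", ")))
  }
  if (length(ca_row) == 0L) stop("no CA atoms found in input")
  residues <- do.call(rbind, res_meta)

  # gap report per chain
  for (ch in unique(residues$chain)) {
    rn <- residues$resno[residues$chain == ch & residues$insert == ""]
    jumps <- which(diff(rn) > 1L)
    if (length(jumps) > 0L) {
      message(sprintf("chain %s: %d author-numbering gap(s) compressed (e.g. %d -> %d)",
                      ch, length(jumps), rn[jumps[1L]], rn[jumps[1L] + 1L]))
    }
  }

  nmod <- if (is.matrix(p$xyz)) nrow(p$xyz) else 1L
  xyz_mat <- if (is.matrix(p$xyz)) p$xyz else matrix(p$xyz, nrow = 1L)
  frame_of <- function(f) {
    co <- matrix(xyz_mat[f, ], ncol = 3L, byrow = TRUE)
    sc <- lapply(seq_along(res_rows), function(i) {
      rows <- res_rows[[i]]
      if (length(rows) == 0L) return(NULL)
      m <- co[rows, , drop = FALSE]
      rownames(m) <- at$elety[match(rows, at$row)]
      m
    })
    new_coarse_structure(residues, co[ca_row, , drop = FALSE], sc, label = label)
  }

  if (identical(model, "all")) {
    if (nmod == 1L) return(frame_of(1L))
    frames <- lapply(seq_len(nmod), frame_of)
    as_structure_ensemble(frames, label = label)
  } else {
    stopifnot(is.numeric(model), model >= 1L, model <= nmod)
    frame_of(as.integer(model))
  }
}

#' Assemble a structure ensemble from aligned frames
#'
#' @param frames List of `coarse_structure` objects sharing an identical
#'   residue identity list (chain, author number, insertion code, type).
#' @param label Ensemble label.
#' @return A `structure_ensemble`.
#' @export
as_structure_ensemble <- function(frames, label = "ensemble") {
  stopifnot(length(frames) >= 1L)
  ref <- residue_key(frames[[1L]]$residues)
  for (f in seq_along(frames)) {
    if (!identical(residue_key(frames[[f]]$residues), ref)) {
      stop(sprintf("ensemble frames are inconsistent: frame %d residue list differs from frame 1", f))
    }
  }
  structure(list(frames = frames, label = label), class = "structure_ensemble")
}

#' Author-to-serial renumbering map
#'
#' Crystal structures carry author numbering with gaps and insertion codes;
#' matrix-valued analyses use consecutive 0-based serial indices. This returns
#' the bijective mapping between the two, one row per residue.
#'
#' @param structure A `coarse_structure`.
#' @return A data frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `serial`.
#' @export
renumber_map <- function(structure) {
  res <- structure$residues
  key <- paste(res$chain, res$resno, res$insert, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (chain, author number, insertion code) keys; renumbering is not bijective")
  }
  res
}

#' Serial indices for author-numbered residues
#'
#' @param structure A `coarse_structure`.
#' @param resno Author residue numbers.
#' @param chain Chain identifiers (recycled); defaults to the first chain.
#' @return 0-based serial indices (NA where unmatched).
#' @export
author_to_serial <- function(structure, resno, chain = NULL) {
  res <- structure$residues
  if (is.null(chain)) chain <- res$chain[1L]
  chain <- rep_len(chain, length(resno))
  idx <- match(paste(chain, resno), paste(res$chain, res$resno))
  res$serial[idx]
}

#' Residue table export
#'
#' @param structure A `coarse_structure`.
#' @param file Optional TSV path; when given the table is also written there.
#' @return The residue table (invisibly when `file` is given).
#' @export
residue_table <- function(structure, file = NULL) {
  tab <- renumber_map(structure)
  if (!is.null(file)) {
    write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

# Flatten one frame to per-atom vectors for PDB emission.
flatten_atoms <- function(structure, b = NULL) {
  res <- structure$residues
  n <- nrow(res)
  if (is.null(b)) b <- rep(0, n)
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- list(elety = "CA", xyz = structure$xyz[i, ], i = i)
    sc <- structure$sidechain[[i]]
    if (!is.null(sc)) {
      for (a in seq_len(nrow(sc))) {
        rows[[length(rows) + 1L]] <- list(elety = rownames(sc)[a], xyz = sc[a, ], i = i)
      }
    }
  }
  idx <- vapply(rows, function(r) r$i, 0L)
  list(
    xyz = as.numeric(vapply(rows, function(r) r$xyz, numeric(3))),
    elety = vapply(rows, function(r) r$elety, ""),
    resno = res$resno[idx], chain = res$chain[idx],
    resid = res$resid[idx], insert = res$insert[idx],
    b = round(b[idx], 2)
  )
}

write_frame_pdb <- function(structure, file, b = NULL) {
  fa <- flatten_atoms(structure, b)
  ins <- ifelse(fa$insert == "", NA, fa$insert)
  bio3d::write.pdb(file = file, xyz = fa$xyz, elety = fa$elety,
                   resno = fa$resno, chain = fa$chain, resid = fa$resid,
                   insert = ins, b = fa$b, o = rep(1, length(fa$elety)))
  invisible(file)
}

#' Write a structure or ensemble as PDB
#'
#' Ensembles are written as multi-MODEL PDB files. The output round-trips
#' through [read_structure()] to the same coarse model (coordinates at the
#' PDB format's 3-decimal precision).
#'
#' @param x A `coarse_structure` or `structure_ensemble`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_structure_pdb <- function(x, file) {
  if (inherits(x, "coarse_structure")) return(write_frame_pdb(x, file))
  stopifnot(inherits(x, "structure_ensemble"))
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_along(x$frames)) {
    tmp <- tempfile(fileext = ".pdb")
    write_frame_pdb(x$frames[[f]], tmp)
    lines <- readLines(tmp)
    unlink(tmp)
    lines <- lines[grepl("^ATOM|^TER", lines)]
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Write a structure with per-residue values in the B-factor column
#'
#' Standard route for coloring structures by a computed per-residue quantity
#' (mobility, frustration density, ...) in a molecular viewer: every atom of
#' residue `i` carries `values[i]`, rounded to the PDB B-factor precision of
#' two decimals.
#'
#' @param structure A `coarse_structure`.
#' @param values Finite numeric vector, one value per residue.
#' @param file Output PDB path.
#' @return `file`, invisibly.
#' @export
write_mobility_pdb <- function(structure, values, file) {
  n <- n_residues(structure)
  if (length(values) != n) {
    stop(sprintf("expected %d per-residue values, got %d", n, length(values)))
  }
  if (!all(is.finite(values))) stop("per-residue values must be finite")
  write_frame_pdb(structure, file, b = values)
}

# CA-CA distance matrix in Angstrom.
ca_dist <- function(structure) {
  as.matrix(dist(structure$xyz))
}
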