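#' @title Multi-model PDB input/output and atom selection
#' @description
#' Containers and I/O for conformational ensembles stored as multi-model PDB
#' files. A [trajectory] holds one shared atom table plus one coordinate row
#' per frame (the layout used by essential-dynamics codes: each row is
#' `x1,y1,z1,x2,y2,z2,...`). A [structure3d] is a single conformer.
#' @name structio
NULL

#' Construct a trajectory
#'
#' @param atoms data.frame with columns `chain` (single character), `resno`
#'   (integer, per-chain residue number), `resname` (3-letter code), `atom`
#'   (PDB atom name), `het` (logical, HETATM record), `element` (element
#'   symbol, may be `""`).
#' @param xyz numeric matrix, one row per frame, `3 * nrow(atoms)` columns in
#'   `x1,y1,z1,...` order.
#' @param frame_interval picoseconds between consecutive frames (default
#'   100 ps, the sampling interval of the simulations the package emulates).
#' @param label free-text label carried through analyses.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(atoms, xyz, frame_interval = 100, label = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("chain", "resno", "resname", "atom", "het", "element")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0)
    stop_mnt(paste("atom table lacks columns:", paste(missing_cols, collapse = ", ")),
             "mnt_shape_error")
  if (nrow(atoms) == 0) stop_mnt("empty atom table", "mnt_shape_error")
  xyz <- as.matrix(xyz)
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop_mnt(sprintf("coordinate matrix has %d columns; expected %d (3 per atom)",
                     ncol(xyz), 3L * nrow(atoms)), "mnt_shape_error")
  if (!all(is.finite(xyz))) stop_mnt("non-finite coordinates", "mnt_shape_error")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 || frame_interval <= 0)
    stop_mnt("frame_interval must be a positive scalar (picoseconds)", "mnt_param_error")
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop_mnt(paste("duplicate (chain, residue, atom) identity:",
                   key[duplicated(key)][1]), "mnt_shape_error")
  structure(list(atoms = atoms, xyz = unname(xyz),
                 frame_interval = frame_interval, label = label,
                 selections = list()),
            class = "trajectory")
}

#' Construct a single-conformer structure
#'
#' @param atoms atom table as in [trajectory()].
#' @param coords numeric `N x 3` coordinate matrix (angstrom).
#' @param label free-text label.
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms, coords, label = "") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop_mnt("coords must be an N x 3 matrix", "mnt_shape_error")
  tr <- trajectory(atoms, matrix(t(coords), nrow = 1), frame_interval = 1, label = label)
  structure(list(atoms = tr$atoms, coords = unname(coords), label = label),
            class = "structure3d")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, %g ps/frame%s\n",
              n_frames(x), n_atoms(x), x$frame_interval,
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  invisible(x)
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d> %d atoms%s\n", nrow(x$atoms),
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj a [trajectory]
#' @return integer scalar
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(traj) nrow(traj$atoms)

#' Coordinates of one frame as an N x 3 matrix
#' @param traj a [trajectory]
#' @param frame 1-based frame index
#' @return numeric `N x 3` matrix
#' @export
frame_coords <- function(traj, frame) {
  if (frame < 1 || frame > n_frames(traj))
    stop_mnt(sprintf("frame %d out of range (1..%d)", frame, n_frames(traj)),
             "mnt_index_error")
  matrix(traj$xyz[frame, ], ncol = 3, byrow = TRUE)
}

#' Extract one frame as a structure3d
#' @inheritParams frame_coords
#' @return a [structure3d]
#' @export
as_structure <- function(traj, frame = 1) {
  structure3d(traj$atoms, frame_coords(traj, frame),
              label = sprintf("%s frame %d", traj$label, frame))
}

#' Promote a structure3d to a one-frame trajectory
#' @param struct a [structure3d]
#' @param frame_interval picoseconds per frame for the result
#' @return a [trajectory] with one frame
#' @export
as_trajectory <- function(struct, frame_interval = 100) {
  trajectory(struct$atoms, matrix(t(struct$coords), nrow = 1),
             frame_interval = frame_interval, label = struct$label)
}

# ---------------------------------------------------------------------------
# PDB reading

pdb_field <- function(lines, from, to) {
  trimws(substr(lines, from, to))
}

#' Read a (possibly multi-model) PDB file or text
#'
#' ATOM and HETATM records are parsed from fixed-width columns; HETATM metal
#' ions are retained as ordinary atoms carrying their element name. Alternate
#' locations other than blank or `'A'` are dropped; insertion-coded residues
#' are rejected. MODEL/ENDMDL blocks become trajectory frames; a file without
#' MODEL records yields a single frame. Every model must present the same
#' (chain, residue, atom) table in the same order.
#'
#' @param source path to a PDB file, or PDB text (a single string with
#'   newlines, or a character vector of lines).
#' @param frame_interval picoseconds between models (annotation only).
#' @param label label for the result; defaults to the file name.
#' @return a [trajectory]
#' @export
read_pdb_models <- function(source, frame_interval = 100, label = NULL) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(label)) label <- basename(source)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
    if (is.null(label)) label <- ""
  }
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- startsWith(rec, "MODEL")
  if (!any(is_atom)) stop_mnt("no ATOM/HETATM records found", "mnt_parse_error")

  # model id per line: 0 when no MODEL records are present
  model_id <- cumsum(is_model)
  atom_lineno <- which(is_atom)
  atom_lines <- lines[atom_lineno]
  atom_model <- model_id[atom_lineno]

  too_short <- nchar(atom_lines) < 54
  if (any(too_short))
    stop_mnt(sprintf("malformed ATOM/HETATM record at line %d (shorter than 54 columns)",
                     atom_lineno[which(too_short)[1]]), "mnt_parse_error")

  altloc <- substr(atom_lines, 17, 17)
  keep <- altloc %in% c(" ", "", "A")
  atom_lines <- atom_lines[keep]
  atom_lineno <- atom_lineno[keep]
  atom_model <- atom_model[keep]

  icode <- substr(atom_lines, 27, 27)
  if (any(icode != " " & icode != "")) {
    bad <- which(icode != " " & icode != "")[1]
    stop_mnt(sprintf("insertion-coded residue at line %d is not supported",
                     atom_lineno[bad]), "mnt_parse_error")
  }

  resno <- suppressWarnings(as.integer(pdb_field(atom_lines, 23, 26)))
  x <- suppressWarnings(as.numeric(pdb_field(atom_lines, 31, 38)))
  y <- suppressWarnings(as.numeric(pdb_field(atom_lines, 39, 46)))
  z <- suppressWarnings(as.numeric(pdb_field(atom_lines, 47, 54)))
  bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0)
    stop_mnt(sprintf("malformed ATOM/HETATM record at line %d (non-numeric field)",
                     atom_lineno[bad[1]]), "mnt_parse_error")

  ident <- paste(substr(atom_lines, 22, 22),
                 resno,
                 pdb_field(atom_lines, 18, 20),
                 pdb_field(atom_lines, 13, 16))

  models <- unique(atom_model)
  first <- atom_model == models[1]
  n_at <- sum(first)
  if (length(models) > 1) {
    for (m in models[-1]) {
      sel <- atom_model == m
      if (sum(sel) != n_at || !identical(ident[sel], ident[first]))
        stop_mnt(sprintf("model %d has a different atom table than model 1",
                         match(m, models)), "mnt_mismatch_error")
    }
  }

  f1 <- which(first)
  elem <- if (all(nchar(atom_lines[f1]) >= 78)) pdb_field(atom_lines[f1], 77, 78) else
    rep("", n_at)
  atoms <- data.frame(
    chain = substr(atom_lines[f1], 22, 22),
    resno = resno[f1],
    resname = pdb_field(atom_lines[f1], 18, 20),
    atom = pdb_field(atom_lines[f1], 13, 16),
    het = substr(atom_lines[f1], 1, 6) == "HETATM",
    element = elem,
    stringsAsFactors = FALSE
  )

  xyz <- matrix(0, nrow = length(models), ncol = 3L * n_at)
  for (k in seq_along(models)) {
    sel <- atom_model == models[k]
    xyz[k, ] <- as.vector(rbind(x[sel], y[sel], z[sel]))
  }
  trajectory(atoms, xyz, frame_interval = frame_interval, label = label)
}

# ---------------------------------------------------------------------------
# PDB writing

format_atom_name <- function(name) {
  # names shorter than 4 characters start in column 14 by PDB convention
  ifelse(nchar(name) >= 4, substr(name, 1, 4), sprintf(" %-3s", name))
}

#' Write a trajectory as a (multi-model) PDB file
#'
#' Single-frame trajectories are written without MODEL records (the
#' single-model dialect); multi-frame trajectories get one MODEL/ENDMDL block
#' per frame. Coordinates are written in the fixed 8.3 field, so round-trips
#' preserve them to three decimals.
#'
#' @param traj a [trajectory] or [structure3d]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_pdb <- function(traj, path) {
  if (inherits(traj, "structure3d")) traj <- as_trajectory(traj)
  if (any(abs(traj$xyz) >= 1e4) || any(traj$xyz <= -1e3))
    stop_mnt("coordinate not representable in the PDB 8.3 fixed-width field",
             "mnt_overflow_error")
  at <- traj$atoms
  n <- nrow(at)
  rectype <- ifelse(at$het, "HETATM", "ATOM  ")
  names4 <- format_atom_name(at$atom)
  serial <- seq_len(n)
  nf <- n_frames(traj)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    body <- sprintf("%s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    rectype, serial, names4, at$resname, at$chain, at$resno,
                    co[, 1], co[, 2], co[, 3], 1, 0,
                    formatC(at$element, width = 2))
    if (nf > 1) body <- c(sprintf("MODEL     %4d", f), body, "ENDMDL")
    writeLines(body, con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Export the atom table (with first-frame coordinates) as CSV
#' @param traj a [trajectory]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_atom_table <- function(traj, path) {
  co <- frame_coords(traj, 1)
  df <- cbind(traj$atoms, x = co[, 1], y = co[, 2], z = co[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Selections

#' Define an atom selection
#'
#' @param chains character vector of chain ids, or `"all"`.
#' @param residues integer vector of residue numbers to keep, or `NULL` for all.
#' @param atom_names character vector of PDB atom names (e.g. `"CA"`), or `"all"`.
#' @param strip_head drop this many residues from the start of each chain.
#' @param strip_tail drop this many residues from the end of each chain.
#'   Terminal stripping (the default pipeline uses 3 head / 7 tail residues)
#'   removes flexible termini that only add noise to clustering and PCA.
#' @param include_het keep HETATM records (metal ions, waters); default drops them.
#' @return an object of class `atom_selection`
#' @export
selection <- function(chains = "all", residues = NULL, atom_names = "all",
                      strip_head = 0, strip_tail = 0, include_het = FALSE) {
  if (strip_head < 0 || strip_tail < 0)
    stop_mnt("strip counts must be non-negative", "mnt_param_error")
  structure(list(chains = chains, residues = residues, atom_names = atom_names,
                 strip_head = as.integer(strip_head),
                 strip_tail = as.integer(strip_tail),
                 include_het = include_het),
            class = "atom_selection")
}

#' Apply a selection to a trajectory
#'
#' Atom order is preserved. Stripping removes the first `strip_head` and last
#' `strip_tail` residues of each (protein) chain, counted along the chain's
#' residue numbering; for a chain numbered 1..L this keeps residues
#' `strip_head+1 .. L-strip_tail`. Applying the identical selection twice is a
#' no-op: the trajectory records which selections have been applied, because
#' strip counts refer to the intact chain termini.
#'
#' @param traj a [trajectory]
#' @param sel an [selection()] object
#' @return the selected [trajectory]
#' @export
apply_selection <- function(traj, sel) {
  stopifnot(inherits(sel, "atom_selection"))
  for (prev in traj$selections) if (identical(prev, sel)) return(traj)

  at <- traj$atoms
  keep <- rep(TRUE, nrow(at))
  if (!identical(sel$chains, "all")) keep <- keep & at$chain %in% sel$chains
  if (!sel$include_het) keep <- keep & !at$het
  keep <- keep & at$element != "H" & !grepl("^[0-9]*H", at$atom)

  if (sel$strip_head > 0 || sel$strip_tail > 0) {
    for (ch in unique(at$chain[keep])) {
      in_ch <- keep & at$chain == ch
      res <- sort(unique(at$resno[in_ch]))
      L <- length(res)
      if (sel$strip_head + sel$strip_tail >= L)
        stop_mnt(sprintf("stripping %d+%d residues exhausts chain %s (length %d)",
                         sel$strip_head, sel$strip_tail, ch, L), "mnt_selection_error")
      drop_res <- c(utils::head(res, sel$strip_head),
                    utils::tail(res, sel$strip_tail))
      keep[in_ch & at$resno %in% drop_res] <- FALSE
    }
  }
  if (!is.null(sel$residues)) keep <- keep & at$resno %in% sel$residues
  if (!identical(sel$atom_names, "all")) keep <- keep & at$atom %in% sel$atom_names

  if (!any(keep)) stop_mnt("selection resolves to zero atoms", "mnt_selection_error")
  idx <- which(keep)
  cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  out <- trajectory(at[idx, , drop = FALSE], traj$xyz[, cols, drop = FALSE],
                    frame_interval = traj$frame_interval, label = traj$label)
  out$selections <- c(traj$selections, list(sel))
  out
}

# ---------------------------------------------------------------------------
# Continuous dimer numbering

#' Residue counts per chain
#' @param traj a [trajectory]
#' @param protein_only count only non-HETATM residues
#' @return named integer vector, chains in alphabetical order
#' @export
chain_lengths <- function(traj, protein_only = TRUE) {
  at <- traj$atoms
  if (protein_only) at <- at[!at$het, , drop = FALSE]
  chains <- sort(unique(at$chain))
  vapply(chains, function(ch) length(unique(at$resno[at$chain == ch])), integer(1))
}

#' Continuous residue numbering across a multi-chain assembly
#'
#' Residue `r` of the k-th chain maps to `r` plus the summed lengths of all
#' preceding chains, so for a 142-residue-per-chain homodimer residue 47 of
#' chain B is continuous residue 189. The mapping is a bijection;
#' [continuous_index_inverse()] inverts it.
#'
#' @param lengths named integer vector of per-chain residue counts, in chain
#'   order (e.g. `c(A = 142, B = 142)`), as from [chain_lengths()].
#' @param chain_id chain identifier (must name an element of `lengths`)
#' @param res_num 1-based residue number within the chain
#' @return integer continuous index
#' @export
continuous_index <- function(lengths, chain_id, res_num) {
  k <- match(chain_id, names(lengths))
  if (is.na(k)) stop_mnt(sprintf("unknown chain '%s'", chain_id), "mnt_index_error")
  if (res_num < 1 || res_num > lengths[[k]])
    stop_mnt(sprintf("residue %d outside chain %s (length %d)",
                     res_num, chain_id, lengths[[k]]), "mnt_index_error")
  offset <- if (k > 1) sum(lengths[seq_len(k - 1)]) else 0L
  as.integer(res_num + offset)
}

#' @rdname continuous_index
#' @param index continuous residue index to invert
#' @return for the inverse: list with `chain_id` and `res_num`
#' @export
continuous_index_inverse <- function(lengths, index) {
  if (index < 1 || index > sum(lengths))
    stop_mnt(sprintf("continuous index %d outside assembly (total %d)",
                     index, sum(lengths)), "mnt_index_error")
  bounds <- cumsum(lengths)
  k <- which(index <= bounds)[1]
  offset <- if (k > 1) bounds[k - 1] else 0L
  list(chain_id = names(lengths)[k], res_num = as.integer(index - offset))
}

# Internal: row index of one atom, with a descriptive error when absent.
atom_index <- function(traj, chain, resno, atom_name) {
  at <- traj$atoms
  i <- which(at$chain == chain & at$resno == resno & at$atom == atom_name)
  if (length(i) == 0)
    stop_mnt(sprintf("atom %s of residue %d in chain %s not found",
                     atom_name, resno, chain), "mnt_atom_error")
  i[1]
}

# Internal: coordinates of one atom across all frames (n_frames x 3).
atom_coords_all <- function(traj, idx) {
  traj$xyz[, c(3L * idx - 2L, 3L * idx - 1L, 3L * idx), drop = FALSE]
}
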