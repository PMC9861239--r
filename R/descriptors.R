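#' @title Geometric activation descriptors
#' @description
#' Frame-by-frame scalar descriptors of metallosensor-dimer activation. The
#' central one is the signed dihedral between the two DNA-binding helices,
#' measured on the backbone carbonyl carbons of residues 47 and 36 of each
#' chain (continuous dimer numbering 47, 36, 189, 178): metal binding locks
#' this angle, so its mean and spread separate metal-free from metal-bound
#' ensembles. Also provided: the linker-helix hinge angle (C atoms of
#' residues 64, 75, 86; vertex at 75), the inter-chain Lys41 C-alpha
#' distance, and the metal-site-2 gap between the Asp8 and Glu99 side-chain
#' carboxylates.
#' @name descriptors
NULL

#' Construct a descriptor series
#'
#' @param name descriptor name (e.g. `"dbh_dihedral"`)
#' @param values one scalar per frame
#' @param units `"degrees"` or `"angstrom"`
#' @param frame_interval picoseconds per frame, propagated from the trajectory
#' @return object of class `descriptor_series`
#' @export
descriptor_series <- function(name, values, units, frame_interval) {
  structure(list(name = name, values = as.numeric(values), units = units,
                 frame_interval = frame_interval),
            class = "descriptor_series")
}

#' @export
print.descriptor_series <- function(x, ...) {
  cat(sprintf("<descriptor_series> %s: %d frames, mean %.3f %s\n",
              x$name, length(x$values), mean(x$values), x$units))
  invisible(x)
}

#' @export
length.descriptor_series <- function(x) length(x$values)

# Default pair of protein chains (alphabetical), overridable everywhere.
dimer_chains <- function(traj, chains = NULL) {
  if (!is.null(chains)) return(chains)
  ch <- sort(unique(traj$atoms$chain[!traj$atoms$het]))
  if (length(ch) < 2)
    stop_mnt("trajectory does not contain two protein chains", "mnt_atom_error")
  ch[1:2]
}

#' Dihedral between the DNA-binding helices, per frame
#'
#' Signed torsion over the backbone carbonyl carbons of residue `res_outer`
#' of chain 1, `res_inner` of chain 1, `res_outer` of chain 2 and `res_inner`
#' of chain 2 (defaults 47 and 36 — continuous dimer numbering 47, 36, 189,
#' 178 for a 142-residue chain).
#'
#' @param traj a [trajectory]
#' @param res_outer,res_inner residue numbers on each chain's DNA-binding helix
#' @param atom atom name to use (`"C"`, the carbonyl carbon, by default;
#'   override to `"CA"` for C-alpha-only models)
#' @param chains length-2 chain ids; default the first two protein chains
#' @return a [descriptor_series()] in degrees
#' @export
dbh_dihedral_series <- function(traj, res_outer = 47L, res_inner = 36L,
                                atom = "C", chains = NULL) {
  ch <- dimer_chains(traj, chains)
  p1 <- atom_coords_all(traj, atom_index(traj, ch[1], res_outer, atom))
  p2 <- atom_coords_all(traj, atom_index(traj, ch[1], res_inner, atom))
  p3 <- atom_coords_all(traj, atom_index(traj, ch[2], res_outer, atom))
  p4 <- atom_coords_all(traj, atom_index(traj, ch[2], res_inner, atom))
  descriptor_series("dbh_dihedral", vec_dihedral(p1, p2, p3, p4),
                    "degrees", traj$frame_interval)
}

#' Linker-helix hinge angle, per frame
#'
#' Vertex angle at the backbone carbonyl carbon of `res_vertex` between those
#' of `res_a` and `res_b` (defaults 64, 75, 86). With `chain = "both"` the
#' per-frame mean over the two chains is returned.
#'
#' @inheritParams dbh_dihedral_series
#' @param chain a chain id, or `"both"` for the two-chain mean
#' @param res_a,res_vertex,res_b residue numbers defining the angle
#' @return a [descriptor_series()] in degrees
#' @export
hinge_angle_series <- function(traj, chain = "both", res_a = 64L,
                               res_vertex = 75L, res_b = 86L, atom = "C") {
  one_chain <- function(ch) {
    vec_angle(atom_coords_all(traj, atom_index(traj, ch, res_a, atom)),
              atom_coords_all(traj, atom_index(traj, ch, res_vertex, atom)),
              atom_coords_all(traj, atom_index(traj, ch, res_b, atom)))
  }
  vals <- if (identical(chain, "both")) {
    ch <- dimer_chains(traj)
    (one_chain(ch[1]) + one_chain(ch[2])) / 2
  } else one_chain(chain)
  descriptor_series("hinge_angle", vals, "degrees", traj$frame_interval)
}

#' Inter-chain C-alpha distance of a symmetric residue pair, per frame
#'
#' Euclidean distance between the C-alpha atoms of residue `res_num` in the
#' two chains (default Lys41, a classic but — for this system — insensitive
#' activation measure).
#'
#' @inheritParams dbh_dihedral_series
#' @param res_num residue number, present in both chains
#' @return a [descriptor_series()] in angstrom
#' @export
interchain_ca_distance_series <- function(traj, res_num = 41L, chains = NULL) {
  ch <- dimer_chains(traj, chains)
  a <- atom_coords_all(traj, atom_index(traj, ch[1], res_num, "CA"))
  b <- atom_coords_all(traj, atom_index(traj, ch[2], res_num, "CA"))
  descriptor_series("interchain_ca_distance", sqrt(rowdot(a - b, a - b)),
                    "angstrom", traj$frame_interval)
}

#' Metal-site-2 gap: Asp8 to Glu99 distance, per frame
#'
#' Minimum distance between the side-chain carboxylate oxygens of residue
#' `res_a` (OD1/OD2) and residue `res_b` (OE1/OE2) of one chain — the gap the
#' second metal ion (or an engineered disulfide) bridges. On models without
#' side chains the C-alpha–C-alpha distance is used instead and the series is
#' flagged (`fallback` attribute).
#'
#' @inheritParams dbh_dihedral_series
#' @param chain chain id
#' @param res_a,res_b residue numbers of the aspartate and glutamate
#' @return a [descriptor_series()] in angstrom; attribute `fallback` is TRUE
#'   when C-alpha atoms were used
#' @export
site2_gap_series <- function(traj, chain, res_a = 8L, res_b = 99L) {
  find_all <- function(resno, names) {
    at <- traj$atoms
    which(at$chain == chain & at$resno == resno & at$atom %in% names)
  }
  ia <- find_all(res_a, c("OD1", "OD2"))
  ib <- find_all(res_b, c("OE1", "OE2"))
  fallback <- FALSE
  if (length(ia) == 0 || length(ib) == 0) {
    ia <- find_all(res_a, "CA")
    ib <- find_all(res_b, "CA")
    fallback <- TRUE
    if (length(ia) == 0 || length(ib) == 0)
      stop_mnt(sprintf(
        "neither carboxylate oxygens nor CA found for residues %d/%d chain %s",
        res_a, res_b, chain), "mnt_atom_error")
  }
  nf <- n_frames(traj)
  best <- rep(Inf, nf)
  for (i in ia) for (j in ib) {
    d <- atom_coords_all(traj, i) - atom_coords_all(traj, j)
    best <- pmin(best, sqrt(rowdot(d, d)))
  }
  out <- descriptor_series("site2_gap", best, "angstrom", traj$frame_interval)
  attr(out, "fallback") <- fallback
  out
}

#' Write a descriptor series as CSV
#'
#' Columns: `frame_index` (1-based), `time_ps`, `value`, `units`.
#'
#' @param series a [descriptor_series()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_descriptor_csv <- function(series, path) {
  n <- length(series$values)
  df <- data.frame(frame_index = seq_len(n),
                   time_ps = (seq_len(n) - 1) * series$frame_interval,
                   value = series$values,
                   units = series$units)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
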