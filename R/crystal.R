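#' Calpha RMSD between two crystal structures
#'
#' Chain-matched comparison of two conformers: the i-th chain (alphabetical)
#' of one structure is paired with the i-th of the other, C-alpha atoms of
#' the residues common to both members of each pair are collected, and the
#' Kabsch-minimised RMSD over all matched atoms is returned. This is the
#' standard way to compare crystallographic conformers of the same dimer
#' solved with different bound metals (for MntR, e.g. PDB entries 2F5F, 2F5C,
#' 2EV6, 2HYF, 2HYG).
#'
#' @param a,b [structure3d]/[trajectory] objects or paths to PDB files
#' @param chains_a,chains_b chain ids to pair, in order; default all chains
#'   of `a` (alphabetical) against the first chains of `b`
#' @return list with `rmsd` (angstrom) and `n_atoms` (matched C-alpha count)
#' @export
crystal_rmsd <- function(a, b, chains_a = NULL, chains_b = NULL) {
  as_traj <- function(x) {
    if (is.character(x)) read_pdb_models(x)
    else if (inherits(x, "structure3d")) as_trajectory(x)
    else x
  }
  ta <- as_traj(a); tb <- as_traj(b)
  ca_table <- function(tr) {
    tr <- apply_selection(tr, selection(atom_names = "CA"))
    list(atoms = tr$atoms, co = frame_coords(tr, 1))
  }
  xa <- ca_table(ta); xb <- ca_table(tb)
  chains_a <- chains_a %||% sort(unique(xa$atoms$chain))
  chains_b <- chains_b %||% sort(unique(xb$atoms$chain))[seq_along(chains_a)]
  if (length(chains_a) != length(chains_b))
    stop_mnt("chain pairings must have equal length", "mnt_shape_error")
  ia <- integer(0); ib <- integer(0)
  for (k in seq_along(chains_a)) {
    ra <- xa$atoms$resno[xa$atoms$chain == chains_a[k]]
    rb <- xb$atoms$resno[xb$atoms$chain == chains_b[k]]
    common <- sort(intersect(ra, rb))
    ia <- c(ia, match(paste(chains_a[k], common),
                      paste(xa$atoms$chain, xa$atoms$resno)))
    ib <- c(ib, match(paste(chains_b[k], common),
                      paste(xb$atoms$chain, xb$atoms$resno)))
  }
  if (length(ia) < 3)
    stop_mnt("fewer than three matched C-alpha atoms", "mnt_selection_error")
  list(rmsd = kabsch(xa$co[ia, , drop = FALSE], xb$co[ib, , drop = FALSE])$rmsd,
       n_atoms = length(ia))
}
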