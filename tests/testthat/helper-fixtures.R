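# Fixtures built in code: toy atom tables, trajectories and PDB text.

toy_atoms <- function(n = 3, chain = "A") {
  data.frame(chain = chain, resno = seq_len(n), resname = "GLY",
             atom = "CA", het = FALSE, element = "C",
             stringsAsFactors = FALSE)
}

# trajectory from a list of N x 3 coordinate matrices
traj_from_frames <- function(frames, atoms = NULL, frame_interval = 100) {
  n_at <- nrow(frames[[1]])
  atoms <- if (is.null(atoms)) toy_atoms(n_at) else atoms
  xyz <- do.call(rbind, lapply(frames, function(m) as.vector(t(m))))
  trajectory(atoms, xyz, frame_interval = frame_interval)
}

random_frame <- function(n, scale = 10) matrix(runif(3 * n, -scale, scale), n, 3)

rigid_motion <- function(coords, R = NULL, t = NULL) {
  R <- if (is.null(R)) random_rotation() else R
  t <- if (is.null(t)) runif(3, -20, 20) else t
  sweep(coords %*% t(R), 2, t, `+`)
}

# Hand-written two-model PDB text: 3 CA atoms per model.
two_model_pdb_text <- function() {
  atom_line <- function(serial, name, resname, chain, resno, x, y, z, alt = " ",
                        record = "ATOM  ", element = " C") {
    sprintf("%s%5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %s",
            record, serial, paste0(" ", name), alt, resname, chain, resno, x, y, z, element)
  }
  paste(c(
    "MODEL        1",
    atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    atom_line(3, "CA", "GLY", "A", 3, 7.6, 0, 0),
    "ENDMDL",
    "MODEL        2",
    atom_line(4, "CA", "GLY", "A", 1, 0, 1, 0),
    atom_line(5, "CA", "GLY", "A", 2, 3.8, 1, 0),
    atom_line(6, "CA", "GLY", "A", 3, 7.6, 1, 0),
    "ENDMDL",
    "END"), collapse = "\n")
}
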