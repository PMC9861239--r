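#' @title Essential-dynamics PCA on Cartesian coordinates
#' @description
#' Principal component analysis of the covariance of Cartesian (typically
#' C-alpha) coordinates over trajectory frames. Frames are first superposed
#' onto an iteratively refined mean structure so that rigid-body motion does
#' not contaminate the covariance; components are collective motions, and
#' per-residue factor loadings locate the residues that carry them.
#' @name pca
NULL

# Superpose every row of a frames x 3N coordinate matrix onto the iteratively
# refined mean structure: fit all frames to the current reference, average,
# refit, until the mean moves by less than `tol` angstrom (RMS).
superpose_to_mean <- function(X, tol = 1e-6, max_iter = 100) {
  n <- nrow(X)
  fit_all <- function(X, ref_mat) {
    t(vapply(seq_len(nrow(X)), function(i) {
      as.vector(t(kabsch(matrix(X[i, ], ncol = 3, byrow = TRUE), ref_mat)$fitted))
    }, numeric(ncol(X))))
  }
  ref <- matrix(X[1, ], ncol = 3, byrow = TRUE)
  for (it in seq_len(max_iter)) {
    X <- fit_all(X, ref)
    new_ref <- matrix(colMeans(X), ncol = 3, byrow = TRUE)
    shift <- sqrt(mean((new_ref - ref)^2))
    ref <- new_ref
    if (shift < tol) break
  }
  X
}

#' Merge trajectories and superpose all frames onto their common mean
#'
#' Concatenates the frames of several trajectories (after an optional
#' selection and time window) and superposes every frame onto the iteratively
#' refined mean structure of the merged set. The default pipeline merges the
#' equilibrated windows of all systems before PCA so that one common basis
#' spans them.
#'
#' @param trajs a [trajectory] or list of trajectories sharing one atom table
#'   (after `sel`)
#' @param sel optional [selection()] applied to each trajectory
#' @param window_ns optional length-2 numeric, keep frames with time (frame
#'   index minus one times the frame interval) inside `[window_ns[1],
#'   window_ns[2]]` nanoseconds
#' @return frames x 3N coordinate matrix with attributes `labels` (source
#'   label per row) and `atoms` (the shared atom table)
#' @export
merge_and_superpose <- function(trajs, sel = NULL, window_ns = NULL) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  trajs <- lapply(trajs, function(tr) if (is.null(sel)) tr else apply_selection(tr, sel))
  ident <- function(tr) paste(tr$atoms$chain, tr$atoms$resno, tr$atoms$atom)
  id1 <- ident(trajs[[1]])
  for (tr in trajs[-1])
    if (!identical(ident(tr), id1))
      stop_mnt("trajectories have inconsistent atom tables", "mnt_mismatch_error")

  rows <- list(); labels <- character(0)
  for (tr in trajs) {
    keep <- seq_len(n_frames(tr))
    if (!is.null(window_ns)) {
      t_ns <- (keep - 1) * tr$frame_interval / 1000
      keep <- keep[t_ns >= window_ns[1] & t_ns <= window_ns[2]]
    }
    if (length(keep) > 0) {
      rows[[length(rows) + 1]] <- tr$xyz[keep, , drop = FALSE]
      labels <- c(labels, rep(tr$label, length(keep)))
    }
  }
  if (length(rows) == 0 || sum(vapply(rows, nrow, integer(1))) == 0)
    stop_mnt("time window excludes every frame", "mnt_window_error")
  X <- superpose_to_mean(do.call(rbind, rows))
  attr(X, "labels") <- labels
  attr(X, "atoms") <- trajs[[1]]$atoms
  X
}

#' Fit a PCA to a coordinate matrix
#'
#' Eigendecomposition of the sample covariance (divisor n-1) of the columns
#' of `coords`. Components are sorted by decreasing eigenvalue; tiny negative
#' eigenvalues from numerical noise are clamped to zero.
#'
#' @param coords frames x 3N coordinate matrix (already superposed)
#' @return object of class `pca_result`: `mean_coords`, `eigenvalues`
#'   (angstrom^2), `eigenvectors` (orthonormal columns), `variance_fractions`,
#'   `component_count`
#' @export
fit_pca <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2)
    stop_mnt("PCA needs at least two frames", "mnt_insufficient_data")
  mu <- colMeans(coords)
  C <- stats::cov(coords)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  total <- sum(ev)
  structure(list(
    mean_coords = mu,
    eigenvalues = ev,
    eigenvectors = e$vectors,
    variance_fractions = if (total > 0) ev / total else rep(0, length(ev)),
    component_count = length(ev),
    total_variance = total
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(3, x$component_count)
  cat(sprintf("<pca_result> %d components; variance fractions PC1..PC%d: %s\n",
              x$component_count, k,
              paste(sprintf("%.3f", x$variance_fractions[seq_len(k)]), collapse = ", ")))
  invisible(x)
}

#' Project frames onto a principal component
#'
#' @param coords frames x 3N coordinate matrix (same atom layout as the fit)
#' @param pca a `pca_result` from [fit_pca()]
#' @param component 1-based component index
#' @return numeric vector, one projection per frame
#' @export
pca_project <- function(coords, pca, component = 1) {
  coords <- as.matrix(coords)
  if (is.vector(coords)) coords <- matrix(coords, nrow = 1)
  if (component < 1 || component > pca$component_count)
    stop_mnt("component index out of range", "mnt_index_error")
  if (ncol(coords) != length(pca$mean_coords))
    stop_mnt("coordinate matrix does not match the fitted PCA", "mnt_shape_error")
  as.vector(sweep(coords, 2, pca$mean_coords) %*% pca$eigenvectors[, component])
}

#' Per-residue factor loadings of a principal component
#'
#' The loading of coordinate i on component k is
#' `v_ik * sqrt(lambda_k) / sd_i` — the correlation between the coordinate
#' and the component's projection series. Per residue (one atom per residue in
#' the usual C-alpha analysis) the Euclidean norm over the x, y, z loadings is
#' reported. Zero-variance coordinates get loading 0 and are flagged.
#'
#' @inheritParams pca_project
#' @param atoms optional atom table (as in a [trajectory]) labelling the
#'   triplets; defaults to the `atoms` attribute of `coords` if present
#' @return data.frame with `chain`, `resno` (when known), `loading`; attribute
#'   `zero_variance_flagged` marks coordinates with no variance
#' @export
residue_loadings <- function(pca, coords, component = 1, atoms = NULL) {
  coords <- as.matrix(coords)
  if (component < 1 || component > pca$component_count)
    stop_mnt("component index out of range", "mnt_index_error")
  sds <- apply(coords, 2, stats::sd)
  v <- pca$eigenvectors[, component]
  lam <- pca$eigenvalues[component]
  zero <- sds < 1e-12
  load <- numeric(length(sds))
  load[!zero] <- v[!zero] * sqrt(lam) / sds[!zero]
  m <- matrix(load, ncol = 3, byrow = TRUE)
  res_load <- sqrt(rowSums(m^2))
  atoms <- atoms %||% attr(coords, "atoms")
  out <- if (!is.null(atoms)) {
    data.frame(chain = atoms$chain, resno = atoms$resno, loading = res_load,
               stringsAsFactors = FALSE)
  } else {
    data.frame(atom_index = seq_along(res_load), loading = res_load)
  }
  attr(out, "zero_variance_flagged") <- any(zero)
  out
}

#' Export scree data (variance fractions) as JSON
#' @param pca a `pca_result`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_scree_json <- function(pca, path) {
  jsonlite::write_json(
    list(component_count = pca$component_count,
         total_variance = pca$total_variance,
         variance_fractions = pca$variance_fractions),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
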