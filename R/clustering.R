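#' @title gromos (Daura) conformational clustering
#' @description
#' Conformational clustering on a matrix of pairwise minimised RMSDs: the
#' frame with the most neighbours within the cutoff becomes a cluster
#' centroid, it and its neighbours are removed, and the step repeats until no
#' frames remain. At a fixed cutoff the number of clusters measures the size
#' of the conformational space an ensemble explores, which is how metal-free
#' and metal-bound ensembles are compared.
#' @name clustering
NULL

#' Pairwise minimised-RMSD matrix
#'
#' Every frame pair is superposed independently (Kabsch on the selected
#' atoms); entry (i, j) is the minimised RMSD. Computed in blocks of frames
#' so that centred coordinates are materialised once; memory stays linear in
#' the number of frames plus the n x n result.
#'
#' @param traj a [trajectory] with at least two frames
#' @param sel optional [selection()] (the default pipeline clusters on
#'   C-alpha atoms of the terminally stripped chains)
#' @return object of class `rmsd_matrix`: a symmetric n x n matrix (angstrom)
#'   with zero diagonal
#' @export
pairwise_rmsd_matrix <- function(traj, sel = NULL) {
  if (!is.null(sel)) traj <- apply_selection(traj, sel)
  n <- n_frames(traj)
  if (n < 2) stop_mnt("need at least two frames", "mnt_insufficient_data")
  na <- n_atoms(traj)
  if (na < 3) stop_mnt("need at least three atoms", "mnt_degenerate_error")
  # centred frames and their squared norms, computed once
  centred <- vector("list", n)
  g <- numeric(n)
  for (i in seq_len(n)) {
    m <- frame_coords(traj, i)
    m <- sweep(m, 2, colMeans(m))
    centred[[i]] <- m
    g[i] <- sum(m * m)
  }
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    Ai <- centred[[i]]
    for (j in (i + 1):n) {
      H <- crossprod(Ai, centred[[j]])
      d <- svd(H, nu = 0, nv = 0)$d
      s <- if (det(H) < 0) -1 else 1
      msd <- (g[i] + g[j] - 2 * (d[1] + d[2] + s * d[3])) / na
      out[i, j] <- out[j, i] <- sqrt(max(msd, 0))
    }
  }
  structure(out, class = c("rmsd_matrix", "matrix", "array"))
}

as_rmsd_matrix <- function(m) {
  m <- as.matrix(unclass(m))
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-6 ||
      any(diag(m) != 0) || any(m < 0))
    stop_mnt("not a valid RMSD matrix (symmetric, zero diagonal, non-negative)",
             "mnt_shape_error")
  m
}

#' gromos (Daura) clustering of an RMSD matrix
#'
#' Iteratively, the unassigned frame with the most unassigned neighbours
#' within `cutoff` (closed ball, distance <= cutoff) becomes a centroid; it
#' and its neighbours form a cluster and are removed. Ties on neighbour count
#' are broken by the lowest frame index, so results are deterministic.
#'
#' @param m an `rmsd_matrix` (or any symmetric non-negative matrix with zero
#'   diagonal)
#' @param cutoff neighbour cutoff in angstrom (the default pipeline value is
#'   1.8)
#' @return object of class `cluster_result`: `assignment` (0-based cluster id
#'   per frame, in discovery order), `centroids` (1-based frame index per
#'   cluster), `sizes`, `n_clusters`, `cutoff`
#' @export
gromos_cluster <- function(m, cutoff = 1.8) {
  m <- as_rmsd_matrix(m)
  if (cutoff <= 0) stop_mnt("cutoff must be positive", "mnt_param_error")
  n <- nrow(m)
  neighbour <- m <= cutoff       # includes self on the diagonal
  alive <- rep(TRUE, n)
  assignment <- rep(NA_integer_, n)
  centroids <- integer(0)
  cl <- 0L
  while (any(alive)) {
    counts <- colSums(neighbour[alive, , drop = FALSE])
    counts[!alive] <- -1L
    centre <- as.integer(which.max(counts))   # ties: lowest index wins
    members <- which(alive & neighbour[, centre])
    assignment[members] <- cl
    centroids <- c(centroids, centre)
    alive[members] <- FALSE
    cl <- cl + 1L
  }
  sizes <- as.integer(table(factor(assignment, levels = 0:(cl - 1L))))
  structure(list(assignment = assignment, centroids = centroids,
                 sizes = sizes, n_clusters = cl, cutoff = cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters at cutoff %.2f; sizes: %s\n",
              x$n_clusters, x$cutoff,
              paste(utils::head(x$sizes, 8), collapse = ", ")))
  invisible(x)
}

#' Centroid conformers of the k most populated clusters
#'
#' @param result a `cluster_result` from [gromos_cluster()]
#' @param traj the clustered [trajectory] (same frame order)
#' @param k how many clusters (by decreasing size; gromos discovery order is
#'   already non-increasing in size)
#' @return list of [structure3d] centroid conformers
#' @export
cluster_centroid_structures <- function(result, traj, k = 5) {
  if (k < 1 || k > result$n_clusters)
    stop_mnt(sprintf("k = %d out of range (1..%d clusters)", k, result$n_clusters),
             "mnt_index_error")
  ord <- order(result$sizes, decreasing = TRUE)[seq_len(k)]
  lapply(ord, function(cl) {
    s <- as_structure(traj, result$centroids[cl])
    s$label <- sprintf("cluster %d centroid (frame %d, size %d)",
                       cl - 1L, result$centroids[cl], result$sizes[cl])
    s
  })
}

#' Export a clustering as CSV / JSON summary
#'
#' The CSV has one row per frame (`frame`, `cluster`, `is_centroid`); the
#' JSON summary records the cutoff, cluster count and sizes.
#'
#' @param result a `cluster_result`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cluster_csv <- function(result, path) {
  n <- length(result$assignment)
  df <- data.frame(frame = seq_len(n),
                   cluster = result$assignment,
                   is_centroid = seq_len(n) %in% result$centroids)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cluster_csv
#' @export
write_cluster_json <- function(result, path) {
  jsonlite::write_json(
    list(cutoff = result$cutoff, n_clusters = result$n_clusters,
         sizes = result$sizes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
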