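test_that("merging and superposing behaves on static and duplicated input", {
  set.seed(51)
  base <- random_frame(6)
  static <- traj_from_frames(rep(list(base), 4))
  X <- merge_and_superpose(static)
  expect_equal(max(abs(sweep(X, 2, colMeans(X)))), 0, tolerance = 1e-8)
  # duplicating the input doubles rows and leaves the covariance unchanged
  tr <- traj_from_frames(lapply(1:6, function(i) base + rnorm(18, sd = 0.3)))
  X1 <- merge_and_superpose(tr)
  X2 <- merge_and_superpose(list(tr, tr))
  expect_equal(nrow(X2), 2 * nrow(X1))
  pop_cov <- function(M) cov(M) * (nrow(M) - 1) / nrow(M)
  expect_equal(unname(pop_cov(X2)), unname(pop_cov(X1)), tolerance = 1e-6)
})

test_that("superposed coordinates match an independently coded fit-to-mean loop", {
  set.seed(52)
  tr <- traj_from_frames(lapply(1:8, function(i) random_frame(5, scale = 3)))
  X <- merge_and_superpose(tr)
  ref <- oracle_fit_to_mean(tr$xyz, iters = 200)
  # the fit-to-mean fixed point is unique up to one global rotation: align
  # the oracle's mean onto the package's mean, then compare frame by frame
  fit <- kabsch(matrix(colMeans(ref), ncol = 3, byrow = TRUE),
                matrix(colMeans(X), ncol = 3, byrow = TRUE))
  aligned <- t(apply(ref, 1, function(row) {
    m <- matrix(row, ncol = 3, byrow = TRUE)
    as.vector(t(sweep(m %*% fit$rotation, 2, fit$translation, `+`)))
  }))
  # agreement is limited by the 1e-6-angstrom mean-shift stopping rule
  expect_lt(max(abs(unname(X) - unname(aligned))), 1e-3)
})

test_that("time windows select frames and reject empty windows", {
  set.seed(53)
  tr <- traj_from_frames(lapply(1:10, function(i) random_frame(4)),
                         frame_interval = 100000)  # 100 ns per frame
  X <- merge_and_superpose(tr, window_ns = c(200, 500))
  expect_equal(nrow(X), 4)   # frames at 200, 300, 400, 500 ns
  expect_error(merge_and_superpose(tr, window_ns = c(5000, 6000)),
               class = "mnt_window_error")
  # inconsistent atom tables across inputs
  other <- traj_from_frames(list(random_frame(5)))
  expect_error(merge_and_superpose(list(tr, other)), class = "mnt_mismatch_error")
})

test_that("eigenpairs agree with an independent SVD route to 1e-8", {
  set.seed(54)
  X <- matrix(rnorm(40 * 12), 40)
  p <- fit_pca(X)
  Xc <- sweep(X, 2, colMeans(X))
  s <- svd(Xc)
  expect_equal(p$eigenvalues, c(s$d^2 / (nrow(X) - 1)), tolerance = 1e-8)
  for (k in 1:3) {
    v <- s$v[, k]
    expect_equal(abs(sum(v * p$eigenvectors[, k])), 1, tolerance = 1e-8)
  }
  # invariants: orthonormal columns, fractions sum to 1, trace conserved
  expect_equal(crossprod(p$eigenvectors), diag(12), tolerance = 1e-8)
  expect_equal(sum(p$variance_fractions), 1, tolerance = 1e-8)
  expect_equal(sum(p$eigenvalues), sum(diag(cov(X))), tolerance = 1e-8)
  expect_error(fit_pca(X[1, , drop = FALSE]), class = "mnt_insufficient_data")
})

test_that("single-direction data puts all variance on PC1; isotropic noise is flat", {
  set.seed(55)
  dirv <- rnorm(9); dirv <- dirv / sqrt(sum(dirv^2))
  X <- outer(rnorm(30), dirv)
  p <- fit_pca(X)
  expect_equal(p$variance_fractions[1], 1, tolerance = 1e-10)
  expect_equal(p$variance_fractions[-1], rep(0, 8), tolerance = 1e-10)
  # isotropic jitter: eigenvalues equal within sampling error at n = 1e4
  Xi <- matrix(rnorm(10000 * 6), 10000)
  pi_ <- fit_pca(Xi)
  expect_true(all(abs(pi_$eigenvalues - 1) < 0.1))
})

test_that("projections reconstruct the centred data and vanish at the mean", {
  set.seed(56)
  X <- matrix(rnorm(25 * 9), 25)
  p <- fit_pca(X)
  expect_equal(pca_project(matrix(p$mean_coords, 1), p, 1), 0, tolerance = 1e-10)
  proj <- vapply(seq_len(p$component_count),
                 function(k) pca_project(X, p, k), numeric(25))
  rebuilt <- sweep(proj %*% t(p$eigenvectors), 2, p$mean_coords, `+`)
  expect_equal(rebuilt, X, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pca_project(X, p, 99), class = "mnt_index_error")
  expect_error(pca_project(X[, 1:6], p, 1), class = "mnt_shape_error")
})

test_that("PCA is invariant to frame order", {
  set.seed(57)
  X <- matrix(rnorm(30 * 9), 30)
  p1 <- fit_pca(X)
  p2 <- fit_pca(X[sample(30), ])
  expect_equal(p1$eigenvalues, p2$eigenvalues, tolerance = 1e-10)
  for (k in 1:3)
    expect_equal(abs(sum(p1$eigenvectors[, k] * p2$eigenvectors[, k])), 1,
                 tolerance = 1e-8)
})

test_that("loadings equal coordinate-projection correlations; zero variance flagged", {
  set.seed(58)
  X <- matrix(rnorm(50 * 12), 50)
  p <- fit_pca(X)
  proj <- pca_project(X, p, 1)
  lam <- p$eigenvalues[1]
  per_coord <- p$eigenvectors[, 1] * sqrt(lam) / apply(X, 2, sd)
  for (j in 1:12)
    expect_equal(per_coord[j], cor(X[, j], proj), tolerance = 1e-8)
  ld <- residue_loadings(p, X, 1)
  expect_equal(ld$loading,
               sqrt(rowSums(matrix(per_coord, ncol = 3, byrow = TRUE)^2)),
               tolerance = 1e-8)
  expect_false(attr(ld, "zero_variance_flagged"))
  # a frozen coordinate gets loading 0 and raises the flag
  X0 <- X; X0[, 4] <- 5
  p0 <- fit_pca(X0)
  ld0 <- residue_loadings(p0, X0, 1)
  expect_true(attr(ld0, "zero_variance_flagged"))
  # single moving coordinate carries the whole loading mass
  X1 <- matrix(0, 20, 9); X1[, 2] <- rnorm(20)
  X1 <- X1 + matrix(rep(rnorm(9), each = 20), 20)   # static offsets
  p1 <- fit_pca(X1)
  ld1 <- residue_loadings(p1, X1, 1)
  expect_equal(ld1$loading, c(1, 0, 0), tolerance = 1e-8)
})

test_that("PC1 separates apo-like and metal-locked synthetic states", {
  sel <- selection(atom_names = "CA", strip_head = 3, strip_tail = 7)
  X <- merge_and_superpose(list(generate_ensemble(preset_params("apo", 60, 5)),
                                generate_ensemble(preset_params("mn", 60, 6))),
                           sel = sel)
  p <- fit_pca(X)
  proj <- pca_project(X, p, 1)
  expect_gt(pooled_sd_separation(proj, attr(X, "labels")), 2)
  # the heaviest PC1 loadings sit in the DNA-binding helix (residues 36-50)
  ld <- residue_loadings(p, X, 1, atoms = attr(X, "atoms"))
  top <- ld[order(-ld$loading)[1:10], ]
  expect_true(all(top$resno >= 36 & top$resno <= 50))
})
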