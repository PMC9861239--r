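# Independent oracle implementations, coded along different routes than the
# package functions they cross-check.

# Torsion via the two-plane acos formula with an explicit sign term
# (the package uses the atan2 form).
oracle_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  phi <- acos(pmin(1, pmax(-1, cosphi))) * 180 / pi
  if (sum(n1 * b3) < 0) phi <- -phi
  phi
}

# Uniform random rotation matrix from a random quaternion.
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Best RMSD over `k` sampled rotations (after centering both sets), optionally
# refined by Nelder-Mead on an axis-angle parameterisation.
oracle_rotation_search <- function(mobile, reference, k = 2000, refine = FALSE) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  rms_for <- function(R) sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  best <- Inf; bestR <- diag(3)
  for (i in seq_len(k)) {
    R <- random_rotation()
    v <- rms_for(R)
    if (v < best) { best <- v; bestR <- R }
  }
  if (refine) {
    rot_vec <- function(w) {
      th <- sqrt(sum(w^2))
      if (th < 1e-12) return(diag(3))
      u <- w / th
      K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
      diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    }
    res <- optim(c(0, 0, 0), function(w) rms_for(rot_vec(w) %*% bestR),
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))
    best <- res$value
  }
  best
}

# Literal re-execution of the Daura neighbour-count clustering with explicit
# loops, independent of the package's vectorised version.
oracle_gromos <- function(m, cutoff) {
  n <- nrow(m)
  remaining <- seq_len(n)
  assignment <- rep(NA_integer_, n)
  centroids <- integer(0)
  cl <- 0L
  while (length(remaining) > 0) {
    best_count <- -1L; best_frame <- NA_integer_
    for (i in remaining) {
      count <- 0L
      for (j in remaining) if (m[i, j] <= cutoff) count <- count + 1L
      if (count > best_count) { best_count <- count; best_frame <- i }
    }
    members <- integer(0)
    for (j in remaining) if (m[best_frame, j] <= cutoff) members <- c(members, j)
    assignment[members] <- cl
    centroids <- c(centroids, best_frame)
    remaining <- setdiff(remaining, members)
    cl <- cl + 1L
  }
  list(assignment = assignment, centroids = centroids)
}

# Two-pass iterative fit-to-mean superposition using bio3d's least-squares
# rotation as the independent engine.
oracle_fit_to_mean <- function(X, iters = 30) {
  fit_one <- function(row, ref) {
    m <- matrix(row, ncol = 3, byrow = TRUE)
    r <- matrix(ref, ncol = 3, byrow = TRUE)
    mc <- sweep(m, 2, colMeans(m)); rc <- sweep(r, 2, colMeans(r))
    H <- t(mc) %*% rc
    s <- svd(H)
    R <- s$u %*% diag(c(1, 1, sign(det(s$v %*% t(s$u))))) %*% t(s$v)
    as.vector(t(sweep(mc %*% R, 2, colMeans(r), `+`)))
  }
  ref <- X[1, ]
  for (it in seq_len(iters)) {
    X <- t(apply(X, 1, fit_one, ref = ref))
    ref <- colMeans(X)
  }
  X
}

pooled_sd_separation <- function(x, g) {
  gs <- unique(g)
  a <- x[g == gs[1]]; b <- x[g == gs[2]]
  abs(mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
}
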