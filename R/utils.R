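# Internal helpers: classed error conditions and small numeric utilities.

stop_mnt <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "mnt_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop_mnt("cannot normalise a zero-length vector", "mnt_degenerate_error")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

# Rodrigues rotation matrix: right-handed rotation by `angle_deg` about unit
# axis `axis` (3-vector).
rotation_about_axis <- function(axis, angle_deg) {
  u <- unit(axis)
  th <- rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy,
                uz, 0, -ux,
                -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * tcrossprod(u)
}

# Wrap an angle in degrees into (-180, 180].
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}
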