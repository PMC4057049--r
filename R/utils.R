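# Small numeric helpers shared across the package.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

norm3 <- function(x) sqrt(sum(x^2))

unit3 <- function(x) {
  n <- norm3(x)
  if (n == 0) stop("cannot normalize a zero vector")
  x / n
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

# Reciprocity pairing matrix: vc(p, q) = t(S_p) %*% .delta6 %*% S_q for
# unit-screw 6-vectors S = c(d, m).
.delta6 <- rbind(cbind(matrix(0, 3, 3), diag(3)),
                 cbind(diag(3), matrix(0, 3, 3)))

# Minimum-norm least-squares solve via SVD with a relative rank cutoff.
pinv_solve <- function(A, b, rtol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rtol * max(sv$d, 0)
  if (!any(keep)) return(rep(0, ncol(A)))
  x <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
  drop(x)
}

# Orthonormal basis of the nullspace of A (rows are constraints).
nullspace_basis <- function(A, rtol = 1e-10) {
  n <- ncol(A)
  sv <- svd(A, nu = 0, nv = n)
  smax <- if (length(sv$d)) max(sv$d) else 0
  r <- sum(sv$d > rtol * smax)
  if (r >= n) return(matrix(0, n, 0))
  sv$v[, seq(r + 1, n), drop = FALSE]
}

mat_rank <- function(A, rtol = 1e-10) {
  d <- svd(A, nu = 0, nv = 0)$d
  if (!length(d)) return(0L)
  sum(d > rtol * max(d))
}

# Rotation about a unit axis by angle (Rodrigues).
rot_axis_angle <- function(axis, angle) {
  u <- unit3(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Rotation-vector logarithm of a proper rotation matrix, robust near 0 and pi.
so3_log <- function(R) {
  tr <- clamp1((sum(diag(R)) - 1) / 2)
  theta <- acos(tr)
  if (theta < 1e-12) return(c(0, 0, 0))
  if (theta < pi - 1e-6) {
    w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    return(theta / (2 * sin(theta)) * w)
  }
  # near pi: use the symmetric part
  B <- (R + diag(3)) / 2
  u <- sqrt(pmax(diag(B), 0))
  i <- which.max(u)
  u <- B[, i] / u[i]
  u <- unit3(u)
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sum(w * u) < 0) u <- -u
  theta * u
}

is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

abort_input <- function(msg, class = "screwgait_error_invalid_input") {
  rlang::abort(msg, class = class)
}
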