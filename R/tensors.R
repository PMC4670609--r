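# ---------------------------------------------------------------------------
# Small dense 3x3 tensor algebra.
#
# All second-order tensors are plain 3x3 numeric matrices expressed in one
# fixed global Cartesian frame. Fiber-frame quantities are obtained by
# explicit rotation with the frame matrix Q = [f0 | s0 | n0], never by
# implicit local storage.
# ---------------------------------------------------------------------------

I3 <- diag(3)

#' Closed-form inverse of a 3x3 tensor
#'
#' Inverts via the adjugate with an explicit determinant pivot check, which is
#' faster and fully deterministic at this size compared to LU factorization.
#'
#' @param A 3x3 numeric matrix.
#' @param tol determinant magnitude below which the tensor is treated as
#'   singular (default `1e-14`).
#' @return The 3x3 inverse.
#' @keywords internal
tensor_inverse <- function(A, tol = 1e-14) {
  d <- tensor_det(A)
  if (!is.finite(d) || abs(d) < tol) {
    stop("invalid-growth-state: singular tensor (|det| < ", tol, ")")
  }
  adj <- matrix(c(
    A[2, 2] * A[3, 3] - A[2, 3] * A[3, 2],
    A[2, 3] * A[3, 1] - A[2, 1] * A[3, 3],
    A[2, 1] * A[3, 2] - A[2, 2] * A[3, 1],
    A[1, 3] * A[3, 2] - A[1, 2] * A[3, 3],
    A[1, 1] * A[3, 3] - A[1, 3] * A[3, 1],
    A[1, 2] * A[3, 1] - A[1, 1] * A[3, 2],
    A[1, 2] * A[2, 3] - A[1, 3] * A[2, 2],
    A[1, 3] * A[2, 1] - A[1, 1] * A[2, 3],
    A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]), 3, 3)
  adj / d
}

#' Determinant of a 3x3 tensor (closed form)
#' @param A 3x3 numeric matrix.
#' @return Scalar determinant.
#' @keywords internal
tensor_det <- function(A) {
  A[1, 1] * (A[2, 2] * A[3, 3] - A[2, 3] * A[3, 2]) -
  A[1, 2] * (A[2, 1] * A[3, 3] - A[2, 3] * A[3, 1]) +
  A[1, 3] * (A[2, 1] * A[3, 2] - A[2, 2] * A[3, 1])
}

# ---------------------------------------------------------------------------
# Batched tensor algebra for the element loops.
#
# A batch of m tensors is an m x 9 matrix whose columns hold the components in
# column-major order: (11, 21, 31, 12, 22, 32, 13, 23, 33). Index helper:
# component (i, j) lives in column i + 3*(j-1).
# ---------------------------------------------------------------------------

#' @keywords internal
bcol <- function(i, j) i + 3L * (j - 1L)

# batch C = A %*% B for m x 9 matrices
#' @keywords internal
bmm <- function(A, B) {
  C <- matrix(0, nrow(A), 9L)
  for (i in 1:3) for (j in 1:3) {
    cc <- bcol(i, j)
    C[, cc] <- A[, bcol(i, 1L)] * B[, bcol(1L, j)] +
               A[, bcol(i, 2L)] * B[, bcol(2L, j)] +
               A[, bcol(i, 3L)] * B[, bcol(3L, j)]
  }
  C
}

# batch transpose
#' @keywords internal
bt <- function(A) A[, c(1L, 4L, 7L, 2L, 5L, 8L, 3L, 6L, 9L), drop = FALSE]

# batch determinant
#' @keywords internal
bdet <- function(A) {
  A[, 1L] * (A[, 5L] * A[, 9L] - A[, 8L] * A[, 6L]) -
  A[, 4L] * (A[, 2L] * A[, 9L] - A[, 8L] * A[, 3L]) +
  A[, 7L] * (A[, 2L] * A[, 6L] - A[, 5L] * A[, 3L])
}

# batch inverse via adjugate; d may be supplied to skip recomputation
#' @keywords internal
binv <- function(A, d = NULL) {
  if (is.null(d)) d <- bdet(A)
  Ai <- matrix(0, nrow(A), 9L)
  Ai[, 1L] <- (A[, 5L] * A[, 9L] - A[, 8L] * A[, 6L]) / d
  Ai[, 2L] <- (A[, 8L] * A[, 3L] - A[, 2L] * A[, 9L]) / d
  Ai[, 3L] <- (A[, 2L] * A[, 6L] - A[, 5L] * A[, 3L]) / d
  Ai[, 4L] <- (A[, 7L] * A[, 6L] - A[, 4L] * A[, 9L]) / d
  Ai[, 5L] <- (A[, 1L] * A[, 9L] - A[, 7L] * A[, 3L]) / d
  Ai[, 6L] <- (A[, 4L] * A[, 3L] - A[, 1L] * A[, 6L]) / d
  Ai[, 7L] <- (A[, 4L] * A[, 8L] - A[, 7L] * A[, 5L]) / d
  Ai[, 8L] <- (A[, 7L] * A[, 2L] - A[, 1L] * A[, 8L]) / d
  Ai[, 9L] <- (A[, 1L] * A[, 5L] - A[, 4L] * A[, 2L]) / d
  Ai
}

# batch A : B (double contraction, sum over all 9 components)
#' @keywords internal
bddot <- function(A, B) rowSums(A * B)

# batch identity
#' @keywords internal
bident <- function(m) {
  A <- matrix(0, m, 9L)
  A[, c(1L, 5L, 9L)] <- 1
  A
}

# batch v (m x 3) outer product a %o% b -> m x 9
#' @keywords internal
bouter <- function(a, b) {
  cbind(a[, 1L] * b[, 1L], a[, 2L] * b[, 1L], a[, 3L] * b[, 1L],
        a[, 1L] * b[, 2L], a[, 2L] * b[, 2L], a[, 3L] * b[, 2L],
        a[, 1L] * b[, 3L], a[, 2L] * b[, 3L], a[, 3L] * b[, 3L])
}

# batch matrix-vector product A (m x 9) times v (m x 3)
#' @keywords internal
bmv <- function(A, v) {
  cbind(A[, 1L] * v[, 1L] + A[, 4L] * v[, 2L] + A[, 7L] * v[, 3L],
        A[, 2L] * v[, 1L] + A[, 5L] * v[, 2L] + A[, 8L] * v[, 3L],
        A[, 3L] * v[, 1L] + A[, 6L] * v[, 2L] + A[, 9L] * v[, 3L])
}
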