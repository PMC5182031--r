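# Internal geometry and interpolation helpers shared across modules.

#' @keywords internal
#' @noRd
as_shape3 <- function(shape) {
  shape <- as.integer(shape)
  if (length(shape) == 2L) shape <- c(shape, 1L)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be 2 or 3 positive integers")
  shape
}

# voxel index (1-based, n x 3) -> physical mm position via 4x4 affine
#' @keywords internal
#' @noRd
voxel_to_physical <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3L)
  # affine maps 0-based voxel indices, the NIfTI convention
  xyz <- cbind(ijk - 1, 1) %*% t(affine[1:3, , drop = FALSE])
  xyz
}

# physical mm -> continuous 1-based voxel coordinate
#' @keywords internal
#' @noRd
physical_to_voxel <- function(xyz, affine) {
  xyz <- matrix(xyz, ncol = 3L)
  inv <- solve(affine)
  cbind(xyz, 1) %*% t(inv[1:3, , drop = FALSE]) + 1
}

# grid of all voxel centres in physical coordinates: (nx*ny*nz) x 3,
# fastest-varying x (R column-major array order)
#' @keywords internal
#' @noRd
grid_physical <- function(shape, affine) {
  shape <- as_shape3(shape)
  ijk <- as.matrix(expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                               k = seq_len(shape[3])))
  voxel_to_physical(ijk, affine)
}

#' @keywords internal
#' @noRd
linear_index <- function(ijk, shape) {
  ijk <- matrix(as.integer(ijk), ncol = 3L)
  1L + (ijk[, 1] - 1L) + (ijk[, 2] - 1L) * shape[1] +
    (ijk[, 3] - 1L) * shape[1] * shape[2]
}

# trilinear interpolation of a 3D array at continuous 1-based voxel coords
# (n x 3); outside the grid the field is treated as `outside` (default 0)
#' @keywords internal
#' @noRd
interp_trilinear <- function(arr, vox, outside = 0) {
  shape <- dim(arr)
  vox <- matrix(vox, ncol = 3L)
  n <- nrow(vox)
  out <- numeric(n)
  i0 <- floor(vox)
  fr <- vox - i0
  # clamp singleton axes: treat as constant along them
  for (a in 1:3) {
    if (shape[a] == 1L) { i0[, a] <- 1; fr[, a] <- 0 }
  }
  val <- function(ii, jj, kk) {
    inside <- ii >= 1 & ii <= shape[1] & jj >= 1 & jj <= shape[2] &
      kk >= 1 & kk <= shape[3]
    v <- rep(outside, n)
    if (any(inside))
      v[inside] <- arr[cbind(ii[inside], jj[inside], kk[inside])]
    v
  }
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di == 1) fr[, 1] else 1 - fr[, 1]) *
         (if (dj == 1) fr[, 2] else 1 - fr[, 2]) *
         (if (dk == 1) fr[, 3] else 1 - fr[, 3])
    if (all(w == 0)) next
    out <- out + w * val(i0[, 1] + di, i0[, 2] + dj, i0[, 3] + dk)
  }
  out
}

# separable Gaussian smoothing of a 3D array, sigma in voxels per axis,
# reflective (mirror) boundary handling; singleton axes untouched
#' @keywords internal
#' @noRd
gaussian_smooth3 <- function(arr, sigma) {
  shape <- dim(arr)
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  for (axis in 1:3) {
    s <- sigma[axis]
    if (s <= 0 || shape[axis] == 1L) next
    r <- max(1L, ceiling(4 * s))
    kern <- exp(-0.5 * ((-r:r) / s)^2)
    kern <- kern / sum(kern)
    arr <- aperm_convolve(arr, axis, kern, r)
  }
  arr
}

# convolve along one axis with mirror padding
#' @keywords internal
#' @noRd
aperm_convolve <- function(arr, axis, kern, r) {
  shape <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  n <- d[1]
  m <- matrix(a, nrow = n)
  # mirror pad (reflect about the edge sample, "symmetric" style)
  idx_top <- rev(seq_len(r)) + 1L; idx_top[idx_top > n] <- n
  idx_bot <- n - seq_len(r); idx_bot[idx_bot < 1L] <- 1L
  padded <- rbind(m[idx_top, , drop = FALSE], m, m[idx_bot, , drop = FALSE])
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (t in seq_along(kern)) {
    out <- out + kern[t] * padded[(t - 1L) + seq_len(n), , drop = FALSE]
  }
  a <- array(out, dim = d)
  aperm(a, order(perm))
}

# all permutations of 1..n as a list (used for exhaustive permutation tests)
#' @keywords internal
#' @noRd
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 1L
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[idx]] <- append(p, n, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}
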