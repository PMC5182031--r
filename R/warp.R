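# Deformation-field algebra.
#
# A deformation field stores, for every template voxel, the corresponding
# physical position (mm) in subject space — the pull-back convention: the
# warp maps template to subject. A displacement field stores the offset
# from each voxel's own physical position. The Jacobian of a deformation
# field is its spatial derivative in physical coordinates; at each voxel it
# is the local affine approximation of the non-linear warp.

#' Deformation and displacement fields
#'
#' @param positions 4D array (nx, ny, nz, 3) of corresponding physical
#'   positions (mm); a 3D array (nx, ny, 3) is accepted for 2D grids.
#' @param affine 4x4 voxel-to-physical matrix of the grid the field lives
#'   on (the template grid).
#' @return An object of class \code{deformation_field} (or
#'   \code{displacement_field}).
#' @export
deformation_field <- function(positions, affine = diag(4)) {
  positions <- vec_field_4d(positions)
  structure(list(shape = dim(positions)[1:3], affine = affine,
                 positions = positions),
            class = "deformation_field")
}

#' @rdname deformation_field
#' @param displacements 4D array (nx, ny, nz, 3) of per-voxel offset
#'   vectors (mm).
#' @export
displacement_field <- function(displacements, affine = diag(4)) {
  displacements <- vec_field_4d(displacements)
  structure(list(shape = dim(displacements)[1:3], affine = affine,
                 displacements = displacements),
            class = "displacement_field")
}

#' @keywords internal
#' @noRd
vec_field_4d <- function(x) {
  d <- dim(x)
  if (length(d) == 3L && d[3] %in% c(2L, 3L)) {
    v <- array(0, dim = c(d[1], d[2], 1L, 3L))
    v[, , 1, seq_len(d[3])] <- x
    x <- v
    d <- dim(x)
  }
  if (length(d) != 4L || d[4] != 3L)
    stop("vector field must be (nx, ny, nz, 3); 2D fields may drop the ",
         "singleton z and third component")
  if (any(!is.finite(x))) stop("vector field contains non-finite values")
  x
}

#' Convert between displacement and deformation fields
#'
#' A deformation field's positions are the grid's own physical voxel
#' positions plus the displacement; the two representations are equivalent
#' and round-trip exactly.
#'
#' @param d A \code{displacement_field}.
#' @return \code{displacement_to_deformation} returns a
#'   \code{deformation_field}; \code{deformation_to_displacement} the
#'   reverse.
#' @export
displacement_to_deformation <- function(d) {
  stopifnot(inherits(d, "displacement_field"))
  base <- grid_positions_array(d$shape, d$affine)
  deformation_field(base + d$displacements, d$affine)
}

#' @rdname displacement_to_deformation
#' @param def A \code{deformation_field}.
#' @export
deformation_to_displacement <- function(def) {
  stopifnot(inherits(def, "deformation_field"))
  base <- grid_positions_array(def$shape, def$affine)
  displacement_field(def$positions - base, def$affine)
}

#' @keywords internal
#' @noRd
grid_positions_array <- function(shape, affine) {
  array(grid_physical(shape, affine), dim = c(shape, 3L))
}

#' Read a warp field from NIfTI
#'
#' @param file 4D NIfTI 3-vector volume.
#' @param kind \code{"deformation"} (absolute mm positions) or
#'   \code{"displacement"} (per-voxel offsets).
#' @return A \code{deformation_field} or \code{displacement_field}.
#' @export
read_warp <- function(file, kind = c("deformation", "displacement")) {
  kind <- match.arg(kind)
  img <- read_nifti_image(file)
  if (kind == "deformation") deformation_field(img$data, img$affine)
  else displacement_field(img$data, img$affine)
}

#' Jacobian field of a deformation
#'
#' Differentiates the deformation field in physical (mm) coordinates:
#' central finite differences in the grid interior, one-sided at the
#' boundaries, composed with the inverse of the affine's linear part so
#' anisotropic voxels are handled. Finite differences of a linear
#' (affine) deformation are exact everywhere. Singleton axes (the z axis of
#' a 2D grid) contribute an identity row and column.
#'
#' @param def A \code{deformation_field}.
#' @return An object of class \code{jacobian_field} with field \code{J}, a
#'   4D-indexed set of per-voxel 3x3 matrices (\code{J[i, j, k, , ]}).
#' @examples
#' d <- displacement_field(array(0, c(4, 4, 2, 3)))
#' jf <- jacobian(displacement_to_deformation(d))
#' all(jf$J[2, 2, 1, , ] == diag(3))
#' @export
jacobian <- function(def) {
  stopifnot(inherits(def, "deformation_field"))
  shape <- def$shape
  pos <- def$positions
  nvox <- prod(shape)
  Ainv <- solve(def$affine[1:3, 1:3])
  singleton <- shape == 1L
  # dpos/dindex by finite differences along each axis: nvox x comp x axis
  Jidx <- array(0, dim = c(nvox, 3L, 3L))
  for (axis in 1:3) {
    if (singleton[axis]) next
    n <- shape[axis]
    lo <- pmax(1L, seq_len(n) - 1L)
    hi <- pmin(n, seq_len(n) + 1L)
    denom <- hi - lo
    d <- sweep_diff(pos, axis, lo, hi, denom)
    Jidx[, , axis] <- matrix(d, nrow = nvox, ncol = 3L)
  }
  # compose with voxel->mm inverse: dpos/dmm = dpos/dindex %*% dindex/dmm
  Jout <- array(0, dim = c(nvox, 3L, 3L))
  for (comp in 1:3) for (mmax in 1:3) {
    acc <- numeric(nvox)
    for (axis in 1:3) {
      if (singleton[axis]) next
      acc <- acc + Jidx[, comp, axis] * Ainv[axis, mmax]
    }
    Jout[, comp, mmax] <- acc
  }
  # singleton axes contribute an identity row and column
  for (axis in which(singleton)) {
    Jout[, axis, ] <- 0
    Jout[, , axis] <- 0
    Jout[, axis, axis] <- 1
  }
  structure(list(shape = shape, affine = def$affine,
                 J = array(Jout, dim = c(shape, 3L, 3L))),
            class = "jacobian_field")
}

# finite difference of the position field along one axis (in index units)
#' @keywords internal
#' @noRd
sweep_diff <- function(pos, axis, lo, hi, denom) {
  d <- dim(pos)
  out <- array(0, dim = d)
  sel <- function(s) {
    switch(axis,
           pos[s, , , , drop = FALSE],
           pos[, s, , , drop = FALSE],
           pos[, , s, , drop = FALSE])
  }
  num <- sel(hi) - sel(lo)
  # divide by the index span (2 interior, 1 at boundaries)
  den <- array(1, dim = d)
  if (axis == 1L) den[] <- denom[slice.index(den, 1)]
  if (axis == 2L) den[] <- denom[slice.index(den, 2)]
  if (axis == 3L) den[] <- denom[slice.index(den, 3)]
  num / den
}

#' Per-voxel Jacobian determinant
#'
#' @param jf A \code{jacobian_field}.
#' @return 3D array of determinants.
#' @export
jacobian_determinant <- function(jf) {
  stopifnot(inherits(jf, "jacobian_field"))
  J <- array(jf$J, dim = c(prod(jf$shape), 3L, 3L))
  d <- J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
    J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
    J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
  array(d, dim = jf$shape)
}
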