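# Fixel reorientation and fibre-bundle cross-section (FC).
#
# For a warp that maps template positions to subject positions (pull-back),
# the local affine behaviour at a voxel is its Jacobian J. A fixel with
# axial direction v transforms as v' = Jv/|Jv|. The Jacobian determinant is
# the local volume-change factor; dividing out the stretch along the fibre
# direction leaves the area change of the plane perpendicular to the fibre:
#
#   FC = det(J) / |J v|
#
# FC > 1 means the encompassing bundle has a larger cross-section in
# subject space than in the template; FC < 1 a smaller one.

#' Reorient a fixel direction through a local affine
#'
#' @param v Unit 3-vector (axial fixel direction).
#' @param J 3x3 Jacobian (local affine) matrix.
#' @return The reoriented unit vector \code{J v / |J v|}.
#' @examples
#' reorient_fixel(c(1, 0, 0), diag(3))
#' @export
reorient_fixel <- function(v, J) {
  w <- drop(J %*% v)
  n <- sqrt(sum(w^2))
  if (!is.finite(n) || n <= 1e-12)
    stop("degenerate warp: Jacobian collapses the fixel direction")
  w / n
}

#' Fibre-bundle cross-section from a local Jacobian
#'
#' The relative change in cross-sectional area perpendicular to the fibre
#' direction: the overall volume change \code{det(J)} with the stretch
#' along the fibre \code{|J v|} factored out.
#'
#' @param v Unit 3-vector (fixel direction in template space).
#' @param J 3x3 Jacobian matrix of the template-to-subject warp; must be
#'   orientation-preserving (\code{det(J) > 0}).
#' @return FC, a positive dimensionless scalar.
#' @examples
#' fibre_cross_section(c(1, 0, 0), diag(c(1, 2, 3)))  # 6
#' @export
fibre_cross_section <- function(v, J) {
  dj <- det(J)
  if (!is.finite(dj) || dj <= 0)
    stop("folded warp: Jacobian determinant is not positive (det = ",
         format(dj), ")")
  n <- sqrt(sum((J %*% v)^2))
  if (n <= 1e-12)
    stop("degenerate warp: Jacobian collapses the fixel direction")
  dj / n
}

#' Cross-section by frame decomposition (test oracle)
#'
#' Computes FC by the tensor-based-morphometry decomposition route: build
#' an orthonormal frame whose first axis is the fibre direction
#' (Gram-Schmidt), express the warp in that frame, and triangularise it
#' (QR); the product of the trailing diagonal entries is the area change of
#' the perpendicular plane. Algebraically identical to
#' \code{\link{fibre_cross_section}} but computed along an independent
#' numerical path; retained as a cross-check oracle.
#'
#' @inheritParams fibre_cross_section
#' @return FC.
#' @export
fc_gram_schmidt_oracle <- function(v, J) {
  dj <- det(J)
  if (!is.finite(dj) || dj <= 0)
    stop("folded warp: Jacobian determinant is not positive")
  # Gram-Schmidt frame with first axis v
  e1 <- v / sqrt(sum(v^2))
  a <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- a - sum(a * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  M <- J %*% matrix(c(e1, e2, e3), 3L, 3L)
  R <- qr.R(qr(M))
  # |r22 * r33|: the area scaling of the plane perpendicular to v
  unname(abs(R[2, 2] * R[3, 3]))
}

#' Combine fibre density and cross-section
#'
#' Elementwise modulation \code{FDC = FD * FC}: weighting the microscopic
#' within-voxel density by the macroscopic cross-section change preserves
#' the total intra-axonal cross-sectional content of a bundle under spatial
#' normalisation.
#'
#' @param fd Per-fixel fibre density values.
#' @param fc Per-fixel cross-section values (positive).
#' @return Per-fixel FDC.
#' @export
modulate_fdc <- function(fd, fc) {
  if (length(fd) != length(fc))
    stop("fd and fc must have equal length (", length(fd), " vs ",
         length(fc), ")")
  if (any(fc <= 0)) stop("fc values must be positive")
  fd * fc
}

#' FC for every fixel of a template grid
#'
#' Computes the fibre-bundle cross-section of each template fixel from the
#' Jacobian of the supplied template-to-subject warp at the fixel's voxel.
#'
#' @param template A \code{\link{fixel_grid}} (the template fixel mask).
#' @param warp A \code{deformation_field} on the template grid.
#' @return The grid with an added/replaced value \code{"fc"}.
#' @export
fc_fixel_map <- function(template, warp) {
  stopifnot(inherits(template, "fixel_grid"),
            inherits(warp, "deformation_field"))
  if (!all(template$shape == warp$shape))
    stop("geometry error: warp grid ", paste(warp$shape, collapse = "x"),
         " does not match template ", paste(template$shape, collapse = "x"))
  jf <- jacobian(warp)
  nf <- n_fixels(template)
  fc <- numeric(nf)
  occupied <- which(as.vector(template$counts) > 0L)
  dets <- jacobian_determinant(jf)
  bad <- occupied[dets[occupied] <= 0]
  if (length(bad))
    stop("folded warp: non-positive Jacobian determinant at in-mask ",
         "voxel(s) ", paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  Jmat <- matrix(jf$J, nrow = prod(jf$shape), ncol = 9L)
  for (li in occupied) {
    J <- matrix(Jmat[li, ], 3L, 3L)
    for (fi in fixel_range(template, li))
      fc[fi] <- fibre_cross_section(template$directions[fi, ], J)
  }
  fixel_values(template, "fc") <- fc
  template
}
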