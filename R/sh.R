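# Real even-order spherical harmonics.
#
# Basis convention (documented so coefficients from standard CSD outputs
# load correctly): real, orthonormal, even degrees l = 0, 2, ..., lmax;
# within each degree, orders m = -l..l with
#   m < 0  ->  sqrt(2) * N_l|m| * P_l^|m|(cos theta) * sin(|m| phi)
#   m = 0  ->  N_l0    * P_l^0 (cos theta)
#   m > 0  ->  sqrt(2) * N_lm  * P_l^m (cos theta) * cos(m phi)
# with N_lm = sqrt((2l+1)/(4 pi) * (l-m)!/(l+m)!) and associated Legendre
# functions including the Condon-Shortley phase (pracma::legendre,
# MATLAB-compatible). Coefficients are stored in that (l, m) order.

#' Number of even-order SH coefficients
#'
#' @param lmax Even non-negative integer.
#' @return \code{(lmax+1)(lmax+2)/2}.
#' @export
sh_ncoef <- function(lmax) {
  stopifnot(lmax >= 0, lmax %% 2 == 0)
  as.integer((lmax + 1) * (lmax + 2) / 2)
}

#' @rdname sh_ncoef
#' @param ncoef Coefficient count.
#' @return \code{sh_lmax} returns the even lmax for a coefficient count, or
#'   errors if the count does not correspond to one.
#' @export
sh_lmax <- function(ncoef) {
  lmax <- (sqrt(8 * ncoef + 1) - 3) / 2
  if (abs(lmax - round(lmax)) > 1e-8 || round(lmax) %% 2 != 0)
    stop("coefficient count ", ncoef,
         " does not correspond to an even-order SH series")
  as.integer(round(lmax))
}

#' Evaluate the real even-order SH basis
#'
#' @param dirs n x 3 matrix of unit direction vectors.
#' @param lmax Even maximum harmonic degree.
#' @return n x \code{sh_ncoef(lmax)} basis matrix; amplitudes are
#'   \code{basis \%*\% coeffs}.
#' @export
sh_basis <- function(dirs, lmax) {
  dirs <- matrix(dirs, ncol = 3L)
  n <- nrow(dirs)
  ct <- pmin(1, pmax(-1, dirs[, 3]))           # cos(theta)
  phi <- atan2(dirs[, 2], dirs[, 1])
  B <- matrix(0, nrow = n, ncol = sh_ncoef(lmax))
  col <- 1L
  for (l in seq(0, lmax, by = 2)) {
    P <- pracma::legendre(l, ct)               # (l+1) x n, rows m = 0..l
    if (l == 0) P <- matrix(P, nrow = 1)
    for (m in -l:l) {
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      if (m < 0) {
        B[, col] <- sqrt(2) * nrm * P[am + 1, ] * sin(am * phi)
      } else if (m == 0) {
        B[, col] <- nrm * P[1, ]
      } else {
        B[, col] <- sqrt(2) * nrm * P[am + 1, ] * cos(am * phi)
      }
      col <- col + 1L
    }
  }
  B
}

#' Evaluate an FOD at directions
#'
#' Linear in the coefficients; antipodally symmetric because only even
#' degrees are represented.
#'
#' @param coeffs Even-order SH coefficient vector.
#' @param dirs n x 3 unit directions.
#' @return Amplitude per direction.
#' @examples
#' sh_eval(c(1, 0, 0, 0, 0, 0), c(0, 0, 1))  # Y00 only: 1/(2*sqrt(pi))
#' @export
sh_eval <- function(coeffs, dirs) {
  lmax <- sh_lmax(length(coeffs))
  drop(sh_basis(dirs, lmax) %*% coeffs)
}

#' Band-limited delta function
#'
#' SH coefficients of the (even-order) band-limited delta peaked at a
#' direction: the projection of an idealised single-fibre orientation onto
#' the basis. Used to construct synthetic FODs with known peaks.
#'
#' @param dir Unit 3-vector.
#' @param lmax Even maximum degree.
#' @param scale Multiplies the coefficients (peak "density").
#' @return Coefficient vector of length \code{sh_ncoef(lmax)}.
#' @export
sh_delta <- function(dir, lmax, scale = 1) {
  scale * drop(sh_basis(matrix(dir, ncol = 3), lmax))
}

#' Spherical-harmonic coefficient image
#'
#' A per-voxel even-order SH coefficient volume representing FODs.
#'
#' @param coeffs 4D array (nx, ny, nz, ncoef) — or 3D (nx, ny, ncoef) for a
#'   2D grid — of SH coefficients.
#' @param affine 4x4 voxel-to-physical matrix.
#' @return An object of class \code{sh_image} with fields \code{shape},
#'   \code{affine}, \code{coeffs} (4D array) and \code{lmax}.
#' @export
sh_image <- function(coeffs, affine = diag(4)) {
  d <- dim(coeffs)
  if (length(d) == 3L) {
    dim(coeffs) <- c(d[1], d[2], 1L, d[3])
    d <- dim(coeffs)
  }
  if (length(d) != 4L) stop("coeffs must be a 4D (or 3D for 2D grids) array")
  lmax <- sh_lmax(d[4])
  structure(list(shape = d[1:3], affine = affine, coeffs = coeffs,
                 lmax = lmax),
            class = "sh_image")
}

#' Read an SH image from NIfTI
#'
#' @param file 4D NIfTI file whose 4th dimension holds even-order SH
#'   coefficients in this package's basis order.
#' @return An \code{\link{sh_image}}.
#' @export
read_sh_image <- function(file) {
  img <- read_nifti_image(file)
  sh_image(img$data, img$affine)
}

#' @export
print.sh_image <- function(x, ...) {
  cat("sh_image:", paste(x$shape, collapse = " x "), "voxels, lmax",
      x$lmax, "\n")
  invisible(x)
}
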