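# Numerical fibre-bundle phantom.
#
# A straight 2D fibre bundle (FD = 1 in every fixel, oriented along x) is
# subjected to pull-back transformations — a pure scale along the fibre, a
# shear, and a smoothed piecewise-cosine displacement that contracts and
# expands the bundle's cross-section. The validation asserts that the sum
# of FDC across the bundle's width equals the pre-transform sum of FD at
# every position along the bundle's length: modulation by FC preserves the
# bundle's total intra-axonal cross-sectional content.

#' Phantom specification
#'
#' @param length_vox Image size along x in voxels (the fibre length,
#'   \code{s_x}); default 48. The cosine displacement amplitude scales with
#'   \code{s_x}, and for a fixed smoothing kernel the warp only remains
#'   diffeomorphic (positive Jacobian determinant) while
#'   \code{s_x/amplitude_divisor} stays below about
#'   \code{smoothing_sigma * sqrt(2*pi)/2}; the default respects that
#'   bound.
#' @param width_vox Bundle width in voxels; default 20, wide enough that
#'   bilinear interpolation error at the bundle's edge ramps stays well
#'   below the 2 percent conservation band of the validation experiment.
#' @param height_vox Image size along y in voxels; default 80.
#' @param voxel_size Isotropic voxel size in mm; default 1.
#' @param fd0 Fibre density assigned to every bundle fixel; default 1.
#' @param smoothing_sigma Gaussian smoothing of the cosine displacement
#'   field, standard deviation in voxels; default 5.
#' @param amplitude_divisor The cosine displacement amplitude is
#'   \code{s_x / amplitude_divisor}; default 8.
#' @param step Sub-voxel step (in voxels) of the cross-section integration;
#'   default 0.1.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(length_vox = 48, width_vox = 20, height_vox = 80,
                         voxel_size = 1, fd0 = 1, smoothing_sigma = 5,
                         amplitude_divisor = 8, step = 0.1) {
  stopifnot(length_vox > 0, width_vox > 0, height_vox >= width_vox,
            voxel_size > 0, fd0 > 0, smoothing_sigma >= 0,
            amplitude_divisor > 0, step > 0, step < 1)
  structure(list(length_vox = as.integer(length_vox),
                 width_vox = width_vox,
                 height_vox = as.integer(height_vox),
                 voxel_size = voxel_size, fd0 = fd0,
                 smoothing_sigma = smoothing_sigma,
                 amplitude_divisor = amplitude_divisor, step = step),
            class = "phantom_spec")
}

# grid affine: x starts at 0, y centred so the bundle mid-line is y = 0
#' @keywords internal
#' @noRd
phantom_affine <- function(spec) {
  vs <- spec$voxel_size
  aff <- diag(c(vs, vs, vs, 1))
  aff[2, 4] <- -(spec$height_vox - 1) / 2 * vs
  aff
}

#' Build the fibre-bundle phantom
#'
#' One fixel per in-bundle voxel (rows with \code{|y| < width/2}), all
#' oriented along x with FD \code{fd0}; voxels outside the bundle are
#' empty.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return A \code{\link{fixel_grid}} with value \code{"fd"}.
#' @examples
#' g <- make_phantom(phantom_spec())
#' all(fixel_values(g, "fd") == 1)
#' @export
make_phantom <- function(spec = phantom_spec()) {
  shape <- c(spec$length_vox, spec$height_vox, 1L)
  aff <- phantom_affine(spec)
  ycoord <- (seq_len(spec$height_vox) - 1) * spec$voxel_size + aff[2, 4]
  in_bundle <- abs(ycoord) < spec$width_vox / 2 * spec$voxel_size
  counts <- array(0L, dim = shape)
  counts[, in_bundle, 1] <- 1L
  nf <- sum(counts)
  fixel_grid(shape, aff, counts,
             directions = matrix(rep(c(1, 0, 0), nf), ncol = 3,
                                 byrow = TRUE),
             values = list(fd = rep(spec$fd0, nf)))
}

#' Linear pull-back warp
#'
#' Deformation field of a linear map: each template voxel stores
#' \code{T \%*\% x} of its own physical position — the pull-back that maps
#' template voxels to the original (subject) space. The finite-difference
#' Jacobian of this field recovers \code{T} exactly at every voxel.
#'
#' @param T 2x2 or 3x3 matrix with positive determinant (2x2 is embedded
#'   with an identity z row/column).
#' @param shape Grid dimensions.
#' @param affine Grid voxel-to-physical matrix.
#' @return A \code{deformation_field}.
#' @export
linear_warp <- function(T, shape, affine = diag(4)) {
  T <- as.matrix(T)
  if (all(dim(T) == c(2L, 2L))) {
    T3 <- diag(3)
    T3[1:2, 1:2] <- T
    T <- T3
  }
  stopifnot(all(dim(T) == c(3L, 3L)))
  if (det(T) <= 0)
    stop("linear warp must be orientation-preserving (det > 0)")
  shape <- as_shape3(shape)
  pos <- grid_physical(shape, affine) %*% t(T)
  deformation_field(array(pos, dim = c(shape, 3L)), affine)
}

#' Smoothed piecewise-cosine warp
#'
#' Builds the non-linear phantom transformation: a displacement along y of
#' \code{+/- s_x/8 * cos(2*pi*x/s_x)} (positive for \code{y > 0}, negative
#' for \code{y < 0}), Gaussian-smoothed with \code{smoothing_sigma} voxels
#' per component to remove the discontinuity at the bundle mid-line, then
#' converted to a deformation field. The field both contracts and expands
#' the bundle's cross-section along its length.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return A \code{deformation_field} on the phantom grid.
#' @export
cosine_warp <- function(spec = phantom_spec()) {
  shape <- c(spec$length_vox, spec$height_vox, 1L)
  aff <- phantom_affine(spec)
  sx <- spec$length_vox * spec$voxel_size
  amp <- sx / spec$amplitude_divisor
  xc <- (seq_len(spec$length_vox) - 1) * spec$voxel_size
  yc <- (seq_len(spec$height_vox) - 1) * spec$voxel_size + aff[2, 4]
  dy <- outer(amp * cos(2 * pi * xc / sx), sign(yc))
  disp <- array(0, dim = c(shape, 3L))
  disp[, , 1, 2] <- dy
  if (spec$smoothing_sigma > 0) {
    for (comp in 1:3) {
      comp_arr <- array(disp[, , , comp], dim = shape)
      disp[, , , comp] <- gaussian_smooth3(comp_arr, spec$smoothing_sigma)
    }
  }
  displacement_to_deformation(displacement_field(disp, aff))
}

#' Transform the phantom through a warp
#'
#' Pulls the phantom's FD through the template-to-subject warp (bilinear
#' resampling of the subject bundle at each template voxel's corresponding
#' position), reorients the fixel directions into template space
#' (\code{J^{-1} v} normalised), computes FC from the Jacobian, and
#' modulates FD by FC.
#'
#' @param phantom The subject-space \code{\link{fixel_grid}} (from
#'   \code{\link{make_phantom}}).
#' @param warp A \code{deformation_field} on the same grid (template to
#'   subject pull-back).
#' @return A template-space \code{\link{fixel_grid}} with values
#'   \code{"fd"}, \code{"fc"} and \code{"fdc"}.
#' @export
transform_phantom <- function(phantom, warp) {
  stopifnot(inherits(phantom, "fixel_grid"),
            inherits(warp, "deformation_field"))
  shape <- warp$shape
  # subject-space voxel maps of fd and dominant direction
  sub_fd <- dominant_value_map(phantom, "fd")
  jf <- jacobian(warp)
  dets <- jacobian_determinant(jf)
  if (any(dets <= 0))
    stop("folded warp: non-positive Jacobian determinant")
  # pull back fd: template voxel -> subject position -> subject voxel coords
  pos <- matrix(warp$positions, ncol = 3L)
  svox <- physical_to_voxel(pos, phantom$affine)
  fd_t <- interp_trilinear(sub_fd, svox)
  keep <- which(fd_t > 1e-9)
  counts <- array(0L, dim = shape)
  counts[keep] <- 1L
  Jmat <- matrix(jf$J, nrow = prod(shape), ncol = 9L)
  nf <- length(keep)
  dirs <- matrix(0, nrow = nf, ncol = 3L)
  fc <- numeric(nf)
  # subject fixel direction at the pulled-back position (nearest voxel)
  near <- pmin(pmax(round(svox), 1), matrix(rep(phantom$shape, each = nrow(svox)), ncol = 3))
  sdir <- dominant_direction_map(phantom)
  for (t in seq_len(nf)) {
    li <- keep[t]
    J <- matrix(Jmat[li, ], 3L, 3L)
    vsub <- sdir[near[li, 1], near[li, 2], near[li, 3], ]
    if (all(vsub == 0)) vsub <- c(1, 0, 0)
    vt <- reorient_fixel(vsub, solve(J))
    dirs[t, ] <- vt
    fc[t] <- fibre_cross_section(vt, J)
  }
  fd <- fd_t[keep]
  fixel_grid(shape, warp$affine, counts, directions = dirs,
             values = list(fd = fd, fc = fc, fdc = modulate_fdc(fd, fc)))
}

# per-voxel value of the dominant (first-stored, largest-metric) fixel
#' @keywords internal
#' @noRd
dominant_value_map <- function(g, metric) {
  out <- array(0, dim = g$shape)
  val <- fixel_values(g, metric)
  occupied <- which(as.vector(g$counts) > 0L)
  for (li in occupied) {
    rng <- fixel_range(g, li)
    out[li] <- max(val[rng])
  }
  out
}

# per-voxel dominant fixel direction (zero vector where empty)
#' @keywords internal
#' @noRd
dominant_direction_map <- function(g) {
  out <- array(0, dim = c(g$shape, 3L))
  nvox <- prod(g$shape)
  occupied <- which(as.vector(g$counts) > 0L)
  m <- matrix(out, nrow = nvox, ncol = 3L)
  for (li in occupied)
    m[li, ] <- g$directions[g$offsets[li], ]
  array(m, dim = c(g$shape, 3L))
}

#' Per-fixel voxel indices
#'
#' @param g A \code{\link{fixel_grid}}.
#' @return n_fixels x 3 integer matrix of 1-based voxel indices.
#' @export
fixel_voxel_indices <- function(g) {
  nf <- n_fixels(g)
  out <- matrix(0L, nrow = nf, ncol = 3L)
  occupied <- which(as.vector(g$counts) > 0L)
  s1 <- g$shape[1]; s12 <- g$shape[1] * g$shape[2]
  for (li in occupied) {
    k <- (li - 1L) %/% s12
    j <- ((li - 1L) %% s12) %/% s1
    i <- (li - 1L) %% s1
    out[fixel_range(g, li), ] <- matrix(rep(c(i, j, k) + 1L,
                                            each = g$counts[li]),
                                        ncol = 3L)
  }
  out
}

#' Sum FD and FDC across the bundle width
#'
#' The conservation experiment: at every voxel position along the bundle's
#' length, numerically integrates FD (and FDC when present) along a curve
#' that starts on the bundle mid-line and advances in sub-voxel steps
#' perpendicular to the locally interpolated fixel orientation, in both
#' directions, until the interpolated FD falls below the bundle-edge
#' threshold. Sums are Riemann sums scaled by the step size.
#'
#' @param g A \code{\link{fixel_grid}} carrying \code{"fd"} (and optionally
#'   \code{"fdc"}).
#' @param spec A \code{\link{phantom_spec}} (supplies the step size and
#'   \code{fd0} for edge detection).
#' @param edge_frac The traverse terminates where interpolated FD drops
#'   below \code{edge_frac * fd0}; default 0.05.
#' @param complete_only Drop cross-sections whose traverse ran into the
#'   grid boundary instead of a genuine bundle edge (the bundle is clipped
#'   by the field of view there, so the sum is not a full width); default
#'   \code{TRUE}.
#' @return A data frame with columns \code{position} (x in mm),
#'   \code{sum_fd}, (if available) \code{sum_fdc}, and \code{complete};
#'   one row per x column whose mid-line lies inside the bundle.
#' @export
cross_section_sums <- function(g, spec = phantom_spec(), edge_frac = 0.05,
                               complete_only = TRUE) {
  fd_map <- dominant_value_map(g, "fd")
  has_fdc <- "fdc" %in% names(g$values)
  fdc_map <- if (has_fdc) dominant_value_map(g, "fdc") else NULL
  dir_map <- dominant_direction_map(g)
  h <- spec$step
  eps <- edge_frac * spec$fd0
  rows <- list()
  for (i in seq_len(g$shape[1])) {
    col_fd <- fd_map[i, , 1]
    if (max(col_fd) < 0.5 * spec$fd0) next   # no solid bundle this column
    jmid <- sum(seq_along(col_fd) * col_fd) / sum(col_fd)
    start <- c(i, jmid, 1)
    if (interp_trilinear(fd_map, start) < eps) next
    sums <- c(fd = 0, fdc = 0)
    complete <- TRUE
    for (sgn in c(1, -1)) {
      p <- start
      ref <- c(1, 0, 0)
      for (stp in seq_len(ceiling(20 * spec$width_vox / h))) {
        v <- interp_direction(dir_map, fd_map, p, ref)
        if (is.null(v)) break
        ref <- v
        perp <- c(-v[2], v[1], 0)
        nrm <- sqrt(sum(perp^2))
        if (nrm < 1e-9) break
        perp <- sgn * perp / nrm
        mid <- p + perp * h / 2
        fd_mid <- interp_trilinear(fd_map, mid)
        if (fd_mid < eps) {
          # a traverse ending at (or beyond) the grid boundary hit the
          # field of view, not the bundle edge
          if (any(mid[1:2] < 1.5) || any(mid[1:2] > dim(fd_map)[1:2] - 0.5))
            complete <- FALSE
          break
        }
        sums["fd"] <- sums["fd"] + fd_mid * h * spec$voxel_size
        if (has_fdc)
          sums["fdc"] <- sums["fdc"] + interp_trilinear(fdc_map, mid) *
            h * spec$voxel_size
        p <- p + perp * h
      }
    }
    pos_mm <- voxel_to_physical(c(i, jmid, 1), g$affine)[1]
    row <- data.frame(position = pos_mm, sum_fd = sums[["fd"]])
    if (has_fdc) row$sum_fdc <- sums[["fdc"]]
    row$complete <- complete
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows))
    stop("mid-line outside bundle: no column contains a solid bundle")
  out <- do.call(rbind, rows)
  if (complete_only) {
    out <- out[out$complete, , drop = FALSE]
    if (!nrow(out))
      stop("no complete cross-section: the bundle is clipped by the grid ",
           "at every sampled position")
  }
  rownames(out) <- NULL
  out
}

# bilinear interpolation of an axial direction field with sign alignment
# to a reference direction; NULL when no oriented mass nearby
#' @keywords internal
#' @noRd
interp_direction <- function(dir_map, fd_map, p, ref) {
  shape <- dim(fd_map)
  i0 <- floor(p)
  fr <- p - i0
  for (a in 1:3) if (shape[a] == 1L) { i0[a] <- 1; fr[a] <- 0 }
  acc <- c(0, 0, 0)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    ii <- i0[1] + di; jj <- i0[2] + dj; kk <- i0[3] + dk
    if (ii < 1 || ii > shape[1] || jj < 1 || jj > shape[2] ||
        kk < 1 || kk > shape[3]) next
    w <- (if (di == 1) fr[1] else 1 - fr[1]) *
         (if (dj == 1) fr[2] else 1 - fr[2]) *
         (if (dk == 1) fr[3] else 1 - fr[3])
    if (w == 0) next
    v <- dir_map[ii, jj, kk, ]
    if (all(v == 0)) next
    if (sum(v * ref) < 0) v <- -v
    acc <- acc + w * v
  }
  n <- sqrt(sum(acc^2))
  if (n < 1e-6) return(NULL)
  acc / n
}
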