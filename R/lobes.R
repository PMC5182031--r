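# FOD lobe segmentation and fixel-specific fibre density.
#
# Each FOD lobe corresponds to a distinct fibre population; its integral
# over the sphere is the apparent fibre density (FD) of that population.
# Lobes are segmented on the hemisphere mesh by steepest-ascent watershed:
# every vertex with positive amplitude walks uphill to its highest
# neighbour until it reaches a local maximum; vertices draining to the same
# maximum form one lobe. Negative amplitudes (small spherical-deconvolution
# residuals) are clamped to zero and take no part in integration.

#' Segment FOD lobes on a hemisphere mesh
#'
#' @param coeffs Even-order SH coefficient vector for one FOD.
#' @param mesh A \code{\link{sphere_mesh}}.
#' @param basis Optional precomputed \code{sh_basis(mesh$vertices, lmax)}
#'   matrix (saves recomputation over many voxels).
#' @return A list of lobes sorted by descending integral; each lobe is a
#'   list with \code{peak_direction} (unit 3-vector, quadratic-fit refined),
#'   \code{peak_vertex}, \code{members} (mesh vertex indices) and
#'   \code{integral} (lobe FD, amplitude-weighted quadrature). An
#'   all-negative or zero FOD yields an empty list.
#' @export
segment_lobes <- function(coeffs, mesh, basis = NULL) {
  if (is.null(basis)) basis <- sh_basis(mesh$vertices, sh_lmax(length(coeffs)))
  amp <- drop(basis %*% coeffs)
  segment_lobes_amp(amp, mesh)
}

# watershed on precomputed amplitudes
#' @keywords internal
#' @noRd
segment_lobes_amp <- function(amp, mesh) {
  D <- length(amp)
  pos <- which(amp > 0)
  if (!length(pos)) return(list())
  # steepest-ascent target per vertex; ties broken by lowest vertex index
  target <- integer(D)
  for (i in pos) {
    nb <- mesh$neighbours[[i]]
    higher <- nb[amp[nb] > amp[i]]
    if (!length(higher)) {
      target[i] <- i                 # local maximum
    } else {
      best <- higher[amp[higher] == max(amp[higher])]
      target[i] <- min(best)
    }
  }
  # follow ascent paths with memoisation
  root <- integer(D)
  resolve <- function(i) {
    path <- integer(0)
    while (root[i] == 0L && target[i] != i) {
      path <- c(path, i)
      i <- target[i]
    }
    r <- if (root[i] != 0L) root[i] else i
    root[path] <<- r
    root[i] <<- r
    r
  }
  for (i in pos) resolve(i)
  # merge plateaus: adjacent vertices with exactly equal positive amplitude
  # belong to one lobe (a flat region contains no trough); without this a
  # constant FOD would fragment into one lobe per vertex
  uf <- seq_len(D)
  uf_find <- function(i) {
    while (uf[i] != i) {
      uf[i] <<- uf[uf[i]]
      i <- uf[i]
    }
    i
  }
  for (i in pos) {
    nb <- mesh$neighbours[[i]]
    for (j in nb[amp[nb] == amp[i] & nb > i]) {
      ri <- uf_find(root[i]); rj <- uf_find(root[j])
      if (ri != rj) uf[max(ri, rj)] <- min(ri, rj)
    }
  }
  root[pos] <- vapply(root[pos], uf_find, integer(1))
  # a merged lobe's peak is its highest-amplitude member (lowest index wins)
  peaks <- sort(unique(root[pos]))
  for (p in peaks) {
    members <- pos[root[pos] == p]
    best <- members[which.max(amp[members])]
    if (best != p) root[members] <- best
  }
  peaks <- sort(unique(root[pos]))
  lobes <- lapply(peaks, function(p) {
    members <- pos[root[pos] == p]
    list(peak_direction = refine_peak(p, amp, mesh),
         peak_vertex = p,
         members = members,
         integral = sum(amp[members] * mesh$weights[members]))
  })
  lobes[order(vapply(lobes, `[[`, numeric(1), "integral"),
              decreasing = TRUE)]
}

# refine a peak direction by a quadratic fit on the tangent plane through
# the peak vertex and its mesh neighbourhood; falls back to the vertex
# direction if the fit is not a well-behaved interior maximum
#' @keywords internal
#' @noRd
refine_peak <- function(p, amp, mesh) {
  v0 <- mesh$vertices[p, ]
  nb <- mesh$neighbours[[p]]
  pts <- mesh$vertices[nb, , drop = FALSE]
  # neighbours may sit on the far side of the equator: use axial sign
  flip <- (pts %*% v0) < 0
  pts[flip, ] <- -pts[flip, ]
  # tangent basis
  e1 <- if (abs(v0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * v0) * v0
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v0[2] * e1[3] - v0[3] * e1[2],
          v0[3] * e1[1] - v0[1] * e1[3],
          v0[1] * e1[2] - v0[2] * e1[1])
  t1 <- drop(pts %*% e1)
  t2 <- drop(pts %*% e2)
  X <- cbind(1, c(0, t1), c(0, t2), c(0, t1^2), c(0, t1 * t2), c(0, t2^2))
  y <- c(amp[p], amp[nb])
  fit <- try(qr.solve(X, y), silent = TRUE)
  if (inherits(fit, "try-error")) return(v0)
  H <- matrix(c(2 * fit[4], fit[5], fit[5], 2 * fit[6]), 2)
  g <- fit[2:3]
  det_h <- H[1, 1] * H[2, 2] - H[1, 2]^2
  if (!(det_h > 0 && H[1, 1] < 0)) return(v0)   # not a local maximum
  delta <- -solve(H, g)
  if (sqrt(sum(delta^2)) > max(abs(c(t1, t2)))) return(v0)
  d <- v0 + delta[1] * e1 + delta[2] * e2
  d / sqrt(sum(d^2))
}

#' Extract fixels with fibre density from an FOD image
#'
#' Segments every voxel's FOD into lobes, thresholds lobes on their
#' integral (apparent fibre density), and emits up to \code{max_fixels}
#' fixels per voxel, largest first. The per-fixel \code{"fd"} value is the
#' lobe integral; the fixel direction is the refined lobe peak.
#'
#' @param fod An \code{\link{sh_image}}.
#' @param mesh A \code{\link{sphere_mesh}} (default level 4, 1281 vertices).
#' @param fd_threshold Minimum lobe integral retained (default 0.10, a
#'   typical template fixel-mask threshold).
#' @param max_fixels Maximum fixels kept per voxel (default 3).
#' @return A \code{\link{fixel_grid}} with value \code{"fd"}.
#' @examples
#' co <- array(0, dim = c(1, 1, 1, 6))
#' co[1, 1, 1, 1] <- 1                     # pure l = 0 FOD
#' g <- fixels_from_fod(sh_image(co), sphere_mesh(2), fd_threshold = 0)
#' abs(fixel_values(g, "fd") - sqrt(pi)) < 1e-9
#' @export
fixels_from_fod <- function(fod, mesh = sphere_mesh(4), fd_threshold = 0.10,
                            max_fixels = 3L) {
  stopifnot(inherits(fod, "sh_image"))
  nc <- dim(fod$coeffs)[4]
  basis <- sh_basis(mesh$vertices, fod$lmax)
  nvox <- prod(fod$shape)
  cmat <- matrix(fod$coeffs, nrow = nvox, ncol = nc)
  counts <- integer(nvox)
  dir_list <- vector("list", nvox)
  fd_list <- vector("list", nvox)
  nz <- which(rowSums(abs(cmat)) > 0)
  amps <- if (length(nz)) cmat[nz, , drop = FALSE] %*% t(basis) else NULL
  for (t in seq_along(nz)) {
    li <- nz[t]
    lobes <- segment_lobes_amp(amps[t, ], mesh)
    if (length(lobes)) {
      keep <- vapply(lobes, `[[`, numeric(1), "integral") >= fd_threshold
      lobes <- lobes[keep]
    }
    if (length(lobes) > max_fixels) lobes <- lobes[seq_len(max_fixels)]
    if (!length(lobes)) next
    counts[li] <- length(lobes)
    dir_list[[li]] <- t(vapply(lobes, `[[`, numeric(3), "peak_direction"))
    fd_list[[li]] <- vapply(lobes, `[[`, numeric(1), "integral")
  }
  dirs <- do.call(rbind, c(list(matrix(numeric(0), ncol = 3)),
                           dir_list[counts > 0]))
  fd <- unlist(fd_list[counts > 0], use.names = FALSE)
  if (is.null(fd)) fd <- numeric(0)
  fixel_grid(fod$shape, fod$affine, counts, directions = dirs,
             values = list(fd = fd))
}
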