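# Hemisphere quadrature mesh.
#
# FODs are antipodally symmetric (even-order SH), so the natural sampling
# domain is a hemisphere of axial directions. We build a full icosphere
# (recursively subdivided icosahedron, which is centrally symmetric), then
# identify each antipodal vertex pair with a single canonical
# representative. Mesh adjacency is mapped through that identification, so
# walks on the hemisphere graph wrap correctly across the equator — this
# matters for watershed lobe segmentation of lobes straddling the equator.

#' Hemisphere sampling mesh
#'
#' Builds a dense quadrature mesh over the hemisphere of axial directions,
#' used to sample FODs for lobe segmentation and numerical integration.
#' Vertex quadrature weights are barycentric: each vertex receives one third
#' of the spherical area of every incident triangle, so the weights sum to
#' the hemisphere area \eqn{2\pi} exactly (up to floating point).
#'
#' @param level Icosphere subdivision level. Level 4 gives 1281 hemisphere
#'   vertices (the default); each level quadruples the triangle count.
#' @return An object of class \code{sphere_mesh} with fields
#'   \code{vertices} (D x 3 unit axial directions), \code{neighbours}
#'   (adjacency list), \code{weights} (steradians per vertex) and
#'   \code{level}.
#' @examples
#' m <- sphere_mesh(2)
#' abs(sum(m$weights) - 2 * pi) < 1e-9
#' @export
sphere_mesh <- function(level = 4) {
  ico <- icosphere(level)
  v <- ico$vertices
  faces <- ico$faces
  nv <- nrow(v)

  # barycentric vertex weights from spherical triangle areas
  w <- numeric(nv)
  a <- v[faces[, 1], , drop = FALSE]
  b <- v[faces[, 2], , drop = FALSE]
  c3 <- v[faces[, 3], , drop = FALSE]
  areas <- spherical_triangle_area(a, b, c3)
  for (k in 1:3) {
    tab <- tapply(areas / 3, faces[, k], sum)
    w[as.integer(names(tab))] <- w[as.integer(names(tab))] + tab
  }

  # canonical sign: keep the member of each antipodal pair with z > 0
  # (ties broken on y, then x)
  eps <- 1e-9
  canon <- v[, 3] > eps |
    (abs(v[, 3]) <= eps & (v[, 2] > eps |
                             (abs(v[, 2]) <= eps & v[, 1] > 0)))
  # match each vertex to its antipode by rounded-coordinate key
  key <- function(m) apply(round(m * 1e6), 1, paste, collapse = ",")
  lookup <- new.env(hash = TRUE)
  ks <- key(v)
  for (i in seq_len(nv)) assign(ks[i], i, envir = lookup)
  anti <- vapply(key(-v), function(k) get(k, envir = lookup), integer(1))
  rep_of <- ifelse(canon, seq_len(nv), anti)
  if (any(!canon[rep_of])) stop("antipodal identification failed")

  reps <- which(canon)
  hemi_index <- integer(nv)            # full-sphere vertex -> hemisphere id
  hemi_index[reps] <- seq_along(reps)
  hemi_index[!canon] <- hemi_index[rep_of[!canon]]

  # hemisphere adjacency via the identification
  edges <- unique(rbind(faces[, c(1, 2)], faces[, c(2, 3)],
                        faces[, c(3, 1)]))
  he <- cbind(hemi_index[edges[, 1]], he2 = hemi_index[edges[, 2]])
  he <- he[he[, 1] != he[, 2], , drop = FALSE]
  he <- unique(rbind(he, he[, 2:1]))
  neighbours <- split(he[, 2], factor(he[, 1], levels = seq_along(reps)))
  neighbours <- lapply(neighbours, function(x) sort(unique(x)))

  # average the two pair members' weights so hemisphere weights sum to 2*pi
  wh <- (w[reps] + w[anti[reps]]) / 2
  structure(list(vertices = v[reps, , drop = FALSE],
                 neighbours = neighbours,
                 weights = wh, level = level),
            class = "sphere_mesh")
}

#' @export
print.sphere_mesh <- function(x, ...) {
  cat("sphere_mesh: level", x$level, "-", nrow(x$vertices),
      "hemisphere vertices\n")
  invisible(x)
}

# icosahedron subdivided `level` times and projected to the unit sphere;
# midpoint subdivision of a centrally symmetric solid stays centrally
# symmetric, which the hemisphere identification relies on
#' @keywords internal
#' @noRd
icosphere <- function(level) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (iter in seq_len(level)) {
    mid_cache <- new.env(hash = TRUE)
    verts <- v
    nextv <- nrow(v)
    midpoint <- function(i, j) {
      k <- paste(min(i, j), max(i, j), sep = "-")
      if (!is.null(mid_cache[[k]])) return(mid_cache[[k]])
      p <- verts[i, ] + verts[j, ]
      p <- p / sqrt(sum(p^2))
      nextv <<- nextv + 1L
      verts <<- rbind(verts, p)
      mid_cache[[k]] <- nextv
      nextv
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (t in seq_len(nrow(f))) {
      i <- f[t, 1]; j <- f[t, 2]; k <- f[t, 3]
      ij <- midpoint(i, j); jk <- midpoint(j, k); ki <- midpoint(k, i)
      nf[4 * t - 3, ] <- c(i, ij, ki)
      nf[4 * t - 2, ] <- c(j, jk, ij)
      nf[4 * t - 1, ] <- c(k, ki, jk)
      nf[4 * t, ] <- c(ij, jk, ki)
    }
    v <- verts
    f <- nf
  }
  dimnames(v) <- NULL
  list(vertices = v, faces = f)
}

# Van Oosterom & Strackee solid angle of spherical triangles (rows paired)
#' @keywords internal
#' @noRd
spherical_triangle_area <- function(a, b, c3) {
  num <- abs(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
             a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
             a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1]))
  den <- 1 + rowSums(a * b) + rowSums(b * c3) + rowSums(a * c3)
  2 * atan2(num, den)
}
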