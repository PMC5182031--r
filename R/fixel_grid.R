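#' Sparse fixel grid
#'
#' A `fixel_grid` stores a sparse set of fixels (specific fibre populations
#' within a voxel) on a regular image grid. Each voxel owns zero or more
#' fixels, stored contiguously in voxel-major order; each fixel carries an
#' axial unit direction (\code{v} and \code{-v} are equivalent) and any
#' number of named per-fixel scalar metrics (e.g. \code{"fd"}, \code{"fc"},
#' \code{"fdc"}).
#'
#' @param shape Integer grid dimensions, length 2 or 3. 2D grids are stored
#'   as 3D with a singleton third axis.
#' @param affine 4x4 voxel-to-physical (mm) matrix (0-based voxel indices,
#'   NIfTI convention). Defaults to identity.
#' @param counts Integer array of per-voxel fixel counts, in grid shape (or
#'   a vector in column-major order).
#' @param directions F x 3 numeric matrix of unit fixel directions, ordered
#'   voxel-major to match \code{counts}.
#' @param values Named list of numeric vectors, each of length F.
#'
#' @return An object of class \code{fixel_grid} with fields \code{shape},
#'   \code{affine}, \code{counts}, \code{offsets} (1-based index of each
#'   voxel's first fixel), \code{directions} and \code{values}.
#' @examples
#' g <- fixel_grid(c(2, 2), counts = c(1, 0, 2, 0),
#'                 directions = rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0)),
#'                 values = list(fd = c(1, 0.5, 0.7)))
#' n_fixels(g)
#' @export
fixel_grid <- function(shape, affine = diag(4), counts = NULL,
                       directions = NULL, values = list()) {
  shape <- as_shape3(shape)
  nvox <- prod(shape)
  if (is.null(counts)) counts <- integer(nvox)
  counts <- array(as.integer(counts), dim = shape)
  if (any(counts < 0L)) stop("fixel counts must be non-negative")
  nf <- sum(counts)
  if (is.null(directions)) directions <- matrix(numeric(0), ncol = 3L)
  directions <- matrix(as.numeric(directions), ncol = 3L)
  if (nrow(directions) != nf)
    stop(sprintf("directions rows (%d) must equal total fixel count (%d)",
                 nrow(directions), nf))
  offsets <- array(cumsum(c(0L, as.integer(counts)))[seq_len(nvox)] + 1L,
                   dim = shape)
  g <- structure(list(shape = shape, affine = affine, counts = counts,
                      offsets = offsets, directions = directions,
                      values = values),
                 class = "fixel_grid")
  validate_fixel_grid(g)
}

#' @rdname fixel_grid
#' @param g A \code{fixel_grid}.
#' @export
n_fixels <- function(g) nrow(g$directions)

#' Validate a fixel grid
#'
#' Checks the structural invariants: unit-norm directions (renormalised with
#' a warning if they deviate by more than 1e-4, rejected beyond 0.05), value
#' arrays of length F with no unexpected NaN, and contiguous voxel offsets.
#'
#' @param g A \code{fixel_grid}.
#' @param tol Maximum tolerated deviation of direction norms from 1 before
#'   renormalisation triggers a warning.
#' @return The (possibly renormalised) grid, invisibly classed.
#' @export
validate_fixel_grid <- function(g, tol = 1e-4) {
  nf <- nrow(g$directions)
  if (sum(g$counts) != nf)
    stop("fixel format error: counts sum to ", sum(g$counts),
         " but directions hold ", nf, " fixels")
  if (nf > 0) {
    nrm <- sqrt(rowSums(g$directions^2))
    if (any(!is.finite(nrm)) || any(nrm < 0.95) || any(nrm > 1.05))
      stop("fixel validation error: non-unit directions beyond tolerance")
    if (any(abs(nrm - 1) > tol)) {
      warning("renormalising fixel directions (max |norm-1| = ",
              format(max(abs(nrm - 1))), ")")
    }
    if (any(abs(nrm - 1) > 1e-9))
      g$directions <- g$directions / nrm
  }
  for (nm in names(g$values)) {
    v <- g$values[[nm]]
    if (length(v) != nf)
      stop(sprintf("fixel format error: value '%s' has length %d, expected %d",
                   nm, length(v), nf))
  }
  g
}

#' Per-fixel metric access
#'
#' Get or set a named per-fixel scalar array on a fixel grid.
#'
#' @param g A \code{fixel_grid}.
#' @param name Metric name, e.g. \code{"fd"}.
#' @param value Numeric vector of length \code{n_fixels(g)}.
#' @return \code{fixel_values} returns the numeric vector;
#'   \code{fixel_values<-} the modified grid.
#' @export
fixel_values <- function(g, name) {
  if (!name %in% names(g$values))
    stop("no per-fixel value named '", name, "'")
  g$values[[name]]
}

#' @rdname fixel_values
#' @export
`fixel_values<-` <- function(g, name, value) {
  if (length(value) != n_fixels(g))
    stop("value length ", length(value), " does not match fixel count ",
         n_fixels(g))
  g$values[[name]] <- as.numeric(value)
  g
}

#' Fixels of one voxel
#'
#' Returns the fixels stored at a voxel, in stored order.
#'
#' @param g A \code{fixel_grid}.
#' @param voxel Integer triple (1-based; a pair is accepted for 2D grids).
#' @return A list with one entry per fixel, each a list with
#'   \code{direction} (unit 3-vector), \code{index} (row in the grid's fixel
#'   arrays) and one entry per registered metric.
#' @examples
#' g <- fixel_grid(c(1, 1), counts = 2,
#'                 directions = rbind(c(1, 0, 0), c(0, 1, 0)),
#'                 values = list(fd = c(0.8, 0.3)))
#' length(voxel_fixels(g, c(1, 1, 1)))
#' @export
voxel_fixels <- function(g, voxel) {
  voxel <- as.integer(voxel)
  if (length(voxel) == 2L) voxel <- c(voxel, 1L)
  if (length(voxel) != 3L || any(voxel < 1L) || any(voxel > g$shape))
    stop("voxel index out of range: (", paste(voxel, collapse = ","), ")")
  li <- linear_index(voxel, g$shape)
  cnt <- g$counts[li]
  if (cnt == 0L) return(list())
  idx <- g$offsets[li] + seq_len(cnt) - 1L
  lapply(idx, function(i) {
    rec <- list(direction = g$directions[i, ], index = i)
    for (nm in names(g$values)) rec[[nm]] <- g$values[[nm]][i]
    rec
  })
}

# linear fixel index range for a voxel linear index; integer(0) if empty
#' @keywords internal
#' @noRd
fixel_range <- function(g, li) {
  cnt <- g$counts[li]
  if (cnt == 0L) return(integer(0))
  g$offsets[li] + seq_len(cnt) - 1L
}

#' @export
print.fixel_grid <- function(x, ...) {
  cat("fixel_grid:", paste(x$shape, collapse = " x "), "voxels,",
      n_fixels(x), "fixels\n")
  if (length(x$values))
    cat("  metrics:", paste(names(x$values), collapse = ", "), "\n")
  vs <- x$affine[1:3, 1:3]
  cat("  voxel size (mm):", paste(signif(sqrt(colSums(vs^2)), 4),
                                  collapse = " x "), "\n")
  invisible(x)
}

#' Voxel-wise scalar image
#'
#' A plain scalar volume sharing grid geometry with a \code{fixel_grid},
#' used for voxel-wise maps such as the total FD map.
#'
#' @param data Numeric array (2D or 3D) of per-voxel values.
#' @param affine 4x4 voxel-to-physical matrix.
#' @return An object of class \code{scalar_image}.
#' @export
scalar_image <- function(data, affine = diag(4)) {
  if (is.null(dim(data))) dim(data) <- c(length(data), 1L, 1L)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  structure(list(shape = as_shape3(dim(data)), affine = affine,
                 data = data),
            class = "scalar_image")
}
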