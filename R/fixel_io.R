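# On-disk fixel directory format.
#
# A fixel directory holds three kinds of NIfTI files:
#   index.nii[.gz]       4D (nx, ny, nz, 2): per-voxel fixel count and
#                        0-based offset into the fixel arrays
#   directions.nii[.gz]  (F, 1, 1, 3): unit fixel directions
#   <metric>.nii[.gz]    (F, 1, 1): one scalar per fixel, registered under
#                        the file stem name
# NIfTI-1 and NIfTI-2 are auto-detected on read; NIfTI-2 is written.

#' Read a fixel directory
#'
#' Loads a sparse fixel dataset from its on-disk directory representation
#' (index, directions and per-metric NIfTI volumes).
#'
#' @param path Directory containing \code{index.nii[.gz]},
#'   \code{directions.nii[.gz]} and zero or more metric volumes.
#' @return A \code{\link{fixel_grid}}; every metric file found is registered
#'   under its file stem.
#' @seealso \code{\link{write_fixel_dir}}
#' @export
read_fixel_dir <- function(path) {
  if (!dir.exists(path)) stop("fixel directory not found: ", path)
  idx_file <- find_nifti(path, "index")
  dir_file <- find_nifti(path, "directions")
  idx_img <- RNifti::readNifti(idx_file)
  affine <- structure(RNifti::xform(idx_img), imagedim = NULL)
  idx <- as.array(idx_img)
  d <- dim(idx)
  if (length(d) != 4L || d[4] != 2L)
    stop("fixel format error: index volume must be 4D with last dim 2")
  shape <- d[1:3]
  counts <- array(as.integer(idx[, , , 1]), dim = shape)
  offsets0 <- array(as.integer(idx[, , , 2]), dim = shape)
  dirs <- as.array(RNifti::readNifti(dir_file))
  nf <- sum(counts)
  dirs <- matrix(dirs, ncol = 3L)
  if (nf == 0L) {
    # empty grids store a single all-zero placeholder row (NIfTI cannot
    # represent zero-extent dimensions)
    if (!(nrow(dirs) == 1L && all(dirs == 0)))
      stop("fixel format error: index claims 0 fixels but directions file ",
           "is not the empty placeholder")
    dirs <- dirs[integer(0), , drop = FALSE]
  } else if (nrow(dirs) != nf) {
    stop("fixel format error: index claims ", nf, " fixels but directions ",
         "file holds ", nrow(dirs))
  }
  # reorder into canonical voxel-major contiguous storage
  perm <- integer(nf)
  pos <- 1L
  ord <- order(as.vector(offsets0)[as.vector(counts) > 0L])
  occupied <- which(as.vector(counts) > 0L)[ord]
  for (li in occupied) {
    cnt <- counts[li]
    perm[pos:(pos + cnt - 1L)] <- offsets0[li] + seq_len(cnt)
    pos <- pos + cnt
  }
  if (nf > 0 && (any(perm < 1L) || any(duplicated(perm))))
    stop("fixel format error: index offsets overlap or fall outside the ",
         "fixel arrays")
  values <- list()
  metric_files <- setdiff(list.files(path, pattern = "\\.nii(\\.gz)?$"),
                          c(basename(idx_file), basename(dir_file)))
  for (f in metric_files) {
    stem <- sub("\\.nii(\\.gz)?$", "", f)
    v <- as.numeric(as.array(RNifti::readNifti(file.path(path, f))))
    if (nf == 0L) {
      values[[stem]] <- numeric(0)
      next
    }
    if (length(v) != nf)
      stop(sprintf("fixel format error: metric '%s' has %d values, expected %d",
                   stem, length(v), nf))
    values[[stem]] <- v[perm]
  }
  fixel_grid(shape, affine, counts,
             directions = dirs[perm, , drop = FALSE], values = values)
}

#' Write a fixel directory
#'
#' Serialises a \code{\link{fixel_grid}} to the on-disk fixel directory
#' layout. Directions and values are stored as float32 (the format's stored
#' precision); \code{\link{read_fixel_dir}} round-trips them bit-exactly at
#' that precision.
#'
#' @param g A \code{\link{fixel_grid}}.
#' @param path Output directory (created if needed).
#' @param gzip Compress volumes (\code{.nii.gz}); plain \code{.nii} written
#'   when \code{FALSE}.
#' @return Invisibly, \code{path}.
#' @export
write_fixel_dir <- function(g, path, gzip = FALSE) {
  g <- validate_fixel_grid(g)
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE,
                                       showWarnings = FALSE)
  if (!ok || file.access(path, 2L) != 0L)
    stop("cannot write fixel directory: ", path)
  ext <- if (gzip) ".nii.gz" else ".nii"
  nf <- n_fixels(g)
  idx <- array(0, dim = c(g$shape, 2L))
  idx[, , , 1] <- g$counts
  idx[, , , 2] <- ifelse(g$counts > 0L, g$offsets - 1L, 0L)
  write_nifti_vol(idx, g$affine, file.path(path, paste0("index", ext)),
                  datatype = "int32")
  dirs <- array(0, dim = c(max(nf, 1L), 1L, 1L, 3L))
  if (nf > 0) dirs[, 1, 1, ] <- g$directions
  write_nifti_vol(dirs, diag(4), file.path(path, paste0("directions", ext)),
                  datatype = "float")
  for (nm in names(g$values)) {
    v <- array(0, dim = c(max(nf, 1L), 1L, 1L))
    if (nf > 0) v[, 1, 1] <- g$values[[nm]]
    write_nifti_vol(v, diag(4), file.path(path, paste0(nm, ext)),
                    datatype = "float")
  }
  invisible(path)
}

#' @keywords internal
#' @noRd
find_nifti <- function(path, stem) {
  for (ext in c(".nii", ".nii.gz")) {
    f <- file.path(path, paste0(stem, ext))
    if (file.exists(f)) return(f)
  }
  stop("fixel format error: missing ", stem, ".nii[.gz] in ", path)
}

#' @keywords internal
#' @noRd
write_nifti_vol <- function(arr, affine, file, datatype = "float") {
  img <- RNifti::asNifti(arr, datatype = datatype)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, file, datatype = datatype, version = 2)
  invisible(file)
}

#' Read/write scalar and vector NIfTI volumes
#'
#' Thin wrappers over RNifti used throughout the package so that grid
#' affines travel with the data.
#'
#' @param file NIfTI file path.
#' @return \code{read_nifti_image} returns a list with \code{data} (array)
#'   and \code{affine} (4x4 matrix).
#' @export
read_nifti_image <- function(file) {
  img <- RNifti::readNifti(file)
  aff <- RNifti::xform(img)
  attributes(aff) <- list(dim = dim(aff))
  list(data = as.array(img), affine = aff)
}

#' @rdname read_nifti_image
#' @param data Numeric array.
#' @param affine 4x4 voxel-to-physical matrix.
#' @export
write_nifti_image <- function(data, affine, file) {
  write_nifti_vol(data, affine, file, datatype = "double")
}
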