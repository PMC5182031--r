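# Streamline handling: the template-derived tractogram used to visualise
# fixel results in 3D. Streamline points are assigned to fixels by voxel
# location and local tangent; points whose fixels did not reach
# significance are cropped away, leaving only the significant segments.

#' Tractogram container
#'
#' @param streamlines List of n x 3 numeric matrices of point coordinates
#'   (mm, physical space), each with at least 2 points.
#' @return An object of class \code{tractogram}.
#' @export
tractogram <- function(streamlines) {
  streamlines <- lapply(streamlines, function(s) {
    s <- matrix(as.numeric(s), ncol = 3L)
    if (nrow(s) < 2L) stop("each streamline needs at least 2 points")
    if (any(!is.finite(s))) stop("streamline coordinates must be finite")
    s
  })
  structure(list(streamlines = streamlines,
                 count = length(streamlines)),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  np <- sum(vapply(x$streamlines, nrow, integer(1)))
  cat("tractogram:", x$count, "streamlines,", np, "points\n")
  invisible(x)
}

#' Read and write streamline files
#'
#' Two formats are supported, chosen by file extension: the common binary
#' track format (\code{.tck}: text header, float32 triplets, NaN-separated
#' streamlines, Inf terminator) and a plain-text fallback (\code{.txt}:
#' one x y z point per line, blank line between streamlines).
#'
#' @param file Path ending in \code{.tck} or \code{.txt}.
#' @return \code{read_tractogram} returns a \code{\link{tractogram}}.
#' @export
read_tractogram <- function(file) {
  if (grepl("\\.tck$", file)) read_tck(file) else read_tracks_text(file)
}

#' @rdname read_tractogram
#' @param t A \code{\link{tractogram}}.
#' @export
write_tractogram <- function(t, file) {
  stopifnot(inherits(t, "tractogram"))
  if (grepl("\\.tck$", file)) write_tck(t, file)
  else write_tracks_text(t, file)
  invisible(file)
}

#' @keywords internal
#' @noRd
read_tck <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "mrtrix tracks"))
    stop("not a tck track file: ", file)
  offset <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || identical(line, "END")) break
    kv <- strsplit(line, ": *")[[1]]
    if (kv[1] == "file") offset <- as.integer(sub("^\\. ", "", kv[2]))
    if (kv[1] == "datatype" && !identical(kv[2], "Float32LE"))
      stop("unsupported tck datatype: ", kv[2])
  }
  if (is.null(offset)) stop("tck header missing file offset")
  seek(con, where = offset, origin = "start")
  raw_vals <- readBin(con, "numeric", n = file.size(file), size = 4L,
                      endian = "little")
  pts <- matrix(raw_vals, ncol = 3L, byrow = TRUE)
  streamlines <- list()
  cur <- list()
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (all(is.infinite(p))) break
    if (any(is.nan(p))) {
      if (length(cur)) streamlines[[length(streamlines) + 1L]] <-
          do.call(rbind, cur)
      cur <- list()
    } else {
      cur[[length(cur) + 1L]] <- p
    }
  }
  if (length(cur)) streamlines[[length(streamlines) + 1L]] <-
      do.call(rbind, cur)
  tractogram(streamlines)
}

#' @keywords internal
#' @noRd
write_tck <- function(t, file) {
  header <- c("mrtrix tracks", "datatype: Float32LE",
              sprintf("count: %d", t$count))
  # the offset line's own length changes the offset; fix by two-pass
  for (off in c(100L, 1000L)) {
    lines <- c(header, sprintf("file: . %d", off), "END")
    need <- sum(nchar(lines, "bytes") + 1L)
    if (need <= off) break
  }
  con <- file(file, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  pad <- off - sum(nchar(lines, "bytes") + 1L)
  if (pad > 0) writeBin(raw(pad), con)
  for (s in t$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, size = 4L,
             endian = "little")
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, size = 4L, endian = "little")
  invisible(file)
}

#' @keywords internal
#' @noRd
read_tracks_text <- function(file) {
  lines <- readLines(file)
  blocks <- split(lines, cumsum(lines == ""))
  streamlines <- list()
  for (b in blocks) {
    b <- b[b != ""]
    if (!length(b)) next
    streamlines[[length(streamlines) + 1L]] <-
      do.call(rbind, lapply(strsplit(trimws(b), "[ \t]+"),
                            function(x) as.numeric(x[1:3])))
  }
  tractogram(streamlines)
}

#' @keywords internal
#' @noRd
write_tracks_text <- function(t, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (s in t$streamlines) {
    writeLines(apply(s, 1, paste, collapse = " "), con)
    writeLines("", con)
  }
  invisible(file)
}

#' Assign streamline points to fixels
#'
#' Each point maps to the fixel of its containing voxel whose direction is
#' angularly closest to the local streamline tangent (central differences
#' of neighbouring points, one-sided at the endpoints); \code{NA} if the
#' voxel holds no fixel, lies outside the grid, or the best angle exceeds
#' \code{max_angle}.
#'
#' @param t A \code{\link{tractogram}} in the grid's physical space.
#' @param g A \code{\link{fixel_grid}}.
#' @param max_angle Maximum tangent-to-fixel angle in degrees (default 30,
#'   the same cutoff used for inter-subject fixel correspondence).
#' @return A list, one integer vector per streamline: the fixel index per
#'   point, \code{NA} where unassigned.
#' @export
assign_streamline_points <- function(t, g, max_angle = 30) {
  stopifnot(inherits(t, "tractogram"), inherits(g, "fixel_grid"))
  lapply(t$streamlines, function(s) {
    n <- nrow(s)
    lo <- pmax(1L, seq_len(n) - 1L)
    hi <- pmin(n, seq_len(n) + 1L)
    tang <- s[hi, , drop = FALSE] - s[lo, , drop = FALSE]
    vox <- round(physical_to_voxel(s, g$affine))
    out <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      v <- vox[i, ]
      if (any(v < 1) || any(v > g$shape)) next
      rng <- fixel_range(g, linear_index(v, g$shape))
      if (!length(rng)) next
      tg <- tang[i, ]
      nt <- sqrt(sum(tg^2))
      if (nt < 1e-12) next
      dots <- abs(g$directions[rng, , drop = FALSE] %*% (tg / nt))
      best <- which.max(dots)
      ang <- acos(min(1, dots[best])) * 180 / pi
      if (ang <= max_angle) out[i] <- rng[best]
    }
    out
  })
}

#' Crop a tractogram by a fixel mask
#'
#' Retains maximal runs of consecutive points whose assigned fixels are in
#' the mask (typically significant fixels); runs shorter than 2 points are
#' dropped (a single point cannot be rendered as a segment). Never creates
#' points: every output point existed in the input.
#'
#' @param t A \code{\link{tractogram}}.
#' @param assignment Output of \code{\link{assign_streamline_points}} for
#'   \code{t}.
#' @param mask Logical vector over fixels (e.g.
#'   \code{fixel_values(g, "fwe_pval") < 0.05}).
#' @return A cropped \code{\link{tractogram}} (possibly with zero
#'   streamlines).
#' @export
crop_tractogram <- function(t, assignment, mask) {
  stopifnot(inherits(t, "tractogram"),
            length(assignment) == t$count)
  out <- list()
  for (k in seq_len(t$count)) {
    s <- t$streamlines[[k]]
    a <- assignment[[k]]
    keep <- !is.na(a) & mask[ifelse(is.na(a), 1L, a)]
    if (!any(keep)) next
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= 2L)) {
      out[[length(out) + 1L]] <- s[starts[j]:ends[j], , drop = FALSE]
    }
  }
  if (!length(out))
    return(structure(list(streamlines = list(), count = 0L),
                     class = "tractogram"))
  tractogram(out)
}
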