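# Angular fixel correspondence.
#
# After a subject's fixels have been warped into template space, each
# template-mask fixel takes its metric value from the same-voxel subject
# fixel with the closest (axial) orientation. If no subject fixel lies
# within the maximum angle — e.g. the subject has no corresponding fibre
# population there — the template fixel is assigned the value 0.

#' Axial angular distance
#'
#' The angle between two fibre orientations, treating each as axial
#' (\code{v} and \code{-v} equivalent): \code{acos(|u . v|)} in degrees,
#' range [0, 90].
#'
#' @param u,v Unit 3-vectors.
#' @return Angle in degrees.
#' @examples
#' angular_distance(c(1, 0, 0), c(0, 1, 0))  # 90
#' angular_distance(c(1, 0, 0), c(-1, 0, 0)) # 0
#' @export
angular_distance <- function(u, v) {
  acos(pmin(1, abs(sum(u * v)))) * 180 / pi
}

#' Match subject fixels to a template fixel mask
#'
#' For every template fixel, finds the angularly closest subject fixel in
#' the same voxel and transfers its metric value; template fixels with no
#' subject fixel within \code{max_angle} are zero-filled. The boundary is
#' inclusive (a candidate at exactly \code{max_angle} matches). A tie
#' between equidistant candidates is broken in favour of the larger metric
#' value (the dominant lobe), deterministically.
#'
#' @param template A \code{\link{fixel_grid}} defining the fixel mask; its
#'   directions and counts are preserved unchanged in the output.
#' @param subject A \code{\link{fixel_grid}} in template space (same shape
#'   and affine).
#' @param metric Name of the subject metric to transfer (default
#'   \code{"fd"}); any metric present on the subject grid may be named.
#' @param max_angle Maximum matching angle in degrees (default 30).
#' @return A list with \code{grid} (template grid carrying the transferred
#'   metric) and \code{matches} (data frame with one row per template
#'   fixel: \code{template_fixel}, \code{subject_fixel} (NA if
#'   zero-filled) and \code{angle} in degrees).
#' @export
match_fixels <- function(template, subject, metric = "fd", max_angle = 30) {
  stopifnot(inherits(template, "fixel_grid"), inherits(subject, "fixel_grid"))
  if (!all(template$shape == subject$shape))
    stop("geometry error: subject grid shape does not match template")
  if (max(abs(template$affine - subject$affine)) > 1e-6)
    stop("geometry error: subject affine does not match template ",
         "(warp the subject to template space first)")
  sval <- fixel_values(subject, metric)
  nf <- n_fixels(template)
  out <- numeric(nf)
  midx <- rep(NA_integer_, nf)
  mang <- rep(NA_real_, nf)
  occupied <- which(as.vector(template$counts) > 0L)
  for (li in occupied) {
    srange <- fixel_range(subject, li)
    for (ti in fixel_range(template, li)) {
      if (!length(srange)) next
      tv <- template$directions[ti, ]
      dots <- abs(subject$directions[srange, , drop = FALSE] %*% tv)
      ang <- acos(pmin(1, dots)) * 180 / pi
      best <- which(ang == min(ang))
      if (length(best) > 1L)
        best <- best[which.max(sval[srange[best]])]
      if (ang[best] <= max_angle) {
        out[ti] <- sval[srange[best]]
        midx[ti] <- srange[best]
        mang[ti] <- ang[best]
      }
    }
  }
  g <- template
  fixel_values(g, metric) <- out
  list(grid = g,
       matches = data.frame(template_fixel = seq_len(nf),
                            subject_fixel = midx, angle = mang))
}
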