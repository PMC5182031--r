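# Numerical fibre-bundle phantom and the cross-section conservation
# experiment.

test_that("the phantom is a unit-FD bundle along x", {
  spec <- phantom_spec()
  g <- make_phantom(spec)
  expect_equal(n_fixels(g), spec$length_vox * spec$width_vox)
  expect_true(all(fixel_values(g, "fd") == spec$fd0))
  expect_true(all(g$directions[, 1] == 1))
  expect_true(all(g$directions[, 2:3] == 0))
  # voxels outside the bundle are empty; the bundle is y-centred
  ys <- fixelr:::grid_physical(g$shape, g$affine)[, 2]
  occupied <- as.vector(g$counts) > 0
  expect_true(all(abs(ys[occupied]) < spec$width_vox / 2))
  expect_true(all(abs(ys[!occupied]) >= spec$width_vox / 2))
})

test_that("linear_warp fields reproduce their matrix through the Jacobian", {
  spec <- small_phantom_spec()
  shape <- c(spec$length_vox, spec$height_vox, 1)
  aff <- make_phantom(spec)$affine
  # identity
  w <- linear_warp(diag(3), shape, aff)
  expect_equal(matrix(w$positions, ncol = 3),
               fixelr:::grid_physical(shape, aff))
  # the printed scale: determinant 2 everywhere
  w <- linear_warp(rbind(c(2, 0), c(0, 1)), shape, aff)
  expect_equal(jacobian_determinant(jacobian(w)), array(2, dim = shape))
  # the printed shear: Jacobian equals the matrix at every voxel
  w <- linear_warp(rbind(c(1, 0), c(0.5, 1)), shape, aff)
  J <- jacobian(w)$J
  expect_equal(J[3, 5, 1, 1:2, 1:2], rbind(c(1, 0), c(0.5, 1)),
               tolerance = 1e-12)
  expect_error(linear_warp(rbind(c(-1, 0), c(0, 1)), shape, aff),
               "orientation-preserving")
})

test_that("the cosine displacement has the printed structure", {
  spec <- phantom_spec(smoothing_sigma = 0)    # unsmoothed field
  w <- fixelr:::phantom_affine(spec)
  sx <- spec$length_vox * spec$voxel_size
  amp <- sx / spec$amplitude_divisor
  def <- cosine_warp(spec)
  disp <- deformation_to_displacement(def)$displacements
  # displacement is along y only
  expect_true(all(disp[, , , c(1, 3)] == 0))
  # bounded by the amplitude, antisymmetric in y
  expect_lte(max(abs(disp)), amp + 1e-12)
  expect_equal(disp[, , 1, 2], -disp[, rev(seq_len(spec$height_vox)), 1, 2])
  # zero column where the cosine vanishes: x = s_x/4 (voxel index s_x/4+1)
  i0 <- spec$length_vox / 4 + 1
  expect_equal(disp[i0, , 1, 2], rep(0, spec$height_vox))
})

test_that("smoothing removes the mid-line discontinuity", {
  spec <- phantom_spec()
  def <- cosine_warp(spec)
  disp <- deformation_to_displacement(def)$displacements
  dy <- disp[, , 1, 2]
  ny <- spec$height_vox
  # the smoothed field is antisymmetric, hence continuous through zero at
  # the mid-line: its interpolation at y = 0 vanishes
  mid <- (dy[, ny / 2] + dy[, ny / 2 + 1]) / 2
  expect_lt(max(abs(mid)), 1e-9)
  # and the row-to-row jump at the mid-line is no longer the dominant one:
  # the profile is smooth at the kernel scale
  jumps <- abs(dy[, -1] - dy[, -ny])
  mid_jump <- max(jumps[, ny / 2])
  expect_lt(mid_jump, 3 * max(jumps[, ny / 2 + c(-3, 3)]))
  # the warp stays diffeomorphic
  expect_true(all(jacobian_determinant(jacobian(def)) > 0))
})

test_that("transform_phantom under the identity warp changes nothing", {
  spec <- small_phantom_spec()
  ph <- make_phantom(spec)
  shape <- c(spec$length_vox, spec$height_vox, 1)
  tp <- transform_phantom(ph, linear_warp(diag(3), shape, ph$affine))
  expect_equal(tp$counts, ph$counts)
  expect_true(all(abs(fixel_values(tp, "fd") - 1) < 1e-12))
  expect_true(all(abs(fixel_values(tp, "fc") - 1) < 1e-12))
  expect_true(all(abs(fixel_values(tp, "fdc") - 1) < 1e-12))
})

test_that("the printed transformations give the closed-form FC", {
  spec <- small_phantom_spec()
  ph <- make_phantom(spec)
  shape <- c(spec$length_vox, spec$height_vox, 1)
  interior <- function(g) {
    vox <- fixel_voxel_indices(g)
    vox[, 1] > 1 & vox[, 1] < shape[1] & vox[, 2] > 1 & vox[, 2] < shape[2]
  }
  # scale: FC identically 1 (cross-section untouched)
  tp <- transform_phantom(ph, linear_warp(rbind(c(2, 0), c(0, 1)),
                                          shape, ph$affine))
  expect_equal(fixel_values(tp, "fc")[interior(tp)],
               rep(1, sum(interior(tp))))
  # shear: FC = sqrt(1.25) > 1 on interior fixels, fdc = fc * fd
  tp <- transform_phantom(ph, linear_warp(rbind(c(1, 0), c(0.5, 1)),
                                          shape, ph$affine))
  fc <- fixel_values(tp, "fc")[interior(tp)]
  expect_equal(fc, rep(sqrt(1.25), length(fc)), tolerance = 1e-12)
  expect_equal(fixel_values(tp, "fdc"),
               fixel_values(tp, "fd") * fixel_values(tp, "fc"))
  # the reoriented direction is the image of x under the inverse shear
  expect_equal(tp$directions[interior(tp), , drop = FALSE][1, ],
               c(1, -0.5, 0) / sqrt(1.25), tolerance = 1e-12)
})

test_that("cross-section sums recover the bundle width before transform", {
  spec <- small_phantom_spec()
  ph <- make_phantom(spec)
  prof <- cross_section_sums(ph, spec)
  # Riemann sum of a constant-1 bundle: the width, within one step
  expect_true(all(abs(prof$sum_fd - spec$width_vox) <
                    spec$step * spec$voxel_size + 0.01))
  # mid-line outside the bundle is an error
  empty <- make_phantom(spec)
  empty$values$fd <- rep(0, n_fixels(empty))
  expect_error(cross_section_sums(empty, spec), "mid-line")
})

test_that("cross-section sums are stable under step refinement", {
  spec <- small_phantom_spec()
  ph <- make_phantom(spec)
  tp <- transform_phantom(ph, cosine_warp(spec))
  p1 <- cross_section_sums(tp, spec)
  spec2 <- spec; spec2$step <- spec$step / 2
  p2 <- cross_section_sums(tp, spec2)
  common <- intersect(p1$position, p2$position)
  a <- p1$sum_fdc[match(common, p1$position)]
  b <- p2$sum_fdc[match(common, p2$position)]
  expect_lt(max(abs(a - b) / b), 0.005)
})

test_that("FDC is conserved across the width under all three printed
           transformations; FD only under scale", {
  spec <- phantom_spec()
  ph <- make_phantom(spec)
  shape <- c(spec$length_vox, spec$height_vox, 1)
  ref <- mean(cross_section_sums(ph, spec)$sum_fd)
  warps <- list(
    scale = linear_warp(rbind(c(2, 0), c(0, 1)), shape, ph$affine),
    shear = linear_warp(rbind(c(1, 0), c(0.5, 1)), shape, ph$affine),
    cosine = cosine_warp(spec))
  for (nm in names(warps)) {
    prof <- cross_section_sums(transform_phantom(ph, warps[[nm]]), spec)
    rel_fdc <- abs(prof$sum_fdc / ref - 1)
    expect_lt(max(rel_fdc), 0.02)
    rel_fd <- abs(prof$sum_fd / ref - 1)
    if (nm == "scale") expect_lt(max(rel_fd), 0.02)
    else expect_gt(max(rel_fd), 0.05)   # FD alone is not conserved
  }
})
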