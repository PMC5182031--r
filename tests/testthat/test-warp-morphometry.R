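# Deformation algebra, Jacobians, fixel reorientation, FC and FDC.

test_that("displacement/deformation conversion round trips", {
  aff <- diag(c(2, 2, 2, 1))          # anisotropy-free but non-unit voxels
  z <- array(0, dim = c(4, 3, 2, 3))
  d0 <- displacement_field(z, aff)
  def <- displacement_to_deformation(d0)
  # zero displacement: positions are the grid's own physical coordinates
  expect_equal(matrix(def$positions, ncol = 3),
               fixelr:::grid_physical(c(4, 3, 2), aff))
  # constant displacement shifts every position by t
  t0 <- c(1.5, -2, 0.5)
  dt <- displacement_field(sweep(z, 4, -t0, `-`), aff)
  deft <- displacement_to_deformation(dt)
  expect_equal(deft$positions - def$positions,
               sweep(z, 4, -t0, `-`))
  # round trip
  back <- deformation_to_displacement(deft)
  expect_equal(back$displacements, dt$displacements)
})

test_that("jacobian of the identity deformation is the identity matrix", {
  aff <- diag(4)
  def <- displacement_to_deformation(
    displacement_field(array(0, dim = c(4, 4, 3, 3)), aff))
  jf <- jacobian(def)
  for (v in list(c(1, 1, 1), c(2, 3, 2), c(4, 4, 3)))
    expect_equal(jf$J[v[1], v[2], v[3], , ], diag(3))
  expect_equal(jacobian_determinant(jf), array(1, dim = c(4, 4, 3)))
})

test_that("finite differences of an affine deformation are exact, including
           anisotropic voxels", {
  set.seed(5)
  A <- diag(3) + matrix(rnorm(9, sd = 0.2), 3, 3)
  aff <- diag(c(1, 2, 3.5, 1))        # anisotropic voxel size
  shape <- c(5, 4, 3)
  pos <- fixelr:::grid_physical(shape, aff) %*% t(A)
  def <- deformation_field(array(pos, dim = c(shape, 3)), aff)
  jf <- jacobian(def)
  # exact at every voxel (one-sided differences of a linear field are
  # exact too)
  for (v in list(c(2, 2, 2), c(1, 1, 1), c(5, 4, 3)))
    expect_equal(jf$J[v[1], v[2], v[3], , ], A, tolerance = 1e-12)
})

test_that("a pure stretch doubles the determinant", {
  shape <- c(6, 5, 1)
  def <- linear_warp(diag(c(2, 1, 1)), shape)
  expect_equal(jacobian_determinant(jacobian(def)),
               array(2, dim = shape))
})

test_that("2D grids get an identity z row and column", {
  def <- linear_warp(rbind(c(1, 0), c(0.5, 1)), c(4, 4, 1))
  J <- jacobian(def)$J[2, 2, 1, , ]
  expect_equal(J[3, ], c(0, 0, 1))
  expect_equal(J[, 3], c(0, 0, 1))
  expect_equal(J[1:2, 1:2], rbind(c(1, 0), c(0.5, 1)))
})

test_that("reorient_fixel matches hand-computed values", {
  v <- c(1, 0, 0)
  expect_equal(reorient_fixel(v, diag(3)), v)
  R <- random_rotation()
  u <- c(random_unit_vectors(1, seed = 3))
  expect_equal(reorient_fixel(u, R), drop(R %*% u), tolerance = 1e-12)
  shear <- rbind(c(1, 0, 0), c(0.5, 1, 0), c(0, 0, 1))
  expect_equal(reorient_fixel(v, shear),
               c(1, 0.5, 0) / sqrt(1.25), tolerance = 1e-12)
  expect_error(reorient_fixel(c(0, 0, 1), diag(c(1, 1, 0))), "degenerate")
})

test_that("fibre_cross_section reproduces closed-form cases", {
  expect_equal(fibre_cross_section(c(1, 0, 0), diag(3)), 1)
  # pure scale along the fibre: length changes, cross-section does not
  scaleJ <- diag(c(2, 1, 1))
  expect_equal(fibre_cross_section(c(1, 0, 0), scaleJ), 1)
  # shear with the reoriented template direction
  shearJ <- rbind(c(1, 0, 0), c(0.5, 1, 0), c(0, 0, 1))
  vt <- reorient_fixel(c(1, 0, 0), solve(shearJ))
  expect_equal(fibre_cross_section(vt, shearJ), sqrt(1.25),
               tolerance = 1e-12)
  # perpendicular-plane area scaling for a diagonal map
  expect_equal(fibre_cross_section(c(1, 0, 0), diag(c(4, 2, 3))), 6)
  expect_error(fibre_cross_section(c(1, 0, 0), diag(c(-1, 1, 1))),
               "folded")
})

test_that("FC satisfies its defining identity and frame equivariance", {
  set.seed(7)
  for (i in 1:50) {
    J <- random_jacobian()
    v <- c(random_unit_vectors(1, seed = 100 + i))
    fc <- fibre_cross_section(v, J)
    # FC * |Jv| = det(J) identically
    expect_equal(fc * sqrt(sum((J %*% v)^2)), det(J), tolerance = 1e-10)
    # rotations change nothing: FC(v, R) = 1
    R <- random_rotation()
    expect_equal(fibre_cross_section(v, R), 1, tolerance = 1e-10)
    # conjugating by a rotation leaves FC unchanged
    expect_equal(fibre_cross_section(drop(R %*% v), R %*% J %*% t(R)),
                 fc, tolerance = 1e-9)
  }
})

test_that("the Gram-Schmidt decomposition oracle agrees to 1e-9", {
  set.seed(97)
  worst <- 0
  for (i in 1:1000) {
    J <- random_jacobian()
    v <- drop(random_unit_vectors(1, seed = 2000 + i))
    worst <- max(worst, abs(fibre_cross_section(v, J) -
                              fc_gram_schmidt_oracle(v, J)))
  }
  expect_lt(worst, 1e-9)
  expect_equal(fc_gram_schmidt_oracle(c(0, 1, 0), diag(3)), 1)
  expect_equal(fc_gram_schmidt_oracle(c(1, 0, 0), diag(c(2, 3, 4))), 12)
})

test_that("modulate_fdc is elementwise with guarded inputs", {
  expect_equal(modulate_fdc(1, 1), 1)
  expect_equal(modulate_fdc(0.8, 1.25), 1)
  expect_equal(modulate_fdc(c(0, 0.5), c(2, 2)), c(0, 1))
  expect_error(modulate_fdc(c(1, 2), 1), "equal length")
  expect_error(modulate_fdc(1, -1), "positive")
})

test_that("fc_fixel_map computes per-fixel FC on the template grid", {
  g <- two_voxel_grid()
  ident <- displacement_to_deformation(
    displacement_field(array(0, dim = c(2, 2, 1, 3)), g$affine))
  out <- fc_fixel_map(g, ident)
  expect_equal(fixel_values(out, "fc"), rep(1, 3))
  expect_equal(out$directions, g$directions)
  # folded warp at an in-mask voxel is a hard error
  folded <- linear_warp(diag(c(1, 1, 1)), c(2, 2, 1), g$affine)
  folded$positions[, , , 1] <- -folded$positions[, , , 1]
  expect_error(fc_fixel_map(g, folded), "folded warp")
})
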