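# Shared fixtures, built in code. Meshes are cached per session (the
# level-4 icosphere is the only expensive object).

.fixture_env <- new.env()

test_mesh <- function(level = 4) {
  key <- paste0("mesh", level)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- sphere_mesh(level)
  .fixture_env[[key]]
}

random_unit_vectors <- function(n, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# well-conditioned random Jacobian with positive determinant
random_jacobian <- function() {
  repeat {
    J <- diag(3) + matrix(rnorm(9, sd = 0.3), 3, 3)
    if (det(J) > 0.2 && kappa(J) < 20) return(J)
  }
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# a small grid with known fixels: voxel (1,1,1) has two crossing fixels,
# voxel (2,1,1) is empty, voxel (1,2,1) has one
two_voxel_grid <- function() {
  counts <- array(0L, dim = c(2, 2, 1))
  counts[1, 1, 1] <- 2L
  counts[1, 2, 1] <- 1L
  fixel_grid(c(2, 2, 1), counts = counts,
             directions = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
             values = list(fd = c(0.8, 0.5, 0.3)))
}

# crossing-fibre FOD image: one voxel with two orthogonal fibre
# populations, one empty voxel
crossing_fod_image <- function(lmax = 8) {
  co <- sh_delta(c(1, 0, 0), lmax) + sh_delta(c(0, 1, 0), lmax)
  arr <- array(0, dim = c(2, 1, 1, length(co)))
  arr[1, 1, 1, ] <- co
  sh_image(arr)
}

# small phantom configuration used where full defaults would be slow
small_phantom_spec <- function() {
  phantom_spec(length_vox = 24, width_vox = 10, height_vox = 40)
}
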