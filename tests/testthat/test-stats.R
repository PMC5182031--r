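# Fixel-wise GLM and permutation-based FWE inference.

two_group_design <- function(n_per_group, flip = FALSE) {
  X <- cbind(intercept = 1,
             group2 = rep(c(0, 1), each = n_per_group))
  design_matrix(X, c(0, if (flip) -1 else 1))
}

test_that("fit_glm reproduces the classical pooled two-sample t", {
  # groups A: 1,2,3 and B: 4,5,6; contrast A - B gives t = -3.674
  d <- two_group_design(3, flip = TRUE)
  t_ab <- fit_glm(matrix(1:6, ncol = 1), d)
  expect_equal(t_ab, -3.674235, tolerance = 1e-6)
  # oracle: classical pooled-variance two-sample t
  oracle <- t.test(1:3, 4:6, var.equal = TRUE)$statistic
  expect_equal(t_ab, unname(oracle), tolerance = 1e-12)
  # identical group means, zero noise: numerically zero
  expect_equal(fit_glm(matrix(rep(c(1, 2, 3), 2), ncol = 1),
                       two_group_design(3)), 0)
})

test_that("an orthogonal nuisance column leaves the projection untouched", {
  set.seed(33)
  n <- 12
  X <- two_group_design(6)$X
  Y <- matrix(rnorm(n * 4), n, 4)
  # construct a column orthogonal to the design AND the data
  extra <- qr.resid(qr(cbind(X, Y)), rnorm(n))
  d1 <- design_matrix(X, c(0, 1))
  d2 <- design_matrix(cbind(X, extra), c(0, 1, 0))
  t1 <- fit_glm(Y, d1)
  t2 <- fit_glm(Y, d2)
  # the contrast estimate and residual sum of squares are unchanged (the
  # projection property); the t-statistic only rescales by the root of the
  # df ratio, one df being spent on the extra column
  df1 <- n - 2; df2 <- n - 3
  expect_equal(t2, t1 * sqrt(df2 / df1), tolerance = 1e-10)
})

test_that("design validation rejects degenerate inputs", {
  X <- cbind(1, rep(c(0, 1), each = 3))
  expect_error(design_matrix(cbind(X, X[, 2]), c(0, 1, 0)),
               "rank deficient")
  expect_error(design_matrix(X, c(0, 0)), "non-zero")
  expect_error(fit_glm(matrix(c(1, NA, 3, 4, 5, 6), ncol = 1),
                       design_matrix(X, c(0, 1))), "non-finite")
})

test_that("permutation_fwe is deterministic and respects the p floor", {
  set.seed(40)
  d <- two_group_design(6)
  Y <- matrix(rnorm(12 * 30), 12, 30)
  r1 <- permutation_fwe(Y, d, n_perm = 300, seed = 9)
  r2 <- permutation_fwe(Y, d, n_perm = 300, seed = 9)
  expect_identical(r1, r2)
  r3 <- permutation_fwe(Y, d, n_perm = 300, seed = 10)
  expect_false(identical(r1$fwe_pval, r3$fwe_pval))
  expect_true(all(r1$fwe_pval >= 1 / 301))
  expect_true(all(r1$fwe_pval <= 1))
  # mask is exactly the alpha threshold on the corrected p
  expect_identical(r1$sig_mask, r1$fwe_pval < 0.05)
  # a massive planted effect attains the floor exactly
  Y2 <- Y; Y2[7:12, 1] <- Y2[7:12, 1] + 50
  r4 <- permutation_fwe(Y2, d, n_perm = 300, seed = 9)
  expect_equal(r4$fwe_pval[1], 1 / 301)
})

test_that("corrected p-values are monotone in the observed statistic", {
  set.seed(41)
  d <- two_group_design(6)
  Y <- matrix(rnorm(12 * 40), 12, 40)
  r <- permutation_fwe(Y, d, n_perm = 200, seed = 3)
  o <- order(abs(r$tstat))
  expect_true(all(diff(r$fwe_pval[o]) <= 0))
})

test_that("small cohorts switch to exhaustive enumeration", {
  d <- design_matrix(cbind(1, c(0, 0, 1, 1, 1)), c(0, 1))
  Y <- matrix(rnorm(5 * 3), 5, 3)
  r <- permutation_fwe(Y, d, n_perm = 500, seed = 1)  # 5! = 120 <= 500
  expect_true(r$exhaustive)
  expect_equal(r$n_perm, 120)
  # exhaustive results do not depend on the seed at all
  r2 <- permutation_fwe(Y, d, n_perm = 500, seed = 99)
  expect_identical(r$fwe_pval, r2$fwe_pval)
  expect_warning(permutation_fwe(Y, d, n_perm = 50, seed = 1),
                 "100 permutations")
})

test_that("the enhancement hook transforms the ranked statistic", {
  set.seed(42)
  d <- two_group_design(6)
  Y <- matrix(rnorm(12 * 10), 12, 10)
  # squaring is monotone on |t|: identical masks, identical p ordering
  r_id <- permutation_fwe(Y, d, n_perm = 200, seed = 5)
  r_sq <- permutation_fwe(Y, d, n_perm = 200, seed = 5,
                          enhance = function(t) t^2)
  expect_equal(order(r_id$fwe_pval), order(r_sq$fwe_pval))
})

test_that("make_synthetic_cohort scales the template by effect and noise", {
  tpl <- make_phantom(small_phantom_spec())
  # no effect, no noise: every subject equals the template
  ch <- make_synthetic_cohort(tpl, 3, effect = 1, noise_sd = 0, seed = 2)
  expect_length(ch$subjects, 6)
  for (g in ch$subjects)
    expect_equal(fixel_values(g, "fd"), fixel_values(tpl, "fd"))
  # group-mean ratio estimates the effect
  ch <- make_synthetic_cohort(tpl, 25, effect = 0.7, noise_sd = 0.1,
                              seed = 3)
  m1 <- rowMeans(sapply(ch$subjects[ch$group == 1],
                        fixel_values, name = "fd"))
  m2 <- rowMeans(sapply(ch$subjects[ch$group == 2],
                        fixel_values, name = "fd"))
  # lognormal noise biases the mean by exp(sd^2/2) in both groups equally
  expect_equal(mean(m2 / m1), 0.7, tolerance = 0.02)
  # determinism per seed
  ch2 <- make_synthetic_cohort(tpl, 25, effect = 0.7, noise_sd = 0.1,
                               seed = 3)
  expect_identical(fixel_values(ch$subjects[[7]], "fd"),
                   fixel_values(ch2$subjects[[7]], "fd"))
  ch3 <- make_synthetic_cohort(tpl, 25, effect = 0.7, noise_sd = 0.1,
                               seed = 4)
  expect_false(identical(fixel_values(ch$subjects[[7]], "fd"),
                         fixel_values(ch3$subjects[[7]], "fd")))
})

test_that("analyse_cohort finds nothing when groups are identical copies", {
  tpl <- make_phantom(phantom_spec(length_vox = 12, width_vox = 4,
                                   height_vox = 12))
  ch <- make_synthetic_cohort(tpl, 6, effect = 1, noise_sd = 0, seed = 5)
  # add microscopic jitter so variances are not exactly zero
  subjects <- lapply(seq_along(ch$subjects), function(i) {
    g <- ch$subjects[[i]]
    set.seed(1000 + i)
    fixel_values(g, "fd") <- fixel_values(g, "fd") +
      rnorm(n_fixels(g), sd = 1e-9)
    g
  })
  res <- analyse_cohort("fd", subjects, tpl, ch$design, n_perm = 200,
                        seed = 6)
  expect_equal(sum(res$result$sig_mask), 0)
  expect_identical(fixel_values(res$grid, "sig_mask"),
                   as.numeric(res$result$fwe_pval < 0.05))
})

test_that("analyse_cohort recovers a planted tract-specific FD deficit", {
  tpl <- make_phantom(phantom_spec(length_vox = 16, width_vox = 6,
                                   height_vox = 16))
  nf <- n_fixels(tpl)
  tract <- seq_len(nf) <= 24                  # a block of the bundle
  # 30% reduction, 10% between-subject noise: effect size d ~ 3
  effect <- ifelse(tract, 0.7, 1)
  ch <- make_synthetic_cohort(tpl, 12, effect = effect, noise_sd = 0.1,
                              seed = 7)
  res <- analyse_cohort("fd", ch$subjects, tpl, ch$design, n_perm = 500,
                        seed = 8)
  sig <- which(res$result$sig_mask)
  expect_gte(sum(sig %in% which(tract)), 0.8 * sum(tract))
  expect_true(all(sig %in% which(tract)))     # no false positives here
})

test_that("analyse_cohort names the subject missing a metric", {
  tpl <- make_phantom(small_phantom_spec())
  ch <- make_synthetic_cohort(tpl, 3, seed = 9)
  expect_error(analyse_cohort("fc", ch$subjects, tpl, ch$design,
                              n_perm = 100),
               "subject 1 is missing")
})

test_that("fdc analysis modulates fd by fc per subject", {
  tpl <- make_phantom(small_phantom_spec())
  ch <- make_synthetic_cohort(tpl, 4, effect = 1, noise_sd = 0.05,
                              seed = 10)
  subjects <- lapply(ch$subjects, function(g) {
    fixel_values(g, "fc") <- rep(1.25, n_fixels(g))
    g
  })
  Yfd <- t(sapply(subjects, fixel_values, name = "fd"))
  res <- analyse_cohort("fdc", subjects, tpl, ch$design, n_perm = 100,
                        seed = 11)
  # fdc with constant fc: t-statistics equal the fd analysis (scale
  # invariance of t)
  res_fd <- analyse_cohort("fd", subjects, tpl, ch$design, n_perm = 100,
                           seed = 11)
  expect_equal(res$result$tstat, res_fd$result$tstat, tolerance = 1e-9)
})
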