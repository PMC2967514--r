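# A spherical nucleus mask on an isotropic grid, used by the radial tests
make_sphere_mask <- function(R = 4, vx = c(0.2, 0.2, 0.2), margin = 0.6) {
  img <- render_ellipsoid(c(R, R, R), vx, margin = margin)
  segment_nuclei(voxel_grid(img, vx, "dapi"))[[1]]
}

test_that("radial_fraction is 0 at the center and near 1 at the outermost voxel", {
  nuc <- make_sphere_mask()
  expect_equal(radial_fraction(nuc$center, nuc), 0)
  # outermost mask voxel along +x
  idx <- which(nuc$mask, arr.ind = TRUE)
  far <- idx[which.max(idx[, 1]), ]
  p <- (far - 0.5) * nuc$voxel_size
  expect_gte(radial_fraction(p, nuc), 0.95)
})

test_that("radial_fraction matches the analytic fraction in a sphere", {
  nuc <- make_sphere_mask(R = 4)
  for (f in c(0.2, 0.45, 0.7)) {
    for (dir in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1) / sqrt(3))) {
      p <- nuc$center + f * 4 * dir
      expect_equal(radial_fraction(p, nuc), f, tolerance = 0.05)
    }
  }
})

test_that("a signal outside the mask is rejected, not clamped", {
  nuc <- make_sphere_mask(R = 3)
  expect_error(radial_fraction(nuc$center + c(3.5, 0, 0), nuc),
               class = "nucleoscape_outside_nucleus")
})

test_that("radial_fraction is invariant under isotropic scaling", {
  nuc1 <- make_sphere_mask(R = 3, vx = c(0.2, 0.2, 0.2), margin = 0.6)
  nuc2 <- make_sphere_mask(R = 6, vx = c(0.4, 0.4, 0.4), margin = 1.2)
  p1 <- nuc1$center + c(1.3, 0.7, -0.4)
  p2 <- nuc2$center + 2 * c(1.3, 0.7, -0.4)
  expect_equal(radial_fraction(p1, nuc1), radial_fraction(p2, nuc2),
               tolerance = 1e-12)
})

test_that("shell binning follows the five 20% shells with closed upper edge", {
  expect_identical(shell_index(c(0.1, 0.3, 0.5, 0.7, 0.9)), 1:5)
  expect_identical(shell_index(0.2), 2L)   # left-closed bins
  expect_identical(shell_index(1.0), 5L)   # 1.0 belongs to the outermost shell
  expect_identical(shell_index(0), 1L)
  expect_error(shell_index(1.2), "0, 1")
  h <- shell_histogram(c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_identical(unname(h$counts), rep(1L, 5))
  expect_identical(h$n, 5L)
})

test_that("shell histogram handles empty input and yields a valid ECDF", {
  h0 <- shell_histogram(numeric(0))
  expect_identical(sum(h0$counts), 0L)
  expect_true(is.na(h0$modal_shell))
  set.seed(2)
  h <- shell_histogram(runif(40))
  expect_identical(sum(h$counts), 40L)
  expect_true(all(diff(h$cum$cumulative) >= 0))
  expect_equal(h$cum$cumulative[40], 1)
})

test_that("peripheral laws produce a modal outermost shell", {
  set.seed(9)
  h <- shell_histogram(runif(120, 0.8, 1))
  expect_identical(h$modal_shell, 5L)
})

test_that("ks_compare matches a brute-force ECDF supremum", {
  set.seed(14)
  for (i in 1:20) {
    a <- runif(10); b <- runif(10)
    expect_equal(ks_compare(a, b)$D, ks_D_bruteforce(a, b), tolerance = 1e-12)
  }
  same <- c(0.2, 0.4, 0.6)
  res <- ks_compare(same, same)
  expect_equal(res$D, 0)
  expect_equal(res$p, 1)
  expect_equal(ks_compare(c(0.1, 0.2), c(0.8, 0.9))$D, 1)
  expect_error(ks_compare(numeric(0), c(0.5)), "at least one")
})

test_that("compare_counts reproduces the pooled-z closed form", {
  res0 <- compare_counts(c(5, 7), c(7, 5))
  expect_equal(res0$z, 0)
  expect_equal(res0$p, 1)
  # group A: 120 objects / 10 nuclei, B: 60 / 10
  a <- rep(12, 10); b <- rep(6, 10)
  res <- compare_counts(a, b)
  pooled <- (120 + 60) / 20
  z_hand <- (12 - 6) / sqrt(pooled * (1 / 10 + 1 / 10))
  expect_equal(res$z, z_hand)
  expect_equal(res$p, 2 * pnorm(-abs(z_hand)))
  # 10-fold rate difference with 50 nuclei per group
  set.seed(6)
  res2 <- compare_counts(rpois(50, 10), rpois(50, 1))
  expect_lt(res2$p, 0.001)
  expect_error(compare_counts(integer(0), c(1, 2)), "at least one")
})

test_that("compare_means agrees with the Welch closed form", {
  expect_equal(compare_means(c(1, 2, 3), c(1, 2, 3))$p, 1)
  a <- c(19.8, 23.4, 21.1, 20.0, 22.5, 24.1)
  b <- c(28.2, 26.9, 25.4, 30.1, 27.7)
  res <- compare_means(a, b)
  # independent closed-form evaluation
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  expect_equal(res$t, t_hand)
  expect_equal(res$df, df_hand)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df_hand))
  expect_error(compare_means(1, c(1, 2)), "at least two")
})

test_that("condition means of 8 vs 6 um^3 at 30% sd are separable at n = 500", {
  set.seed(12)
  sdl <- sqrt(log(1 + 0.09))
  a <- rlnorm(500, log(8) - sdl^2 / 2, sdl)
  b <- rlnorm(500, log(6) - sdl^2 / 2, sdl)
  expect_lt(compare_means(a, b)$p, 0.05)
})

test_that("summarize_condition aggregates counts, volumes and intensities", {
  nuclei <- data.frame(nucleus_id = 1L, volume = 250, condition = "control")
  objects <- data.frame(nucleus_id = c(1L, 1L), volume = c(3, 5),
                        mean_intensity = c(90, 110), condition = "control")
  s <- summarize_condition(objects, nuclei, "control")
  expect_equal(s$mean_volume, 4)
  expect_equal(s$se_volume, 1)
  expect_equal(s$objects_per_nucleus, 2)
  expect_equal(s$mean_nuclear_volume, 250)

  s0 <- summarize_condition(objects[0, ], nuclei, "control")
  expect_equal(s0$n_objects, 0L)
  expect_true(is.na(s0$mean_volume))
  expect_error(summarize_condition(objects, nuclei, "absent"), "not present")
})

test_that("splitting conserved chromocenter material raises counts and lowers volumes", {
  # same total heterochromatin: 3 x 8 um^3 vs 6 x 4 um^3 per nucleus
  cfg_a <- generation_config(n_nuclei = 12, seed = 41, nucleus_cv = 0,
                             chromocenter_count_law = list(law = "fixed", mean = 3),
                             chromocenter_volume_law = list(law = "lognormal", mean = 8, sd = 2.4))
  cfg_b <- generation_config(n_nuclei = 12, seed = 42, nucleus_cv = 0,
                             chromocenter_count_law = list(law = "fixed", mean = 6),
                             chromocenter_volume_law = list(law = "lognormal", mean = 4, sd = 1.2))
  qa <- quantify_dataset(generate_nuclei_dataset(cfg_a), condition = "control")
  qb <- quantify_dataset(generate_nuclei_dataset(cfg_b), condition = "scattered")
  sa <- summarize_condition(qa$objects, qa$nuclei, "control")
  sb <- summarize_condition(qb$objects, qb$nuclei, "scattered")
  expect_gt(sb$objects_per_nucleus, sa$objects_per_nucleus)
  expect_lt(sb$mean_volume, sa$mean_volume)
  # nuclear volume unchanged (same geometry set point)
  expect_lt(abs(sb$mean_nuclear_volume - sa$mean_nuclear_volume) /
              sa$mean_nuclear_volume, 0.05)
})
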