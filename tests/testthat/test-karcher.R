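test_that("arc-length resampling is idempotent and symmetric", {
  # an equal-arc 32-point circle starting at the top resamples to itself
  th <- pi / 2 + 2 * pi * (0:31) / 32
  circ <- as_outline(cbind(cos(th), sin(th)))
  rs <- resample_outline(circ, 32)
  expect_equal(unclass(rs), unclass(circ), tolerance = 1e-9)
  # k = 16 on a dense circle gives a regular 16-gon
  g16 <- resample_outline(regular_ngon(4096), 16)
  seg <- sqrt(diff(c(g16[, 1], g16[1, 1]))^2 + diff(c(g16[, 2], g16[1, 2]))^2)
  expect_lt(diff(range(seg)) / mean(seg), 1e-4)
  expect_equal(unname(g16[1, 2]), max(g16[, 2]), tolerance = 1e-6)
})

test_that("resampling preserves total arc length on smooth outlines", {
  ell <- ellipse_outline(a = 1, b = 0.5, n = 4096)
  rs <- resample_outline(ell, 200)
  expect_equal(poly_perimeter(rs), ellipse_perimeter_exact(1, 0.5),
               tolerance = 0.005)
})

test_that("alignment recovers rotations, refuses reflections", {
  o <- resample_outline(cladescan:::keyhole_profile_outline(1, 1.7, 0.35, 0.15, 300),
                        128)
  o <- as_outline(sweep(o, 2, poly_centroid(o)))
  self <- cladescan:::align_one(o, o)
  expect_lt(self$residual, 1e-12)
  expect_equal(self$roll, 0)
  rot <- as_outline(cladescan:::rotate_points(o, 0.6))
  al <- cladescan:::align_one(rot, o)
  expect_lt(al$residual, 1e-12)
  # an asymmetric shape cannot be aligned to its mirror image
  scalene <- resample_outline(as_outline(rbind(c(0, 0), c(4, 0.3), c(2.7, 2.2),
                                               c(0.6, 1.1))), 64)
  mirror <- as_outline(cbind(-scalene[, 1], scalene[, 2]))
  expect_gt(cladescan:::align_one(mirror, scalene)$residual, 1e-3)
  expect_error(align_set(list(o), resample_outline(o, 64)), "same number")
})

# normalization-stable template: normalizing again after resampling makes
# the final renormalization inside karcher_mean an exact identity
stable_template <- function(p = 0.4, k = 100) {
  normalize_outline(resample_outline(normalize_outline(
    cladescan:::keyhole_profile_outline(1, 1.8, p, 0.15, 300)), k))
}

test_that("karcher mean of identical shapes is that shape", {
  o <- stable_template()
  km <- karcher_mean(list(o, o, o), tol = 1e-8)
  expect_true(km$converged)
  al <- cladescan:::align_one(km$mean_outline, o)
  expect_lt(al$residual / 100, 1e-10)
})

test_that("karcher mean of symmetric rotations recovers the template", {
  o <- stable_template()
  plus <- as_outline(cladescan:::rotate_points(o, 10 * pi / 180))
  minus <- as_outline(cladescan:::rotate_points(o, -10 * pi / 180))
  km <- karcher_mean(list(plus, minus), tol = 1e-9, max_iter = 200)
  al <- cladescan:::align_one(km$mean_outline, o)
  expect_lt(sqrt(al$residual / 100), 1e-4)
  expect_true(all(diff(km$objective_trace) <= 1e-15))
})

test_that("karcher mean is invariant to input order and global rigid motion", {
  set.seed(5)
  os <- lapply(1:6, function(i) {
    resample_outline(normalize_outline(cladescan:::fourier_jitter(
      cladescan:::keyhole_profile_outline(1, 1.8, 0.3, 0.15, 300), 0.02)), 100)
  })
  km1 <- karcher_mean(os, tol = 1e-9)
  km2 <- karcher_mean(rev(os), tol = 1e-9)
  expect_lt(cladescan:::align_one(km2$mean_outline, km1$mean_outline)$residual,
            1e-8)
  moved <- lapply(os, function(o) {
    as_outline(sweep(cladescan:::rotate_points(o, 0.8), 2, c(3, -1), "+"))
  })
  km3 <- karcher_mean(moved, tol = 1e-9)
  expect_lt(cladescan:::align_one(km3$mean_outline, km1$mean_outline)$residual,
            1e-8)
})

test_that("landmark widths of any ellipse follow the 0.8660 cross-section rule", {
  for (ab in list(c(1, 0.5), c(2, 1.99), c(3, 0.4))) {
    o <- normalize_outline(ellipse_outline(ab[1], ab[2], n = 4096))
    lw <- landmark_widths(o)
    expect_equal(lw$width_25 / lw$width_50, sqrt(3) / 2, tolerance = 1e-3)
    expect_equal(lw$width_75 / lw$width_50, sqrt(3) / 2, tolerance = 1e-3)
    expect_true(all(lw$multiplicity == 2))
    # landmarks lie on the requested levels, symmetric about the axis
    expect_equal(lw$landmarks["left_50", "x"], -lw$landmarks["right_50", "x"],
                 tolerance = 1e-3)
  }
  # circle: central width equals the diameter (major axis = 1 normalized)
  lw <- landmark_widths(normalize_outline(regular_ngon(2048)))
  expect_equal(lw$width_50, 1, tolerance = 1e-3)
})

test_that("the planted pinch yields the 1.425 quartile/central ratio", {
  p <- solve_pinch_for_ratio(1.425)
  o <- normalize_outline(cladescan:::keyhole_profile_outline(1, 1.8, p, 0.15, 500))
  lw <- landmark_widths(o)
  expect_equal(mean(c(lw$width_25, lw$width_75)) / lw$width_50, 1.425,
               tolerance = 0.01)
})

test_that("clade contrast arithmetic", {
  rep_s <- list(minor_axis_width = 0.5, width_25 = 0.3, width_50 = 0.35,
                width_75 = 0.3)
  expect_equal(clade_contrast(rep_s, rep_s)$pct_minor_axis_narrower, 0)
  rep_n <- rep_s
  rep_n$minor_axis_width <- 0.88 * rep_s$minor_axis_width
  cc <- clade_contrast(rep_n, rep_s)
  expect_equal(cc$pct_minor_axis_narrower, 12, tolerance = 1e-12)
  expect_equal(cc$quartile_over_central_ratio_N,
               cc$quartile_over_central_ratio_S)
  bad <- rep_s; bad$width_50 <- 0
  expect_error(clade_contrast(bad, rep_s), "zero widths")
})
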