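test_that("pinch-free symmetric keyhole profile is a circle", {
  out <- cladescan:::keyhole_profile_outline(2, 2, 0, 0.15, 400)
  r <- sqrt(out[, 1]^2 + (out[, 2] - 1)^2)
  expect_true(all(abs(r - 1) < 1e-9))
})

test_that("solve_pinch_for_ratio inverts the width-profile ratio", {
  # independent oracle: evaluate the half-width profile numerically
  ratio_of <- function(p, sigma = 0.15) {
    hw <- function(h) sqrt(pmax(0, 1 - (2 * h - 1)^2)) *
      (1 - p * exp(-(h - 0.5)^2 / (2 * sigma^2)))
    mean(c(hw(0.25), hw(0.75))) / hw(0.5)
  }
  expect_equal(solve_pinch_for_ratio(sqrt(3) / 2), 0)
  p1 <- solve_pinch_for_ratio(1.425)
  expect_equal(p1, 0.4623, tolerance = 1e-3)
  expect_equal(ratio_of(p1), 1.425, tolerance = 1e-9)
  p2 <- solve_pinch_for_ratio(1.0)
  expect_equal(ratio_of(p2), 1.0, tolerance = 1e-9)
  expect_equal(p2, 0.17087, tolerance = 1e-4)
  expect_error(solve_pinch_for_ratio(0.5), "not reachable")
})

test_that("keyhole_like preset plants a 12% fitted minor-axis contrast", {
  cfg <- generator_config("keyhole_like", n_per_clade = 4, seed = 1)
  pn <- cladescan:::keyhole_clade_params(cfg, "Northern")
  ps <- cladescan:::keyhole_clade_params(cfg, "Southern")
  fit_ba <- function(par) {
    f <- ellipse_fit(cladescan:::keyhole_profile_outline(par$W, par$H, par$p,
                                                         cfg$pinch_sigma, 400))
    f$b / f$a
  }
  expect_equal(100 * (1 - fit_ba(pn) / fit_ba(ps)), 12, tolerance = 0.05)
  # quartile/central ratio of the Northern profile is the planted 1.425
  lw <- landmark_widths(normalize_outline(
    cladescan:::keyhole_profile_outline(pn$W, pn$H, pn$p, cfg$pinch_sigma, 400)))
  expect_equal(mean(c(lw$width_25, lw$width_75)) / lw$width_50, 1.425,
               tolerance = 1e-3)
})

test_that("planted-effect monotonicity: stronger pinch raises the width ratio", {
  ratios <- vapply(c(0, 0.15, 0.3, 0.45, 0.6), function(p) {
    lw <- landmark_widths(normalize_outline(
      cladescan:::keyhole_profile_outline(1, 1.8, p, 0.15, 400)))
    mean(c(lw$width_25, lw$width_75)) / lw$width_50
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("outline generators are deterministic and produce valid outlines", {
  cfg <- generator_config("keyhole_like", n_per_clade = 4, seed = 1)
  k1 <- generate_keyhole_outline(cfg, "Northern", seed = 7)
  k2 <- generate_keyhole_outline(cfg, "Northern", seed = 7)
  expect_identical(k1, k2)
  s1 <- generate_shell_outline(cfg, "Southern", seed = 7)
  s2 <- generate_shell_outline(cfg, "Southern", seed = 7)
  expect_identical(s1, s2)
  for (o in list(k1, s1)) {
    expect_gte(nrow(o), 3)
    expect_gt(poly_area(o), 0)
    expect_true(cladescan:::poly_is_simple(o))
  }
})

test_that("unperturbed shell outline is a circle; ridges lower solidity", {
  cfg0 <- generator_config("keyhole_like", n_per_clade = 4, seed = 1,
                           ridge_amp_N = 0, ridge_amp_S = 0)
  cfg0$shell_harmonic_sd <- 0
  s <- generate_shell_outline(cfg0, "Northern", seed = 3)
  ctr <- poly_centroid(s)
  r <- sqrt((s[, 1] - ctr[1])^2 + (s[, 2] - ctr[2])^2)
  expect_lt(diff(range(r)) / mean(r), 1e-9)
  # Monte-Carlo: Northern (large-ridge) mean solidity below Southern, with
  # solidity computed through an independent convex-hull oracle
  cfg <- generator_config("ridge_like", n_per_clade = 4, seed = 1)
  sol <- function(clade, seed) {
    o <- generate_shell_outline(cfg, clade, seed = seed)
    hull <- o[chull(o[, 1], o[, 2]), ]
    abs(poly_area(o)) / abs(poly_area(hull))
  }
  sn <- vapply(1:100, function(i) sol("Northern", i), numeric(1))
  ss <- vapply(1:100, function(i) sol("Southern", 1000 + i), numeric(1))
  expect_lt(mean(sn), mean(ss))
})

test_that("rejected configurations raise informative errors", {
  expect_error(generator_config("keyhole_like", pinch_S = 1.2), "pinch_S")
  expect_error(generator_config("keyhole_like", keyhole_width_S = -1),
               "keyhole_width_S")
  expect_error(generator_config("keyhole_like", n_per_clade = 2,
                                n_locations_per_clade = 5), "n_locations")
  expect_error(cladescan:::keyhole_profile_outline(1, 1, 1.0001, 0.15),
               "pinch")
})

test_that("render_specimen produces consistent image and masks", {
  cfg <- generator_config("keyhole_like", n_per_clade = 4, image_size = 64,
                          seed = 1)
  sh <- generate_shell_outline(cfg, "Northern", seed = 5)
  kh <- generate_keyhole_outline(cfg, "Northern", seed = 6)
  r1 <- render_specimen(sh, kh, cfg, "Northern", seed = 9)
  r2 <- render_specimen(sh, kh, cfg, "Northern", seed = 9)
  expect_identical(r1, r2)
  expect_true(all(r1$image >= 0 & r1$image <= 1))
  # masks match the rasterized outline areas within 2%
  expect_equal(sum(r1$shell_mask), abs(poly_area(sh)), tolerance = 0.02)
  expect_equal(sum(r1$keyhole_mask), abs(poly_area(kh)), tolerance = 0.02)
  expect_true(all(r1$shell_mask[r1$keyhole_mask > 0] == 1))
  # an outline poking out of the frame is scaled back in with a warning
  big <- as_outline(sweep(sweep(sh, 2, c(32.5, 32.5)), 2, c(3, 3), "*") +
                      matrix(32.5, nrow(sh), 2))
  expect_warning(rb <- render_specimen(big, NULL, cfg, "Northern", seed = 1),
                 "frame")
  expect_true(all(rowSums(rb$shell_mask)[c(1, 64)] == 0))
})

test_that("generate_dataset writes a complete, reproducible dataset", {
  d1 <- small_dataset("keyhole_like", n = 6, image_size = 48, seed = 21)
  expect_equal(nrow(d1), 12)
  expect_true(all(file.exists(d1$image_path)))
  expect_true(all(file.exists(d1$mask_path)))
  expect_true(all(file.exists(d1$keyhole_mask_path)))
  md <- readr::read_csv(file.path(dirname(dirname(d1$image_path[1])),
                                  "metadata.csv"), show_col_types = FALSE)
  expect_identical(names(md),
                   c("specimen_id", "species", "clade", "location",
                     "orientation", "image_path", "mask_path",
                     "keyhole_mask_path", "major_axis_mm"))
  expect_setequal(unique(d1$clade), c("Northern", "Southern"))
  # regenerating with the same config gives byte-identical metadata
  dir2 <- file.path(tempdir(), "ds_repro")
  generate_dataset(generator_config("keyhole_like", n_per_clade = 6,
                                    image_size = 48, seed = 21), dir2)
  f1 <- file.path(dirname(dirname(d1$image_path[1])), "metadata.csv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(file.path(dir2, "metadata.csv"), "raw",
                           file.size(file.path(dir2, "metadata.csv"))))
})

test_that("clade size distributions overlap (no planted size signal)", {
  for (preset in c("keyhole_like", "weak_signal_like")) {
    d <- small_dataset(preset, n = 30, image_size = 32, seed = 31)
    rn <- range(d$major_axis_mm[d$clade == "Northern"])
    rs <- range(d$major_axis_mm[d$clade == "Southern"])
    expect_true(rn[1] < rs[2] && rs[1] < rn[2])
    ut <- mann_whitney_u(d$major_axis_mm[d$clade == "Northern"],
                         d$major_axis_mm[d$clade == "Southern"])
    expect_gt(ut$p_value, 0.05)
  }
})
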