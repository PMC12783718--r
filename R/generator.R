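#' Generator configuration for synthetic shell images
#'
#' Builds the full parameter set for the synthetic-data generator. The
#' generator emulates standardized photographs of limpet shells from two
#' genetically defined clades (Northern/Southern): a roughly circular shell
#' disc with low-order harmonic irregularity and radial ridge bumps, and --
#' for keyhole-bearing forms -- an elongated apical aperture whose Northern
#' form is narrower along the fitted minor axis and centrally pinched.
#'
#' Presets plant clade contrasts of different kinds and strengths:
#' \describe{
#'   \item{keyhole_like}{strong keyhole contrast: Northern fitted minor axis
#'     12\% narrower and quartile/central width ratio 1.425 (pinch solved by
#'     [solve_pinch_for_ratio()]); shells otherwise identical.}
#'   \item{ridge_like}{shell-outline contrast: Northern ridge bumps larger
#'     (lower solidity/extent); keyholes identical.}
#'   \item{weak_signal_like}{keyhole contrasts reduced to 25\% of
#'     `keyhole_like`, a deliberately weak-signal regime.}
#'   \item{band_like}{concentric intensity-band contrast (texture, not
#'     outline); shapes identical between clades.}
#' }
#'
#' The Northern keyhole width is calibrated so that the *measured*
#' moment-ellipse minor axis of the noise-free Northern profile is exactly
#' `(1 - keyhole_narrowing)` times the Southern one: the central pinch by
#' itself shrinks the fitted minor axis, so planting the narrowing on the raw
#' width would confound the two planted effects (see the methods vignette).
#'
#' @param species_preset one of `"keyhole_like"`, `"ridge_like"`,
#'   `"weak_signal_like"`, `"band_like"`.
#' @param n_per_clade specimens per clade.
#' @param n_locations_per_clade sampling locations per clade.
#' @param image_size square image side in pixels.
#' @param keyhole_width_S Southern mean keyhole width as a fraction of image
#'   width.
#' @param keyhole_narrowing planted fractional reduction of the Northern
#'   keyhole's fitted minor axis (default 0.12).
#' @param pinch_N,pinch_S central pinch amplitude per clade, in `[0, 1)`.
#'   `pinch_N = NULL` (default) solves for the preset's planted
#'   quartile/central width ratio.
#' @param pinch_sigma pinch Gaussian width as a fraction of keyhole height.
#' @param keyhole_aspect keyhole height / width.
#' @param ridge_count number of radial ridge bumps on the shell outline.
#' @param ridge_amp_N,ridge_amp_S ridge bump amplitude per clade (fraction of
#'   shell radius).
#' @param fourier_noise_sd per-specimen low-order Fourier boundary jitter
#'   (radial, relative).
#' @param shape_jitter_sdlog per-specimen lognormal jitter on keyhole width
#'   and height.
#' @param pinch_jitter_sd per-specimen Gaussian jitter on the pinch
#'   amplitude.
#' @param size_mean_mm,size_sd_mm per-clade normal parameters of the shell
#'   major-axis length in mm; scalars are recycled to both clades (the
#'   default: size distributions overlap completely, carrying no clade
#'   signal).
#' @param band_amp_N,band_amp_S concentric band intensity amplitude per
#'   clade.
#' @param texture_sd pixel-level Gaussian texture noise inside the shell.
#' @param seed integer seed controlling the whole dataset.
#' @return a `generator_config` list.
#' @export
generator_config <- function(species_preset = c("keyhole_like", "ridge_like",
                                                "weak_signal_like", "band_like"),
                             n_per_clade = 200L,
                             n_locations_per_clade = 3L,
                             image_size = 128L,
                             keyhole_width_S = 0.18,
                             keyhole_narrowing = NULL,
                             pinch_N = NULL,
                             pinch_S = 0,
                             pinch_sigma = 0.15,
                             keyhole_aspect = 1.8,
                             ridge_count = 9L,
                             ridge_amp_N = NULL,
                             ridge_amp_S = NULL,
                             fourier_noise_sd = 0.01,
                             shape_jitter_sdlog = 0.06,
                             pinch_jitter_sd = 0.04,
                             size_mean_mm = 18.3,
                             size_sd_mm = 2.5,
                             band_amp_N = NULL,
                             band_amp_S = NULL,
                             texture_sd = 0.03,
                             seed = 1L) {
  species_preset <- match.arg(species_preset)
  full_pinch <- solve_pinch_for_ratio(1.425, pinch_sigma)
  defaults <- switch(species_preset,
    keyhole_like = list(narrow = 0.12, pinch = full_pinch,
                        ridge_N = 0.02, ridge_S = 0.02,
                        band_N = 0.06, band_S = 0.06),
    # weak-signal regime: all clade contrasts at 25% of keyhole_like
    weak_signal_like = list(narrow = 0.25 * 0.12, pinch = 0.25 * full_pinch,
                            ridge_N = 0.02, ridge_S = 0.02,
                            band_N = 0.06, band_S = 0.06),
    ridge_like = list(narrow = 0, pinch = 0,
                      ridge_N = 0.07, ridge_S = 0.02,
                      band_N = 0.06, band_S = 0.06),
    band_like = list(narrow = 0, pinch = 0,
                     ridge_N = 0.02, ridge_S = 0.02,
                     band_N = 0.20, band_S = 0.07))
  cfg <- list(
    species_preset = species_preset,
    n_per_clade = as.integer(n_per_clade),
    n_locations_per_clade = as.integer(n_locations_per_clade),
    image_size = as.integer(image_size),
    keyhole_width_S = keyhole_width_S,
    keyhole_narrowing = if (is.null(keyhole_narrowing)) defaults$narrow else keyhole_narrowing,
    pinch_N = if (is.null(pinch_N)) defaults$pinch else pinch_N,
    pinch_S = pinch_S,
    pinch_sigma = pinch_sigma,
    keyhole_aspect = keyhole_aspect,
    ridge_count = as.integer(ridge_count),
    ridge_amp_N = if (is.null(ridge_amp_N)) defaults$ridge_N else ridge_amp_N,
    ridge_amp_S = if (is.null(ridge_amp_S)) defaults$ridge_S else ridge_amp_S,
    fourier_noise_sd = fourier_noise_sd,
    shape_jitter_sdlog = shape_jitter_sdlog,
    pinch_jitter_sd = pinch_jitter_sd,
    size_mean_mm = rep(size_mean_mm, length.out = 2),
    size_sd_mm = rep(size_sd_mm, length.out = 2),
    band_amp_N = if (is.null(band_amp_N)) defaults$band_N else band_amp_N,
    band_amp_S = if (is.null(band_amp_S)) defaults$band_S else band_amp_S,
    texture_sd = texture_sd,
    shell_harmonic_sd = 0.025,
    shell_intensity = 0.55,
    keyhole_intensity = 0.07,
    seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_per_clade >= 1, cfg$image_size >= 16)
  if (cfg$n_per_clade < cfg$n_locations_per_clade) {
    stop("n_per_clade must be >= n_locations_per_clade", call. = FALSE)
  }
  for (p in c("pinch_N", "pinch_S")) {
    if (cfg[[p]] < 0 || cfg[[p]] >= 1) {
      stop("rejected configuration: ", p, " must lie in [0, 1)", call. = FALSE)
    }
  }
  for (p in c("keyhole_width_S", "pinch_sigma", "keyhole_aspect")) {
    if (cfg[[p]] <= 0) {
      stop("rejected configuration: ", p, " must be positive", call. = FALSE)
    }
  }
  if (cfg$keyhole_narrowing < 0 || cfg$keyhole_narrowing >= 1) {
    stop("rejected configuration: keyhole_narrowing must lie in [0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' Solve the pinch amplitude producing a target quartile/central width ratio
#'
#' The noise-free keyhole half-width profile is
#' `hw(h) = (W/2) sqrt(1 - (2h/H - 1)^2) (1 - p exp(-(h - H/2)^2 / (2 sigma^2)))`.
#' Its mean quartile-to-central width ratio is
#' `sqrt(3)/2 * (1 - q p) / (1 - p)` with `q = exp(-(1/4)^2 / (2 sigma^2))`
#' (`sigma` as a fraction of the height `H`), linear in `p`; this inverts it.
#'
#' @param target_ratio desired `mean(width_25, width_75) / width_50`.
#' @param pinch_sigma pinch Gaussian width as a fraction of keyhole height.
#' @return the pinch amplitude `p` in `[0, 1)`.
#' @export
#' @examples
#' solve_pinch_for_ratio(1.425)      # ~0.4623, the strong-pinch default
#' solve_pinch_for_ratio(sqrt(3)/2)  # 0: the pure-ellipse ratio
solve_pinch_for_ratio <- function(target_ratio, pinch_sigma = 0.15) {
  s32 <- sqrt(3) / 2
  q <- exp(-(1 / 4)^2 / (2 * pinch_sigma^2))
  p <- (target_ratio - s32) / (target_ratio - s32 * q)
  if (!is.finite(p) || p < 0 || p >= 1) {
    stop("target ratio ", target_ratio, " is not reachable with p in [0, 1)",
         call. = FALSE)
  }
  p
}

# Noise-free keyhole profile outline in local coordinates (centered on x = 0,
# y from 0 to H), counter-clockwise, built from the half-width formula.
keyhole_profile_outline <- function(W, H, p, sigma_frac, n_side = 120L) {
  if (W <= 0 || H <= 0) stop("rejected configuration: keyhole width/height must be positive", call. = FALSE)
  # p < 0 (a central bulge) is geometrically valid and occurs for jittered
  # draws around a zero-pinch clade mean; p >= 1 would close the waist
  if (p <= -1 || p >= 1) stop("rejected configuration: pinch amplitude must lie in (-1, 1)", call. = FALSE)
  h <- seq(0, H, length.out = n_side)
  hw <- (W / 2) * sqrt(pmax(0, 1 - (2 * h / H - 1)^2)) *
    (1 - p * exp(-(h - H / 2)^2 / (2 * (sigma_frac * H)^2)))
  pts <- rbind(cbind(hw, h),                                   # up the right side
               cbind(-rev(hw[-c(1, n_side)]), rev(h[-c(1, n_side)])))  # down the left
  as_outline(pts)
}

# Shrink factor of the fitted minor/major ratio caused by a pinch of
# amplitude p (relative to the unpinched profile at the same W, H). Used to
# plant keyhole_narrowing in measurement space.
pinch_minor_shrink <- function(p, sigma_frac, aspect) {
  if (p == 0) return(1)
  ba <- function(pp) {
    f <- ellipse_fit(keyhole_profile_outline(1, aspect, pp, sigma_frac, 400L))
    f$b / f$a
  }
  ba(p) / ba(0)
}

# Clade-level mean keyhole parameters (widths in pixels).
keyhole_clade_params <- function(config, clade) {
  W_S <- config$keyhole_width_S * config$image_size
  if (clade == "Southern") {
    list(W = W_S, H = config$keyhole_aspect * W_S, p = config$pinch_S)
  } else {
    f_S <- pinch_minor_shrink(config$pinch_S, config$pinch_sigma, config$keyhole_aspect)
    f_N <- pinch_minor_shrink(config$pinch_N, config$pinch_sigma, config$keyhole_aspect)
    W_N <- (1 - config$keyhole_narrowing) * W_S * f_S / f_N
    list(W = W_N, H = config$keyhole_aspect * W_S, p = config$pinch_N)
  }
}

# Low-order radial Fourier jitter applied about the centroid.
fourier_jitter <- function(outline, sd, orders = 2:5) {
  if (sd <= 0) return(outline)
  ctr <- poly_centroid(outline)
  dx <- outline[, 1] - ctr[1]; dy <- outline[, 2] - ctr[2]
  th <- atan2(dy, dx)
  f <- rep(1, length(th))
  for (k in orders) {
    f <- f + rnorm(1, 0, sd / k) * cos(k * th + runif(1, 0, 2 * pi))
  }
  as_outline(cbind(ctr[1] + dx * f, ctr[2] + dy * f))
}

#' Generate one synthetic keyhole outline
#'
#' Draws per-specimen keyhole width, height and pinch from clade-specific
#' distributions, evaluates the half-width profile, and adds seeded low-order
#' Fourier boundary jitter. The outline is returned in image coordinates,
#' centered on the image center.
#'
#' @param config a [generator_config()].
#' @param clade `"Northern"` or `"Southern"`.
#' @param seed optional integer; if `NULL` the current RNG stream is used.
#' @return an [as_outline()] polygon.
#' @export
generate_keyhole_outline <- function(config, clade = c("Northern", "Southern"),
                                     seed = NULL) {
  clade <- match.arg(clade)
  with_seed(seed, {
    par <- keyhole_clade_params(config, clade)
    W <- par$W * rlnorm(1, 0, config$shape_jitter_sdlog)
    H <- par$H * rlnorm(1, 0, config$shape_jitter_sdlog)
    p <- min(max(par$p + rnorm(1, 0, config$pinch_jitter_sd), -0.95), 0.95)
    out <- keyhole_profile_outline(W, H, p, config$pinch_sigma)
    out <- fourier_jitter(out, config$fourier_noise_sd)
    ctr <- c(config$image_size / 2 + 0.5, config$image_size / 2 + 0.5)
    pc <- poly_centroid(out)
    out <- as_outline(cbind(out[, 1] - pc[1] + ctr[1], out[, 2] - pc[2] + ctr[2]))
    if (!poly_is_simple(out)) {
      stop("rejected configuration: pinch/noise parameters produced a ",
           "self-intersecting keyhole outline", call. = FALSE)
    }
    out
  })
}

#' Generate one synthetic shell outline
#'
#' Radial model `r(theta) = R (1 + sum_k a_k cos(k theta + phi_k) + ridges)`
#' sampled at 256 angles, where the harmonic amplitudes are per-specimen
#' noise and the ridge bumps are narrow positive Gaussian bumps in `theta`
#' whose amplitude is the clade's `ridge_amp`. Returned in image coordinates,
#' scaled by the specimen's size factor.
#'
#' @inheritParams generate_keyhole_outline
#' @param size_factor multiplicative shell radius factor (1 = the preset's
#'   average size).
#' @return an [as_outline()] polygon.
#' @export
generate_shell_outline <- function(config, clade = c("Northern", "Southern"),
                                   size_factor = 1, seed = NULL) {
  clade <- match.arg(clade)
  with_seed(seed, {
    R <- 0.36 * config$image_size * size_factor
    amp <- if (clade == "Northern") config$ridge_amp_N else config$ridge_amp_S
    amp <- amp * rlnorm(1, 0, 0.2)
    th <- seq(0, 2 * pi, length.out = 257L)[-257L]
    r <- rep(1, length(th))
    for (k in 2:6) {
      r <- r + rnorm(1, 0, config$shell_harmonic_sd / sqrt(k)) *
        cos(k * th + runif(1, 0, 2 * pi))
    }
    if (config$ridge_count > 0 && amp > 0) {
      centers <- runif(1, 0, 2 * pi) + 2 * pi * seq_len(config$ridge_count) /
        config$ridge_count
      sig <- 0.25 * 2 * pi / config$ridge_count
      for (ctheta in centers) {
        d <- (th - ctheta + pi) %% (2 * pi) - pi   # wrapped angular distance
        r <- r + amp * exp(-d^2 / (2 * sig^2))
      }
    }
    if (any(r <= 0)) {
      stop("rejected configuration: harmonic/ridge amplitudes drove the ",
           "shell radius non-positive", call. = FALSE)
    }
    ctr <- config$image_size / 2 + 0.5
    as_outline(cbind(ctr + R * r * cos(th), ctr + R * r * sin(th)))
  })
}

#' Render one specimen to an image and binary masks
#'
#' Anti-aliased (2x2 supersampled) filled rendering of the shell on a black
#' background, with seeded pixel texture noise inside the shell, concentric
#' intensity bands whose amplitude is the clade's `band_amp`, and a dark
#' keyhole aperture. Masks are binary (pixel-center rasterization of the
#' outlines).
#'
#' @param shell shell outline in image coordinates.
#' @param keyhole keyhole outline or `NULL`.
#' @param config a [generator_config()].
#' @param clade clade label (selects the band amplitude).
#' @param seed optional integer seed for the texture noise.
#' @return list with `image` (numeric matrix in `[0, 1]`), `shell_mask` and
#'   `keyhole_mask` (0/1 integer matrices; `keyhole_mask` is `NULL` when no
#'   keyhole outline is given).
#' @export
render_specimen <- function(shell, keyhole, config, clade = "Southern", seed = NULL) {
  n <- config$image_size
  shrink_into_frame <- function(out) {
    lim <- range(out)
    if (lim[1] < 1 || lim[2] > n) {
      warning("outline exceeds the image frame; scaling to fit")
      ctr <- poly_centroid(out)
      reach <- pmax(abs(out[, 1] - ctr[1]), abs(out[, 2] - ctr[2]))
      allow <- min(ctr - 1, n - ctr)
      sc <- 0.96 * allow / max(reach)
      out <- as_outline(cbind(ctr[1] + sc * (out[, 1] - ctr[1]),
                              ctr[2] + sc * (out[, 2] - ctr[2])))
    }
    out
  }
  shell <- shrink_into_frame(shell)
  if (!is.null(keyhole)) keyhole <- shrink_into_frame(keyhole)
  with_seed(seed, {
    cover <- polygon_raster(shell, n, n, ss = 2L)
    shell_mask <- polygon_raster(shell, n, n, ss = 1L)
    band_amp <- if (clade == "Northern") config$band_amp_N else config$band_amp_S
    ctr <- poly_centroid(shell)
    rr <- sqrt(outer((seq_len(n) - ctr[2])^2, (seq_len(n) - ctr[1])^2, "+"))
    period <- 0.09 * n * runif(1, 0.9, 1.1)
    base <- config$shell_intensity *
      (1 + band_amp * sin(2 * pi * rr / period + runif(1, 0, 2 * pi)))
    img <- base * cover
    img <- img + (cover > 0) * matrix(rnorm(n * n, 0, config$texture_sd), n, n)
    keyhole_mask <- NULL
    if (!is.null(keyhole)) {
      kcover <- polygon_raster(keyhole, n, n, ss = 2L)
      img <- img * (1 - kcover) + config$keyhole_intensity * kcover
      keyhole_mask <- polygon_raster(keyhole, n, n, ss = 1L)
    }
    img <- pmin(pmax(img, 0), 1)
    list(image = img,
         shell_mask = shell_mask + 0,
         keyhole_mask = if (is.null(keyhole_mask)) NULL else keyhole_mask + 0)
  })
}

#' Generate a complete labeled synthetic dataset
#'
#' Writes `n_per_clade * 2` specimens (images, shell masks, keyhole masks as
#' PNG; metadata as CSV) under `out_dir`, fully reproducible from
#' `config$seed`. Specimens are split across locations at random; per-clade
#' major-axis lengths are drawn from overlapping normal distributions;
#' orientations alternate dorsal/ventral.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a tibble of specimen records (one row per specimen,
#'   with absolute file paths); also written as `metadata.csv` (relative
#'   paths) in `out_dir`.
#' @export
generate_dataset <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("images", "masks", "keyhole_masks")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  records <- with_seed(config$seed, {
    rows <- vector("list", 2L * config$n_per_clade)
    i <- 0L
    for (clade in c("Northern", "Southern")) {
      ci <- if (clade == "Northern") 1L else 2L
      locs <- sprintf("%s_loc%d", substr(clade, 1, 1), seq_len(config$n_locations_per_clade))
      for (j in seq_len(config$n_per_clade)) {
        i <- i + 1L
        id <- sprintf("%s_%s%04d", config$species_preset, substr(clade, 1, 1), j)
        mm <- rnorm(1, config$size_mean_mm[ci], config$size_sd_mm[ci])
        mm <- max(mm, 0.4 * config$size_mean_mm[ci])
        size_factor <- min(max(mm / config$size_mean_mm[ci], 0.75), 1.25)
        shell <- generate_shell_outline(config, clade, size_factor)
        keyhole <- generate_keyhole_outline(config, clade)
        rend <- render_specimen(shell, keyhole, config, clade)
        ip <- file.path("images", paste0(id, ".png"))
        mp <- file.path("masks", paste0(id, ".png"))
        kp <- file.path("keyhole_masks", paste0(id, ".png"))
        png::writePNG(rend$image, file.path(out_dir, ip))
        png::writePNG(rend$shell_mask, file.path(out_dir, mp))
        png::writePNG(rend$keyhole_mask, file.path(out_dir, kp))
        rows[[i]] <- tibble::tibble(
          specimen_id = id, species = config$species_preset, clade = clade,
          location = sample(locs, 1L),
          orientation = if (j %% 2L == 1L) "dorsal" else "ventral",
          image_path = ip, mask_path = mp, keyhole_mask_path = kp,
          major_axis_mm = round(mm, 3))
      }
    }
    dplyr::bind_rows(rows)
  })
  readr::write_csv(records, file.path(out_dir, "metadata.csv"))
  records$image_path <- file.path(out_dir, records$image_path)
  records$mask_path <- file.path(out_dir, records$mask_path)
  records$keyhole_mask_path <- file.path(out_dir, records$keyhole_mask_path)
  invisible(records)
}

#' Load a generated dataset's metadata
#'
#' @param dir dataset directory containing `metadata.csv`.
#' @return tibble of specimen records with absolute file paths.
#' @export
load_dataset <- function(dir) {
  md <- readr::read_csv(file.path(dir, "metadata.csv"), show_col_types = FALSE)
  for (col in c("image_path", "mask_path", "keyhole_mask_path")) {
    md[[col]] <- file.path(dir, md[[col]])
  }
  md
}
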