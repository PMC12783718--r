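#' Extract a sub-pixel contour from a binary mask
#'
#' Marching-squares iso-contour at level 0.5 with linear interpolation
#' (via [grDevices::contourLines()]) after a light Gaussian pre-smoothing of
#' the binary mask, which removes the half-pixel staircase bias of contouring
#' a hard 0/1 field. The mask must contain exactly one foreground component
#' of at least `min_px` pixels; the largest closed contour is returned,
#' counter-clockwise.
#'
#' @param mask numeric or logical matrix (nonzero = foreground).
#' @param min_px smallest accepted component size in pixels.
#' @param smooth_sigma standard deviation (pixels) of the Gaussian
#'   pre-smoothing; 0 disables it.
#' @return an [as_outline()] polygon in image coordinates (x = column,
#'   y = row).
#' @export
extract_contour <- function(mask, min_px = 9L, smooth_sigma = 0.8) {
  m <- (mask > 0) + 0
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(as.integer(lab))
  big <- which(sizes >= min_px)
  if (length(big) == 0) {
    stop("segmentation error: no foreground component of >= ", min_px,
         " pixels (component sizes: ", paste(sizes, collapse = ", "), ")",
         call. = FALSE)
  }
  if (length(big) > 1) {
    stop("segmentation error: ", length(big), " foreground components of >= ",
         min_px, " pixels (sizes: ", paste(sizes[big], collapse = ", "), ")",
         call. = FALSE)
  }
  m <- (lab == big) + 0
  if (smooth_sigma > 0) m <- gaussian_smooth(m, smooth_sigma)
  # contourLines: z[i, j] is the value at (x[i], y[j]); our matrix is
  # indexed [row, col], so x = rows, y = cols, then swap back.
  cl <- contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)), z = m,
                     levels = 0.5)
  if (length(cl) == 0) stop("segmentation error: no contour at level 0.5", call. = FALSE)
  polys <- lapply(cl, function(ct) cbind(x = ct$y, y = ct$x))
  areas <- vapply(polys, function(p) abs(poly_area(p)), numeric(1))
  as_outline(polys[[which.max(areas)]])
}

# Separable Gaussian smoothing with reflected edges.
gaussian_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_reflect <- function(x, r) {
    n <- nrow(x)
    x[c(pmin(pmax(seq(1 + r, 2, -1), 1), n), 1:n,
        pmin(pmax(seq(n - 1, n - r), 1), n)), , drop = FALSE]
  }
  conv1 <- function(x) {
    xp <- pad_reflect(x, r)
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_along(k)) out <- out + k[i] * xp[i:(i + nrow(x) - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}

#' Normalize an outline to major-axis length 1.0
#'
#' Translates the outline to its area centroid, rotates it so the
#' moment-ellipse major axis is vertical, and uniformly scales it so the
#' fitted major-axis length equals 1.0, preserving aspect ratio exactly.
#' Idempotent up to numerical precision.
#'
#' @param outline an [as_outline()] polygon.
#' @return the normalized outline.
#' @export
normalize_outline <- function(outline) {
  fit <- ellipse_fit(outline)
  p <- cbind(outline[, 1] - fit$center[1], outline[, 2] - fit$center[2])
  # smallest rotation that makes the major axis vertical: stable (and hence
  # idempotent) when the axis is already near-vertical, where the fitted
  # angle's sign is arbitrary
  theta <- (pi / 2 - fit$angle) %% pi
  if (theta > pi / 2) theta <- theta - pi
  p <- rotate_points(p, theta)
  as_outline(p / fit$major_length)
}

#' The five shape descriptors of a region outline
#'
#' Computed on the sub-pixel polygon (not pixel counts): circularity
#' `4 pi A / P^2`, eccentricity `sqrt(a^2 - b^2) / a` from the moment-based
#' ellipse fit (the foci distance over the major-axis length), solidity
#' `A / A_hull` via the convex hull of the vertices, extent `A / A_bbox`
#' with the bounding box taken after normalization (object-aligned), and
#' `minor_axis_length = b / a` (the fitted minor axis after scaling the
#' major axis to 1.0). `raw_area` and `raw_perimeter` refer to the input
#' outline before normalization.
#'
#' @param outline an [as_outline()] polygon.
#' @param normalize normalize first via [normalize_outline()] (the
#'   descriptors assume it; set `FALSE` only if already normalized).
#' @return one-row tibble: circularity, eccentricity, solidity, extent,
#'   minor_axis_length, raw_area, raw_perimeter.
#' @export
compute_shape_metrics <- function(outline, normalize = TRUE) {
  raw_area <- abs(poly_area(outline))
  raw_perimeter <- poly_perimeter(outline)
  if (raw_area < 1e-12) stop("degenerate outline: zero area", call. = FALSE)
  o <- if (normalize) normalize_outline(outline) else outline
  a_ <- abs(poly_area(o))
  p_ <- poly_perimeter(o)
  hull <- o[chull(o[, 1], o[, 2]), , drop = FALSE]
  fit <- ellipse_fit(o)
  bbox <- (max(o[, 1]) - min(o[, 1])) * (max(o[, 2]) - min(o[, 2]))
  tibble::tibble(
    circularity = 4 * pi * a_ / p_^2,
    eccentricity = sqrt(max(0, fit$a^2 - fit$b^2)) / fit$a,
    solidity = a_ / abs(poly_area(hull)),
    extent = a_ / bbox,
    minor_axis_length = fit$minor_length / fit$major_length,
    raw_area = raw_area,
    raw_perimeter = raw_perimeter)
}

#' Shape metrics for every specimen in a dataset
#'
#' Runs mask -> sub-pixel contour -> normalization -> descriptors for the
#' chosen region of each record.
#'
#' @param records specimen records tibble.
#' @param region `"keyhole"` or `"shell"` (selects the mask column).
#' @return tibble: specimen_id, clade, location, region, the five
#'   descriptors, raw_area, raw_perimeter.
#' @export
metrics_for_dataset <- function(records, region = c("keyhole", "shell")) {
  region <- match.arg(region)
  col <- if (region == "keyhole") "keyhole_mask_path" else "mask_path"
  rows <- lapply(seq_len(nrow(records)), function(i) {
    mask <- png::readPNG(records[[col]][i])
    met <- compute_shape_metrics(extract_contour(mask))
    dplyr::bind_cols(tibble::tibble(specimen_id = records$specimen_id[i],
                                    clade = records$clade[i],
                                    location = records$location[i],
                                    region = region), met)
  })
  dplyr::bind_rows(rows)
}

#' Contours for every specimen in a dataset
#'
#' @inheritParams metrics_for_dataset
#' @param normalize normalize each contour to major-axis length 1.0.
#' @return named list of outlines (by specimen id).
#' @export
contours_for_dataset <- function(records, region = c("keyhole", "shell"),
                                 normalize = TRUE) {
  region <- match.arg(region)
  col <- if (region == "keyhole") "keyhole_mask_path" else "mask_path"
  out <- lapply(seq_len(nrow(records)), function(i) {
    ct <- extract_contour(png::readPNG(records[[col]][i]))
    if (normalize) normalize_outline(ct) else ct
  })
  names(out) <- records$specimen_id
  out
}
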