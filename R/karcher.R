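#' Resample an outline to k points uniform in arc length
#'
#' Points are spaced uniformly along the closed boundary, starting at the
#' topmost vertex (maximum y), preserving counter-clockwise order. This
#' establishes point-wise correspondence for shape averaging.
#'
#' @param outline an [as_outline()] polygon.
#' @param k number of points (>= 16).
#' @return a k x 2 outline.
#' @export
resample_outline <- function(outline, k = 200L) {
  stopifnot(k >= 16)
  n <- nrow(outline)
  start <- which.max(outline[, 2])
  p <- outline[c(start:n, seq_len(start - 1L)), , drop = FALSE]
  pc <- rbind(p, p[1, ])
  seg <- sqrt(diff(pc[, 1])^2 + diff(pc[, 2])^2)
  cs <- c(0, cumsum(seg))
  L <- cs[n + 1]
  s <- L * (seq_len(k) - 1) / k
  j <- findInterval(s, cs, rightmost.closed = TRUE)
  t <- (s - cs[j]) / pmax(seg[j], 1e-300)
  as_outline(cbind(pc[j, 1] + t * (pc[j + 1, 1] - pc[j, 1]),
                   pc[j, 2] + t * (pc[j + 1, 2] - pc[j, 2])))
}

# Optimal rigid alignment (rotation + cyclic start-index roll, no reflection,
# no scaling) of outline z onto reference w, both centered k x 2 matrices.
# Works in the complex plane: the cross-correlation over all rolls is done
# with one FFT; the best roll maximizes |C_s| and the rotation is -Arg(C_s).
align_one <- function(z, w) {
  k <- nrow(z)
  zc <- complex(real = z[, 1], imaginary = z[, 2])
  wc <- complex(real = w[, 1], imaginary = w[, 2])
  zc <- zc - mean(zc); wc <- wc - mean(wc)
  cs <- fft(fft(zc) * Conj(fft(wc)), inverse = TRUE) / k
  s <- which.max(Mod(cs))
  theta <- -Arg(cs[s])
  rolled <- if (s == 1) zc else c(zc[s:k], zc[seq_len(s - 1L)])
  al <- rolled * exp(1i * theta)
  resid <- sum(Mod(al - wc)^2)
  list(points = cbind(x = Re(al), y = Im(al)), residual = resid,
       roll = s - 1L, angle = theta)
}

#' Align a set of outlines to a reference
#'
#' Each outline is translated to its centroid, cyclically rolled and rotated
#' (least-squares, reflection excluded, scale untouched) to best match the
#' reference.
#'
#' @param outlines list of k x 2 outlines (equal k).
#' @param reference k x 2 reference outline.
#' @return list with `aligned` (list of outlines) and `residuals` (summed
#'   squared distances to the reference).
#' @export
align_set <- function(outlines, reference) {
  ks <- vapply(outlines, nrow, integer(1))
  if (length(unique(c(ks, nrow(reference)))) != 1) {
    stop("all outlines must be resampled to the same number of points",
         call. = FALSE)
  }
  res <- lapply(outlines, align_one, w = reference)
  list(aligned = lapply(res, `[[`, "points"),
       residuals = vapply(res, `[[`, numeric(1), "residual"))
}

#' Karcher-mean outline of a set of shapes
#'
#' The average shape: iteratively aligns all outlines to the current mean,
#' replaces the mean by the point-wise average, and renormalizes it to
#' major-axis length 1.0, until the mean displacement falls below `tol`.
#' The objective (mean squared alignment residual per point) is recorded
#' per iteration and is non-increasing.
#'
#' @param outlines list of normalized outlines (equal point count; use
#'   [normalize_outline()] then [resample_outline()]).
#' @param tol convergence tolerance on the mean point displacement.
#' @param max_iter iteration cap (a warning flag is set if reached).
#' @return a `mean_shape_report`: `mean_outline`, `n_shapes`,
#'   `convergence_iterations`, `final_objective`, `objective_trace`,
#'   `converged`, plus the six landmarks and widths of [landmark_widths()].
#' @export
karcher_mean <- function(outlines, tol = 1e-6, max_iter = 100L) {
  stopifnot(length(outlines) >= 2)
  k <- nrow(outlines[[1]])
  mean_o <- outlines[[1]]
  trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    al <- align_set(outlines, mean_o)
    trace <- c(trace, mean(al$residuals) / k)
    # alignment minimizes the objective over poses given the mean; the
    # point-wise average minimizes it over the mean given the poses, so the
    # recorded objective is non-increasing. The mean is renormalized to
    # major-axis length 1.0 once, after convergence (the inputs are already
    # normalized, so the iterates stay at that scale up to averaging).
    new_mean <- as_outline(Reduce(`+`, al$aligned) / length(al$aligned))
    disp <- sqrt(mean((new_mean - mean_o)^2))
    mean_o <- new_mean
    if (disp < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("karcher_mean: no convergence within ", max_iter, " iterations")
  }
  mean_o <- normalize_outline(mean_o)
  lw <- landmark_widths(mean_o)
  structure(c(list(mean_outline = mean_o, n_shapes = length(outlines),
                   convergence_iterations = iters,
                   final_objective = tail(trace, 1),
                   objective_trace = trace, converged = converged), lw),
            class = "mean_shape_report")
}

#' Six landmarks and widths at the height quartiles
#'
#' For a normalized outline (major axis vertical), takes the maximum height
#' H (the vertical extent), intersects horizontal lines at 25\%, 50\% and
#' 75\% of H (measured from the bottom) with the outline, and keeps the
#' leftmost and rightmost intersection at each level as the landmark pair.
#' The width at each level is the distance between its pair;
#' `minor_axis_width` is the fitted ellipse minor axis.
#'
#' @param outline a normalized outline.
#' @return list: `landmarks` (6 x 2 matrix: left/right at 25/50/75),
#'   `width_25`, `width_50`, `width_75`, `minor_axis_width`,
#'   `multiplicity` (intersection count per level, > 2 logged when the
#'   outline is non-convex at that height).
#' @export
landmark_widths <- function(outline) {
  ylim <- range(outline[, 2])
  H <- diff(ylim)
  if (H <= 0) stop("degenerate outline: zero height", call. = FALSE)
  levels <- ylim[1] + c(0.25, 0.5, 0.75) * H
  x <- outline[, 1]; y <- outline[, 2]
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  lm <- matrix(NA_real_, 6, 2,
               dimnames = list(c("left_25", "right_25", "left_50", "right_50",
                                 "left_75", "right_75"), c("x", "y")))
  widths <- numeric(3)
  mult <- integer(3)
  for (i in seq_along(levels)) {
    yl <- levels[i]
    hit <- (y <= yl & y2 > yl) | (y2 <= yl & y > yl)
    t <- (yl - y[hit]) / (y2[hit] - y[hit])
    xs <- x[hit] + t * (x2[hit] - x[hit])
    if (length(xs) < 2) stop("landmark level without two intersections", call. = FALSE)
    mult[i] <- length(xs)
    lm[2 * i - 1, ] <- c(min(xs), yl)
    lm[2 * i, ] <- c(max(xs), yl)
    widths[i] <- max(xs) - min(xs)
  }
  fit <- ellipse_fit(outline)
  list(landmarks = lm, width_25 = widths[1], width_50 = widths[2],
       width_75 = widths[3],
       minor_axis_width = fit$minor_length / fit$major_length,
       multiplicity = mult)
}

#' Clade contrast between two mean-shape reports
#'
#' `pct_minor_axis_narrower` = 100 (minor_S - minor_N) / minor_S (the wider,
#' Southern, form is the reference), and the quartile-over-central width
#' ratio `mean(width_25, width_75) / width_50` per clade.
#'
#' @param report_N,report_S `mean_shape_report`s for the Northern and
#'   Southern clades (normalized outlines).
#' @return list: `pct_minor_axis_narrower`,
#'   `quartile_over_central_ratio_N`, `quartile_over_central_ratio_S`.
#' @export
clade_contrast <- function(report_N, report_S) {
  if (report_S$minor_axis_width <= 0 || report_N$width_50 <= 0 ||
      report_S$width_50 <= 0) {
    stop("geometry error: zero widths in mean shape", call. = FALSE)
  }
  list(pct_minor_axis_narrower =
         100 * (report_S$minor_axis_width - report_N$minor_axis_width) /
         report_S$minor_axis_width,
       quartile_over_central_ratio_N =
         mean(c(report_N$width_25, report_N$width_75)) / report_N$width_50,
       quartile_over_central_ratio_S =
         mean(c(report_S$width_25, report_S$width_75)) / report_S$width_50)
}

#' Karcher means and clade contrast for a dataset region
#'
#' Convenience pipeline: masks -> sub-pixel contours -> normalization ->
#' arc-length resampling -> per-clade Karcher mean -> landmark widths ->
#' clade contrast.
#'
#' @param records specimen records.
#' @param region `"keyhole"` or `"shell"`.
#' @param k resampled points per outline.
#' @param tol,max_iter passed to [karcher_mean()].
#' @return list: `report_N`, `report_S`, `contrast`.
#' @export
karcher_contrast <- function(records, region = "keyhole", k = 200L,
                             tol = 1e-6, max_iter = 100L) {
  cts <- contours_for_dataset(records, region, normalize = TRUE)
  cts <- lapply(cts, resample_outline, k = k)
  rep_n <- karcher_mean(cts[records$clade == "Northern"], tol, max_iter)
  rep_s <- karcher_mean(cts[records$clade == "Southern"], tol, max_iter)
  list(report_N = rep_n, report_S = rep_s,
       contrast = clade_contrast(rep_n, rep_s))
}
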