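#' SmoothGrad saliency configuration
#'
#' Defaults follow the ranges recommended by the original SmoothGrad work:
#' 25 noisy samples with noise standard deviation 15\% of the input
#' intensity range, averaging absolute input gradients.
#'
#' @param n_samples number of noisy copies averaged.
#' @param noise_sd Gaussian noise sd as a fraction of the intensity range.
#' @param normalization `"unit_max"` (rescale so the maximum is 1) or
#'   `"raw"`.
#' @return a `saliency_config` list.
#' @export
saliency_config <- function(n_samples = 25L, noise_sd = 0.15,
                            normalization = c("unit_max", "raw")) {
  stopifnot(n_samples >= 1, noise_sd >= 0)
  cfg <- list(n_samples = as.integer(n_samples), noise_sd = noise_sd,
              normalization = match.arg(normalization))
  class(cfg) <- "saliency_config"
  cfg
}

#' SmoothGrad saliency map for one image
#'
#' Averages the absolute input-gradient magnitude of the target-class logit
#' over `n_samples` Gaussian-noise-perturbed copies of the image, then
#' normalizes to unit maximum (skipped for an all-zero map). With
#' `n_samples = 1` and `noise_sd = 0` this is the vanilla gradient map.
#'
#' @param model a trained `cnn_model` (or any object supported by
#'   [input_gradient()]).
#' @param image numeric image matrix in `[0, 1]`.
#' @param target_class class label/index; `NULL` uses the model's predicted
#'   class for the clean image.
#' @param config a [saliency_config()].
#' @param seed optional integer seed for the noise draws.
#' @return a `saliency_map` list: `values` (matrix, same size as the model
#'   input), `target_class`, `normalization`.
#' @export
smoothgrad_map <- function(model, image, target_class = NULL,
                           config = saliency_config(), seed = NULL) {
  x <- as.numeric(image)
  X1 <- matrix(x, length(x), 1)
  if (is.null(target_class)) {
    target_class <- predict_classes(model, X1)[1]
  }
  side <- model$config$input_size
  with_seed(seed, {
    rng <- diff(range(x))
    sdv <- config$noise_sd * if (rng > 0) rng else 1
    Xn <- matrix(rep(x, config$n_samples), length(x), config$n_samples)
    if (sdv > 0) Xn <- Xn + matrix(rnorm(length(Xn), 0, sdv), nrow(Xn))
    g <- input_gradient(model, Xn, target_class)
    vals <- matrix(rowMeans(abs(g)), side, side)
    if (config$normalization == "unit_max" && max(vals) > 0) {
      vals <- vals / max(vals)
    }
    structure(list(values = vals, target_class = target_class,
                   normalization = config$normalization),
              class = "saliency_map")
  })
}

#' Aggregate saliency maps by pixel-wise mean
#'
#' @param maps list of `saliency_map` objects sharing dimensions.
#' @return a `saliency_map` with the unit-max-renormalized mean values.
#' @export
aggregate_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  dims <- dim(maps[[1]]$values)
  vals <- Reduce(`+`, lapply(maps, function(m) {
    if (!identical(dim(m$values), dims)) {
      stop("saliency maps have mismatched dimensions", call. = FALSE)
    }
    m$values
  })) / length(maps)
  if (max(vals) > 0) vals <- vals / max(vals)
  structure(list(values = vals, target_class = NA_character_,
                 normalization = "unit_max"),
            class = "saliency_map")
}

#' Fraction of saliency mass inside a region, and attention enrichment
#'
#' `region_fraction` is the sum of saliency inside the region divided by the
#' total sum; `area_fraction` is the region's share of pixels; their ratio
#' is the attention `enrichment` (1 = no preference; > 1 = the model looks
#' at the region more than its size alone explains).
#'
#' @param map a `saliency_map` (or numeric matrix).
#' @param region_mask matrix of the same dimensions, nonzero inside the
#'   region. Rescaled by nearest neighbour if its size differs from the map
#'   (e.g. masks rendered at full resolution, model input downscaled).
#' @return list with `region_fraction`, `area_fraction`, `enrichment`.
#' @export
region_fraction <- function(map, region_mask) {
  vals <- if (inherits(map, "saliency_map")) map$values else map
  if (!identical(dim(vals), dim(region_mask))) {
    region_mask <- resize_nearest(region_mask, nrow(vals), ncol(vals))
  }
  tot <- sum(vals)
  if (tot <= 0) stop("all-zero saliency map: region fraction undefined", call. = FALSE)
  inside <- region_mask > 0
  list(region_fraction = sum(vals[inside]) / tot,
       area_fraction = mean(inside),
       enrichment = (sum(vals[inside]) / tot) / mean(inside))
}

resize_nearest <- function(m, out_h, out_w) {
  r <- round((seq_len(out_h) - 0.5) * nrow(m) / out_h + 0.5)
  c <- round((seq_len(out_w) - 0.5) * ncol(m) / out_w + 0.5)
  m[pmin(pmax(r, 1), nrow(m)), pmin(pmax(c, 1), ncol(m)), drop = FALSE]
}

#' Keyhole attention enrichment across a set of specimens
#'
#' Convenience wrapper: SmoothGrad map per specimen (predicted class),
#' enrichment of saliency inside the given region mask.
#'
#' @param model trained model.
#' @param records specimen records for the specimens to score.
#' @param images pixels x n image matrix.
#' @param masks pixels x n region-mask matrix (same specimen ids).
#' @param config a [saliency_config()].
#' @param seed integer seed.
#' @return tibble: specimen_id, target_class, region_fraction,
#'   area_fraction, enrichment.
#' @export
attention_enrichment <- function(model, records, images, masks,
                                 config = saliency_config(), seed = 1L) {
  side_m <- as.integer(round(sqrt(nrow(masks))))
  rows <- lapply(seq_len(nrow(records)), function(i) {
    id <- records$specimen_id[i]
    side_i <- as.integer(round(sqrt(nrow(images))))
    img <- matrix(images[, id], side_i, side_i)
    sm <- smoothgrad_map(model, img, config = config, seed = seed + i)
    rf <- region_fraction(sm, matrix(masks[, id], side_m, side_m))
    tibble::tibble(specimen_id = id, target_class = sm$target_class,
                   region_fraction = rf$region_fraction,
                   area_fraction = rf$area_fraction,
                   enrichment = rf$enrichment)
  })
  dplyr::bind_rows(rows)
}
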