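#' Resampling protocol configuration
#'
#' Defaults are set at full survey scale: 120 training and 30
#' validation images per class, a class-balanced Even-test of 20 per class,
#' a cap of 100 specimens per sampling location (surplus routed to the test
#' pool), and 100 seeded iterations. Training/validation images are
#' augmented by rotation, flips and scaling; test images never are.
#'
#' @param n_train_per_class,n_val_per_class,n_even_test_per_class per-class
#'   counts for training, validation and the class-balanced Even-test.
#' @param location_cap maximum specimens per location admitted to the
#'   training/validation pool.
#' @param n_iterations number of resampling iterations.
#' @param base_seed iteration `i` uses seed `base_seed + i`.
#' @param rotation_degrees augmentation rotation range (degrees).
#' @param flip_horizontal,flip_vertical allow the respective flip (applied
#'   with probability 0.5 each).
#' @param scale_range augmentation scale range.
#' @return a `protocol_config` list.
#' @export
protocol_config <- function(n_train_per_class = 120L, n_val_per_class = 30L,
                            n_even_test_per_class = 20L, location_cap = 100L,
                            n_iterations = 100L, base_seed = 0L,
                            rotation_degrees = c(-30, 30),
                            flip_horizontal = TRUE, flip_vertical = TRUE,
                            scale_range = c(0.9, 1.1)) {
  cfg <- list(n_train_per_class = as.integer(n_train_per_class),
              n_val_per_class = as.integer(n_val_per_class),
              n_even_test_per_class = as.integer(n_even_test_per_class),
              location_cap = as.integer(location_cap),
              n_iterations = as.integer(n_iterations),
              base_seed = as.integer(base_seed),
              augmentation = list(rotation_degrees = rotation_degrees,
                                  flip_horizontal = flip_horizontal,
                                  flip_vertical = flip_vertical,
                                  scale_range = scale_range))
  stopifnot(cfg$n_train_per_class > 0, cfg$n_val_per_class > 0,
            cfg$n_even_test_per_class > 0, cfg$location_cap >= 1,
            cfg$n_iterations >= 1)
  class(cfg) <- "protocol_config"
  cfg
}

#' Cap the number of specimens per location
#'
#' Locations with more than `cap` specimens have exactly `cap` randomly
#' retained for the training/validation pool; the surplus is routed to the
#' test pool. Locations at or under the cap pass through unchanged.
#'
#' @param records tibble of specimen records with a `location` column.
#' @param cap maximum specimens per location.
#' @param seed optional integer seed.
#' @return list with `kept` and `overflow` tibbles (disjoint; their union is
#'   the input).
#' @export
cap_locations <- function(records, cap, seed = NULL) {
  stopifnot(cap >= 1)
  if (nrow(records) == 0) {
    return(list(kept = records, overflow = records[0, ]))
  }
  with_seed(seed, {
    keep_flag <- rep(TRUE, nrow(records))
    for (loc in unique(records$location)) {
      idx <- which(records$location == loc)
      if (length(idx) > cap) {
        keep_flag[idx[!idx %in% sample(idx, cap)]] <- FALSE
      }
    }
    list(kept = records[keep_flag, ], overflow = records[!keep_flag, ])
  })
}

#' Build one iteration's split plan
#'
#' Applies the location cap, then assigns per class: `n_train_per_class` to
#' training, `n_val_per_class` to validation, and the remainder (plus all
#' location overflow) to the Full-test pool; the Even-test is an equal
#' per-class draw from the Full-test pool. The split is a pure function of
#' `(records, config, iteration_id, label_col)` through the seed
#' `base_seed + iteration_id`.
#'
#' @param records tibble of specimen records.
#' @param config a [protocol_config()].
#' @param iteration_id integer iteration number.
#' @param label_col column of `records` holding the class label
#'   (default `"clade"`; use the mixed-group label column for control runs).
#' @return a `split_plan` list: `train_ids`, `val_ids`, `even_test_ids`,
#'   `full_test_ids`, `label_map` (named character vector), `seed`,
#'   `iteration_id`, `mixed`.
#' @export
make_split <- function(records, config, iteration_id = 1L, label_col = "clade") {
  seed <- config$base_seed + as.integer(iteration_id)
  labels <- records[[label_col]]
  classes <- sort(unique(labels))
  with_seed(seed, {
    capped <- cap_locations(records, config$location_cap)
    pool <- capped$kept
    train_ids <- character(0); val_ids <- character(0); test_ids <- capped$overflow$specimen_id
    for (cl in classes) {
      ids <- pool$specimen_id[pool[[label_col]] == cl]
      need <- config$n_train_per_class + config$n_val_per_class
      if (length(ids) < need) {
        stop(sprintf("insufficient pool for class '%s': need %d, have %d",
                     cl, need, length(ids)), call. = FALSE)
      }
      picked <- sample(ids, need)
      train_ids <- c(train_ids, picked[seq_len(config$n_train_per_class)])
      val_ids <- c(val_ids, picked[-seq_len(config$n_train_per_class)])
      test_ids <- c(test_ids, setdiff(ids, picked))
    }
    even_ids <- character(0)
    test_labels <- labels[match(test_ids, records$specimen_id)]
    for (cl in classes) {
      ids <- test_ids[test_labels == cl]
      if (length(ids) < config$n_even_test_per_class) {
        stop(sprintf("insufficient test pool for class '%s': need %d, have %d",
                     cl, config$n_even_test_per_class, length(ids)), call. = FALSE)
      }
      even_ids <- c(even_ids, sample(ids, config$n_even_test_per_class))
    }
    # the four id lists are kept pairwise disjoint: the Even-test draw is
    # removed from the Full-test list and reported separately
    plan <- list(iteration_id = as.integer(iteration_id), seed = seed,
                 train_ids = train_ids, val_ids = val_ids,
                 even_test_ids = even_ids,
                 full_test_ids = setdiff(test_ids, even_ids),
                 label_map = setNames(labels, records$specimen_id),
                 classes = classes, mixed = label_col != "clade")
    class(plan) <- "split_plan"
    plan
  })
}

#' Relabel the pool into balanced mixed groups
#'
#' Replaces the two clade labels with two synthetic classes, each containing
#' equal numbers of true-Northern and true-Southern specimens, so that any
#' clade-specific signal is removed and a classifier should perform at
#' chance. True labels are retained in the `clade` column for audit.
#'
#' @param records tibble of specimen records with a `clade` column.
#' @param seed optional integer seed for the random mixing.
#' @return the records with an added `mixed_class` column (`"mixA"` /
#'   `"mixB"`); if a clade has an odd count, one of its specimens is dropped
#'   at random (with a message).
#' @export
make_mixed_groups <- function(records, seed = NULL) {
  with_seed(seed, {
    out <- records
    out$mixed_class <- NA_character_
    drop_ids <- character(0)
    for (cl in c("Northern", "Southern")) {
      ids <- out$specimen_id[out$clade == cl]
      if (length(ids) %% 2L == 1L) {
        dropped <- sample(ids, 1L)
        drop_ids <- c(drop_ids, dropped)
        ids <- setdiff(ids, dropped)
        message("make_mixed_groups: dropped one '", cl,
                "' specimen to balance parity")
      }
      half <- sample(ids, length(ids) / 2L)
      out$mixed_class[out$specimen_id %in% half] <- "mixA"
      out$mixed_class[out$specimen_id %in% setdiff(ids, half)] <- "mixB"
    }
    out[!out$specimen_id %in% drop_ids, ]
  })
}

#' Serialize a split plan to JSON
#'
#' @param plan a `split_plan`.
#' @param path file to write.
#' @return the path, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(
    list(iteration_id = plan$iteration_id, seed = plan$seed, mixed = plan$mixed,
         classes = plan$classes, train_ids = plan$train_ids,
         val_ids = plan$val_ids, even_test_ids = plan$even_test_ids,
         full_test_ids = plan$full_test_ids),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Augment an image by seeded rotation, flips and scaling
#'
#' A single bilinear affine resampling about the image center combining a
#' rotation drawn uniformly from the configured degree range, a scale drawn
#' from the scale range, and optional horizontal/vertical flips (probability
#' 0.5 each when enabled). Output dimensions equal input dimensions; pixels
#' mapped from outside the frame are filled with background (0). Degenerate
#' ranges with no flips reproduce the input exactly.
#'
#' @param image numeric matrix.
#' @param aug augmentation settings (the `augmentation` element of a
#'   [protocol_config()]).
#' @param seed optional integer seed.
#' @return augmented image matrix, same dimensions.
#' @export
augment_image <- function(image, aug, seed = NULL) {
  with_seed(seed, {
    ang <- runif(1, aug$rotation_degrees[1], aug$rotation_degrees[2]) * pi / 180
    sc <- runif(1, aug$scale_range[1], aug$scale_range[2])
    fh <- isTRUE(aug$flip_horizontal) && runif(1) < 0.5
    fv <- isTRUE(aug$flip_vertical) && runif(1) < 0.5
    affine_resample(image, angle = ang, scale = sc,
                    flip_h = fh, flip_v = fv)
  })
}

# Inverse-mapped bilinear affine resampling about the image center.
affine_resample <- function(image, angle = 0, scale = 1,
                            flip_h = FALSE, flip_v = FALSE) {
  h <- nrow(image); w <- ncol(image)
  if (angle == 0 && scale == 1 && !flip_h && !flip_v) return(image)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  dy <- g$r - cy; dx <- g$c - cx
  if (flip_h) dx <- -dx
  if (flip_v) dy <- -dy
  # inverse map: rotate by -angle, divide by scale
  ct <- cos(-angle); st <- sin(-angle)
  sx <- (ct * dx - st * dy) / scale + cx
  sy <- (st * dx + ct * dy) / scale + cy
  bilinear_sample(image, sx, sy, dim_out = c(h, w))
}

bilinear_sample <- function(image, sx, sy, dim_out) {
  h <- nrow(image); w <- ncol(image)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  val <- numeric(length(sx))
  px <- function(yy, xx) {
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    v <- numeric(length(yy))
    v[ok] <- image[cbind(yy[ok], xx[ok])]
    v
  }
  val <- px(y0, x0) * (1 - fx) * (1 - fy) + px(y0, x0 + 1) * fx * (1 - fy) +
    px(y0 + 1, x0) * (1 - fx) * fy + px(y0 + 1, x0 + 1) * fx * fy
  matrix(val, dim_out[1], dim_out[2])
}

# Bilinear resize to out_h x out_w (used for model-input resizing and
# region crops). Maps pixel centers proportionally.
resize_bilinear <- function(image, out_h, out_w) {
  h <- nrow(image); w <- ncol(image)
  if (h == out_h && w == out_w) return(image)
  ry <- h / out_h; rx <- w / out_w
  g <- expand.grid(r = seq_len(out_h), c = seq_len(out_w))
  sy <- (g$r - 0.5) * ry + 0.5
  sx <- (g$c - 0.5) * rx + 0.5
  bilinear_sample(image, sx, sy, dim_out = c(out_h, out_w))
}
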