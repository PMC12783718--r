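#' Model configuration for the small convolutional classifier
#'
#' A compact, fully seeded CNN trained from scratch: `length(conv_channels)`
#' blocks of 3x3 same-padding convolution + ReLU + 2x2 max pooling, then a
#' dense ReLU layer and a 2-way softmax output, optimized by Adam with
#' early stopping on validation loss. The model object exposes class scores
#' and input gradients, which the SmoothGrad saliency module requires. A
#' different backbone can be plugged in via `backbone` provided it honours
#' the same score/gradient interface.
#'
#' @param backbone `"small_cnn"` (built in) or a function
#'   `function(model_config)` returning a compatible model object.
#' @param conv_channels integer vector of channels per conv block.
#' @param dense_units units in the dense layer.
#' @param input_size square input side in pixels; images of other sizes are
#'   bilinearly resized.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping (best weights restored).
#' @param augment augment training/validation batches each epoch.
#' @param seed integer seed for initialization, shuffling and augmentation.
#' @return a `model_config` list.
#' @export
model_config <- function(backbone = "small_cnn", conv_channels = c(8L, 16L, 32L),
                         dense_units = 32L, input_size = 64L, epochs = 15L,
                         batch_size = 15L, learning_rate = 2e-3,
                         early_stop_patience = 5L, augment = TRUE, seed = 1L) {
  cfg <- list(backbone = backbone, conv_channels = as.integer(conv_channels),
              dense_units = as.integer(dense_units),
              input_size = as.integer(input_size), epochs = as.integer(epochs),
              batch_size = as.integer(batch_size), learning_rate = learning_rate,
              early_stop_patience = as.integer(early_stop_patience),
              augment = isTRUE(augment), seed = as.integer(seed))
  stopifnot(cfg$epochs >= 1, cfg$batch_size >= 1,
            cfg$input_size %% 2^length(cfg$conv_channels) == 0)
  class(cfg) <- "model_config"
  cfg
}

# He-initialized parameter set. Feature-map layout: h + H*w + H*W*c.
cnn_init <- function(cfg, n_classes = 2L) {
  sz <- cfg$input_size
  chans <- c(1L, cfg$conv_channels)
  conv <- list()
  for (i in seq_along(cfg$conv_channels)) {
    fan_in <- chans[i] * 9
    conv[[i]] <- list(W = matrix(rnorm(chans[i + 1] * fan_in, 0, sqrt(2 / fan_in)),
                                 chans[i + 1], fan_in),
                      b = rep(0, chans[i + 1]))
    sz <- sz %/% 2L
  }
  feat <- sz * sz * tail(chans, 1)
  list(conv = conv,
       d1 = list(W = matrix(rnorm(cfg$dense_units * feat, 0, sqrt(2 / feat)),
                            cfg$dense_units, feat),
                 b = rep(0, cfg$dense_units)),
       d2 = list(W = matrix(rnorm(n_classes * cfg$dense_units, 0,
                                  sqrt(2 / cfg$dense_units)),
                            n_classes, cfg$dense_units),
                 b = rep(0, n_classes)))
}

# Forward pass. X: (input_size^2) x B matrix of grayscale images in [0, 1].
# Returns logits (n_classes x B) and the layer caches for backprop.
cnn_forward <- function(params, cfg, X) {
  H <- cfg$input_size; W <- cfg$input_size
  caches <- list()
  A <- X
  for (i in seq_along(params$conv)) {
    Z <- nn_conv_fwd(A, params$conv[[i]]$W, params$conv[[i]]$b, H, W)
    R <- Z * (Z > 0)
    pl <- nn_pool_fwd(R, H, W)
    caches[[i]] <- list(A_in = A, Z = Z, amax = pl$amax, H = H, W = W)
    A <- pl$Y
    H <- H %/% 2L; W <- W %/% 2L
  }
  Z1 <- params$d1$W %*% A + params$d1$b
  A1 <- Z1 * (Z1 > 0)
  logits <- params$d2$W %*% A1 + params$d2$b
  list(logits = logits, caches = caches, flat = A, Z1 = Z1, A1 = A1)
}

# Backward pass from a gradient on the logits. Returns parameter gradients
# and (optionally) the gradient with respect to the input image.
cnn_backward <- function(params, cfg, fw, dlogits, need_dx = FALSE) {
  grads <- list(conv = vector("list", length(params$conv)), d1 = NULL, d2 = NULL)
  grads$d2 <- list(W = dlogits %*% t(fw$A1), b = rowSums(dlogits))
  dA1 <- t(params$d2$W) %*% dlogits
  dZ1 <- dA1 * (fw$Z1 > 0)
  grads$d1 <- list(W = dZ1 %*% t(fw$flat), b = rowSums(dZ1))
  dA <- t(params$d1$W) %*% dZ1
  for (i in rev(seq_along(params$conv))) {
    cc <- fw$caches[[i]]
    dR <- nn_pool_bwd(dA, cc$amax, nrow(cc$Z))
    dZ <- dR * (cc$Z > 0)
    bw <- nn_conv_bwd(cc$A_in, params$conv[[i]]$W, dZ, cc$H, cc$W,
                      need_dx || i > 1)
    grads$conv[[i]] <- list(W = bw$dW, b = as.numeric(bw$db))
    dA <- bw$dX
  }
  list(grads = grads, dX = dA)
}

softmax_probs <- function(logits) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), "/")
}

# Adam update, flat over the nested parameter list.
adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t); vh <- v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  walk(params, grads, state$m, state$v)
}

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like) else p * 0
}

#' Train the two-class classifier on one split
#'
#' @param split a `split_plan` from [make_split()].
#' @param images numeric matrix of flattened grayscale images (pixels x n)
#'   with specimen ids as column names, as from [load_images()].
#' @param cfg a [model_config()].
#' @param aug augmentation settings (the `augmentation` element of a
#'   [protocol_config()]); `NULL` disables augmentation.
#' @return a `cnn_model` list with the trained parameters, the class-label
#'   ordering, the training history, and the configs used.
#' @export
train_classifier <- function(split, images, cfg, aug = NULL) {
  if (is.function(cfg$backbone)) return(cfg$backbone(cfg, split, images, aug))
  if (length(split$train_ids) == 0) stop("empty training set", call. = FALSE)
  classes <- split$classes
  get_xy <- function(ids) {
    list(X = images[, ids, drop = FALSE],
         y = match(split$label_map[ids], classes))
  }
  tr <- get_xy(split$train_ids); va <- get_xy(split$val_ids)
  side <- sqrt(nrow(images))
  with_seed(cfg$seed + split$seed, {
    params <- cnn_init(cfg, n_classes = length(classes))
    state <- list(m = zero_like(params), v = zero_like(params))
    best <- list(loss = Inf, params = params, epoch = 0L)
    t_step <- 0L
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    do_aug <- cfg$augment && !is.null(aug)
    aug_batch <- function(X) {
      if (!do_aug) return(X)
      for (j in seq_len(ncol(X))) {
        X[, j] <- as.numeric(augment_image(matrix(X[, j], side, side), aug))
      }
      X
    }
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(ncol(tr$X))
      ep_loss <- 0; nb <- 0L
      for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
        X <- aug_batch(tr$X[, idx, drop = FALSE])
        y <- tr$y[idx]
        fw <- cnn_forward(params, cfg, X)
        probs <- softmax_probs(fw$logits)
        loss <- -mean(log(pmax(probs[cbind(y, seq_along(y))], 1e-12)))
        dlogits <- probs
        dlogits[cbind(y, seq_along(y))] <- dlogits[cbind(y, seq_along(y))] - 1
        dlogits <- dlogits / length(y)
        bw <- cnn_backward(params, cfg, fw, dlogits)
        t_step <- t_step + 1L
        upd <- adam_step(params, bw$grads, state, cfg$learning_rate, t_step)
        params <- upd$p; state <- list(m = upd$m, v = upd$v)
        ep_loss <- ep_loss + loss; nb <- nb + 1L
      }
      Xv <- aug_batch(va$X)
      fv <- cnn_forward(params, cfg, Xv)
      pv <- softmax_probs(fv$logits)
      val_loss <- -mean(log(pmax(pv[cbind(va$y, seq_along(va$y))], 1e-12)))
      history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                           val_loss = val_loss))
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
      } else if (epoch - best$epoch >= cfg$early_stop_patience) {
        break
      }
    }
    structure(list(params = best$params, classes = classes, config = cfg,
                   history = history, best_epoch = best$epoch,
                   split_seed = split$seed),
              class = "cnn_model")
  })
}

#' Class-probability scores for images
#'
#' @param model a trained `cnn_model`.
#' @param images pixels x n matrix (columns are flattened grayscale images).
#' @return n x n_classes matrix of softmax probabilities (rows sum to 1),
#'   columns named by class.
#' @export
predict_scores <- function(model, images) {
  images <- conform_images(images, model$config$input_size)
  fw <- cnn_forward(model$params, model$config, images)
  pr <- t(softmax_probs(fw$logits))
  colnames(pr) <- model$classes
  rownames(pr) <- colnames(images)
  pr
}

#' Predicted class labels for images
#'
#' @inheritParams predict_scores
#' @return character vector of class labels.
#' @export
predict_classes <- function(model, images) {
  pr <- predict_scores(model, images)
  model$classes[max.col(pr, ties.method = "first")]
}

#' Gradient of a class logit with respect to the input pixels
#'
#' The raw ingredient of saliency mapping: d logit(target_class) / d pixel,
#' evaluated by backpropagation through the trained network.
#'
#' @param model a trained `cnn_model`.
#' @param images pixels x n matrix.
#' @param target_class class label or index.
#' @return pixels x n matrix of gradients.
#' @export
input_gradient <- function(model, images, target_class) {
  if (is.character(target_class)) {
    target_class <- match(target_class, model$classes)
  }
  images <- conform_images(images, model$config$input_size)
  fw <- cnn_forward(model$params, model$config, images)
  dlogits <- matrix(0, length(model$classes), ncol(images))
  dlogits[target_class, ] <- 1
  cnn_backward(model$params, model$config, fw, dlogits, need_dx = TRUE)$dX
}

# Resize flattened images to the model input side if needed.
conform_images <- function(images, input_size) {
  side <- as.integer(round(sqrt(nrow(images))))
  if (side == input_size) return(images)
  out <- matrix(0, input_size^2, ncol(images),
                dimnames = list(NULL, colnames(images)))
  for (j in seq_len(ncol(images))) {
    out[, j] <- as.numeric(resize_bilinear(matrix(images[, j], side, side),
                                           input_size, input_size))
  }
  out
}

#' Macro-F1 evaluation of a trained model on a test set
#'
#' Per-class precision, recall and F1 (harmonic mean of precision and
#' recall), and their macro average. Zero-division convention: a class with
#' no predicted positives has precision 0, and F1 is 0 whenever
#' precision + recall = 0.
#'
#' @param model a trained `cnn_model`.
#' @param images pixels x n image matrix with specimen-id column names.
#' @param ids test specimen ids.
#' @param label_map named vector mapping specimen id to true class.
#' @param test_kind `"even"` or `"full"` (recorded in the result).
#' @return an `f1_result` list: `per_class` (tibble of precision/recall/f1),
#'   `macro_f1`, `n_test`, `test_kind`.
#' @export
evaluate_f1 <- function(model, images, ids, label_map, test_kind = "even") {
  if (length(ids) == 0) stop("empty test set", call. = FALSE)
  truth <- label_map[ids]
  if (any(is.na(truth)) || !all(truth %in% model$classes)) {
    stop("test ids with missing or unknown labels", call. = FALSE)
  }
  pred <- predict_classes(model, images[, ids, drop = FALSE])
  f1_from_labels(truth, pred, model$classes, test_kind)
}

#' Macro-F1 from true and predicted label vectors
#'
#' The confusion-table computation behind [evaluate_f1()], usable directly
#' on any pair of label vectors.
#'
#' @param truth,pred character vectors of true and predicted class labels.
#' @param classes class ordering for the per-class table.
#' @param test_kind recorded in the result.
#' @return an `f1_result` list (see [evaluate_f1()]).
#' @export
f1_from_labels <- function(truth, pred, classes, test_kind = "even") {
  per <- lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    tibble::tibble(class = cl, precision = precision, recall = recall, f1 = f1)
  })
  per <- dplyr::bind_rows(per)
  structure(list(per_class = per, macro_f1 = mean(per$f1),
                 n_test = length(truth), test_kind = test_kind),
            class = "f1_result")
}

#' Run the full seeded resampling classification experiment
#'
#' For each iteration: build the (clade-based or mixed-group) split, train
#' the classifier, and evaluate macro-F1 on the Even-test and the Full-test
#' pool. Mixed-group runs draw a fresh balanced random relabeling per
#' iteration and rebuild the split from it with identical settings. A failed
#' iteration is recorded and skipped; more than 20\% failures aborts.
#'
#' @param records specimen records (one class column must be `clade`).
#' @param images pixels x n image matrix, specimen ids as column names.
#' @param protocol a [protocol_config()].
#' @param model_cfg a [model_config()].
#' @param mixed logical: run the mixed-group randomized-label control.
#' @param verbose print one line per iteration.
#' @return tibble with one row per iteration x test kind x class, plus
#'   `macro_f1`, `seed`, `mixed` (class `iteration_results`).
#' @export
run_iterations <- function(records, images, protocol, model_cfg, mixed = FALSE,
                           verbose = FALSE) {
  out <- vector("list", protocol$n_iterations)
  failures <- 0L
  for (it in seq_len(protocol$n_iterations)) {
    res <- tryCatch({
      recs <- records
      label_col <- "clade"
      if (mixed) {
        recs <- make_mixed_groups(records, seed = protocol$base_seed + 10000L + it)
        label_col <- "mixed_class"
      }
      split <- make_split(recs, protocol, iteration_id = it, label_col = label_col)
      model <- train_classifier(split, images, model_cfg, aug = protocol$augmentation)
      even <- evaluate_f1(model, images, split$even_test_ids, split$label_map, "even")
      # the Full-test evaluation covers the entire held-out pool, i.e. the
      # stored disjoint full list plus the Even-test draw
      full <- evaluate_f1(model, images,
                          c(split$even_test_ids, split$full_test_ids),
                          split$label_map, "full")
      dplyr::bind_rows(lapply(list(even, full), function(r) {
        dplyr::mutate(r$per_class, macro_f1 = r$macro_f1, n_test = r$n_test,
                      test_kind = r$test_kind)
      })) |>
        dplyr::mutate(iteration = it, seed = split$seed, mixed = mixed,
                      .before = 1)
    }, error = function(e) {
      warning(sprintf("iteration %d failed: %s", it, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) {
      failures <- failures + 1L
      if (failures > 0.2 * protocol$n_iterations) {
        stop("more than 20% of iterations failed; aborting", call. = FALSE)
      }
    } else {
      out[[it]] <- res
      if (verbose) {
        ev <- res$macro_f1[res$test_kind == "even"][1]
        message(sprintf("iteration %d/%d: even macro-F1 %.3f", it,
                        protocol$n_iterations, ev))
      }
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("iteration_results", class(res))
  res
}

#' Crop an image to a mask region with a margin
#'
#' The axis-aligned bounding box of the region, expanded by
#' `margin_fraction` of its size on each side, clipped to the image, and
#' resized to `out_size` (used for the keyhole-crop re-classification
#' experiment).
#'
#' @param image numeric matrix.
#' @param region_mask matrix of the same size, nonzero inside the region.
#' @param margin_fraction fraction of the box size added on each side.
#' @param out_size output side in pixels (`NULL` keeps the cropped size).
#' @return cropped (and resized) image matrix.
#' @export
crop_to_region <- function(image, region_mask, margin_fraction = 0.1,
                           out_size = NULL) {
  idx <- which(region_mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty region mask", call. = FALSE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  mr <- round(margin_fraction * (r1 - r0 + 1))
  mc <- round(margin_fraction * (c1 - c0 + 1))
  r0 <- max(1, r0 - mr); r1 <- min(nrow(image), r1 + mr)
  c0 <- max(1, c0 - mc); c1 <- min(ncol(image), c1 + mc)
  out <- image[r0:r1, c0:c1, drop = FALSE]
  if (!is.null(out_size)) out <- resize_bilinear(out, out_size, out_size)
  out
}

#' Load dataset images as a flattened matrix
#'
#' @param records specimen records tibble.
#' @param path_col which path column to read (`"image_path"`,
#'   `"mask_path"`, or `"keyhole_mask_path"`).
#' @return pixels x n numeric matrix, column names = specimen ids.
#' @export
load_images <- function(records, path_col = "image_path") {
  imgs <- lapply(records[[path_col]], function(p) as.numeric(png::readPNG(p)))
  m <- do.call(cbind, imgs)
  colnames(m) <- records$specimen_id
  m
}
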